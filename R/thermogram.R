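#' mwrisk: breast cancer risk assessment from microwave radiometry and miRNA
#'
#' Tools for scoring bilateral breast thermograms recorded by passive
#' microwave radiometry (MWR, internal temperature) paired with infrared
#' (IR, skin temperature) at ten points per breast plus two body reference
#' points, for building a thermogram feature space and training a low/high
#' risk classifier on synthetic cohorts, and for scoring an eight-marker
#' circulating miRNA oncopanel by direction-aware fold change. The
#' radiometric and molecular results are fused into a single rule-based
#' patient assessment.
#'
#' @keywords internal
"_PACKAGE"

# Breast measurement points are numbered 0-9 on each side; reference points
# T1/T2 sit on the body (not the gland) and are excluded from scoring pools.
POINT_IDS <- 0:9
REF_IDS <- c("T1", "T2")

.point_names <- function() paste0("p", POINT_IDS)

#' Construct a bilateral MWR/IR thermogram
#'
#' One examination holds 44 temperatures: internal (microwave, `mw`) and
#' skin (infrared, `ir`) readings at points 0-9 of each breast, plus the two
#' body reference points T1 and T2 on both channels.
#'
#' @param patient_id Opaque patient identifier.
#' @param t_skin_right,t_skin_left Numeric length-10 vectors, skin (IR)
#'   temperature in degrees Celsius at points 0-9.
#' @param t_int_right,t_int_left Numeric length-10 vectors, internal
#'   (microwave) temperature in degrees Celsius at points 0-9.
#' @param t_skin_ref,t_int_ref Numeric length-2 vectors, reference points
#'   T1 and T2 on the skin and internal channels.
#' @param visit_date Visit date, coerced to `Date` (ISO `"YYYY-MM-DD"`).
#'
#' @return An object of class `thermogram`.
#' @examples
#' tg <- thermogram("demo", rep(31, 10), rep(31, 10),
#'                  rep(34, 10), rep(34, 10))
#' validate_thermogram(tg)$valid
#' @export
thermogram <- function(patient_id,
                       t_skin_right, t_skin_left,
                       t_int_right, t_int_left,
                       t_skin_ref = c(31.0, 31.0),
                       t_int_ref = c(34.0, 34.0),
                       visit_date = Sys.Date()) {
  vec10 <- function(x) {
    x <- as.numeric(x)
    if (length(x) == 10L) names(x) <- .point_names()
    x
  }
  vec2 <- function(x) {
    x <- as.numeric(x)
    if (length(x) == 2L) names(x) <- REF_IDS
    x
  }
  structure(
    list(
      patient_id = as.character(patient_id),
      visit_date = as.Date(visit_date),
      t_skin_right = vec10(t_skin_right),
      t_skin_left = vec10(t_skin_left),
      t_int_right = vec10(t_int_right),
      t_int_left = vec10(t_int_left),
      t_skin_ref = vec2(t_skin_ref),
      t_int_ref = vec2(t_int_ref)
    ),
    class = "thermogram"
  )
}

#' @export
print.thermogram <- function(x, ...) {
  cat(sprintf("<thermogram> patient %s, visit %s\n",
              x$patient_id, format(x$visit_date)))
  fmt <- function(v) paste(sprintf("%.1f", v), collapse = " ")
  cat("  skin  R:", fmt(x$t_skin_right), "\n")
  cat("  skin  L:", fmt(x$t_skin_left), "\n")
  cat("  int   R:", fmt(x$t_int_right), "\n")
  cat("  int   L:", fmt(x$t_int_left), "\n")
  cat("  ref skin (T1,T2):", fmt(x$t_skin_ref),
      " int (T1,T2):", fmt(x$t_int_ref), "\n")
  invisible(x)
}

#' Validate a thermogram before scoring
#'
#' Scoring requires a complete examination: every vector at its full length,
#' no missing values, and every temperature inside a physiological
#' plausibility window. Violations are reported, not thrown, so a batch
#' reader can surface all problems at once.
#'
#' @param tg A [thermogram].
#' @param window Length-2 numeric, allowed temperature range in degrees
#'   Celsius (closed interval).
#' @return A list of class `validation_report` with elements `valid`
#'   (logical) and `violations` (character vector, empty when valid).
#' @export
validate_thermogram <- function(tg, window = c(20.0, 45.0)) {
  stopifnot(inherits(tg, "thermogram"), length(window) == 2L)
  expected <- c(t_skin_right = 10L, t_skin_left = 10L,
                t_int_right = 10L, t_int_left = 10L,
                t_skin_ref = 2L, t_int_ref = 2L)
  violations <- character(0)
  for (field in names(expected)) {
    v <- tg[[field]]
    if (length(v) != expected[[field]]) {
      violations <- c(violations, sprintf(
        "%s: length %d != %d", field, length(v), expected[[field]]))
      next
    }
    bad <- which(!is.finite(v))
    if (length(bad)) {
      violations <- c(violations, sprintf(
        "%s[%s]: missing or non-finite value", field,
        paste(names(v)[bad], collapse = ",")))
    }
    out <- which(is.finite(v) & (v < window[1] | v > window[2]))
    if (length(out)) {
      violations <- c(violations, sprintf(
        "%s[%s]: %.1f degC out of window [%.1f, %.1f]",
        field, names(v)[out], v[out], window[1], window[2]))
    }
  }
  structure(list(valid = length(violations) == 0L, violations = violations),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  if (x$valid) {
    cat("valid thermogram (0 violations)\n")
  } else {
    cat(length(x$violations), "violation(s):\n")
    cat(paste0("  - ", x$violations, collapse = "\n"), "\n")
  }
  invisible(x)
}

.assert_valid_thermogram <- function(tg, window = c(20.0, 45.0)) {
  rep <- validate_thermogram(tg, window)
  if (!rep$valid) {
    stop("invalid thermogram: ", paste(rep$violations, collapse = "; "),
         call. = FALSE)
  }
  invisible(tg)
}

#' Group the 44 temperatures of an examination
#'
#' Partitions a thermogram into the six named groups used throughout
#' scoring: skin (`ir`) and internal (`mw`) temperatures of the right and
#' left breast (10 points each) and of the body reference points (2 each).
#'
#' @param tg A valid [thermogram].
#' @return A list of class `temperature_groups` with elements `t_r_ir`,
#'   `t_l_ir`, `t_a_ir`, `t_r_mw`, `t_l_mw`, `t_a_mw`.
#' @export
group_temperatures <- function(tg) {
  .assert_valid_thermogram(tg)
  structure(
    list(
      t_r_ir = tg$t_skin_right,
      t_l_ir = tg$t_skin_left,
      t_a_ir = tg$t_skin_ref,
      t_r_mw = tg$t_int_right,
      t_l_mw = tg$t_int_left,
      t_a_mw = tg$t_int_ref
    ),
    class = "temperature_groups"
  )
}

#' Rebuild a thermogram from its temperature groups
#'
#' Inverse of [group_temperatures()]; useful for round-trip checks and for
#' constructing exams group-wise.
#'
#' @param groups A `temperature_groups` list.
#' @param patient_id,visit_date Passed to [thermogram()].
#' @return A [thermogram].
#' @export
from_groups <- function(groups, patient_id = "unknown",
                        visit_date = Sys.Date()) {
  stopifnot(inherits(groups, "temperature_groups"))
  thermogram(patient_id,
             t_skin_right = groups$t_r_ir, t_skin_left = groups$t_l_ir,
             t_int_right = groups$t_r_mw, t_int_left = groups$t_l_mw,
             t_skin_ref = groups$t_a_ir, t_int_ref = groups$t_a_mw,
             visit_date = visit_date)
}

.assert_groups <- function(groups) {
  if (!inherits(groups, "temperature_groups")) {
    stop("expected a 'temperature_groups' object; see group_temperatures()",
         call. = FALSE)
  }
  sizes <- c(t_r_ir = 10L, t_l_ir = 10L, t_a_ir = 2L,
             t_r_mw = 10L, t_l_mw = 10L, t_a_mw = 2L)
  for (nm in names(sizes)) {
    v <- groups[[nm]]
    if (length(v) != sizes[[nm]] || !all(is.finite(v))) {
      stop(sprintf("incomplete temperature group '%s'", nm), call. = FALSE)
    }
  }
  invisible(groups)
}
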