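#' Thermogram simulation profile
#'
#' Describes the population a simulated examination is drawn from. The
#' healthy profile is a spatially uniform temperature field with
#' independent Gaussian noise per point: skin spread stays below 2 degC and
#' the breasts are symmetric, so scoring classifies it benign. The
#' high-risk profile superimposes a hot focus on one breast: the internal
#' channel rises by `focus_delta_int` in a small neighborhood of
#' `focus_point`, the skin above it by `focus_delta_int -
#' focus_gradient_reduction` (the locally reduced internal gradient of a
#' near-surface proliferative process). This produces the high-risk
#' signatures scoring looks for: skin spread above 2 degC, a hot area, a
#' reduced gradient over it, and strong left-right asymmetry.
#'
#' Baseline means and noise are population stand-ins chosen to sit in the
#' physiological range (skin around 31.5 degC, internal around 34.5 degC,
#' point-to-point noise 0.25 degC); no raw temperature tables exist to fit
#' them to.
#'
#' @param profile_kind `"healthy"` or `"high_risk"`.
#' @param skin_base,int_base Baseline means, degrees Celsius.
#' @param noise_sd Per-point Gaussian noise, degrees Celsius.
#' @param focus_point Focus center 0-9, or `NA` to draw uniformly per
#'   examination (high-risk only).
#' @param focus_side `"left"`, `"right"`, or `NA` to draw per examination.
#' @param focus_delta_int Internal-channel elevation at the focus, degC.
#' @param focus_gradient_reduction How much less the skin rises than the
#'   internal channel at the focus, degC.
#' @return An object of class `thermogram_profile`.
#' @export
thermogram_profile <- function(profile_kind = c("healthy", "high_risk"),
                               skin_base = 31.5, int_base = 34.5,
                               noise_sd = 0.25,
                               focus_point = NA, focus_side = NA,
                               focus_delta_int = 3.0,
                               focus_gradient_reduction = 1.0) {
  profile_kind <- match.arg(profile_kind)
  if (profile_kind == "high_risk") {
    if (focus_delta_int <= 0) {
      stop("high_risk profile requires focus_delta_int > 0", call. = FALSE)
    }
    if (!is.na(focus_point) && !(focus_point %in% POINT_IDS)) {
      stop("focus_point must be in 0-9 or NA", call. = FALSE)
    }
    if (!is.na(focus_side) && !(focus_side %in% c("left", "right"))) {
      stop("focus_side must be 'left', 'right' or NA", call. = FALSE)
    }
  }
  structure(
    list(profile_kind = profile_kind, skin_base = skin_base,
         int_base = int_base, noise_sd = noise_sd,
         focus_point = focus_point, focus_side = focus_side,
         focus_delta_int = focus_delta_int,
         focus_gradient_reduction = focus_gradient_reduction),
    class = "thermogram_profile"
  )
}

#' Simulate one thermogram
#'
#' Baseline temperatures are i.i.d. normal per channel around the profile
#' means. For a high-risk profile the focus elevation is added over the
#' focus point and its immediate neighbors on the measurement ring (up to
#' 3 points), on the internal channel in full and on the skin channel
#' reduced by `focus_gradient_reduction`. Reproducible: the same seed
#' yields the same examination.
#'
#' @param profile A [thermogram_profile()].
#' @param seed Integer seed; `NULL` continues the current RNG stream.
#' @param patient_id Identifier stamped on the exam.
#' @return A valid [thermogram].
#' @export
generate_thermogram <- function(profile, seed = NULL,
                                patient_id = "synthetic") {
  if (!inherits(profile, "thermogram_profile")) {
    stop("expected a 'thermogram_profile'", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  p <- profile
  draw10 <- function(base) stats::rnorm(10L, base, p$noise_sd)
  draw2 <- function(base) stats::rnorm(2L, base, p$noise_sd)
  t_skin_r <- draw10(p$skin_base)
  t_skin_l <- draw10(p$skin_base)
  t_int_r <- draw10(p$int_base)
  t_int_l <- draw10(p$int_base)
  t_skin_ref <- draw2(p$skin_base)
  t_int_ref <- draw2(p$int_base)
  if (p$profile_kind == "high_risk") {
    fp <- if (is.na(p$focus_point)) sample(POINT_IDS, 1L) else p$focus_point
    fs <- if (is.na(p$focus_side)) {
      sample(c("left", "right"), 1L)
    } else {
      p$focus_side
    }
    nbhd <- intersect((fp - 1L):(fp + 1L), POINT_IDS) + 1L  # 1-based
    d_int <- p$focus_delta_int
    d_skin <- max(0, p$focus_delta_int - p$focus_gradient_reduction)
    if (fs == "left") {
      t_int_l[nbhd] <- t_int_l[nbhd] + d_int
      t_skin_l[nbhd] <- t_skin_l[nbhd] + d_skin
    } else {
      t_int_r[nbhd] <- t_int_r[nbhd] + d_int
      t_skin_r[nbhd] <- t_skin_r[nbhd] + d_skin
    }
  }
  thermogram(patient_id,
             t_skin_right = t_skin_r, t_skin_left = t_skin_l,
             t_int_right = t_int_r, t_int_left = t_int_l,
             t_skin_ref = t_skin_ref, t_int_ref = t_int_ref)
}

#' miRNA panel simulation profile
#'
#' Concentrations are log-normal around per-marker geometric means; the
#' default `norm_means` are the observed normal-range concentrations of
#' the eight panel markers (copies/uL). For a high-risk draw each marker's
#' pathology concentration is displaced by `risk_multipliers` in the
#' marker's risk direction: multiplied for `up_is_risk` markers, divided
#' for `down_is_risk` markers. The default high-risk multipliers are the
#' clinically observed pathology/norm displacement of each marker.
#'
#' @param risk_level `"low"` (all multipliers 1) or `"high"`.
#' @param norm_means Named numeric vector of geometric means, copies/uL,
#'   over [mirna_panel_markers()]'s markers.
#' @param lognormal_sd Dispersion of the log-normal noise (log scale).
#' @param risk_multipliers Named per-marker folds (>= applied in risk
#'   direction); defaults depend on `risk_level`.
#' @return An object of class `panel_profile`.
#' @export
panel_profile <- function(risk_level = c("low", "high"),
                          norm_means = default_norm_means(),
                          lognormal_sd = 0.25,
                          risk_multipliers = NULL) {
  risk_level <- match.arg(risk_level)
  defs <- mirna_panel_markers()
  norm_means <- norm_means[defs$marker]
  if (anyNA(norm_means) || any(norm_means <= 0)) {
    stop("norm_means must cover all eight markers with positive values",
         call. = FALSE)
  }
  if (is.null(risk_multipliers)) {
    risk_multipliers <- if (risk_level == "low") {
      stats::setNames(rep(1, nrow(defs)), defs$marker)
    } else {
      default_risk_multipliers()
    }
  }
  risk_multipliers <- risk_multipliers[defs$marker]
  if (anyNA(risk_multipliers) || any(risk_multipliers <= 0)) {
    stop("risk_multipliers must cover all eight markers with positive values",
         call. = FALSE)
  }
  structure(
    list(risk_level = risk_level, norm_means = norm_means,
         lognormal_sd = lognormal_sd, risk_multipliers = risk_multipliers),
    class = "panel_profile"
  )
}

#' Normal-range geometric means of the panel markers (copies/uL)
#' @return Named numeric vector over the eight markers.
#' @export
default_norm_means <- function() {
  c("miR-155" = 28294, "miR-199a-3p" = 104809, "miR-222-3p" = 159928,
    "let-7a-5p" = 13327568, "miR-196a-2" = 1665957,
    "miR-106a-5p" = 380633, "miR-21-5p" = 22209402, "miR-137" = 555235050)
}

#' Observed pathology displacement of each marker, in its risk direction
#'
#' The fold by which each marker's concentration moves from norm to
#' pathology, expressed along the marker's risk direction (so protective
#' markers that drop five-fold carry a multiplier near 5). Used as the
#' high-risk panel default.
#' @return Named numeric vector over the eight markers.
#' @export
default_risk_multipliers <- function() {
  path <- c("miR-155" = 202238, "miR-199a-3p" = 324654,
            "miR-222-3p" = 88908, "let-7a-5p" = 2665531,
            "miR-196a-2" = 333191, "miR-106a-5p" = 76126,
            "miR-21-5p" = 111047010, "miR-137" = 111047010)
  norm <- default_norm_means()
  defs <- mirna_panel_markers()
  up <- defs$risk_direction == "up_is_risk"
  m <- ifelse(up, path[defs$marker] / norm[defs$marker],
              norm[defs$marker] / path[defs$marker])
  stats::setNames(as.numeric(m), defs$marker)
}

#' Simulate one eight-marker panel measurement
#'
#' @param profile A [panel_profile()].
#' @param seed Integer seed; `NULL` continues the current RNG stream.
#' @return A data.frame with columns `marker`, `norm_conc`, `path_conc`.
#' @export
generate_panel <- function(profile, seed = NULL) {
  if (!inherits(profile, "panel_profile")) {
    stop("expected a 'panel_profile'", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  defs <- mirna_panel_markers()
  sd <- profile$lognormal_sd
  norm_conc <- profile$norm_means * exp(stats::rnorm(nrow(defs), 0, sd))
  mult <- ifelse(defs$risk_direction == "up_is_risk",
                 profile$risk_multipliers,
                 1 / profile$risk_multipliers)
  path_conc <- norm_conc * mult * exp(stats::rnorm(nrow(defs), 0, sd))
  data.frame(marker = defs$marker, norm_conc = as.numeric(norm_conc),
             path_conc = as.numeric(path_conc), stringsAsFactors = FALSE)
}

#' Simulate a labeled low/high risk cohort
#'
#' Draws `n_low` healthy-profile and `n_high` high-risk-profile
#' examinations (default proportions around 8:1 mirror the imbalance of
#' screening cohorts), builds their feature vectors and labels them.
#'
#' @param n_low,n_high Cohort sizes (>= 1).
#' @param seed Integer seed; the whole cohort is reproducible from it.
#' @param healthy,high_risk Optional [thermogram_profile()] overrides.
#' @return A list with `exams` (list of thermograms), `features` (the
#'   feature data.frame of [build_feature_matrix()] plus a `label`
#'   column).
#' @export
generate_cohort <- function(n_low = 500L, n_high = 60L, seed = 1L,
                            healthy = thermogram_profile("healthy"),
                            high_risk = thermogram_profile("high_risk")) {
  stopifnot(n_low >= 1L, n_high >= 1L)
  set.seed(seed)
  exams <- vector("list", n_low + n_high)
  labels <- c(rep("low", n_low), rep("high", n_high))
  for (i in seq_len(n_low)) {
    exams[[i]] <- generate_thermogram(healthy, seed = NULL,
                                      patient_id = sprintf("low-%04d", i))
  }
  for (j in seq_len(n_high)) {
    exams[[n_low + j]] <- generate_thermogram(
      high_risk, seed = NULL, patient_id = sprintf("high-%04d", j))
  }
  features <- build_feature_matrix(exams)
  features$label <- labels
  list(exams = exams, features = features)
}
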