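#' The eight-marker circulating miRNA oncopanel
#'
#' Each marker has a risk direction: `up_is_risk` markers (oncogenic; e.g.
#' miR-21-5p drives proliferation through PI3K/Akt, miR-155 raises oxidative
#' stress) signal risk when their concentration rises above the norm, while
#' `down_is_risk` markers (protective; e.g. let-7a-5p and miR-137 restrain
#' proliferation) signal risk when they fall.
#'
#' @return A data.frame with columns `marker` and `risk_direction`.
#' @export
mirna_panel_markers <- function() {
  data.frame(
    marker = c("miR-155", "miR-199a-3p", "miR-222-3p", "let-7a-5p",
               "miR-196a-2", "miR-106a-5p", "miR-21-5p", "miR-137"),
    risk_direction = c("up_is_risk", "up_is_risk", "up_is_risk",
                       "down_is_risk", "down_is_risk", "down_is_risk",
                       "up_is_risk", "down_is_risk"),
    stringsAsFactors = FALSE
  )
}

#' Canonicalize a miRNA marker name
#'
#' Vendor and literature spellings vary ("Hsa-miR-21-5p", "Has-miR-21-5p",
#' "Micro-196a-2", "microRNA-155"); this strips species/assay prefixes and
#' case so panel rows can be matched to the panel definition. The spelling
#' "miR-196a-3p" occurring in some panel printouts is treated as an alias
#' of miR-199a-3p (the panel carries miR-196a-2 separately and defines no
#' ninth marker).
#'
#' @param name Character vector of marker names.
#' @return Character vector of canonical names; unrecognized names raise an
#'   error naming the offender.
#' @examples
#' normalize_marker(c("Hsa-let-7a-5p", "Micro-196a-2", "Has-miR-21-5p"))
#' @export
normalize_marker <- function(name) {
  x <- tolower(trimws(name))
  x <- sub("^(hsa-|has-)", "", x)
  x <- sub("^micro-rna-", "mir-", x)
  x <- sub("^microrna-", "mir-", x)
  x <- sub("^micro-", "mir-", x)
  x <- sub("^mirna-", "mir-", x)
  x <- sub("^mir-196a-3p$", "mir-199a-3p", x)
  canon <- mirna_panel_markers()$marker
  idx <- match(x, tolower(canon))
  if (anyNA(idx)) {
    stop("unknown miRNA marker(s): ",
         paste(unique(name[is.na(idx)]), collapse = ", "), call. = FALSE)
  }
  canon[idx]
}

#' Round half away from zero
#'
#' Reporting convention for fold changes: `round()` in R rounds half to
#' even, which would turn e.g. 0.25 into 0.2; clinical tables round half
#' up.
#' @noRd
.round_half_up <- function(x, digits = 1L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Fold change of a marker between norm and pathology
#'
#' The pathology-to-norm concentration ratio. The exact ratio is retained
#' internally; the reported value rounds half-up to one decimal, matching
#' clinical reporting.
#'
#' @param norm_conc,path_conc Concentrations in copies/uL; both must be
#'   strictly positive.
#' @return A list with `fold` (exact ratio) and `fold_reported` (1-decimal).
#' @examples
#' fold_change(28294, 202238)$fold_reported  # 7.1
#' @export
fold_change <- function(norm_conc, path_conc) {
  if (!all(is.finite(c(norm_conc, path_conc))) ||
      any(c(norm_conc, path_conc) <= 0)) {
    stop("fold_change: concentrations must be finite and > 0", call. = FALSE)
  }
  fold <- path_conc / norm_conc
  list(fold = fold, fold_reported = .round_half_up(fold, 1L))
}

#' Magnitude of change in a marker's risk-relevant direction
#'
#' Converts a raw fold change into a magnitude >= 1 measured along the
#' marker's risk direction: for `up_is_risk` markers the fold itself (when
#' >= 1), for `down_is_risk` markers the reciprocal of the fold (when
#' <= 1). A change opposite to the risk direction carries no risk and maps
#' to magnitude 1.
#'
#' @param fold Raw fold change (> 0).
#' @param direction `"up_is_risk"` or `"down_is_risk"`.
#' @return Numeric magnitude >= 1.
#' @examples
#' effective_change(0.2, "down_is_risk")  # 5: a 5-fold drop of a protector
#' effective_change(0.6, "up_is_risk")    # 1: opposite to risk direction
#' @export
effective_change <- function(fold,
                             direction = c("up_is_risk", "down_is_risk")) {
  direction <- match.arg(direction)
  stopifnot(is.finite(fold), fold > 0)
  if (direction == "up_is_risk") {
    if (fold >= 1) fold else 1
  } else {
    if (fold <= 1) 1 / fold else 1
  }
}

#' Score a risk-direction magnitude on the 0-3 ordinal scale
#'
#' Changes of 1.5-2 times are a slight increase in risk (score 1), 2-5
#' times a moderate increase (score 2), and 5 times or above a significant
#' increase (score 3); smaller changes score 0. Bands are half-open,
#' boundaries assigned upward: `[1.5, 2) -> 1`, `[2, 5) -> 2`, `[5, Inf)
#' -> 3`.
#'
#' @param magnitude Magnitude >= 1 from [effective_change()].
#' @param bands Ascending cut points of the three risk bands.
#' @return Integer score in 0-3.
#' @export
score_marker <- function(magnitude, bands = c(1.5, 2, 5)) {
  stopifnot(is.finite(magnitude), magnitude > 0, length(bands) == 3L)
  as.integer(findInterval(magnitude, bands))
}

#' Map a categorical expression label to its 0-3 score
#'
#' Accepts the label dialect of clinical panel reports: "Norm", "Slight
#' increase", "Moderate increase", "Pronounced increase", "Significant
#' increase", with or without an attached score suffix (em dash or hyphen,
#' e.g. "Pronounced increase—3").
#'
#' @param label Character vector of labels.
#' @return Integer vector of scores 0-3; unknown labels raise an error.
#' @examples
#' label_to_score(c("Norm", "Slight increase", "Pronounced increase—3"))
#' @export
label_to_score <- function(label) {
  x <- tolower(trimws(label))
  x <- sub("[—–-][0-3]$", "", x)       # strip "...-3" suffixes
  x <- trimws(sub("\\s+increase$", "", x))
  map <- c(norm = 0L, normal = 0L, slight = 1L, moderate = 2L,
           pronounced = 3L, significant = 3L)
  out <- unname(map[x])
  if (anyNA(out)) {
    stop("unknown expression label(s): ",
         paste(unique(label[is.na(out)]), collapse = ", "), call. = FALSE)
  }
  out
}

#' Score a complete eight-marker panel
#'
#' Each marker is scored 0-3 from its concentrations (fold change taken in
#' the marker's risk direction, then banded) or, in the label dialect, from
#' its categorical expression label. Scores are summed into the panel risk
#' factor and the panel is categorized low or high risk.
#'
#' @param panel A data.frame with column `marker` plus either `norm_conc`
#'   and `path_conc` (copies/uL) or `label`. When both are present the
#'   label takes precedence (it is the clinician's call).
#' @param low_high_cutoff Risk-factor sums below this are categorized
#'   `low`, others `high`. Default 5 (observed anchors: a sum of 3 is
#'   typical of low risk, a sum of 7 of high risk).
#' @param bands Passed to [score_marker()].
#' @return An object of class `panel_result` with `scores` (named integer
#'   vector over the eight markers), `risk_sum` and `category`.
#' @examples
#' panel <- data.frame(
#'   marker = mirna_panel_markers()$marker,
#'   label = c("Norm", "Norm", "Slight increase", "Slight increase",
#'             "Norm", "Slight increase", "Norm", "Norm"))
#' panel_risk(panel)  # risk factor 3, low
#' @export
panel_risk <- function(panel, low_high_cutoff = 5, bands = c(1.5, 2, 5)) {
  stopifnot(is.data.frame(panel), "marker" %in% names(panel))
  defs <- mirna_panel_markers()
  marker <- normalize_marker(panel$marker)
  if (anyDuplicated(marker)) {
    stop("duplicate marker(s) in panel: ",
         paste(unique(marker[duplicated(marker)]), collapse = ", "),
         call. = FALSE)
  }
  missing <- setdiff(defs$marker, marker)
  if (length(missing)) {
    stop("panel incomplete; missing marker(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  ord <- match(defs$marker, marker)
  has_label <- "label" %in% names(panel) && !all(is.na(panel$label))
  has_conc <- all(c("norm_conc", "path_conc") %in% names(panel))
  if (!has_label && !has_conc) {
    stop("panel needs either a 'label' column or 'norm_conc'/'path_conc'",
         call. = FALSE)
  }
  scores <- integer(nrow(defs))
  folds <- rep(NA_real_, nrow(defs))
  for (i in seq_len(nrow(defs))) {
    row <- ord[i]
    if (has_label && !is.na(panel$label[row])) {
      scores[i] <- label_to_score(panel$label[row])
      if (has_conc) {
        folds[i] <- fold_change(panel$norm_conc[row],
                                panel$path_conc[row])$fold_reported
      }
    } else {
      fc <- fold_change(panel$norm_conc[row], panel$path_conc[row])
      folds[i] <- fc$fold_reported
      mag <- effective_change(fc$fold, defs$risk_direction[i])
      scores[i] <- score_marker(mag, bands)
    }
  }
  names(scores) <- defs$marker
  names(folds) <- defs$marker
  risk_sum <- sum(scores)
  structure(
    list(scores = scores, fold_reported = folds, risk_sum = risk_sum,
         category = if (risk_sum < low_high_cutoff) "low" else "high",
         low_high_cutoff = low_high_cutoff),
    class = "panel_result"
  )
}

#' @export
print.panel_result <- function(x, ...) {
  cat("<panel_result> eight-marker miRNA oncopanel\n")
  for (m in names(x$scores)) {
    fold_txt <- if (is.na(x$fold_reported[[m]])) "" else
      sprintf(" (fold %.1f)", x$fold_reported[[m]])
    cat(sprintf("  %-12s score %d%s\n", m, x$scores[[m]], fold_txt))
  }
  cat(sprintf("  risk factor %d -> %s risk (cutoff %g)\n",
              x$risk_sum, x$category, x$low_high_cutoff))
  invisible(x)
}
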