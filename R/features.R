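#' Internal temperature gradients per breast
#'
#' The internal gradient is the difference between the deep (microwave) and
#' skin (infrared) temperature at the same measurement point. A tumor close
#' to the surface heats the skin towards the internal reading, so a locally
#' reduced gradient is a risk signature.
#'
#' @param groups A `temperature_groups` object.
#' @return A list with `grad_right` and `grad_left`, length-10 vectors.
#' @export
compute_gradients <- function(groups) {
  .assert_groups(groups)
  list(
    grad_right = groups$t_r_mw - groups$t_r_ir,
    grad_left = groups$t_l_mw - groups$t_l_ir
  )
}

#' Signed thermal-asymmetry vectors per channel
#'
#' Element-wise left-minus-right differences at symmetric points, per
#' channel. Unlike the scalar coefficients of [compute_asymmetry()] these
#' stay signed: a downstream classifier can learn sidedness from them.
#'
#' @param groups A `temperature_groups` object.
#' @return A list with `asym_skin` and `asym_int`, length-10 vectors.
#' @export
compute_asymmetry_vectors <- function(groups) {
  .assert_groups(groups)
  list(
    asym_skin = groups$t_l_ir - groups$t_r_ir,
    asym_int = groups$t_l_mw - groups$t_r_mw
  )
}

.FEATURE_FAMILIES <- c("grad_right", "grad_left", "asym_skin", "asym_int",
                       "skin_right", "skin_left", "int_right", "int_left")
.AGGREGATES <- c("min", "max", "mean", "range")

#' Names of the thermogram feature vector, in order
#'
#' The feature space is fixed and versioned: the four derived 10-vectors
#' (right/left internal gradients, skin/internal asymmetries), then
#' min/max/mean/range aggregates of those four vectors and of the four raw
#' breast temperature groups (the range is the "oscillation" of a group and
#' captures temperature spread; the max captures hot areas), then `q_max`
#' and `r`. With `include_reference = TRUE` the four reference-point
#' temperatures are appended.
#'
#' @param include_reference Append reference-point temperatures T1/T2
#'   (both channels)? Default `FALSE`.
#' @return Character vector of feature names (length 74, or 78 with
#'   reference points).
#' @export
feature_names <- function(include_reference = FALSE) {
  vec_names <- c(t(outer(c("grad_right", "grad_left", "asym_skin", "asym_int"),
                         POINT_IDS, paste, sep = "_")))
  agg_names <- c(t(outer(.FEATURE_FAMILIES, .AGGREGATES, paste, sep = "_")))
  nm <- c(vec_names, agg_names, "q_max", "r")
  if (include_reference) {
    nm <- c(nm, "skin_ref_T1", "skin_ref_T2", "int_ref_T1", "int_ref_T2")
  }
  nm
}

#' Build the per-examination feature vector
#'
#' Deterministic, fixed-length numeric vector over the layout documented in
#' [feature_names()]. Two calls on the same thermogram return identical
#' vectors; no NaN is produced for a valid examination.
#'
#' @param tg A valid [thermogram].
#' @param include_reference Append reference-point temperatures? Default
#'   `FALSE`.
#' @return Named numeric vector of class `feature_vector`.
#' @export
build_feature_vector <- function(tg, include_reference = FALSE) {
  groups <- group_temperatures(tg)
  grads <- compute_gradients(groups)
  asyms <- compute_asymmetry_vectors(groups)
  families <- list(
    grad_right = grads$grad_right, grad_left = grads$grad_left,
    asym_skin = asyms$asym_skin, asym_int = asyms$asym_int,
    skin_right = groups$t_r_ir, skin_left = groups$t_l_ir,
    int_right = groups$t_r_mw, int_left = groups$t_l_mw
  )
  aggs <- unlist(lapply(families, function(v) {
    c(min = min(v), max = max(v), mean = mean(v), range = diff(range(v)))
  }))
  qc <- compute_qmax(groups)
  rr <- compute_r(groups)
  fv <- c(grads$grad_right, grads$grad_left,
          asyms$asym_skin, asyms$asym_int,
          aggs, q_max = qc$q_max, r = rr$r)
  if (include_reference) {
    fv <- c(fv, groups$t_a_ir, groups$t_a_mw)
  }
  names(fv) <- feature_names(include_reference)
  class(fv) <- "feature_vector"
  fv
}

#' Feature matrix for a list of thermograms
#'
#' @param tgs List of [thermogram] objects.
#' @param include_reference Passed to [build_feature_vector()].
#' @return A data.frame, one row per examination, columns
#'   [feature_names()] preceded by `patient_id`.
#' @export
build_feature_matrix <- function(tgs, include_reference = FALSE) {
  stopifnot(is.list(tgs), length(tgs) > 0L)
  rows <- lapply(tgs, function(tg) {
    fv <- build_feature_vector(tg, include_reference)
    cbind(data.frame(patient_id = tg$patient_id,
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(unclass(fv)), check.names = FALSE))
  })
  do.call(rbind, rows)
}
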