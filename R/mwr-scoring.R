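#' Focal-heating statistic Qmax
#'
#' Pools the 20 breast temperatures of each channel (both breasts, reference
#' points excluded) and takes the larger of `max - mean` over the internal
#' (microwave) pool and over the skin (infrared) pool. A hot focus inside
#' the gland raises the pooled maximum far more than the pooled mean, so
#' Qmax measures focal heating relative to the gland average; it is zero for
#' a perfectly uniform temperature field and never negative.
#'
#' @param groups A `temperature_groups` object from [group_temperatures()].
#' @return A list with `q_max` and the components `t_max_mw`, `t_max_ir`,
#'   `t_mean_mw`, `t_mean_ir` (degrees Celsius).
#' @export
compute_qmax <- function(groups) {
  .assert_groups(groups)
  pool_mw <- c(groups$t_r_mw, groups$t_l_mw)
  pool_ir <- c(groups$t_r_ir, groups$t_l_ir)
  t_max_mw <- max(pool_mw)
  t_max_ir <- max(pool_ir)
  t_mean_mw <- mean(pool_mw)
  t_mean_ir <- mean(pool_ir)
  list(
    q_max = max(t_max_mw - t_mean_mw, t_max_ir - t_mean_ir),
    t_max_mw = t_max_mw, t_max_ir = t_max_ir,
    t_mean_mw = t_mean_mw, t_mean_ir = t_mean_ir
  )
}

#' Thermal asymmetry coefficients k_int and k_skin
#'
#' The maximum left-right temperature difference over the ten symmetric
#' point pairs, per channel. The default convention takes absolute
#' differences so a right-sided focus is detected symmetrically to a
#' left-sided one; `sign_convention = "signed"` keeps the raw left-minus-
#' right maxima. Argmax ties go to the lowest point index.
#'
#' @param groups A `temperature_groups` object.
#' @param sign_convention `"absolute"` (default) or `"signed"`.
#' @return A list with `k_int`, `n_int`, `k_skin`, `n_skin`; `n_*` are the
#'   point indices (0-9) where each maximum is attained.
#' @export
compute_asymmetry <- function(groups,
                              sign_convention = c("absolute", "signed")) {
  .assert_groups(groups)
  sign_convention <- match.arg(sign_convention)
  diff_of <- function(l, r) {
    d <- l - r
    if (sign_convention == "absolute") abs(d) else d
  }
  d_mw <- diff_of(groups$t_l_mw, groups$t_r_mw)
  d_ir <- diff_of(groups$t_l_ir, groups$t_r_ir)
  n_int <- which.max(d_mw)  # which.max: first (lowest-index) maximum
  n_skin <- which.max(d_ir)
  list(
    k_int = d_mw[[n_int]], n_int = POINT_IDS[n_int],
    k_skin = d_ir[[n_skin]], n_skin = POINT_IDS[n_skin]
  )
}

#' Combined asymmetry statistic R
#'
#' When the two channels attain their maximum asymmetry at the same point,
#' R is simply `k_int + k_skin`. When the argmax points differ, the larger
#' coefficient is kept and the left-right difference measured by the OTHER
#' sensor at that same point is added: if the skin sensor gave the larger
#' coefficient at point n, the internal-channel difference at n is the
#' addend, and vice versa. A `k_int == k_skin` tie with distinct points is
#' resolved in favor of the internal channel.
#'
#' @param groups A `temperature_groups` object.
#' @param asym Result of [compute_asymmetry()]; computed when missing.
#' @param sign_convention `"absolute"` (default) or `"signed"`; must match
#'   the convention used for `asym`.
#' @return A list with `r` and `branch` (`"same_point"` or
#'   `"cross_channel"`).
#' @export
compute_r <- function(groups, asym = NULL,
                      sign_convention = c("absolute", "signed")) {
  .assert_groups(groups)
  sign_convention <- match.arg(sign_convention)
  if (is.null(asym)) asym <- compute_asymmetry(groups, sign_convention)
  if (asym$n_int == asym$n_skin) {
    return(list(r = asym$k_int + asym$k_skin, branch = "same_point"))
  }
  internal_wins <- asym$k_int >= asym$k_skin
  n <- if (internal_wins) asym$n_int else asym$n_skin
  k_star <- if (internal_wins) asym$k_int else asym$k_skin
  # the addend comes from the second sensor at the winning point
  other_l <- if (internal_wins) groups$t_l_ir else groups$t_l_mw
  other_r <- if (internal_wins) groups$t_r_ir else groups$t_r_mw
  d <- other_l[[n + 1L]] - other_r[[n + 1L]]
  if (sign_convention == "absolute") d <- abs(d)
  list(r = k_star + d, branch = "cross_channel")
}

#' Three-way MWR classification from Qmax and R
#'
#' Both statistics strictly above their thresholds suggest a malignant
#' tumor; both strictly below suggest a benign one. Any other combination
#' (including exact threshold equality) leaves both possibilities open and
#' is reported as ambiguous.
#'
#' @param q_max,r Numeric statistics in degrees Celsius.
#' @param q_threshold,r_threshold Decision thresholds; defaults 2.0 / 2.5.
#' @return One of `"malignant_suspected"`, `"benign"`, `"ambiguous"`.
#' @examples
#' classify_mwr(2.45, 3.2)  # malignant_suspected
#' classify_mwr(1.7, 1.9)   # benign
#' @export
classify_mwr <- function(q_max, r, q_threshold = 2.0, r_threshold = 2.5) {
  vals <- c(q_max = q_max, r = r,
            q_threshold = q_threshold, r_threshold = r_threshold)
  if (!all(is.finite(vals))) {
    stop("classify_mwr: non-finite input (",
         paste(names(vals)[!is.finite(vals)], collapse = ", "), ")",
         call. = FALSE)
  }
  if (q_max > q_threshold && r > r_threshold) return("malignant_suspected")
  if (q_max < q_threshold && r < r_threshold) return("benign")
  "ambiguous"
}

#' Score one thermogram: Qmax, asymmetry coefficients, R and MWR class
#'
#' Convenience wrapper running [compute_qmax()], [compute_asymmetry()],
#' [compute_r()] and [classify_mwr()] on a validated examination.
#'
#' @param tg A [thermogram].
#' @param q_threshold,r_threshold Decision thresholds in degrees Celsius.
#' @param sign_convention Asymmetry convention, see [compute_asymmetry()].
#' @return An object of class `mwr_score` carrying every component
#'   statistic, the argmax bookkeeping, the R branch taken and `mwr_class`.
#' @examples
#' tg <- thermogram("demo", rep(31, 10), rep(31, 10),
#'                  rep(34, 10), c(rep(34, 4), 37, rep(34, 5)))
#' score_mwr(tg)
#' @export
score_mwr <- function(tg, q_threshold = 2.0, r_threshold = 2.5,
                      sign_convention = c("absolute", "signed")) {
  sign_convention <- match.arg(sign_convention)
  groups <- group_temperatures(tg)
  qc <- compute_qmax(groups)
  asym <- compute_asymmetry(groups, sign_convention)
  rr <- compute_r(groups, asym, sign_convention)
  structure(
    list(
      patient_id = tg$patient_id,
      visit_date = tg$visit_date,
      t_max_mw = qc$t_max_mw, t_max_ir = qc$t_max_ir,
      t_mean_mw = qc$t_mean_mw, t_mean_ir = qc$t_mean_ir,
      q_max = qc$q_max,
      k_int = asym$k_int, n_int = asym$n_int,
      k_skin = asym$k_skin, n_skin = asym$n_skin,
      r = rr$r, branch = rr$branch,
      q_threshold = q_threshold, r_threshold = r_threshold,
      sign_convention = sign_convention,
      mwr_class = classify_mwr(qc$q_max, rr$r, q_threshold, r_threshold)
    ),
    class = "mwr_score"
  )
}

#' @export
print.mwr_score <- function(x, ...) {
  cat(sprintf("<mwr_score> patient %s\n", x$patient_id))
  cat(sprintf("  Qmax = %.1f degC (threshold %.1f)\n", x$q_max, x$q_threshold))
  cat(sprintf("  k_int = %.1f at point %d; k_skin = %.1f at point %d\n",
              x$k_int, x$n_int, x$k_skin, x$n_skin))
  cat(sprintf("  R = %.1f degC (threshold %.1f, %s branch)\n",
              x$r, x$r_threshold, x$branch))
  cat("  MWR class:", x$mwr_class, "\n")
  invisible(x)
}
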