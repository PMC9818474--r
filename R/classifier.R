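#' Train a low/high risk classifier on thermogram features
#'
#' A small trainable stand-in for the production risk model: either a
#' ridge-regularized logistic regression (`"logistic"`, default) or a
#' single-hidden-layer perceptron (`"small_mlp"`). Features are
#' standardized with training-set statistics; class imbalance (risk
#' cohorts run roughly 8 low : 1 high) is handled by inverse-frequency
#' observation weights. A stratified 80/20 split is drawn from `seed` and
#' the held-out F1, precision and recall for the high class are recorded
#' in `training_meta`.
#'
#' @param cohort A data.frame with feature columns ([feature_names()]) and
#'   a `label` column of `"low"`/`"high"`; as produced by
#'   [generate_cohort()].
#' @param kind `"logistic"` or `"small_mlp"`.
#' @param seed Integer seed controlling the split (and, for the MLP, the
#'   weight initialization); training is reproducible from it.
#' @param hidden Hidden-layer size for the MLP.
#' @return An object of class `risk_model`.
#' @export
train_risk_model <- function(cohort, kind = c("logistic", "small_mlp"),
                             seed = 1L, hidden = 5L) {
  kind <- match.arg(kind)
  stopifnot(is.data.frame(cohort), "label" %in% names(cohort))
  label <- factor(cohort$label, levels = c("low", "high"))
  if (anyNA(label) || nlevels(droplevels(label)) < 2L) {
    stop("cohort must contain both 'low' and 'high' labels", call. = FALSE)
  }
  feats <- intersect(feature_names(TRUE), names(cohort))
  if (length(feats) < 2L) stop("cohort carries no feature columns",
                               call. = FALSE)
  x <- as.matrix(cohort[, feats, drop = FALSE])
  if (!all(is.finite(x))) stop("non-finite feature values", call. = FALSE)

  split <- .stratified_split(label, holdout_frac = 0.2, seed = seed)
  x_tr <- x[split$train, , drop = FALSE]
  y_tr <- label[split$train]

  center <- colMeans(x_tr)
  scale_ <- apply(x_tr, 2L, stats::sd)
  scale_[scale_ < 1e-12] <- 1          # constant columns carry no signal
  z_tr <- sweep(sweep(x_tr, 2L, center), 2L, scale_, "/")

  w <- as.numeric(length(y_tr) / (2L * table(y_tr)[y_tr]))

  if (kind == "logistic") {
    fit <- glmnet::glmnet(z_tr, y_tr, family = "binomial", alpha = 0,
                          lambda = 0.01, weights = w, standardize = FALSE)
    beta <- as.numeric(fit$beta)
    params <- list(intercept = as.numeric(fit$a0), beta = beta)
  } else {
    set.seed(seed)
    fit <- nnet::nnet(z_tr, as.numeric(y_tr == "high"), size = hidden,
                      decay = 0.01, maxit = 300, weights = w,
                      entropy = TRUE, trace = FALSE)
    params <- list(wts = as.numeric(fit$wts), n_in = ncol(z_tr),
                   n_hidden = as.integer(hidden))
  }
  model <- structure(
    list(model_kind = kind, features = feats, center = center,
         scale = scale_, parameters = params,
         training_meta = list(seed = as.integer(seed),
                              n_low = sum(label == "low"),
                              n_high = sum(label == "high"))),
    class = "risk_model"
  )
  held <- predict_risk(model, cohort[split$holdout, feats, drop = FALSE])
  m <- .binary_metrics(label[split$holdout], held$label)
  model$training_meta <- c(model$training_meta, m)
  model
}

.stratified_split <- function(label, holdout_frac, seed) {
  set.seed(seed)
  holdout <- integer(0)
  for (lv in levels(label)) {
    idx <- which(label == lv)
    n_hold <- max(1L, round(holdout_frac * length(idx)))
    holdout <- c(holdout, sample(idx, n_hold))
  }
  list(train = setdiff(seq_along(label), holdout), holdout = sort(holdout))
}

.binary_metrics <- function(truth, pred, positive = "high") {
  tp <- sum(truth == positive & pred == positive)
  fp <- sum(truth != positive & pred == positive)
  fn <- sum(truth == positive & pred != positive)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  list(f1 = f1, precision = precision, recall = recall)
}

.sigmoid <- function(z) 1 / (1 + exp(-z))

.model_scores <- function(model, z) {
  p <- model$parameters
  if (model$model_kind == "logistic") {
    as.numeric(.sigmoid(p$intercept + z %*% p$beta))
  } else {
    # nnet weight layout: per hidden unit (bias, inputs...), then the
    # output unit (bias, hidden...)
    n_in <- p$n_in
    n_h <- p$n_hidden
    w <- p$wts
    w1 <- matrix(w[seq_len((n_in + 1L) * n_h)], nrow = n_in + 1L)
    w2 <- w[(n_in + 1L) * n_h + seq_len(n_h + 1L)]
    h <- .sigmoid(cbind(1, z) %*% w1)
    as.numeric(.sigmoid(cbind(1, h) %*% w2))
  }
}

#' Predict risk for one or more feature vectors
#'
#' @param model A trained [train_risk_model()] object.
#' @param fv A `feature_vector`, a named numeric vector, or a data.frame
#'   of feature columns. Column/name schema must cover the model's
#'   features.
#' @return A data.frame with `score` (probability of high risk, in
#'   \[0, 1\]) and `label` (`"low"`/`"high"` at the 0.5 cut).
#' @export
predict_risk <- function(model, fv) {
  stopifnot(inherits(model, "risk_model"))
  if (inherits(fv, "feature_vector") ||
      (is.numeric(fv) && !is.null(names(fv)))) {
    fv <- as.data.frame(as.list(unclass(fv)), check.names = FALSE)
  }
  stopifnot(is.data.frame(fv))
  missing <- setdiff(model$features, names(fv))
  if (length(missing)) {
    stop("feature schema mismatch; missing: ",
         paste(utils::head(missing, 5L), collapse = ", "),
         if (length(missing) > 5L) ", ..." else "", call. = FALSE)
  }
  x <- as.matrix(fv[, model$features, drop = FALSE])
  z <- sweep(sweep(x, 2L, model$center), 2L, model$scale, "/")
  score <- .model_scores(model, z)
  data.frame(score = score,
             label = ifelse(score >= 0.5, "high", "low"),
             stringsAsFactors = FALSE)
}

#' @export
print.risk_model <- function(x, ...) {
  tm <- x$training_meta
  cat(sprintf("<risk_model> %s over %d features\n",
              x$model_kind, length(x$features)))
  cat(sprintf("  cohort: %d low / %d high (seed %d)\n",
              tm$n_low, tm$n_high, tm$seed))
  cat(sprintf("  held-out F1 %.3f (precision %.3f, recall %.3f)\n",
              tm$f1, tm$precision, tm$recall))
  invisible(x)
}
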