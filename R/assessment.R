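#' Fuse MWR class, classifier label and miRNA category
#'
#' Rule-based decision table codifying the clinical workflow: microwave
#' radiometry screens first; an ambiguous or discordant picture triggers a
#' recommendation for the miRNA oncopanel; concordant high signals refer
#' the patient onward. The table is total and deterministic, and a high
#' miRNA category never downgrades the overall level.
#'
#' Overall levels:
#' * `benign_monitor` - routine monitoring (with a follow-up note when the
#'   classifier flagged high but the oncopanel was low);
#' * `elevated_recommend_mirna` - elevated suspicion, oncopanel (or
#'   repeat oncopanel) recommended;
#' * `high_risk_refer` - refer for histological work-up;
#' * `discordant_review` - the radiometric and molecular pictures
#'   disagree (MWR malignant, oncopanel low); clinical review required.
#'
#' @param mwr_class `"malignant_suspected"`, `"benign"` or `"ambiguous"`.
#' @param classifier_label Optional `"low"`/`"high"` from [predict_risk()].
#' @param mirna_category Optional `"low"`/`"high"` from [panel_risk()].
#' @return An object of class `assessment` with `overall` and an ordered
#'   `rationale` rule trace.
#' @examples
#' assess("benign", classifier_label = "high", mirna_category = "low")
#' assess("malignant_suspected", mirna_category = "high")
#' @export
assess <- function(mwr_class, classifier_label = NULL,
                   mirna_category = NULL) {
  mwr_class <- match.arg(mwr_class,
                         c("malignant_suspected", "benign", "ambiguous"))
  if (!is.null(classifier_label)) {
    classifier_label <- match.arg(classifier_label, c("low", "high"))
  }
  if (!is.null(mirna_category)) {
    mirna_category <- match.arg(mirna_category, c("low", "high"))
  }
  rationale <- sprintf("MWR classification: %s", mwr_class)
  if (mwr_class == "malignant_suspected") {
    rationale <- c(rationale,
                   paste("Qmax and R above thresholds indicate a",
                         "probability of developing breast cancer of",
                         "over 85%"))
  }
  if (!is.null(classifier_label)) {
    rationale <- c(rationale,
                   sprintf("feature-space classifier: %s risk",
                           classifier_label))
  }
  if (!is.null(mirna_category)) {
    rationale <- c(rationale,
                   sprintf("miRNA oncopanel category: %s", mirna_category))
  }

  clf_high <- !is.null(classifier_label) && classifier_label == "high"
  mirna <- if (is.null(mirna_category)) "absent" else mirna_category

  overall <- if (mwr_class == "malignant_suspected") {
    if (mirna == "low") {
      rationale <- c(rationale,
                     "radiometric and molecular findings disagree")
      "discordant_review"
    } else {
      "high_risk_refer"
    }
  } else if (mwr_class == "ambiguous") {
    if (mirna == "high") "high_risk_refer" else "elevated_recommend_mirna"
  } else {                                       # benign MWR
    if (clf_high) {
      switch(mirna,
             high = "high_risk_refer",
             low = {
               rationale <- c(rationale,
                              paste("classifier flagged high risk but",
                                    "oncopanel is low: schedule follow-up"))
               "benign_monitor"
             },
             absent = "elevated_recommend_mirna")
    } else {
      if (mirna == "high") "elevated_recommend_mirna" else "benign_monitor"
    }
  }
  rationale <- c(rationale, sprintf("overall: %s", overall))
  structure(
    list(mwr_class = mwr_class,
         classifier_label = classifier_label,
         mirna_category = mirna_category,
         overall = overall, rationale = rationale),
    class = "assessment"
  )
}

#' @export
print.assessment <- function(x, ...) {
  cat("<assessment>", x$overall, "\n")
  cat(paste0("  - ", x$rationale, collapse = "\n"), "\n")
  invisible(x)
}
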