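#' Fuse per-specimen predictions for one subject
#'
#' Combines the decision-tree predictions obtained from a subject's saliva,
#' GCF and plaque samples. With fewer than two specimen predictions the
#' subject is `indeterminate`; otherwise the majority class wins and a 1-1
#' tie falls to `tieBreak` (default the positive class — a screening test
#' favours sensitivity).
#'
#' @param predictions named character vector/list, names in
#'   saliva/gcf/plaque, values `periodontitis`/`control`.
#' @param tieBreak `"positive"` or `"negative"`.
#' @param subject optional subject id carried into the result.
#' @return list with `subject`, `predictions`, `fused` (periodontitis /
#'   control / indeterminate), `rule`.
#' @export
fusePredictions <- function(predictions, tieBreak = c("positive", "negative"),
                            subject = NA_character_) {
  tieBreak <- match.arg(tieBreak)
  predictions <- unlist(predictions)
  bad <- setdiff(names(predictions), SAMPLE_TYPES)
  if (length(bad) || (length(predictions) && is.null(names(predictions))))
    stopf("unknown sample type key(s): %s",
          paste(if (length(bad)) bad else "<unnamed>", collapse = ", "))
  checkGroup(setdiff(unique(predictions), character(0)))
  fused <- if (length(predictions) < 2L) {
    "indeterminate"
  } else {
    pos <- sum(predictions == POSITIVE_CLASS)
    neg <- sum(predictions == NEGATIVE_CLASS)
    if (pos > neg) POSITIVE_CLASS
    else if (neg > pos) NEGATIVE_CLASS
    else if (tieBreak == "positive") POSITIVE_CLASS else NEGATIVE_CLASS
  }
  list(subject = subject, predictions = as.list(predictions), fused = fused,
       rule = sprintf("majority, minimum 2 specimens, tie->%s", tieBreak))
}

## exact (Clopper-Pearson) binomial confidence interval
clopperPearson <- function(x, n, conf = 0.95) {
  a <- 1 - conf
  lower <- if (x == 0) 0 else stats::qbeta(a / 2, x, n - x + 1)
  upper <- if (x == n) 1 else stats::qbeta(1 - a / 2, x + 1, n - x)
  c(lower = lower, upper = upper)
}

#' Evaluate fused subject-level predictions
#'
#' Sensitivity, specificity, positive and negative predictive value over the
#' determinate subjects, each with an exact Clopper-Pearson 95\% confidence
#' interval (for x = n successes the lower bound is `(alpha/2)^(1/n)`).
#' Indeterminate subjects are counted and excluded from the metrics.
#'
#' @param fused data.frame with columns `subject` and `fused`
#'   (periodontitis / control / indeterminate), or a list of
#'   [fusePredictions()] results.
#' @param truth named character vector of true groups per subject.
#' @param conf confidence level (default 0.95).
#' @return list of class `"FusionEval"`: per metric `estimate`, `ci`,
#'   `x`, `n`; plus `nIndeterminate`, `nDeterminate`.
#' @export
evaluateFusion <- function(fused, truth, conf = 0.95) {
  if (is.list(fused) && !is.data.frame(fused) && !is.null(fused[[1L]]$fused))
    fused <- data.frame(
      subject = vapply(fused, function(z) as.character(z$subject), character(1)),
      fused = vapply(fused, function(z) z$fused, character(1)),
      stringsAsFactors = FALSE)
  stopifnot(all(c("subject", "fused") %in% names(fused)))
  tr <- truth[fused$subject]
  if (anyNA(tr)) stopf("truth missing for subject(s): %s",
                       paste(fused$subject[is.na(tr)], collapse = ", "))
  det <- fused$fused != "indeterminate"
  if (!any(det & tr == POSITIVE_CLASS) || !any(det & tr == NEGATIVE_CLASS))
    stopf("need at least one determinate subject per class")
  pred <- fused$fused[det]
  tr <- tr[det]
  metric <- function(x, n) {
    est <- x / n
    list(estimate = est, ci = clopperPearson(x, n, conf), x = x, n = n)
  }
  tp <- sum(pred == POSITIVE_CLASS & tr == POSITIVE_CLASS)
  fn <- sum(pred != POSITIVE_CLASS & tr == POSITIVE_CLASS)
  tn <- sum(pred == NEGATIVE_CLASS & tr == NEGATIVE_CLASS)
  fp <- sum(pred != NEGATIVE_CLASS & tr == NEGATIVE_CLASS)
  structure(list(
    sensitivity = metric(tp, tp + fn),
    specificity = metric(tn, tn + fp),
    ppv = metric(tp, tp + fp),
    npv = metric(tn, tn + fn),
    nDeterminate = sum(det),
    nIndeterminate = sum(!det),
    conf = conf), class = "FusionEval")
}

#' @export
print.FusionEval <- function(x, ...) {
  for (m in c("sensitivity", "specificity", "ppv", "npv")) {
    v <- x[[m]]
    cat(sprintf("  %-12s %.3f (CI %d%% = [%.3f; %.3f], %d/%d)\n", m,
                v$estimate, round(100 * x$conf), v$ci["lower"],
                v$ci["upper"], v$x, v$n))
  }
  cat(sprintf("  determinate %d, indeterminate %d\n",
              x$nDeterminate, x$nIndeterminate))
  invisible(x)
}
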