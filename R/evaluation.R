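# Confusion-matrix metrics and ROC AUC per cross-validation fold, and
# their unweighted averaging across folds.

.isPositive <- function(labels) {
  if (is.character(labels) || is.factor(labels)) {
    lb <- as.character(labels)
    bad <- !lb %in% .CLASS_LEVELS
    if (any(bad)) stopData("unknown labels: ",
                           paste(unique(lb[bad]), collapse = ", "))
    lb == "hypertension"
  } else as.logical(labels)
}

#' Confusion counts at a score threshold
#'
#' A score at or above `threshold` predicts hypertension. TP/TN/FP/FN
#' follow the clinical convention: hypertension is the positive class.
#'
#' @param scores numeric vector of hypertension scores.
#' @param labels class labels (character `"hypertension"` /
#'   `"non-hypertension"`, or logical/0-1 with TRUE/1 = hypertension).
#' @param threshold decision threshold, default 0.5.
#' @return a [ConfusionCounts-class].
#' @export
confusionCounts <- function(scores, labels, threshold = 0.5) {
  if (length(scores) != length(labels))
    stopData("scores and labels must have equal length")
  if (length(scores) < 1L) stopData("need at least one score")
  pos <- .isPositive(labels)
  pred <- scores >= threshold
  new("ConfusionCounts",
      tp = sum(pred & pos), tn = sum(!pred & !pos),
      fp = sum(pred & !pos), fn = sum(!pred & pos))
}

#' Metrics from confusion counts
#'
#' accuracy = (TP+TN)/(TP+TN+FP+FN), specificity = TN/(TN+FP),
#' precision = TP/(TP+FP), recall = TP/(TP+FN). A metric whose denominator
#' is zero is returned as `NA` and named in the report's `undefined` slot,
#' never silently as 0.
#'
#' @param counts a [ConfusionCounts-class].
#' @param auc optional AUC to attach to the report.
#' @param fold fold label for the report.
#' @return a [MetricsReport-class].
#' @export
computeMetrics <- function(counts, auc = NA_real_, fold = "1") {
  stopifnot(is(counts, "ConfusionCounts"))
  tp <- counts@tp; tn <- counts@tn; fp <- counts@fp; fn <- counts@fn
  n <- tp + tn + fp + fn
  safe <- function(num, den) if (den == 0) NA_real_ else num / den
  acc <- safe(tp + tn, n)
  spec <- safe(tn, tn + fp)
  prec <- safe(tp, tp + fp)
  rec <- safe(tp, tp + fn)
  vals <- c(accuracy = acc, specificity = spec, precision = prec,
            recall = rec, auc = auc)
  new("MetricsReport", accuracy = acc, specificity = spec,
      precision = prec, recall = rec, auc = as.numeric(auc),
      undefined = names(vals)[is.na(vals)], fold = as.character(fold),
      nImages = as.integer(n))
}

#' ROC AUC (Mann-Whitney form)
#'
#' Equals the probability that a random positive outscores a random
#' negative, with ties credited one half:
#' \eqn{P(s_+ > s_-) + \frac{1}{2} P(s_+ = s_-)}. Computed via midranks.
#'
#' @param scores numeric hypertension scores.
#' @param labels class labels (see [confusionCounts()]).
#' @export
aucScore <- function(scores, labels) {
  pos <- .isPositive(labels)
  nP <- sum(pos); nN <- sum(!pos)
  if (nP == 0L || nN == 0L)
    stopData("AUC is undefined with a single class present")
  r <- rank(scores)  # midranks handle ties
  (sum(r[pos]) - nP * (nP + 1) / 2) / (nP * nN)
}

#' Average cross-validation reports
#'
#' Unweighted arithmetic mean of each metric over the fold reports,
#' producing the "average" row of a cross-validation table. Permutation
#' invariant in fold order. Report percentages to two decimals and AUC to
#' four via [formatMetricsReport()].
#'
#' @param foldReports list of [MetricsReport-class] (typically 5).
#' @return a [MetricsReport-class] with fold label `"average"`.
#' @export
aggregateCv <- function(foldReports) {
  stopifnot(length(foldReports) >= 1L,
            all(vapply(foldReports, is, TRUE, "MetricsReport")))
  getv <- function(sl) vapply(foldReports, methods::slot, 0, sl)
  mn <- function(sl) mean(getv(sl))
  vals <- c(accuracy = mn("accuracy"), specificity = mn("specificity"),
            precision = mn("precision"), recall = mn("recall"),
            auc = mn("auc"))
  new("MetricsReport", accuracy = vals[["accuracy"]],
      specificity = vals[["specificity"]], precision = vals[["precision"]],
      recall = vals[["recall"]], auc = vals[["auc"]],
      undefined = names(vals)[is.na(vals)], fold = "average",
      nImages = sum(vapply(foldReports, methods::slot, 0L, "nImages")))
}

#' Format a metrics report in table style
#'
#' Percentages rounded half-up to two decimals, AUC to four decimals;
#' internal values keep full precision.
#'
#' @param report a [MetricsReport-class].
#' @return named character vector.
#' @export
formatMetricsReport <- function(report) {
  pct <- function(v) if (is.na(v)) "undefined"
  else sprintf("%.2f%%", floor(v * 10000 + 0.5) / 100)
  c(accuracy = pct(report@accuracy), specificity = pct(report@specificity),
    precision = pct(report@precision), recall = pct(report@recall),
    auc = if (is.na(report@auc)) "undefined"
    else sprintf("%.4f", floor(report@auc * 10000 + 0.5) / 10000))
}

#' Cross-validation table as a data.frame
#'
#' One row per fold plus the "average" row, in the layout of a
#' cross-validation results table.
#'
#' @param foldReports list of per-fold [MetricsReport-class].
#' @return data.frame with columns fold, accuracy, specificity, precision,
#'   recall, auc, n.
#' @export
cvTable <- function(foldReports) {
  avg <- aggregateCv(foldReports)
  do.call(rbind, lapply(c(foldReports, list(avg)), metricsTable))
}
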