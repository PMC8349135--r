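# Diagnostic metric suite for a binary (sick vs healthy) classifier.
# All twelve metrics are simple ratios of the confusion counts; a zero
# denominator makes the metric *undefined*, carried as NA throughout and
# rendered "NA" in tables. Computation is at full floating precision;
# rounding happens only at formatting time.

#' Construct confusion counts
#'
#' @param tp,tn,fp,fn non-negative integer counts of true positives, true
#'   negatives, false positives, false negatives.
#' @return a [ConfusionCounts-class].
#' @examples
#' confusionCounts(258, 304, 0, 0)
#' @export
confusionCounts <- function(tp, tn, fp, fn) {
  v <- c(tp, tn, fp, fn)
  if (anyNA(v) || any(v != as.integer(v)))
    stop("counts must be integers")
  if (any(v < 0)) stop("counts must be non-negative")
  methods::new("ConfusionCounts", tp = as.integer(tp), tn = as.integer(tn),
               fp = as.integer(fp), fn = as.integer(fn))
}

.safeRatio <- function(num, den) if (den == 0) NA_real_ else num / den

#' Evaluate the twelve diagnostic metrics
#'
#' Computes precision `TP/(TP+FP)`, accuracy `(TP+TN)/total` (percent),
#' specificity `TN/(FP+TN)`, sensitivity `TP/(TP+FN)`, NPV `TN/(TN+FN)`,
#' FPR `FP/(TN+FP)`, FNR `FN/(TP+FN)`, LRP `Sen/(1-Spe)`,
#' LRN `(1-Sen)/Spe`, AUC `(Sen+Spe)/2` (balanced accuracy), EER `1-AUC`
#' and F1 `2*Sen*P/(Sen+P)`. Any zero denominator yields an undefined
#' (`NA`) metric: precision is undefined when `TP+FP = 0`, LRP when
#' specificity is 1 (or undefined), F1 when `Sen + P = 0` or precision is
#' undefined, and so on.
#'
#' @param counts a [ConfusionCounts-class] (or the result of
#'   [confusionCounts()]).
#' @return a [MetricReport-class].
#' @examples
#' evaluateCounts(confusionCounts(257, 303, 1, 1))
#' @export
evaluateCounts <- function(counts) {
  stopifnot(methods::is(counts, "ConfusionCounts"))
  methods::validObject(counts)
  tp <- counts@tp; tn <- counts@tn; fp <- counts@fp; fn <- counts@fn
  total <- tp + tn + fp + fn
  sen <- .safeRatio(tp, tp + fn)
  spe <- .safeRatio(tn, fp + tn)
  prec <- .safeRatio(tp, tp + fp)
  npv <- .safeRatio(tn, tn + fn)
  fpr <- if (is.na(spe)) NA_real_ else 1 - spe
  fnr <- if (is.na(sen)) NA_real_ else 1 - sen
  lrp <- if (is.na(sen) || is.na(spe) || spe == 1) NA_real_ else
    sen / (1 - spe)
  lrn <- if (is.na(sen) || is.na(spe) || spe == 0) NA_real_ else
    (1 - sen) / spe
  auc <- if (is.na(sen) || is.na(spe)) NA_real_ else (sen + spe) / 2
  eer <- if (is.na(auc)) NA_real_ else 1 - auc
  f1 <- if (is.na(sen) || is.na(prec) || sen + prec == 0) NA_real_ else
    2 * sen * prec / (sen + prec)
  methods::new("MetricReport",
    counts = counts,
    accuracy = 100 * (tp + tn) / total,
    sensitivity = sen, specificity = spe, precision = prec, npv = npv,
    fpr = fpr, fnr = fnr, lrp = lrp, lrn = lrn, auc = auc, eer = eer,
    f1 = f1)
}

#' Tally confusion counts from label sequences
#'
#' @param trueLabels,predictedLabels equal-length vectors of binary labels.
#' @param positiveLabel the label treated as positive (default
#'   `"sick"`).
#' @param negativeLabel the label treated as negative (default
#'   `"healthy"`); any other label is rejected.
#' @return a [ConfusionCounts-class]; `tp + fn` equals the number of true
#'   positives in `trueLabels`, `tn + fp` the number of negatives.
#' @export
confusionFromPredictions <- function(trueLabels, predictedLabels,
                                     positiveLabel = "sick",
                                     negativeLabel = "healthy") {
  if (length(trueLabels) != length(predictedLabels))
    stop("label sequences must have equal length")
  if (length(trueLabels) < 1L) stop("label sequences must be non-empty")
  seen <- unique(c(trueLabels, predictedLabels))
  if (length(setdiff(seen, c(positiveLabel, negativeLabel))))
    stop("labels must be binary; unseen label: ",
         paste(setdiff(seen, c(positiveLabel, negativeLabel)),
               collapse = ", "))
  tpos <- trueLabels == positiveLabel
  ppos <- predictedLabels == positiveLabel
  confusionCounts(sum(tpos & ppos), sum(!tpos & !ppos),
                  sum(!tpos & ppos), sum(tpos & !ppos))
}

.metricColumns <- c("TP", "TN", "FP", "FN", "Accu", "Sen", "Spe", "P",
                    "NPV", "FPR", "FNR", "LRP", "LRN", "AUC", "EER", "F1")

.fmt3 <- function(x) ifelse(is.na(x), "NA", sprintf("%.3f", x))

#' Render metric reports as a performance table
#'
#' One row per report with columns in the conventional order TP, TN, FP,
#' FN, Accu, Sen, Spe, P, NPV, FPR, FNR, LRP, LRN, AUC, EER, F1. Accuracy
#' is rendered as percent with 2 decimals, all other metrics with 3
#' decimals; undefined metrics render as `"NA"`.
#'
#' @param reports named list of [MetricReport-class] objects (names become
#'   the `Method` column), or a single report.
#' @param path optional CSV file to write.
#' @return data.frame of rendered strings (plus integer count columns).
#' @export
formatReportTable <- function(reports, path = NULL) {
  if (methods::is(reports, "MetricReport")) reports <- list(report = reports)
  rows <- lapply(names(reports), function(nm) {
    r <- reports[[nm]]
    cc <- r@counts
    acc <- sprintf("%.2f", r@accuracy)
    acc <- sub("^100\\.00$", "100", acc)  # printed convention for a perfect run
    data.frame(Method = nm, TP = cc@tp, TN = cc@tn, FP = cc@fp, FN = cc@fn,
               Accu = acc, Sen = .fmt3(r@sensitivity),
               Spe = .fmt3(r@specificity), P = .fmt3(r@precision),
               NPV = .fmt3(r@npv), FPR = .fmt3(r@fpr), FNR = .fmt3(r@fnr),
               LRP = .fmt3(r@lrp), LRN = .fmt3(r@lrn), AUC = .fmt3(r@auc),
               EER = .fmt3(r@eer), F1 = .fmt3(r@f1),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  out
}

#' Read a counts CSV and evaluate every row
#'
#' The CSV must have columns `name`, `tp`, `tn`, `fp`, `fn` (case
#' insensitive).
#'
#' @param path CSV file.
#' @return named list of [MetricReport-class] objects.
#' @export
evaluateCountsFile <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  need <- c("name", "tp", "tn", "fp", "fn")
  if (!all(need %in% names(df)))
    stop("counts CSV must have columns: ", paste(need, collapse = ", "))
  stats::setNames(lapply(seq_len(nrow(df)), function(i)
    evaluateCounts(confusionCounts(df$tp[i], df$tn[i], df$fp[i], df$fn[i]))),
    df$name)
}

#' @describeIn ConfusionCounts-class display.
#' @param object a `ConfusionCounts`.
#' @export
setMethod("show", "ConfusionCounts", function(object) {
  cat(sprintf("ConfusionCounts: TP=%d TN=%d FP=%d FN=%d (n=%d)\n",
              object@tp, object@tn, object@fp, object@fn,
              object@tp + object@tn + object@fp + object@fn))
})

#' @describeIn MetricReport-class one-row table display.
#' @param object a `MetricReport`.
#' @export
setMethod("show", "MetricReport", function(object) {
  tab <- formatReportTable(list(report = object))
  cat("MetricReport\n")
  print(tab[, -1], row.names = FALSE)
})
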