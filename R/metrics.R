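## Confusion-matrix metrics: accuracy, precision, recall, F1.

#' Compute classification metrics from labels and predictions
#'
#' Accuracy is `(TP + TN) / (TP + TN + FP + FN)`; precision, recall and F1
#' are computed one-vs-rest per class with zero-denominator cases mapping
#' to 0, then aggregated by support-weighted averaging (the default
#' reported by the accessors) and by macro averaging.
#'
#' @param yTrue integer vector of true labels in \{0, 1\}.
#' @param yPred integer vector of predicted labels in \{0, 1\}, same
#'   length.
#' @param splitDescriptor free-text split description for the report.
#' @param seed seed to record (bookkeeping only).
#' @return an [EvalReport-class].
#' @examples
#' ## TP = 3, FP = 1, FN = 2, TN = 4 for the positive class
#' y  <- c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0)
#' yh <- c(1, 1, 1, 0, 0, 1, 0, 0, 0, 0)
#' rep <- computeMetrics(y, yh)
#' accuracy(rep)   # 0.7
#' @export
computeMetrics <- function(yTrue, yPred, splitDescriptor = "",
                           seed = NA_integer_) {
  yTrue <- as.integer(yTrue)
  yPred <- as.integer(yPred)
  if (length(yTrue) != length(yPred)) {
    stop("yTrue and yPred must have equal length")
  }
  if (!length(yTrue)) stop("cannot compute metrics on empty input")
  if (!all(c(yTrue, yPred) %in% c(0L, 1L))) {
    stop("labels must be binary (0/1)")
  }
  n <- length(yTrue)
  perClass <- do.call(rbind, lapply(c(0L, 1L), function(cl) {
    tp <- sum(yTrue == cl & yPred == cl)
    fp <- sum(yTrue != cl & yPred == cl)
    fn <- sum(yTrue == cl & yPred != cl)
    tn <- sum(yTrue != cl & yPred != cl)
    precision <- if (tp + fp > 0) tp / (tp + fp) else 0
    recall <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (precision + recall > 0) {
      2 * precision * recall / (precision + recall)
    } else 0
    data.frame(class = cl, support = tp + fn, tp = tp, fp = fp, fn = fn,
               tn = tn, precision = precision, recall = recall, f1 = f1)
  }))
  acc <- sum(yTrue == yPred) / n
  wgt <- perClass$support / n
  weighted <- c(precision = sum(wgt * perClass$precision),
                recall = sum(wgt * perClass$recall),
                f1 = sum(wgt * perClass$f1))
  macro <- c(precision = mean(perClass$precision),
             recall = mean(perClass$recall),
             f1 = mean(perClass$f1))
  new("EvalReport", perClass = perClass, accuracy = acc, weighted = weighted,
      macro = macro, averaging = "weighted",
      splitDescriptor = splitDescriptor, seed = as.integer(seed))
}

#' Flatten an EvalReport to a one-row data.frame
#'
#' Accuracy and the weighted/macro aggregates as percentages, in the
#' column layout used by the ablation tables (two decimals when
#' formatted).
#'
#' @param report an [EvalReport-class].
#' @param method row label for the method column.
#' @return one-row data.frame: method, accuracy, precision, recall, f1,
#'   macroF1 (percent).
#' @export
reportRow <- function(report, method = "DSCnet") {
  data.frame(method = method,
             accuracy = 100 * report@accuracy,
             precision = 100 * report@weighted[["precision"]],
             recall = 100 * report@weighted[["recall"]],
             f1 = 100 * report@weighted[["f1"]],
             macroF1 = 100 * report@macro[["f1"]])
}

#' Serialize an EvalReport
#'
#' Writes a flat key-value JSON report and (optionally) a CSV metrics row
#' with percentages rounded to two decimals.
#'
#' @param report an [EvalReport-class].
#' @param jsonPath path for the JSON report, or NULL to skip.
#' @param csvPath path for the CSV row, or NULL to skip.
#' @param method row label used in the CSV.
#' @return (invisibly) the flat list that was serialized.
#' @export
writeEvalReport <- function(report, jsonPath = NULL, csvPath = NULL,
                            method = "DSCnet") {
  flat <- list(
    accuracy = report@accuracy,
    precision_weighted = report@weighted[["precision"]],
    recall_weighted = report@weighted[["recall"]],
    f1_weighted = report@weighted[["f1"]],
    precision_macro = report@macro[["precision"]],
    recall_macro = report@macro[["recall"]],
    f1_macro = report@macro[["f1"]],
    per_class = report@perClass,
    split = report@splitDescriptor,
    seed = report@seed)
  if (!is.null(jsonPath)) {
    jsonlite::write_json(flat, jsonPath, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  }
  if (!is.null(csvPath)) {
    row <- reportRow(report, method)
    row[-1] <- lapply(row[-1], function(x) sprintf("%.2f", x))
    utils::write.csv(row, csvPath, row.names = FALSE, quote = FALSE)
  }
  invisible(flat)
}
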