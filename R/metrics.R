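# Evaluation metrics: confusion matrix, per-class precision/recall/F1,
# accuracy and one-vs-rest ROC AUC.

#' Multi-class classification report
#'
#' Standard definitions: per-class precision (column-wise), recall
#' (row-wise), F1 (harmonic mean), support, overall accuracy and the C x C
#' confusion matrix (rows = truth, columns = prediction). Macro averages
#' summarise the per-class values. Division by zero (a class never
#' predicted, or absent from the truth) yields 0 with a warning, matching
#' common report tooling.
#'
#' @param truth integer true class indices (1-based).
#' @param predicted integer predicted class indices, same length.
#' @param nClasses number of classes C (default: max observed).
#' @param classNames optional class names for the output.
#' @return an object of class `classReport`: list with `confusion`,
#'   `perClass` (data.frame), `accuracy`, `macro`.
#' @export
#' @examples
#' classificationReport(c(1, 1, 2, 2), c(1, 2, 2, 2), nClasses = 2)
classificationReport <- function(truth, predicted,
                                 nClasses = max(c(truth, predicted)),
                                 classNames = NULL) {
  truth <- as.integer(truth); predicted <- as.integer(predicted)
  if (length(truth) != length(predicted))
    stop("truth and predicted must have equal length", call. = FALSE)
  C <- as.integer(nClasses)
  stopIfNot(all(c(truth, predicted) >= 1L) && all(c(truth, predicted) <= C),
            "labels out of range 1..C")
  if (is.null(classNames)) classNames <- paste0("class", seq_len(C))
  conf <- matrix(0L, C, C, dimnames = list(truth = classNames,
                                           predicted = classNames))
  tab <- table(factor(truth, levels = seq_len(C)),
               factor(predicted, levels = seq_len(C)))
  conf[] <- as.integer(tab)
  tp <- diag(conf)
  support <- rowSums(conf)
  predTot <- colSums(conf)
  safeDiv <- function(num, den, what) {
    out <- ifelse(den > 0, num / den, 0)
    if (any(den == 0))
      warning("zero denominator in ", what, "; reporting 0", call. = FALSE)
    out
  }
  precision <- safeDiv(tp, predTot, "precision")
  recall <- safeDiv(tp, support, "recall")
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  perClass <- data.frame(class = classNames, precision = precision,
                         recall = recall, f1 = f1,
                         support = as.integer(support),
                         stringsAsFactors = FALSE, row.names = NULL)
  structure(list(
    confusion = conf,
    perClass = perClass,
    accuracy = sum(tp) / length(truth),
    macro = c(precision = mean(precision), recall = mean(recall),
              f1 = mean(f1))),
    class = "classReport")
}

#' @export
print.classReport <- function(x, ...) {
  cat(sprintf("Accuracy: %.4f  (n = %d)\n", x$accuracy, sum(x$confusion)))
  print(x$perClass, digits = 4)
  cat(sprintf("Macro: P %.4f  R %.4f  F1 %.4f\n",
              x$macro["precision"], x$macro["recall"], x$macro["f1"]))
  invisible(x)
}

#' One-vs-rest ROC AUC per class
#'
#' AUC computed from the rank statistic (equivalent to the Mann-Whitney
#' U), with midranks for tied scores. A class absent from the truth has
#' undefined AUC and is reported as `NA`.
#'
#' @param truth integer true class indices (1-based).
#' @param probs a [ProbabilityMatrix-class] or `n x C` score matrix.
#' @return named numeric vector of per-class AUC values.
#' @export
#' @examples
#' p <- probabilityMatrix(rbind(a = c(0.9, 0.1), b = c(0.2, 0.8)))
#' rocAucOvr(c(1, 2), p)
rocAucOvr <- function(truth, probs) {
  v <- probValues(probs)
  truth <- as.integer(truth)
  stopIfNot(length(truth) == nrow(v), "truth must align with rows")
  C <- ncol(v)
  out <- rep(NA_real_, C)
  names(out) <- colnames(v) %||% paste0("class", seq_len(C))
  for (k in seq_len(C)) {
    pos <- truth == k
    n1 <- sum(pos); n0 <- sum(!pos)
    if (n1 == 0L || n0 == 0L) next
    r <- rank(v[, k], ties.method = "average")
    out[k] <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a classification report to disk
#'
#' `report.json` (per-class + macro + accuracy) and `confusion.csv`.
#'
#' @param report a `classReport`.
#' @param dir output directory (created if needed).
#' @return invisible vector of paths written.
#' @export
writeClassReport <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonPath <- file.path(dir, "report.json")
  jsonlite::write_json(list(accuracy = report$accuracy,
                            perClass = report$perClass,
                            macro = as.list(report$macro)),
                       jsonPath, auto_unbox = TRUE, digits = NA)
  confPath <- file.path(dir, "confusion.csv")
  utils::write.csv(report$confusion, confPath)
  invisible(c(jsonPath, confPath))
}
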