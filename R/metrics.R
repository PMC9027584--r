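# Multiclass evaluation: K x K confusion matrix (rows = actual class,
# columns = predicted class) and the one-vs-rest counts derived from it,
# feeding per-class sensitivity/specificity and macro summary metrics.

#' Confusion matrix from labels and predictions
#'
#' `C[i, j]` counts samples whose actual class is `i` and predicted class is
#' `j` (0-based ids). Rows are actuals, so a row sum minus the diagonal gives
#' the false negatives of that class.
#'
#' @param y_true integer actual class ids in \[0, K).
#' @param y_pred integer predicted class ids in \[0, K).
#' @param K number of classes.
#' @return K x K integer matrix with dimnames giving the class ids.
#' @examples
#' confusion_matrix(c(0, 0, 1, 2), c(0, 1, 1, 2), K = 3)
#' @export
confusion_matrix <- function(y_true, y_pred, K) {
  if (length(y_true) != length(y_pred))
    abort_input("`y_true` and `y_pred` must have equal length")
  y_true <- as.integer(y_true); y_pred <- as.integer(y_pred)
  K <- as.integer(K)
  if (length(y_true) > 0 &&
      (any(y_true < 0L) || any(y_true >= K) || any(y_pred < 0L) || any(y_pred >= K)))
    abort_input("class ids must lie in [0, K)")
  C <- matrix(0L, K, K, dimnames = list(actual = as.character(0:(K - 1)),
                                        predicted = as.character(0:(K - 1))))
  if (length(y_true) > 0) {
    tab <- table(factor(y_true, levels = 0:(K - 1)),
                 factor(y_pred, levels = 0:(K - 1)))
    C[] <- as.integer(tab)
  }
  C
}

#' One-vs-rest counts per class
#'
#' Derives, for each class `i`, the true positives (diagonal entry), false
#' negatives (rest of row `i`), false positives (rest of column `i`) and true
#' negatives (everything else) from a confusion matrix.
#'
#' @param C confusion matrix (rows = actual).
#' @return `data.frame` with columns `class`, `TP`, `FN`, `FP`, `TN`;
#'   each row satisfies `TP + FN + FP + TN == sum(C)`.
#' @export
per_class_counts <- function(C) {
  C <- validate_confusion(C)
  tp <- diag(C)
  fn <- rowSums(C) - tp
  fp <- colSums(C) - tp
  tn <- sum(C) - tp - fn - fp
  data.frame(class = 0:(nrow(C) - 1L), TP = as.integer(tp),
             FN = as.integer(fn), FP = as.integer(fp), TN = as.integer(tn))
}

validate_confusion <- function(C) {
  if (!is.matrix(C) || nrow(C) != ncol(C))
    abort_input("a confusion matrix must be square")
  if (any(C < 0) || any(C != round(C)))
    abort_input("confusion-matrix entries must be non-negative integers")
  C
}

#' Per-class multiclass sensitivity and specificity
#'
#' Sensitivity of class `i` is `TP / (TP + FN)` (ability to recognize members
#' of the class); specificity is `TN / (TN + FP)` (ability to recognize
#' non-members). A class with a zero denominator — e.g. absent from the
#' actual labels — is reported as `NA` with its `*_defined` flag set to
#' `FALSE`, never silently coerced to 0, so macro averages are not distorted.
#'
#' @param x a confusion matrix or a counts `data.frame` from
#'   [per_class_counts()].
#' @return `data.frame` with `class`, `sensitivity`, `specificity`,
#'   `sensitivity_defined`, `specificity_defined`.
#' @export
sensitivity_specificity <- function(x) {
  counts <- if (is.matrix(x)) per_class_counts(x) else x
  sn_den <- counts$TP + counts$FN
  sp_den <- counts$TN + counts$FP
  data.frame(
    class = counts$class,
    sensitivity = ifelse(sn_den > 0, counts$TP / sn_den, NA_real_),
    specificity = ifelse(sp_den > 0, counts$TN / sp_den, NA_real_),
    sensitivity_defined = sn_den > 0,
    specificity_defined = sp_den > 0)
}

#' Macro accuracy, precision, and recall
#'
#' Accuracy is `trace(C) / sum(C)`; macro precision and recall are unweighted
#' means of the per-class ratios over the classes for which they are defined.
#'
#' @param C confusion matrix (rows = actual).
#' @return list with elements `accuracy`, `precision`, `recall`.
#' @export
summary_metrics <- function(C) {
  C <- validate_confusion(C)
  total <- sum(C)
  if (total == 0) abort_input("cannot summarize an empty confusion matrix")
  counts <- per_class_counts(C)
  prec <- counts$TP / (counts$TP + counts$FP)
  rec <- counts$TP / (counts$TP + counts$FN)
  list(accuracy = sum(diag(C)) / total,
       precision = mean(prec[is.finite(prec)]),
       recall = mean(rec[is.finite(rec)]))
}

#' Serialize a metrics report
#'
#' Writes the confusion matrix as CSV and the per-class + summary metrics as
#' JSON next to it.
#'
#' @param C confusion matrix.
#' @param dir output directory.
#' @return named list of the two file paths, invisibly.
#' @export
write_metrics_report <- function(C, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cm_path <- file.path(dir, "confusion.csv")
  utils::write.csv(as.data.frame(C), cm_path, row.names = TRUE)
  js_path <- file.path(dir, "metrics.json")
  jsonlite::write_json(
    list(per_class = sensitivity_specificity(C),
         counts = per_class_counts(C),
         summary = summary_metrics(C)),
    js_path, auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(list(confusion = cm_path, metrics = js_path))
}
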