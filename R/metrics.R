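# Evaluation metrics. Per class (one-vs-rest): Sen = TP/(TP+FN),
# Spe = TN/(TN+FP), Ppv = TP/(TP+FP), Acc = (TP+TN)/total, all reported as
# percentages; F1 = 2*Sen*Ppv/(Sen+Ppv) = 2TP/(2TP+FP+FN) on the 0..1 scale.
# The mean row is the unweighted average over classes; the overall accuracy
# is the confusion-matrix trace over the total.

#' Confusion matrix from label vectors
#'
#' @param truth,pred vectors of true and predicted class labels.
#' @param classes fixed class order; defaults to the sorted union.
#' @return A `confusion_matrix`: integer matrix, rows = true classes,
#'   columns = predicted classes.
#' @export
confusion_matrix <- function(truth, pred, classes = NULL) {
  truth <- as.character(truth); pred <- as.character(pred)
  if (length(truth) != length(pred)) stop("truth and pred must align")
  classes <- classes %||% sort(unique(c(truth, pred)))
  m <- table(factor(truth, levels = classes), factor(pred, levels = classes))
  out <- matrix(as.integer(m), nrow = length(classes),
                dimnames = list(true = classes, predicted = classes))
  class(out) <- c("confusion_matrix", class(out))
  out
}

#' Performance metrics from a confusion matrix
#'
#' Computes per-class (one-vs-rest) sensitivity, specificity, positive
#' predictive value and accuracy as percentages, the F1 score on the 0..1
#' scale, an unweighted mean row over classes, and the overall accuracy
#' (trace / total). A class with no positive samples has undefined
#' sensitivity: it is reported as `NA`, excluded from the means, and flagged
#' with a warning.
#'
#' @param cm a `confusion_matrix` (or plain square matrix with dimnames).
#' @param positive optional positive class for binary tasks (affects only
#'   which row is conventionally read first; all classes are reported).
#' @return An `evaluation_report`: list with `per_class` (data frame),
#'   `mean` (named vector), `overall_acc` (percent), `confusion` (the
#'   matrix), `classes`.
#' @export
#' @examples
#' cm <- matrix(c(90, 20, 10, 80), 2,
#'              dimnames = list(c("MI", "HC"), c("MI", "HC")))
#' compute_metrics(cm, positive = "MI")
compute_metrics <- function(cm, positive = NULL) {
  cm <- unclass(as.matrix(cm))
  if (nrow(cm) != ncol(cm) || sum(cm) == 0) stop("nonempty square matrix required")
  classes <- rownames(cm) %||% as.character(seq_len(nrow(cm)))
  if (!is.null(positive)) {
    ord <- c(match(positive, classes), setdiff(seq_along(classes), match(positive, classes)))
    cm <- cm[ord, ord, drop = FALSE]
    classes <- classes[ord]
  }
  total <- sum(cm)
  rows <- lapply(seq_along(classes), function(i) {
    tp <- cm[i, i]
    fn <- sum(cm[i, ]) - tp
    fp <- sum(cm[, i]) - tp
    tn <- total - tp - fn - fp
    sen <- if (tp + fn == 0) NA_real_ else tp / (tp + fn)
    spe <- if (tn + fp == 0) NA_real_ else tn / (tn + fp)
    ppv <- if (tp + fp == 0) NA_real_ else tp / (tp + fp)
    acc <- (tp + tn) / total
    f1 <- if (is.na(sen) || is.na(ppv) || (sen + ppv) == 0) NA_real_ else
      2 * sen * ppv / (sen + ppv)
    c(Sen = 100 * sen, Spe = 100 * spe, Ppv = 100 * ppv, Acc = 100 * acc, F1 = f1)
  })
  per_class <- as.data.frame(do.call(rbind, rows))
  rownames(per_class) <- classes
  if (anyNA(per_class$Sen)) {
    warning("class(es) without positive samples excluded from mean metrics: ",
            paste(classes[is.na(per_class$Sen)], collapse = ", "))
  }
  means <- colMeans(per_class, na.rm = TRUE)
  structure(
    list(per_class = per_class, mean = means,
         overall_acc = 100 * sum(diag(cm)) / total,
         confusion = cm, classes = classes, positive = positive),
    class = "evaluation_report"
  )
}

#' @export
print.evaluation_report <- function(x, digits = 2, ...) {
  cat(sprintf("<evaluation_report> overall Acc %.2f%%\n", x$overall_acc))
  print(round(x$per_class, digits))
  cat("mean:", paste(sprintf("%s %.2f", names(x$mean), x$mean), collapse = ", "), "\n")
  invisible(x)
}
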