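#' Classification metrics report
#'
#' Builds the confusion matrix and computes percent accuracy, micro- and
#' macro-averaged precision and recall, and the F-measure. Micro averages
#' pool true/false positives over classes, so for single-label
#' classification micro precision = micro recall = accuracy/100 (asserted
#' internally). Macro averages are unweighted means over classes; a class
#' that receives no predictions contributes precision 0 and is flagged in
#' the report. The F-measure is the harmonic mean of macro precision and
#' macro recall (a documented choice; the definition is often left
#' unstated in the literature).
#'
#' @param true_labels,predicted_labels Vectors of equal length over a finite
#'   class set (factors or characters).
#' @return Object of class `rpo_metrics`: list with `accuracy` (percent),
#'   `micro_precision`, `micro_recall`, `macro_precision`, `macro_recall`,
#'   `f_measure`, `confusion` (table), `per_class` (data.frame) and
#'   `zero_prediction_classes` (character).
#' @examples
#' evaluate_metrics(c("a", "a", "b"), c("a", "b", "b"))$accuracy
#' @export
evaluate_metrics <- function(true_labels, predicted_labels) {
  if (length(true_labels) != length(predicted_labels)) {
    stop("label vectors must have equal length", call. = FALSE)
  }
  classes <- sort(unique(c(as.character(true_labels),
                           as.character(predicted_labels))))
  truth <- factor(as.character(true_labels), levels = classes)
  pred <- factor(as.character(predicted_labels), levels = classes)
  cm <- table(truth = truth, predicted = pred)

  tp <- diag(cm)
  pred_n <- colSums(cm)
  true_n <- rowSums(cm)
  precision <- ifelse(pred_n > 0, tp / pred_n, 0)
  recall <- ifelse(true_n > 0, tp / true_n, 0)

  accuracy <- 100 * sum(tp) / sum(cm)
  micro_p <- sum(tp) / sum(pred_n) # pooled over classes
  micro_r <- sum(tp) / sum(true_n)
  stopifnot(abs(micro_p - accuracy / 100) < 1e-12,
            abs(micro_r - accuracy / 100) < 1e-12)
  macro_p <- mean(precision)
  macro_r <- mean(recall)
  f_meas <- if (macro_p + macro_r > 0) {
    2 * macro_p * macro_r / (macro_p + macro_r)
  } else 0

  structure(
    list(accuracy = accuracy, micro_precision = micro_p,
         micro_recall = micro_r, macro_precision = macro_p,
         macro_recall = macro_r, f_measure = f_meas, confusion = cm,
         per_class = data.frame(class = classes, precision = precision,
                                recall = recall, row.names = NULL),
         zero_prediction_classes = classes[pred_n == 0]),
    class = "rpo_metrics"
  )
}

#' @export
print.rpo_metrics <- function(x, ...) {
  cat(sprintf("<rpo_metrics> accuracy %.2f%% | micro P=R %.4f | macro P %.4f R %.4f | F %.4f\n",
              x$accuracy, x$micro_precision, x$macro_precision,
              x$macro_recall, x$f_measure))
  if (length(x$zero_prediction_classes)) {
    cat("  classes never predicted:",
        paste(x$zero_prediction_classes, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Nominal execution-time metric
#'
#' The cost of a wrapper feature-selection run is summarized as
#' `n * z`: agents times realized iterations (`z = z_o` when the early stop
#' fired before the full budget).
#'
#' @param n Number of search agents.
#' @param z Realized iteration count.
#' @return The integer product `n * z`.
#' @examples
#' execution_time_metric(25, 50)
#' @export
execution_time_metric <- function(n, z) {
  n <- as.integer(n); z <- as.integer(z)
  if (is.na(n) || is.na(z) || n < 0L || z < 0L) {
    stop("`n` and `z` must be non-negative integers", call. = FALSE)
  }
  n * z
}
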