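# Confusion-matrix construction and the four screening metrics
# (accuracy, precision, recall as percentages; F1 on the unit scale),
# with "adulterated" as the positive class.

#' Confusion matrix for binary adulteration screening
#'
#' Positive class = adulterated (label 1): TP counts adulterated samples
#' flagged adulterated, TN pure samples cleared, FP pure samples wrongly
#' flagged, FN adulterated samples missed.
#'
#' @param y_true,y_pred equal-length vectors of 0/1 labels.
#' @return an object of class `confusion_matrix` with fields TP, TN, FP, FN.
#' @export
confusion_matrix <- function(y_true, y_pred) {
  y_true <- as.integer(y_true)
  y_pred <- as.integer(y_pred)
  if (length(y_true) != length(y_pred)) {
    stop("y_true and y_pred must have the same length", call. = FALSE)
  }
  if (length(y_true) < 1L) stop("need at least one sample", call. = FALSE)
  if (!all(y_true %in% c(0L, 1L)) || !all(y_pred %in% c(0L, 1L))) {
    stop("labels must be 0 or 1", call. = FALSE)
  }
  structure(list(TP = sum(y_true == 1L & y_pred == 1L),
                 TN = sum(y_true == 0L & y_pred == 0L),
                 FP = sum(y_true == 0L & y_pred == 1L),
                 FN = sum(y_true == 1L & y_pred == 0L)),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion_matrix> TP=%d TN=%d FP=%d FN=%d\n",
              x$TP, x$TN, x$FP, x$FN))
  invisible(x)
}

#' Screening metrics from a confusion matrix
#'
#' Accuracy `(TP+TN)/total`, precision `TP/(TP+FP)` and recall `TP/(TP+FN)`
#' as percentages; F1 as the harmonic mean of precision and recall on the
#' unit scale. A metric whose denominator is zero is reported as `NA`
#' (undefined), never raised as an error; F1 is `NA` whenever precision or
#' recall is.
#'
#' @param cm a [confusion_matrix()].
#' @return an object of class `metrics_report` with fields ACC, PRE, REC
#'   (percent) and F1 (unit scale), unrounded.
#' @export
compute_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  total <- cm$TP + cm$TN + cm$FP + cm$FN
  if (total < 1L) stop("empty confusion matrix", call. = FALSE)
  acc <- 100 * (cm$TP + cm$TN) / total
  pre <- if (cm$TP + cm$FP > 0L) 100 * cm$TP / (cm$TP + cm$FP) else NA_real_
  rec <- if (cm$TP + cm$FN > 0L) 100 * cm$TP / (cm$TP + cm$FN) else NA_real_
  f1 <- if (is.na(pre) || is.na(rec)) {
    NA_real_
  } else if (pre + rec == 0) {
    0
  } else {
    2 * pre * rec / (pre + rec) / 100
  }
  structure(list(ACC = acc, PRE = pre, REC = rec, F1 = f1),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  fmt <- function(v, d) if (is.na(v)) "undefined" else formatC(v, format = "f", digits = d)
  cat(sprintf("ACC %s%%  PRE %s%%  REC %s%%  F1 %s\n",
              fmt(x$ACC, 2), fmt(x$PRE, 2), fmt(x$REC, 2), fmt(x$F1, 4)))
  invisible(x)
}

#' @export
as.data.frame.metrics_report <- function(x, ...) {
  data.frame(ACC = x$ACC, PRE = x$PRE, REC = x$REC, F1 = x$F1)
}
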