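#' Confusion counts for binary classification
#'
#' Tallies true/false positives and negatives between true and predicted
#' labels. Labels must be binary; the positive class defaults to the first
#' level in sorted order of the true labels.
#'
#' @param y_true,y_pred equal-length label vectors.
#' @param positive the label counted as positive.
#' @return Object of class `confusion_counts` with integer fields `tp`,
#'   `tn`, `fp`, `fn` and the `positive` label.
#' @examples
#' confusion(c(1, 1, 0, 0), c(1, 0, 1, 0), positive = 1)
#' @export
confusion <- function(y_true, y_pred, positive = NULL) {
  y_true <- as.character(y_true)
  y_pred <- as.character(y_pred)
  if (length(y_true) != length(y_pred))
    stop("y_true and y_pred must have equal length", call. = FALSE)
  lev <- sort(unique(c(y_true, y_pred)))
  if (length(unique(y_true)) > 2L || length(lev) > 2L)
    stop("labels must be binary; got levels: ", paste(lev, collapse = ", "),
         call. = FALSE)
  if (is.null(positive)) positive <- sort(unique(y_true))[1L]
  positive <- as.character(positive)
  tp <- sum(y_true == positive & y_pred == positive)
  tn <- sum(y_true != positive & y_pred != positive)
  fp <- sum(y_true != positive & y_pred == positive)
  fn <- sum(y_true == positive & y_pred != positive)
  structure(list(tp = tp, tn = tn, fp = fp, fn = fn, positive = positive),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> tp=%d tn=%d fp=%d fn=%d (positive: %s)\n",
              x$tp, x$tn, x$fp, x$fn, x$positive))
  invisible(x)
}

#' Classification metrics from confusion counts
#'
#' The six standard scores:
#' \deqn{ERR = \frac{FP+FN}{FP+FN+TP+TN}, \quad ACC = 1 - ERR, \quad
#'       SPE = \frac{TN}{FP+TN},}
#' \deqn{SEN = \frac{TP}{FN+TP}, \quad PRE = \frac{TP}{FP+TP}, \quad
#'       F1 = \frac{2 \cdot PRE \cdot SEN}{PRE + SEN}.}
#' A metric whose denominator is zero (e.g. precision with no predicted
#' positives) is reported as 0 with a warning.
#'
#' @param cc a [confusion()] object.
#' @return Object of class `metrics_report` with fields `acc`, `err`,
#'   `pre`, `sen`, `spe`, `f1`, all in `[0, 1]`.
#' @examples
#' compute_metrics(confusion(c(1, 1, 0, 0), c(1, 0, 1, 0), positive = 1))
#' @export
compute_metrics <- function(cc) {
  stopifnot(inherits(cc, "confusion_counts"))
  total <- cc$tp + cc$tn + cc$fp + cc$fn
  if (total == 0L) stop("no evaluated samples", call. = FALSE)
  safe_div <- function(num, den, what) {
    if (den == 0) {
      warning("zero denominator for ", what, "; reporting 0", call. = FALSE)
      0
    } else num / den
  }
  err <- (cc$fp + cc$fn) / total
  pre <- safe_div(cc$tp, cc$fp + cc$tp, "precision")
  sen <- safe_div(cc$tp, cc$fn + cc$tp, "sensitivity")
  spe <- safe_div(cc$tn, cc$fp + cc$tn, "specificity")
  f1 <- if (pre + sen == 0) 0 else 2 * pre * sen / (pre + sen)
  structure(list(acc = 1 - err, err = err, pre = pre, sen = sen, spe = spe, f1 = f1),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> ACC %.4f  ERR %.4f  PRE %.4f  SEN %.4f  SPE %.4f  F1 %.4f\n",
              x$acc, x$err, x$pre, x$sen, x$spe, x$f1))
  invisible(x)
}
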