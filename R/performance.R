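# Thresholding de novo scores and summarising classifier performance as the
# sensitivity/specificity pair (w1, w2) the Random Draw model consumes.

#' Classify variants at a score threshold
#'
#' A variant is called "likely de novo" (class 1) iff its de novo score
#' strictly exceeds the threshold, "likely inherited" (class 0) otherwise.
#'
#' @param scores numeric de novo scores.
#' @param threshold threshold c in \[0, 1\].
#' @return Integer vector of 0/1 predicted classes.
#' @examples
#' classify_at_threshold(c(0.69, 0.7, 0.71), 0.7)
#' @export
classify_at_threshold <- function(scores, threshold) {
  stopifnot(is.numeric(scores), length(threshold) == 1L,
            threshold >= 0, threshold <= 1)
  as.integer(scores > threshold)
}

#' Estimate sensitivity and specificity from labeled predictions
#'
#' Sensitivity `w1 = P(X = 1 | I = 1)` is the fraction of true de novo
#' variants predicted de novo; specificity `w2 = P(X = 0 | I = 0)` is the
#' fraction of true inherited variants predicted inherited.
#'
#' @param labels true inheritance labels (1 = de novo).
#' @param predicted predicted classes (0/1).
#' @return Named numeric vector `c(w1 = ..., w2 = ...)`.
#' @examples
#' estimate_performance(c(1, 1, 0, 0), c(1, 0, 0, 1))
#' @export
estimate_performance <- function(labels, predicted) {
  labels <- as.integer(labels)
  predicted <- as.integer(predicted)
  stopifnot(length(labels) == length(predicted),
            all(labels %in% c(0L, 1L)), all(predicted %in% c(0L, 1L)))
  if (!any(labels == 1L))
    stop("sensitivity undefined: no true de novo variants in data")
  if (!any(labels == 0L))
    stop("specificity undefined: no true inherited variants in data")
  c(w1 = mean(predicted[labels == 1L] == 1L),
    w2 = mean(predicted[labels == 0L] == 0L))
}

#' Sensitivity/specificity across a threshold grid
#'
#' Evaluates `(w1, w2)` at each threshold.  Sensitivity is non-increasing
#' and specificity non-decreasing along the grid: raising the threshold
#' makes the classifier more conservative in calling de novo.
#'
#' @param labels true inheritance labels (1 = de novo).
#' @param scores de novo scores.
#' @param thresholds sorted threshold grid within \[0, 1\].
#' @return data.frame of class `performance_curve` with columns
#'   `threshold`, `sensitivity`, `specificity`.
#' @examples
#' pc <- performance_curve(c(1, 1, 0, 0), c(0.9, 0.4, 0.3, 0.6),
#'                         seq(0, 1, 0.25))
#' pc
#' @export
performance_curve <- function(labels, scores, thresholds = seq(0, 1, 0.01)) {
  stopifnot(all(thresholds >= 0), all(thresholds <= 1),
            !is.unsorted(thresholds))
  perf <- vapply(thresholds, function(c0)
    estimate_performance(labels, classify_at_threshold(scores, c0)),
    numeric(2))
  structure(data.frame(threshold = thresholds,
                       sensitivity = perf["w1", ],
                       specificity = perf["w2", ]),
            class = c("performance_curve", "data.frame"))
}

#' @export
print.performance_curve <- function(x, ...) {
  cat("ClassDn performance curve (", nrow(x), " thresholds)\n", sep = "")
  print.data.frame(head(as.data.frame(x), 10), row.names = FALSE, ...)
  if (nrow(x) > 10) cat("  ... ", nrow(x) - 10, " more rows\n", sep = "")
  invisible(x)
}

#' Plot a sensitivity/specificity curve
#'
#' @param x a `performance_curve`.
#' @param ... passed to `matplot`.
#' @export
plot.performance_curve <- function(x, ...) {
  graphics::matplot(x$threshold, cbind(x$sensitivity, x$specificity),
                    type = "l", lty = 1, col = c("firebrick", "steelblue"),
                    xlab = "threshold c", ylab = "rate", ylim = c(0, 1), ...)
  graphics::legend("right", c("sensitivity (w1)", "specificity (w2)"),
                   lty = 1, col = c("firebrick", "steelblue"), bty = "n")
  invisible(x)
}
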