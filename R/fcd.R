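step_peaks <- function(metrics) {
  stopifnot(inherits(metrics, "response_metrics"))
  m <- metrics[metrics$is_step & seq_len(nrow(metrics)) > 1L, , drop = FALSE]
  if (nrow(m) == 0L) stop("no stimulation (step) intervals in the metrics")
  m
}

check_pair <- function(m1, m2) {
  if (!is.null(m2)) {
    if (nrow(m1) != nrow(m2)) stop("profiles have unequal interval counts")
    u1 <- attr(m1, "unit"); u2 <- attr(m2, "unit")
    if (!is.null(u1) && !is.null(u2) && !identical(u1, u2))
      stop("mixed-unit comparison: ", u1, " vs ", u2)
  }
}

#' Absolute peak-ratio statistics between fold responses
#'
#' On the per-interval peak responses `y_j` (stimulation intervals only,
#' i.e. intervals that begin with a level change), computes the three
#' absolute-ratio sequences `|y1_{j+1} / y1_j|`, `|y1_j / y1_{j+1}|` and,
#' when a second profile is supplied, `|y1_j / y2_j|`.
#'
#' @param m1 [interval_peaks()] metrics of the reference profile (A1).
#' @param m2 Optional metrics of the comparison profile (A2), aligned by
#'   interval index.
#' @return Data frame with columns `j`, `ratio_fwd`, `ratio_bwd` (length
#'   `n - 1`, `NA`-padded at the last row) and `cross` when `m2` is given.
#' @export
ratio_statistics <- function(m1, m2 = NULL) {
  check_pair(m1, m2)
  y1 <- step_peaks(m1)$peak
  if (any(y1 == 0)) stop("zero peak value: ratio undefined")
  n <- length(y1)
  out <- data.frame(j = seq_len(n),
                    ratio_fwd = c(abs(y1[-1] / y1[-n]), NA),
                    ratio_bwd = c(abs(y1[-n] / y1[-1]), NA))
  if (!is.null(m2)) {
    y2 <- step_peaks(m2)$peak
    if (any(y2 == 0)) stop("zero peak value: ratio undefined")
    out$cross <- abs(y1 / y2)
  }
  out
}

#' Relative-difference statistics between fold responses
#'
#' The three sequences `|(y1_{j+1} - y1_j) / y1_j|`,
#' `|(y1_j - y1_{j+1}) / y1_{j+1}|` and (with `m2`)
#' `|(y1_j - y2_j) / y2_j|` on stimulation-interval peaks: the 10%-amplitude
#' fold-change-detection criterion operates on these.
#'
#' @inheritParams ratio_statistics
#' @return Data frame with columns `j`, `rel_fwd`, `rel_bwd` and `cross`
#'   when `m2` is given.
#' @export
relative_difference_statistics <- function(m1, m2 = NULL) {
  check_pair(m1, m2)
  y1 <- step_peaks(m1)$peak
  if (any(y1 == 0)) stop("zero peak value: relative difference undefined")
  n <- length(y1)
  out <- data.frame(j = seq_len(n),
                    rel_fwd = c(abs((y1[-1] - y1[-n]) / y1[-n]), NA),
                    rel_bwd = c(abs((y1[-n] - y1[-1]) / y1[-1]), NA))
  if (!is.null(m2)) {
    y2 <- step_peaks(m2)$peak
    if (any(y2 == 0)) stop("zero peak value: relative difference undefined")
    out$cross <- abs((y1 - y2) / y2)
  }
  out
}

#' Fold-change-detection verdict at an amplitude threshold
#'
#' Fold-change detection is reported when all supplied per-interval values
#' (relative differences, or `|ratio - 1|` for ratio statistics) are at or
#' below the threshold, 10% by default.
#'
#' @param values Numeric vector of per-interval statistic values (`NA`s from
#'   the padded last row are dropped).
#' @param threshold Positive amplitude threshold (fraction, default 0.10).
#' @param statistic Optional statistic name carried into the report.
#' @return An `fcd_report`: list with `statistic`, `values`, `max_value`,
#'   `threshold`, `pass` and the indices of `violations`.
#' @export
fcd_verdict <- function(values, threshold = 0.10, statistic = "relative") {
  stopifnot(threshold > 0)
  values <- values[!is.na(values)]
  if (length(values) == 0L) stop("no statistic values supplied")
  viol <- which(values > threshold)
  structure(list(statistic = statistic, values = values,
                 max_value = max(values), threshold = threshold,
                 pass = length(viol) == 0L, violations = viol),
            class = "fcd_report")
}

#' @export
print.fcd_report <- function(x, ...) {
  cat(sprintf("<fcd_report> %s: max %.4f vs threshold %.2f -> %s\n",
              x$statistic, x$max_value, x$threshold,
              if (x$pass) "FCD holds" else
                paste("violated at interval(s)",
                      paste(x$violations, collapse = ", "))))
  invisible(x)
}
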