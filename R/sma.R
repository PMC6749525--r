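#' Signal magnitude area of one window
#'
#' SMA is the mean over the selected samples of the summed absolute
#' accelerations of the three axes, `(1/n) * sum(|x| + |y| + |z|)`, computed
#' on the *total* (unfiltered) acceleration. It is a cheap proxy for
#' physical-activity intensity and is the quantity the change detector
#' monitors. With `use_half = TRUE` (the default, matching the gated
#' pipeline) only the newest `ceiling(w/2)` samples of the window enter the
#' sum and the divisor is that count; under 50% overlap this is exactly the
#' stride of new samples, so every raw sample contributes to one SMA value.
#'
#' @param x a `signal_window` or an n x 3 total-acceleration matrix.
#' @param use_half use only the newest half of the window.
#' @return SMA in m/s^2 (non-negative scalar).
#' @export
compute_sma <- function(x, use_half = TRUE) {
  m <- if (inherits(x, "signal_window")) x$total else as.matrix(x)
  if (ncol(m) != 3L) stop("window must have 3 axes")
  if (nrow(m) == 0L) stop("cannot compute SMA of an empty window")
  if (use_half) {
    keep <- ceiling(nrow(m) / 2)
    m <- m[(nrow(m) - keep + 1L):nrow(m), , drop = FALSE]
  }
  sum(abs(m)) / nrow(m)
}

#' SMA series of a window set
#'
#' @param windows a `window_set` from [segment_stream()].
#' @param use_half see [compute_sma()].
#' @return numeric vector, one SMA per window in stream order, with
#'   attribute `half_window` recording the selection mode.
#' @export
sma_series <- function(windows, use_half = TRUE) {
  stopifnot(inherits(windows, "window_set"))
  v <- vapply(windows$windows, compute_sma, numeric(1), use_half = use_half)
  attr(v, "half_window") <- use_half
  v
}

#' Decide whether the activity changed between two consecutive windows
#'
#' Fires when the absolute difference of consecutive SMA values reaches the
#' threshold: `|SMA(t) - SMA(t-1)| >= T` (the difference is taken with
#' absolute value so that transitions to lower-intensity activities --
#' e.g. standing to sitting -- are detected too). Equality with the
#' threshold counts as a change.
#'
#' @param sma_t,sma_prev SMA of the current and previous window (m/s^2).
#' @param threshold non-negative change threshold (m/s^2).
#' @return `"new_activity"` or `"same_activity"`.
#' @export
decide_change <- function(sma_t, sma_prev, threshold) {
  if (threshold < 0) stop("threshold must be >= 0")
  # small slack so that differences mathematically equal to the threshold
  # (e.g. 0.3 - 0.1 vs 0.2) are not lost to floating-point rounding
  if (abs(sma_t - sma_prev) >= threshold - 1e-12) "new_activity"
  else "same_activity"
}

#' Gate a window sequence: classify or carry over
#'
#' Walks the SMA series in order and issues one verdict per window:
#' `classify_change` when the change rule fires (the first window always
#' classifies, since no history exists), `classify_forced` when
#' `force_every` windows have elapsed since the last classifier invocation
#' of either kind, and `carry_over` otherwise. The elapsed counter resets on
#' every classifier invocation.
#'
#' @param sma numeric SMA series (one value per window, stream order).
#' @param threshold change threshold (m/s^2).
#' @param force_every force a classification every this many windows
#'   (>= 1) when no change fires.
#' @return data frame with columns `window`, `sma`, `sma_delta` (NA for the
#'   first window), `verdict`.
#' @export
gate_windows <- function(sma, threshold = 0.2, force_every = 30L) {
  if (threshold < 0) stop("threshold must be >= 0")
  if (force_every < 1L) stop("force_every must be >= 1")
  n <- length(sma)
  if (n == 0L)
    return(data.frame(window = integer(0), sma = numeric(0),
                      sma_delta = numeric(0), verdict = character(0)))
  verdict <- character(n)
  delta <- c(NA_real_, diff(sma))
  verdict[1L] <- "classify_change"
  last_call <- 1L
  for (i in seq_len(n)[-1L]) {
    if (abs(delta[i]) >= threshold - 1e-12) {
      verdict[i] <- "classify_change"
      last_call <- i
    } else if (i - last_call >= force_every) {
      verdict[i] <- "classify_forced"
      last_call <- i
    } else {
      verdict[i] <- "carry_over"
    }
  }
  data.frame(window = seq_len(n), sma = as.numeric(sma), sma_delta = delta,
             verdict = verdict, stringsAsFactors = FALSE)
}

#' Write a gate trace to CSV
#'
#' @param trace data frame from [gate_windows()] (or a prediction trace
#'   containing its columns).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gate_trace <- function(trace, path) {
  write.csv(trace, path, row.names = FALSE)
  invisible(path)
}
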