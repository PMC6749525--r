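#' Separate body acceleration from gravity with a high-pass Butterworth filter
#'
#' Applies a third-order high-pass Butterworth filter (cutoff 0.3 Hz by
#' default) to each axis, removing the quasi-static gravity component and
#' leaving the body acceleration. Filtering is zero-phase
#' (forward-backward), so body and total channels stay time-aligned, and it
#' is applied to whole contiguous runs before any windowing so that windows
#' never contain filter edge transients from artificial boundaries.
#'
#' @param x n x 3 matrix of total acceleration (m/s^2), one contiguous run.
#' @param fs sampling rate (Hz).
#' @param cutoff high-pass cutoff frequency (Hz).
#' @param order filter order.
#' @return n x 3 matrix of body acceleration.
#' @export
highpass_body <- function(x, fs = 20, cutoff = 0.3, order = 3) {
  x <- as.matrix(x)
  if (ncol(x) != 3L) stop("x must be an n x 3 acceleration matrix")
  if (fs <= 2 * cutoff) stop("fs must exceed twice the cutoff frequency")
  minlen <- 3L * order + 1L
  if (nrow(x) < minlen)
    stop("run too short to filter: need at least ", minlen, " samples")
  bf <- signal::butter(order, cutoff / (fs / 2), type = "high")
  apply(x, 2L, function(col) zero_phase_filter(bf$b, bf$a, col))
}

# Continue a centered series for `m` samples by Burg linear prediction.
# An AR fit continues periodic gait components with the right phase, so the
# filter sees no artificial kink at the signal ends; Burg estimates are
# always stable, so the extension cannot diverge.
ar_extend <- function(x, m, max_order = 15L) {
  n <- length(x)
  if (m < 1L) return(numeric(0))
  if (sd(x) < 1e-12) return(rep(x[n], m))
  ord <- min(max_order, n - 1L)
  fit <- tryCatch(stats::ar.burg(x, aic = FALSE, order.max = ord,
                                 demean = FALSE),
                  error = function(e) NULL)
  if (is.null(fit) || fit$order == 0L) return(rep(0, m))
  cf <- fit$ar
  p <- length(cf)
  buf <- c(x[(n - p + 1L):n], numeric(m))
  for (i in seq_len(m))
    buf[p + i] <- sum(cf * buf[(p + i - 1L):(p + i - p)])
  buf[(p + 1L):(p + m)]
}

# Zero-phase filtering: forward-backward application of an IIR filter. The
# series is mean-centered, extended at both ends by linear prediction, and
# filtered with steady-state initial conditions, so a constant (gravity)
# input maps to exactly zero and periodic components pass without edge
# transients. The sample recursion runs in compiled code.
zero_phase_filter <- function(b, a, x) {
  b <- b / a[1L]; a <- a / a[1L]
  nfilt <- max(length(a), length(b))
  b <- c(b, rep(0, nfilt - length(b)))
  a <- c(a, rep(0, nfilt - length(a)))
  n <- length(x)
  if (n <= 3L * (nfilt - 1L))
    stop("signal too short for zero-phase filtering")
  # pad long enough for the slowest filter mode to ring out (~9 time
  # constants of the largest pole radius)
  r <- max(Mod(polyroot(rev(a))))
  pad <- max(3L * (nfilt - 1L),
             min(n - 1L, as.integer(ceiling(-9 / log(min(r, 0.999))))))
  mu <- mean(x)
  xc <- x - mu
  xx <- c(rev(ar_extend(rev(xc), pad)), xc, ar_extend(xc, pad))
  # steady-state filter state for a unit-step input
  K <- cbind(-a[2:nfilt], rbind(diag(1, nfilt - 2L), rep(0, nfilt - 2L)))
  zi <- solve(diag(nfilt - 1L) - K, b[2:nfilt] - b[1L] * a[2:nfilt])
  y <- iir_filter_cpp(b, a, xx, zi * xx[1L])
  y <- rev(iir_filter_cpp(b, a, rev(y), zi * y[length(y)]))
  y[(pad + 1L):(pad + n)]
}

#' Per-sample Euclidean magnitude of a tri-axial series
#'
#' @param m n x 3 matrix.
#' @return numeric vector of length n, `sqrt(x^2 + y^2 + z^2)` per row.
#' @export
magnitude <- function(m) {
  m <- as.matrix(m)
  if (ncol(m) != 3L) stop("m must be an n x 3 matrix")
  sqrt(rowSums(m^2))
}

#' Start indices of fixed-size sliding windows
#'
#' Fixed-size overlapping sliding-window (FOSW) segmentation: windows of `w`
#' samples start every `stride = round(w * (1 - overlap))` samples while they
#' fit entirely inside the run; trailing samples that do not fill a window
#' are dropped. `overlap = 0` gives the non-overlapping (FNSW) scheme.
#'
#' @param n run length in samples.
#' @param w window length in samples.
#' @param overlap fraction of overlap between consecutive windows, in [0, 1).
#' @return integer vector of 1-based start indices (possibly empty).
#' @export
fosw_starts <- function(n, w, overlap = 0.5) {
  if (overlap < 0 || overlap >= 1) stop("overlap must lie in [0, 1)")
  if (w < 1) stop("window length must be >= 1 sample")
  n <- as.integer(n)
  w <- as.integer(round(w))
  stride <- max(1L, as.integer(round(w * (1 - overlap))))
  if (n < w) return(integer(0))
  seq.int(1L, n - w + 1L, by = stride)
}

#' Segment a stream into sliding windows with body-acceleration channels
#'
#' For each contiguous run: the body acceleration is computed once for the
#' whole run with [highpass_body()], then the run is cut into fixed-size
#' windows with [fosw_starts()]. Windows never straddle run boundaries. Each
#' window keeps its total and body acceleration, its subject, its majority
#' ground-truth label (with the fraction of samples carrying it; ties are
#' broken toward the most recent samples), and its start offset.
#'
#' @param stream an `accel_stream`.
#' @param window_seconds window length in seconds (default 4.5 s = 90
#'   samples at 20 Hz).
#' @param overlap window overlap fraction (default 0.5).
#' @param fs sampling rate (Hz).
#' @param cutoff,order high-pass filter parameters, see [highpass_body()].
#' @return a `window_set`: list with `windows` (list of `signal_window`
#'   objects), `info` (one row per window: run, subject, label, purity,
#'   start), and the segmentation parameters `w`, `stride`, `fs`.
#' @export
segment_stream <- function(stream, window_seconds = 4.5, overlap = 0.5,
                           fs = 20, cutoff = 0.3, order = 3) {
  stopifnot(inherits(stream, "accel_stream"))
  w <- as.integer(round(window_seconds * fs))
  stride <- max(1L, as.integer(round(w * (1 - overlap))))
  windows <- list()
  info <- list()
  for (run in stream_runs(stream)) {
    if (nrow(run) < w) next
    total <- as.matrix(run[, c("x", "y", "z")])
    body <- highpass_body(total, fs = fs, cutoff = cutoff, order = order)
    for (s in fosw_starts(nrow(run), w, overlap)) {
      idx <- s:(s + w - 1L)
      labs <- run$label[idx]
      tab <- table(labs)
      top <- names(tab)[tab == max(tab)]
      if (length(top) > 1L) {
        # ties (e.g. a transition splitting the window in half) go to the
        # label seen most recently -- the causally sensible choice for a
        # streaming recognizer
        lab <- top[which.max(vapply(top, function(l) max(which(labs == l)),
                                    integer(1)))]
      } else lab <- top
      purity <- as.numeric(max(tab)) / w
      win <- structure(
        list(total = total[idx, , drop = FALSE],
             body = body[idx, , drop = FALSE],
             subject = run$subject[1L], label = lab, purity = purity,
             start_index = s, run = run$run[1L], w = w),
        class = "signal_window")
      windows[[length(windows) + 1L]] <- win
      info[[length(info) + 1L]] <- data.frame(
        run = run$run[1L], subject = run$subject[1L],
        label = lab, purity = purity,
        start = s, stringsAsFactors = FALSE)
    }
  }
  structure(
    list(windows = windows,
         info = if (length(info)) do.call(rbind, info) else
           data.frame(run = integer(0), subject = character(0),
                      label = character(0), purity = numeric(0),
                      start = integer(0)),
         w = w, stride = stride, fs = fs),
    class = "window_set")
}

#' @export
length.window_set <- function(x) length(x$windows)

#' @export
print.window_set <- function(x, ...) {
  cat(sprintf("<window_set> %d window(s) of %d samples (stride %d) at %g Hz\n",
              length(x$windows), x$w, x$stride, x$fs))
  invisible(x)
}
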