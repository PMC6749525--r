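#' Run the gated recognition loop over a stream
#'
#' Segments the stream, computes the half-window SMA series, gates every
#' window with [gate_windows()], and invokes the classifier only on windows
#' whose verdict demands it; all other windows carry over the most recent
#' classifier output. Gate decisions depend only on the SMA series, so the
#' classified windows can be batched through the model without changing the
#' semantics of the sequential loop (which itself needs only O(1) state:
#' last SMA, last label, elapsed counter).
#'
#' @param stream an `accel_stream`.
#' @param model a trained `har_model`.
#' @param window_seconds,overlap,fs,cutoff,order segmentation parameters,
#'   see [segment_stream()].
#' @param threshold SMA change threshold (m/s^2); 0 classifies every window.
#' @param force_every forced-classification interval in windows.
#' @param use_half compute SMA on the newest half of each window.
#' @return a `prediction_trace` data frame: one row per window with
#'   `window`, `run`, `start`, `true_label`, `purity`, `sma`, `sma_delta`,
#'   `verdict`, `source` (`"classifier"` or `"carried_over"`), and
#'   `predicted_label`.
#' @export
run_gated <- function(stream, model, window_seconds = 4.5, overlap = 0.5,
                      fs = 20, threshold = 0.2, force_every = 30L,
                      use_half = TRUE, cutoff = 0.3, order = 3) {
  stopifnot(inherits(model, "har_model"))
  w <- as.integer(round(window_seconds * fs))
  if (8L * w != prod(model$spec$input_shape))
    stop("window of ", w, " samples encodes to ", 8L * w,
         " values but the model expects ", prod(model$spec$input_shape))
  windows <- segment_stream(stream, window_seconds = window_seconds,
                            overlap = overlap, fs = fs, cutoff = cutoff,
                            order = order)
  if (length(windows) == 0L)
    stop("stream produced no windows (runs shorter than ", w, " samples)")
  sma <- sma_series(windows, use_half = use_half)
  gate <- gate_windows(sma, threshold = threshold, force_every = force_every)

  std <- !is.null(model$encoding) && !is.null(model$encoding$stats)
  enc <- encode_windows(windows,
                        height = model$spec$input_shape[1L],
                        width = model$spec$input_shape[2L],
                        standardize = std,
                        stats = if (std) model$encoding$stats else NULL)

  call_idx <- which(gate$verdict != "carry_over")
  pred_call <- predict(model, enc$images[, , call_idx, drop = FALSE])
  predicted <- character(length(sma))
  predicted[call_idx] <- pred_call
  last <- NA_character_
  for (i in seq_along(predicted)) {
    if (gate$verdict[i] == "carry_over") predicted[i] <- last
    else last <- predicted[i]
  }

  trace <- data.frame(
    window = gate$window, run = windows$info$run,
    start = windows$info$start, true_label = windows$info$label,
    purity = windows$info$purity, sma = gate$sma,
    sma_delta = gate$sma_delta, verdict = gate$verdict,
    source = ifelse(gate$verdict == "carry_over", "carried_over",
                    "classifier"),
    predicted_label = predicted, stringsAsFactors = FALSE)
  class(trace) <- c("prediction_trace", class(trace))
  trace
}

#' Evaluate a prediction trace
#'
#' Accuracy scores every window against its majority true label (windows
#' spanning an activity transition count toward the label occupying most of
#' the window); the usage rate is the fraction of windows actually sent to
#' the classifier.
#'
#' @param trace a `prediction_trace` from [run_gated()].
#' @return a `pipeline_report`: list with `accuracy`, `usage_rate`,
#'   `calls_by_cause`, `n_windows`.
#' @export
evaluate_trace <- function(trace) {
  if (is.null(trace$true_label) || anyNA(trace$true_label))
    stop("trace has no (complete) true labels to score against")
  calls <- c(classify_change = sum(trace$verdict == "classify_change"),
             classify_forced = sum(trace$verdict == "classify_forced"))
  structure(list(
    accuracy = mean(trace$predicted_label == trace$true_label),
    usage_rate = sum(calls) / nrow(trace),
    calls_by_cause = calls,
    n_windows = nrow(trace)), class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("<pipeline_report> %d windows: accuracy %.4f, usage rate %.4f\n",
              x$n_windows, x$accuracy, x$usage_rate))
  cat(sprintf("  classifier calls: %d on SMA change, %d forced\n",
              x$calls_by_cause[["classify_change"]],
              x$calls_by_cause[["classify_forced"]]))
  invisible(x)
}

#' Sweep the change threshold and record the usage-rate/accuracy trade-off
#'
#' The stream is segmented and classified once (the classifier's output for
#' a window does not depend on the threshold); each threshold then replays
#' the gate over the same SMA series, substituting carried-over labels where
#' the gate withholds the classifier. Usage rate is non-increasing in the
#' threshold.
#'
#' @inheritParams run_gated
#' @param thresholds numeric vector of thresholds to evaluate.
#' @return data frame with one row per threshold: `threshold`,
#'   `usage_rate`, `accuracy`, `calls_change`, `calls_forced`.
#' @export
threshold_sweep <- function(stream, model, thresholds, force_every = 30L,
                            window_seconds = 4.5, overlap = 0.5, fs = 20,
                            use_half = TRUE, cutoff = 0.3, order = 3) {
  if (length(thresholds) < 1L) stop("need at least one threshold")
  windows <- segment_stream(stream, window_seconds = window_seconds,
                            overlap = overlap, fs = fs, cutoff = cutoff,
                            order = order)
  sma <- sma_series(windows, use_half = use_half)
  std <- !is.null(model$encoding) && !is.null(model$encoding$stats)
  enc <- encode_windows(windows,
                        height = model$spec$input_shape[1L],
                        width = model$spec$input_shape[2L],
                        standardize = std,
                        stats = if (std) model$encoding$stats else NULL)
  all_pred <- predict(model, enc$images)
  truth <- windows$info$label
  rows <- lapply(thresholds, function(T) {
    gate <- gate_windows(sma, threshold = T, force_every = force_every)
    predicted <- character(length(sma))
    last <- NA_character_
    for (i in seq_along(predicted)) {
      if (gate$verdict[i] == "carry_over") predicted[i] <- last
      else { predicted[i] <- all_pred[i]; last <- all_pred[i] }
    }
    data.frame(threshold = T,
               usage_rate = mean(gate$verdict != "carry_over"),
               accuracy = mean(predicted == truth),
               calls_change = sum(gate$verdict == "classify_change"),
               calls_forced = sum(gate$verdict == "classify_forced"))
  })
  do.call(rbind, rows)
}

#' Segmentation and gate-usage summary of a stream corpus
#'
#' Computes, without any classifier, the quantities that characterise a
#' corpus under the gated pipeline: the number of sliding windows its runs
#' produce and the fraction of windows the gate would send to the
#' classifier. Useful for reproducing dataset-level statistics on a local
#' copy of a corpus such as WISDM v2.0.
#'
#' @inheritParams run_gated
#' @return list with `n_runs`, `n_samples`, `n_windows`, `usage_rate`,
#'   `calls_by_cause`, `skipped_records`.
#' @export
stream_report <- function(stream, window_seconds = 4.5, overlap = 0.5,
                          fs = 20, threshold = 0.2, force_every = 30L,
                          use_half = TRUE, cutoff = 0.3, order = 3) {
  windows <- segment_stream(stream, window_seconds = window_seconds,
                            overlap = overlap, fs = fs, cutoff = cutoff,
                            order = order)
  sma <- sma_series(windows, use_half = use_half)
  gate <- gate_windows(sma, threshold = threshold, force_every = force_every)
  list(n_runs = length(unique(stream$samples$run)),
       n_samples = nrow(stream$samples),
       n_windows = length(windows),
       usage_rate = if (length(windows)) mean(gate$verdict != "carry_over")
                    else NA_real_,
       calls_by_cause = c(
         classify_change = sum(gate$verdict == "classify_change"),
         classify_forced = sum(gate$verdict == "classify_forced")),
       skipped_records = stream$skipped)
}
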