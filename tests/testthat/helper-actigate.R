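# Shared fixtures, built in code at test time.

# Concatenate window sets from several streams (same segmentation settings).
merge_window_sets <- function(sets) {
  structure(list(windows = do.call(c, lapply(sets, `[[`, "windows")),
                 info = do.call(rbind, lapply(sets, `[[`, "info")),
                 w = sets[[1L]]$w, stride = sets[[1L]]$stride,
                 fs = sets[[1L]]$fs),
            class = "window_set")
}

# Window set from a multi-subject corpus of per-bout recordings.
corpus_windows <- function(n_streams, seed0, n_segments = 12L,
                           min_seconds = 60, max_seconds = 120) {
  sets <- lapply(seq_len(n_streams), function(s)
    segment_stream(generate_stream(
      random_schedule(sprintf("s%02d", s), seed0 + s,
                      n_segments = n_segments, min_seconds = min_seconds,
                      max_seconds = max_seconds),
      run_per_segment = TRUE)))
  merge_window_sets(sets)
}

# Noiseless profile variants (deterministic signals, exactly constant SMA
# for static postures).
noiseless_profiles <- function() {
  lapply(default_profiles(), function(p) {
    p$noise_sd <- 0
    p
  })
}

# A small trained recognizer shared across pipeline tests. FCN-I on ~800
# pure windows trains in seconds and is accurate enough to exercise the
# gated loop; cached so the suite trains it once.
.fixture_env <- new.env(parent = emptyenv())
tiny_model <- function() {
  if (is.null(.fixture_env$model)) {
    ws <- corpus_windows(2L, seed0 = 500L, n_segments = 12L,
                         min_seconds = 50, max_seconds = 90)
    enc <- encode_windows(ws, standardize = TRUE)
    cfg <- training_config(learning_rate = 1e-3, max_epochs = 15L,
                           patience = 4L, seed = 7L)
    .fixture_env$model <- train_model(build_spec("FCN-I"), enc$images,
                                      enc$labels, cfg,
                                      encoding = list(stats = enc$stats))
  }
  .fixture_env$model
}
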