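test_that("a noiseless static schedule reproduces pure gravity exactly", {
  profs <- noiseless_profiles()
  st <- generate_stream(activity_schedule("sitting", 10, seed = 1L),
                        profiles = profs)
  o <- profs$sitting$gravity_orientation
  expect_equal(nrow(st$samples), 200L)  # 10 s at 20 Hz
  expect_true(all(st$samples$x == 9.81 * o[1L]))
  expect_true(all(st$samples$y == 9.81 * o[2L]))
  expect_true(all(st$samples$z == 9.81 * o[3L]))
})

test_that("identical schedule and seed give bitwise-identical streams", {
  sched <- activity_schedule(c("walking", "jogging"), c(20, 20), seed = 42L)
  a <- generate_stream(sched)
  b <- generate_stream(sched)
  expect_identical(a$samples, b$samples)
  # a different seed changes the stream
  c <- generate_stream(activity_schedule(c("walking", "jogging"), c(20, 20),
                                         seed = 43L))
  expect_false(identical(a$samples$x, c$samples$x))
})

test_that("sample labels follow the schedule with at most one-sample rounding", {
  sched <- activity_schedule(c("walking", "sitting", "jogging"),
                             c(12.3, 7.7, 30), seed = 5L)
  st <- generate_stream(sched)
  expect_equal(nrow(st$samples), ceiling(50 * 20))
  counts <- table(st$samples$label)[c("walking", "sitting", "jogging")]
  expect_true(all(abs(as.numeric(counts) - c(12.3, 7.7, 30) * 20) <= 1))
})

test_that("jogging section carries strictly higher window SMA than walking", {
  st <- generate_stream(activity_schedule(c("walking", "jogging"),
                                          c(60, 60), seed = 9L))
  ws <- segment_stream(st)
  sma <- sma_series(ws)
  expect_gt(mean(sma[ws$info$label == "jogging"]),
            mean(sma[ws$info$label == "walking"]))
})

test_that("generator rejects missing profiles and bad sampling rates", {
  sched <- activity_schedule(c("walking", "cartwheeling"), c(5, 5))
  expect_error(generate_stream(sched), "cartwheeling")
  expect_error(generate_stream(activity_schedule("walking", 5), fs = -1),
               "positive")
  expect_error(generate_stream(activity_schedule("jogging", 5), fs = 5),
               "twice")
})

test_that("default profiles cover the six activities with static postures at rest", {
  profs <- default_profiles()
  expect_length(profs, 6L)
  expect_setequal(names(profs), ACTIVITY_LABELS)
  for (p in profs) {
    expect_s3_class(p, "activity_profile")
    expect_equal(sqrt(sum(p$gravity_orientation^2)), 1, tolerance = 1e-10)
  }
  expect_equal(profs$sitting$body_amplitude, 0)
  expect_equal(profs$standing$body_amplitude, 0)
})

test_that("SMA of a noiseless static window is g times the L1 norm of the orientation", {
  profs <- noiseless_profiles()
  st <- generate_stream(activity_schedule("sitting", 10, seed = 2L),
                        profiles = profs)
  win <- as.matrix(st$samples[1:45, c("x", "y", "z")])
  o <- profs$sitting$gravity_orientation
  expect_equal(compute_sma(win, use_half = FALSE), 9.81 * sum(abs(o)),
               tolerance = 1e-12)
})

test_that("jogging and walking window SMAs are separated by more than the change threshold", {
  st <- generate_stream(activity_schedule(c("walking", "jogging"),
                                          c(120, 120), seed = 31L))
  ws <- segment_stream(st)
  sma <- sma_series(ws)
  gap <- mean(sma[ws$info$label == "jogging"]) -
    mean(sma[ws$info$label == "walking"])
  expect_gt(gap, 0.2)
})

test_that("dynamic-vs-static SMA gaps exceed three within-activity standard deviations", {
  sets <- lapply(ACTIVITY_LABELS, function(lab)
    segment_stream(generate_stream(activity_schedule(lab, 120, seed = 77L))))
  names(sets) <- ACTIVITY_LABELS
  stats <- lapply(sets, function(ws) {
    s <- sma_series(ws)
    c(mean = mean(s), sd = sd(s))
  })
  dynamic <- c("walking", "jogging", "upstairs", "downstairs")
  static <- c("sitting", "standing")
  for (d in dynamic)
    for (s in static) {
      gap <- abs(stats[[d]]["mean"] - stats[[s]]["mean"])
      expect_gt(gap, 3 * max(stats[[d]]["sd"], stats[[s]]["sd"]))
    }
})
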