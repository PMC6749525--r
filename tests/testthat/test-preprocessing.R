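central <- function(n, frac = 0.8) {
  drop <- floor(n * (1 - frac) / 2)
  (drop + 1L):(n - drop)
}

test_that("the high-pass filter removes the gravity (DC) component", {
  x <- matrix(rep(c(0, 0, 9.81), each = 600), ncol = 3)
  body <- highpass_body(x, fs = 20, cutoff = 0.3, order = 3)
  idx <- central(600)
  expect_lt(max(abs(body[idx, ])), 1e-3)
})

test_that("a 5 Hz component passes with gain within 1%", {
  t <- (0:599) / 20
  s <- sin(2 * pi * 5 * t)
  x <- cbind(s, 0, 0)
  body <- highpass_body(x, fs = 20)
  idx <- central(600)
  expect_lt(max(abs(body[idx, 1] - s[idx])), 0.01)
})

test_that("DC plus 5 Hz filters to the 5 Hz component alone (superposition)", {
  t <- (0:599) / 20
  s <- sin(2 * pi * 5 * t)
  x <- cbind(s + 9.81, s - 3, 9.81)
  body <- highpass_body(x, fs = 20)
  idx <- central(600)
  expect_lt(max(abs(body[idx, 1] - s[idx])), 0.02)
  expect_lt(max(abs(body[idx, 2] - s[idx])), 0.02)
  expect_lt(max(abs(body[idx, 3])), 0.02)
})

test_that("runs too short to filter raise an informative error", {
  expect_error(highpass_body(matrix(0, 5, 3), order = 3), "at least 10")
})

test_that("magnitude matches the per-row Euclidean norm", {
  expect_equal(magnitude(matrix(c(3, 4, 0), 1)), 5)
  expect_equal(magnitude(matrix(0, 1, 3)), 0)
  set.seed(11)
  m <- matrix(rnorm(300), ncol = 3)
  brute <- vapply(seq_len(100), function(i)
    sqrt(m[i, 1]^2 + m[i, 2]^2 + m[i, 3]^2), numeric(1))
  expect_equal(magnitude(m), brute, tolerance = 1e-12)
  expect_error(magnitude(matrix(0, 3, 2)), "n x 3")
})

test_that("sliding-window starts follow the stride arithmetic", {
  expect_equal(fosw_starts(180, 90, 0.5), c(1L, 46L, 91L))
  expect_equal(fosw_starts(89, 90, 0.5), integer(0))
  expect_equal(fosw_starts(90, 90, 0.5), 1L)
  expect_error(fosw_starts(100, 90, 1), "overlap")
  expect_error(fosw_starts(100, 90, -0.1), "overlap")
})

test_that("window counts equal exhaustive enumeration of valid starts", {
  set.seed(21)
  for (L in sample(90:5000, 40)) {
    starts <- fosw_starts(L, 90, 0.5)
    brute <- integer(0)
    s <- 1L
    while (s + 90L - 1L <= L) { brute <- c(brute, s); s <- s + 45L }
    expect_identical(starts, brute)
    expect_length(starts, floor((L - 90) / 45) + 1)
  }
})

test_that("with 50% overlap every interior sample falls in exactly two windows", {
  L <- 450L
  coverage <- integer(L)
  for (s in fosw_starts(L, 90, 0.5))
    coverage[s:(s + 89L)] <- coverage[s:(s + 89L)] + 1L
  # interior = samples past the first stride and before the trailing remnant
  expect_true(all(coverage[46:405] == 2L))
})

test_that("windows never straddle run boundaries", {
  st <- generate_stream(activity_schedule(c("walking", "jogging"), c(30, 30),
                                          seed = 3L),
                        run_per_segment = TRUE)
  ws <- segment_stream(st)
  expect_true(all(ws$info$purity == 1))
  per_run <- vapply(stream_runs(st), function(run)
    length(fosw_starts(nrow(run), 90, 0.5)), integer(1))
  expect_equal(length(ws), sum(per_run))
})

test_that("transition-straddling windows take the majority label, ties to the newest", {
  st <- generate_stream(activity_schedule(c("walking", "jogging"), c(30, 30),
                                          seed = 3L))
  ws <- segment_stream(st)
  mixed <- which(ws$info$purity < 1)
  expect_gt(length(mixed), 0L)
  for (i in mixed) {
    win <- ws$windows[[i]]
    labs <- st$samples$label[win$start_index:(win$start_index + 89L)]
    tab <- table(labs)
    expect_equal(ws$info$purity[i], max(tab) / 90)
    if (length(unique(as.numeric(tab))) > 1L)
      expect_equal(ws$info$label[i], names(tab)[which.max(tab)])
    else  # exact tie: the label of the newest samples wins
      expect_equal(ws$info$label[i], labs[90L])
  }
})
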