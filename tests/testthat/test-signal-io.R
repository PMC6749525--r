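wisdm_lines <- function(...) {
  path <- withr::local_tempfile(fileext = ".txt",
                                .local_envir = parent.frame())
  writeLines(c(...), path)
  path
}

test_that("well-formed WISDM records with regular spacing form one run", {
  path <- wisdm_lines("33,Jogging,100,1.1,2.2,3.3;",
                      "33,Jogging,150,1.2,2.3,3.4;",
                      "33,Jogging,200,1.3,2.4,3.5;")
  st <- read_wisdm_raw(path)
  expect_equal(nrow(st$samples), 3L)
  expect_equal(unique(st$samples$run), 1L)
  expect_equal(st$samples$timestamp_ms, c(100, 150, 200))
  expect_equal(st$skipped, 0L)
})

test_that("malformed records are skipped and counted, the rest parsed", {
  path <- wisdm_lines("33,Jogging,100,1.1,2.2,3.3;",
                      "33,Jogging,150,1.2,2.3;",       # missing axis
                      "33,Jogging,200,1.3,2.4,3.5;")
  st <- read_wisdm_raw(path)
  expect_equal(nrow(st$samples), 2L)
  expect_equal(st$skipped, 1L)
  # a file with nothing well-formed is an error naming the path
  bad <- wisdm_lines("not,a,record", "still,not")
  expect_error(read_wisdm_raw(bad), basename(bad))
})

test_that("subject or activity changes and large gaps start new runs", {
  path <- wisdm_lines("1,Walking,100,0,0,9.8;",
                      "1,Walking,150,0,0,9.8;",
                      "1,Jogging,200,0,0,9.8;",   # activity change
                      "1,Jogging,1000,0,0,9.8;",  # gap > 250 ms
                      "2,Jogging,1050,0,0,9.8;")  # subject change
  st <- read_wisdm_raw(path)
  expect_equal(st$samples$run, c(1L, 1L, 2L, 3L, 4L))
})

test_that("non-increasing timestamps break a run rather than corrupt it", {
  path <- wisdm_lines("1,Walking,100,0,0,9.8;",
                      "1,Walking,100,0,0,9.8;",
                      "1,Walking,150,0,0,9.8;")
  st <- read_wisdm_raw(path)
  expect_equal(length(unique(st$samples$run)), 2L)
  for (run in stream_runs(st))
    expect_true(all(diff(run$timestamp_ms) > 0))
})

test_that("a synthetic stream round-trips through the WISDM dialect", {
  st <- generate_stream(random_schedule("s7", 123L, n_segments = 4L,
                                        min_seconds = 10, max_seconds = 15),
                        run_per_segment = TRUE)
  path <- withr::local_tempfile(fileext = ".txt")
  write_stream(st, path, dialect = "wisdm")
  expect_true(all(endsWith(trimws(readLines(path)), ";")))
  back <- read_wisdm_raw(path)
  expect_identical(back$samples$timestamp_ms, st$samples$timestamp_ms)
  expect_identical(back$samples$x, st$samples$x)
  expect_identical(back$samples$y, st$samples$y)
  expect_identical(back$samples$z, st$samples$z)
  expect_identical(back$samples$label, st$samples$label)
  expect_identical(back$samples$run, st$samples$run)
})

test_that("a synthetic stream round-trips through the CSV dialect", {
  st <- generate_stream(random_schedule("s8", 124L, n_segments = 3L,
                                        min_seconds = 10, max_seconds = 15),
                        run_per_segment = TRUE)
  path <- withr::local_tempfile(fileext = ".csv")
  write_stream(st, path, dialect = "csv")
  back <- read_accel_csv(path)
  expect_identical(back$samples$timestamp_ms, st$samples$timestamp_ms)
  expect_identical(back$samples$x, st$samples$x)
  expect_identical(back$samples$label, st$samples$label)
  expect_identical(back$samples$run, st$samples$run)
})

test_that("a header-only CSV file is rejected", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines("subject,label,timestamp_ms,x,y,z", path)
  expect_error(read_accel_csv(path), "no well-formed")
})

test_that("empty streams cannot be constructed or written", {
  empty <- data.frame(run = integer(0), subject = character(0),
                      label = character(0), timestamp_ms = numeric(0),
                      x = numeric(0), y = numeric(0), z = numeric(0))
  expect_error(accel_stream(empty), "must contain samples")
})
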