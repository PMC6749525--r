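#' Assemble an accelerometer stream object
#'
#' An `accel_stream` holds timestamped tri-axial samples grouped into
#' contiguous recording runs. Within a run, timestamps are strictly
#' increasing and no gap exceeds the reader's gap tolerance; downstream
#' segmentation never lets a window straddle a run boundary.
#'
#' @param samples data frame with columns `run`, `subject`, `label`,
#'   `timestamp_ms`, `x`, `y`, `z`.
#' @param source provenance string.
#' @param skipped number of malformed input records dropped while reading.
#' @param fs nominal sampling rate in Hz.
#' @return an `accel_stream` object with fields `samples`, `source`,
#'   `skipped`, `fs`.
#' @export
accel_stream <- function(samples, source = "memory", skipped = 0L, fs = 20) {
  need <- c("run", "subject", "label", "timestamp_ms", "x", "y", "z")
  if (!all(need %in% names(samples)))
    stop("samples must have columns: ", paste(need, collapse = ", "))
  if (nrow(samples) == 0L) stop("an accel_stream must contain samples")
  dt <- stats::ave(samples$timestamp_ms, samples$run,
                   FUN = function(v) c(1, diff(v)))
  if (any(dt <= 0))
    stop("timestamps must be strictly increasing within each run")
  structure(list(samples = samples, source = source,
                 skipped = as.integer(skipped), fs = fs),
            class = "accel_stream")
}

#' @export
print.accel_stream <- function(x, ...) {
  cat(sprintf("<accel_stream> %d samples, %d run(s), %d subject(s) [%s]\n",
              nrow(x$samples), length(unique(x$samples$run)),
              length(unique(x$samples$subject)), x$source))
  if (x$skipped > 0L) cat(sprintf("  %d malformed record(s) skipped\n", x$skipped))
  invisible(x)
}

#' Split samples of an accelerometer stream by recording run
#'
#' @param stream an `accel_stream`.
#' @return list of per-run data frames, in stream order.
#' @export
stream_runs <- function(stream) {
  split(stream$samples, stream$samples$run)
}

# Assign maximal contiguous run ids: a new run starts whenever the subject or
# label changes, the timestamp does not increase, or the gap exceeds the
# tolerance. Rows must already be in file order.
assign_runs <- function(df, gap_tolerance_ms) {
  n <- nrow(df)
  if (n == 0L) return(integer(0))
  brk <- rep(FALSE, n)
  if (n > 1L) {
    i <- 2:n
    dt <- df$timestamp_ms[i] - df$timestamp_ms[i - 1L]
    brk[i] <- df$subject[i] != df$subject[i - 1L] |
      df$label[i] != df$label[i - 1L] |
      dt <= 0 | dt > gap_tolerance_ms
  }
  cumsum(c(TRUE, brk[-1L]))
}

finish_read <- function(df, path, skipped, gap_tolerance_ms, source) {
  if (nrow(df) == 0L)
    stop("no well-formed accelerometer records in ", path)
  df$run <- assign_runs(df, gap_tolerance_ms)
  df <- df[, c("run", "subject", "label", "timestamp_ms", "x", "y", "z")]
  rownames(df) <- NULL
  accel_stream(df, source = source, skipped = skipped)
}

#' Read a stream in the WISDM raw dialect
#'
#' Parses plain-text records of the form `user,activity,timestamp,x,y,z;`
#' (the published WISDM convention; several records may share a physical
#' line). Malformed records are skipped and counted, never fatal. Samples are
#' grouped into maximal contiguous runs: a new run starts when the subject or
#' activity changes, the timestamp does not increase, or the timestamp gap
#' exceeds `gap_tolerance_ms`.
#'
#' @param path file to read.
#' @param gap_tolerance_ms largest within-run timestamp gap, in the timestamp
#'   units of the file. Default 250 = five nominal 20 Hz periods in ms; scale
#'   it if the file stores nanosecond timestamps.
#' @return an `accel_stream`; `$skipped` counts dropped records.
#' @export
read_wisdm_raw <- function(path, gap_tolerance_ms = 250) {
  lines <- tryCatch(readLines(path, warn = FALSE),
                    error = function(e) stop("cannot read ", path, ": ",
                                             conditionMessage(e)))
  recs <- trimws(unlist(strsplit(lines, ";", fixed = TRUE)))
  recs <- recs[nzchar(recs)]
  parts <- strsplit(recs, ",", fixed = TRUE)
  ok <- lengths(parts) == 6L
  flat <- unlist(parts[ok], use.names = FALSE)
  if (length(flat)) {
    m <- matrix(flat, ncol = 6L, byrow = TRUE)
    ts <- suppressWarnings(as.numeric(m[, 3L]))
    x <- suppressWarnings(as.numeric(m[, 4L]))
    y <- suppressWarnings(as.numeric(m[, 5L]))
    z <- suppressWarnings(as.numeric(m[, 6L]))
    good <- !(is.na(ts) | is.na(x) | is.na(y) | is.na(z)) &
      nzchar(m[, 1L]) & nzchar(m[, 2L])
    df <- data.frame(subject = m[good, 1L], label = m[good, 2L],
                     timestamp_ms = ts[good], x = x[good], y = y[good],
                     z = z[good], stringsAsFactors = FALSE)
    skipped <- sum(!ok) + sum(!good)
  } else {
    df <- data.frame(subject = character(0), label = character(0),
                     timestamp_ms = numeric(0), x = numeric(0),
                     y = numeric(0), z = numeric(0))
    skipped <- sum(!ok)
  }
  finish_read(df, path, skipped, gap_tolerance_ms, source = path)
}

#' Read a stream in the generic CSV dialect
#'
#' Expects a header `subject,label,timestamp_ms,x,y,z`. Rows with missing or
#' non-numeric values are skipped and counted. Run grouping as in
#' [read_wisdm_raw()].
#'
#' @inheritParams read_wisdm_raw
#' @return an `accel_stream`.
#' @export
read_accel_csv <- function(path, gap_tolerance_ms = 250) {
  df <- tryCatch(read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) stop("cannot read ", path, ": ",
                                          conditionMessage(e)))
  need <- c("subject", "label", "timestamp_ms", "x", "y", "z")
  if (!all(need %in% names(df)))
    stop(path, " must have columns: ", paste(need, collapse = ", "))
  df <- df[, need]
  df$subject <- as.character(df$subject)
  df$label <- as.character(df$label)
  for (col in c("timestamp_ms", "x", "y", "z"))
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  good <- stats::complete.cases(df) & nzchar(df$subject) & nzchar(df$label)
  skipped <- sum(!good)
  finish_read(df[good, , drop = FALSE], path, skipped, gap_tolerance_ms,
              source = path)
}

#' Write a stream to disk
#'
#' Writes either the generic CSV dialect (`subject,label,timestamp_ms,x,y,z`
#' with header) or the WISDM raw dialect (`user,activity,timestamp,x,y,z;`).
#' Values are written at full precision so that reading the file back
#' reproduces the samples exactly.
#'
#' @param stream an `accel_stream`.
#' @param path output file.
#' @param dialect `"csv"` or `"wisdm"`.
#' @return `path`, invisibly.
#' @export
write_stream <- function(stream, path, dialect = c("csv", "wisdm")) {
  stopifnot(inherits(stream, "accel_stream"))
  dialect <- match.arg(dialect)
  s <- stream$samples
  if (nrow(s) == 0L) stop("cannot write an empty stream")
  num <- function(v) sub("e", "E", sprintf("%.17g", v), fixed = TRUE)
  if (dialect == "csv") {
    out <- c("subject,label,timestamp_ms,x,y,z",
             paste(s$subject, s$label, num(s$timestamp_ms),
                   num(s$x), num(s$y), num(s$z), sep = ","))
  } else {
    out <- paste0(s$subject, ",", s$label, ",", num(s$timestamp_ms), ",",
                  num(s$x), ",", num(s$y), ",", num(s$z), ";")
  }
  tryCatch(writeLines(out, path),
           error = function(e) stop("cannot write ", path, ": ",
                                    conditionMessage(e)))
  invisible(path)
}
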