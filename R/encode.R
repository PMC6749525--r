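#' Stack the eight per-window signal sequences into channel rows
#'
#' Row order is fixed package-wide so that trained models and encoders stay
#' consistent: total x/y/z, body x/y/z, then the Euclidean magnitudes of the
#' total and body acceleration.
#'
#' @param window a `signal_window` (from [segment_stream()]).
#' @return 8 x w numeric matrix with named rows.
#' @export
stack_channels <- function(window) {
  stopifnot(inherits(window, "signal_window"))
  total <- window$total
  body <- window$body
  if (nrow(total) != nrow(body))
    stop("total and body series have mismatched lengths: ",
         nrow(total), " vs ", nrow(body))
  out <- rbind(t(total), t(body), magnitude(total), magnitude(body))
  rownames(out) <- c("total_x", "total_y", "total_z",
                     "body_x", "body_y", "body_z",
                     "mag_total", "mag_body")
  out
}

#' Reshape stacked channel rows into the classifier's input image
#'
#' The rows of the 8 x w matrix are concatenated top-to-bottom into one
#' sequence of length `8 * w`, then refilled row by row into a
#' `height x width` image. The mapping is a fixed bijection (row-major in
#' both directions), so [decode_image()] inverts it exactly.
#'
#' @param stacked 8 x w matrix from [stack_channels()].
#' @param height,width image dimensions; `height * width` must equal
#'   `8 * w` (720 for the defaults w = 90, 30 x 24).
#' @return `height x width` matrix with attribute `channel_order`.
#' @export
encode_image <- function(stacked, height = 30L, width = 24L) {
  if (nrow(stacked) != 8L) stop("stacked matrix must have 8 rows")
  if (length(stacked) != height * width)
    stop("cannot reshape ", nrow(stacked), " x ", ncol(stacked), " (",
         length(stacked), " values) into ", height, " x ", width, " (",
         height * width, " values)")
  img <- matrix(as.vector(t(stacked)), nrow = height, ncol = width,
                byrow = TRUE)
  attr(img, "channel_order") <- rownames(stacked)
  img
}

#' Invert [encode_image()]
#'
#' @param img matrix produced by [encode_image()].
#' @param channels number of channel rows to restore (8).
#' @return `channels x w` matrix.
#' @export
decode_image <- function(img, channels = 8L) {
  v <- as.vector(t(img))
  if (length(v) %% channels != 0L)
    stop("image size ", length(v), " is not divisible by ", channels)
  matrix(v, nrow = channels, byrow = TRUE)
}

#' Encode all windows of a window set into an image array
#'
#' Optionally z-scores each of the eight channels. When `stats` is `NULL`
#' and `standardize = TRUE`, per-channel means and standard deviations are
#' computed from these windows (training-set statistics) and returned so
#' they can be re-applied to held-out data.
#'
#' @param windows a `window_set`.
#' @param height,width image dimensions, see [encode_image()].
#' @param standardize z-score each channel.
#' @param stats optional list with `mean` and `sd` vectors of length 8, as
#'   returned by a previous call.
#' @return list with `images` (array height x width x n), `labels`
#'   (majority true label per window), and `stats` (`NULL` unless
#'   standardizing).
#' @export
encode_windows <- function(windows, height = 30L, width = 24L,
                           standardize = FALSE, stats = NULL) {
  stopifnot(inherits(windows, "window_set"))
  n <- length(windows$windows)
  stacks <- lapply(windows$windows, stack_channels)
  if (standardize) {
    if (is.null(stats)) {
      all_rows <- do.call(cbind, stacks)
      stats <- list(mean = rowMeans(all_rows),
                    sd = pmax(apply(all_rows, 1L, sd), 1e-8))
    }
    stacks <- lapply(stacks, function(s) (s - stats$mean) / stats$sd)
  } else {
    stats <- NULL
  }
  images <- array(0, dim = c(height, width, n))
  for (i in seq_len(n)) images[, , i] <- encode_image(stacks[[i]], height, width)
  list(images = images, labels = windows$info$label, stats = stats)
}
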