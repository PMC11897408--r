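#' Image frame and time-lapse containers
#'
#' An `image_frame` is a 2D intensity grid (numeric matrix, rows = image
#' rows, origin top-left, 0-based pixel-center coordinates in all geometric
#' conventions) plus the physical pixel size in micrometres and a channel
#' tag. It is the unit every operator in the package consumes. A
#' `time_lapse` is an ordered list of frames sharing a frame interval in
#' minutes.
#'
#' @param data numeric matrix of intensities (must be non-negative finite).
#' @param pixel_size_um pixel edge length in micrometres (default 0.11,
#'   a common 60x spinning-disk sampling).
#' @param channel channel tag, e.g. `"chromatin"` or `"marker"`.
#' @param frame_index 0-based index of this frame within its movie.
#' @return An `image_frame` object (matrix with attributes).
#' @examples
#' f <- image_frame(matrix(runif(64), 8, 8))
#' dim(f)
#' @export
image_frame <- function(data, pixel_size_um = 0.11, channel = "chromatin",
                        frame_index = 0L) {
  if (!is.matrix(data) || !is.numeric(data)) {
    stop("`data` must be a numeric matrix")
  }
  if (any(!is.finite(data))) stop("image contains non-finite values")
  if (!is.numeric(pixel_size_um) || pixel_size_um <= 0) {
    stop("`pixel_size_um` must be > 0")
  }
  structure(data,
            pixel_size_um = pixel_size_um,
            channel = channel,
            frame_index = as.integer(frame_index),
            class = c("image_frame", "matrix", "array"))
}

#' @rdname image_frame
#' @param x an `image_frame`.
#' @param ... ignored.
#' @export
print.image_frame <- function(x, ...) {
  cat(sprintf("<image_frame> %d x %d px, %.4g um/px, channel '%s', frame %d\n",
              nrow(x), ncol(x), attr(x, "pixel_size_um"),
              attr(x, "channel"), attr(x, "frame_index")))
  cat(sprintf("  intensity range [%.4g, %.4g]\n", min(x), max(x)))
  invisible(x)
}

#' @rdname image_frame
#' @param frames list of `image_frame` objects in temporal order.
#' @param frame_interval_min frame spacing in minutes (> 0).
#' @export
time_lapse <- function(frames, frame_interval_min) {
  if (!length(frames) || !all(vapply(frames, inherits, TRUE, "image_frame"))) {
    stop("`frames` must be a non-empty list of image_frame objects")
  }
  if (!is.numeric(frame_interval_min) || frame_interval_min <= 0) {
    stop("`frame_interval_min` must be > 0")
  }
  structure(list(frames = frames, frame_interval_min = frame_interval_min),
            class = "time_lapse")
}

#' @rdname image_frame
#' @export
print.time_lapse <- function(x, ...) {
  cat(sprintf("<time_lapse> %d frames, %.3g min interval, %d x %d px\n",
              length(x$frames), x$frame_interval_min,
              nrow(x$frames[[1]]), ncol(x$frames[[1]])))
  invisible(x)
}

#' @rdname image_frame
#' @export
length.time_lapse <- function(x) length(x$frames)

# strip image_frame attributes down to a plain matrix
as_plain_matrix <- function(x) {
  matrix(as.numeric(x), nrow(x), ncol(x))
}
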