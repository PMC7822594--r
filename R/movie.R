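#' Multi-channel time-lapse movie
#'
#' Container for a 2D multi-channel time-lapse (the maximum-projection
#' representation on which all quantification operates): a T x C x Y x X
#' intensity array with named channels and acquisition calibration.
#'
#' @param data Numeric array, dimensions T x C x Y x X, non-negative.
#' @param channels Character vector of channel names, length C.
#' @param pixel_size_um Pixel size, um/pixel (> 0).
#' @param frame_interval_min Frame interval, minutes (> 0).
#' @return A `movie` object.
#' @export
movie <- function(data, channels, pixel_size_um, frame_interval_min) {
  stopifnot(is.array(data), length(dim(data)) == 4L,
            dim(data)[2] == length(channels),
            pixel_size_um > 0, frame_interval_min > 0)
  if (any(data < 0, na.rm = TRUE)) stop("movie intensities must be non-negative")
  structure(
    list(data = data, channels = as.character(channels),
         pixel_size_um = pixel_size_um,
         frame_interval_min = frame_interval_min),
    class = "movie"
  )
}

#' @export
print.movie <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "Movie: %d frames x %d channels (%s), %d x %d px, %.3g um/px, %.3g min/frame\n",
    d[1], d[2], paste(x$channels, collapse = ", "), d[3], d[4],
    x$pixel_size_um, x$frame_interval_min
  ))
  invisible(x)
}

#' @rdname movie
#' @param x A `movie`.
#' @export
n_frames <- function(x) dim(x$data)[1]

#' @rdname movie
#' @param channel Channel name.
#' @export
channel_index <- function(x, channel) {
  i <- match(channel, x$channels)
  if (is.na(i)) {
    stop(sprintf("channel '%s' not in movie (has: %s)", channel,
                 paste(x$channels, collapse = ", ")))
  }
  i
}

#' Extract one frame of one channel as a matrix
#'
#' @param x A `movie`.
#' @param frame Frame index (1-based).
#' @param channel Channel name.
#' @return Y x X numeric matrix.
#' @export
get_frame <- function(x, frame, channel) {
  x$data[frame, channel_index(x, channel), , ]
}
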