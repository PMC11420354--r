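#' Calibrated time-lapse image stack
#'
#' The common container for all imaging data in the package: a
#' `T x C x H x W` time-lapse (stored internally as an `H x W x C x T`
#' numeric array) together with its spatial and temporal calibration.
#' All coordinates used by the package are pixel coordinates with
#' `x = column`, `y = row`, y increasing downward, and the origin at the
#' centre of pixel `(0, 0)` (so R index `[i, j]` is at `x = j - 1`,
#' `y = i - 1`).
#'
#' @param data numeric array. Accepted shapes: `H x W` (one frame, one
#'   channel), `H x W x T` (one channel) or `H x W x C x T`.
#' @param pixel_size pixel size in micrometres per pixel (isotropic).
#' @param frame_interval time between consecutive frames in seconds.
#' @param channels character vector of unique channel labels; defaults to
#'   `c("GFP", "chloroplast")` for two channels, `"ch<i>"` otherwise.
#'
#' @return An object of class `calibrated_stack`.
#' @examples
#' st <- calibrated_stack(array(0, c(8, 8, 1, 3)), pixel_size = 0.13,
#'                        frame_interval = 0.1, channels = "GFP")
#' n_frames(st)
#' @export
calibrated_stack <- function(data, pixel_size, frame_interval,
                             channels = NULL) {
  if (!is.numeric(data)) stop("`data` must be a numeric array")
  d <- dim(data)
  if (is.null(d) || length(d) == 2L) {
    data <- array(data, c(dim(as.matrix(data)), 1L, 1L))
  } else if (length(d) == 3L) {
    data <- array(data, c(d[1L], d[2L], 1L, d[3L]))
  } else if (length(d) != 4L) {
    stop("`data` must have 2, 3 or 4 dimensions")
  }
  d <- dim(data)
  if (any(d < 1L)) stop("all stack dimensions must be >= 1")
  stopifnot(is.numeric(pixel_size), length(pixel_size) == 1L,
            is.numeric(frame_interval), length(frame_interval) == 1L)
  if (pixel_size <= 0) stop("`pixel_size` must be positive")
  if (frame_interval <= 0) stop("`frame_interval` must be positive")
  if (is.null(channels)) {
    channels <- if (d[3L] == 2L) c("GFP", "chloroplast") else
      paste0("ch", seq_len(d[3L]))
  }
  if (length(channels) != d[3L]) stop("one label per channel required")
  if (anyDuplicated(channels)) stop("channel labels must be unique")
  structure(list(data = data,
                 pixel_size = pixel_size,
                 frame_interval = frame_interval,
                 channels = as.character(channels)),
            class = "calibrated_stack")
}

#' @rdname calibrated_stack
#' @param x a `calibrated_stack`.
#' @export
n_frames <- function(x) {
  stopifnot(inherits(x, "calibrated_stack"))
  dim(x$data)[4L]
}

#' @rdname calibrated_stack
#' @export
n_channels <- function(x) {
  stopifnot(inherits(x, "calibrated_stack"))
  dim(x$data)[3L]
}

#' Extract a single frame of one channel as a matrix
#'
#' @param x a `calibrated_stack`.
#' @param frame 1-based frame index.
#' @param channel channel label or 1-based index.
#' @return `H x W` numeric matrix.
#' @export
get_frame <- function(x, frame, channel = 1L) {
  stopifnot(inherits(x, "calibrated_stack"))
  ci <- resolve_channel(x, channel)
  if (frame < 1L || frame > n_frames(x)) stop("frame index out of range")
  x$data[, , ci, frame]
}

resolve_channel <- function(x, channel) {
  if (is.character(channel)) {
    ci <- match(channel, x$channels)
    if (is.na(ci)) stop("unknown channel label: ", channel)
    ci
  } else {
    ci <- as.integer(channel)
    if (ci < 1L || ci > n_channels(x)) stop("channel index out of range")
    ci
  }
}

#' @export
print.calibrated_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<calibrated_stack> %d frame(s), %d channel(s) [%s], %d x %d px\n",
    d[4L], d[3L], paste(x$channels, collapse = ", "), d[1L], d[2L]))
  cat(sprintf("  pixel size %.4g um/px, frame interval %.4g s\n",
              x$pixel_size, x$frame_interval))
  invisible(x)
}

#' @export
dim.calibrated_stack <- function(x) dim(x$data)
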