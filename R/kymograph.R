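#' Build a calibrated space-time image (kymograph)
#'
#' Collapses a band of rows of every frame into one kymograph row by
#' maximum projection: `K[t, x] = max over y in row_band of I[t, y, x]`.
#' This is the row-wise reslice-and-maximum-project construction that
#' makes the paths of fluorescent entities across the whole cell width
#' visible in a single image. Columns are space along the (registered)
#' cell axis, rows are time increasing downward.
#'
#' @param stack a [calibrated_stack()] (normally the registered GFP
#'   channel stack).
#' @param row_band `(y_min, y_max)` 1-based inclusive row range to
#'   combine; `NULL` uses all rows.
#' @param channel channel label or index.
#' @return a numeric matrix of class `kymograph` (`n_frames` rows,
#'   stack-width columns) with attributes `pixel_size`, `frame_interval`
#'   and `row_band`.
#' @export
build_kymograph <- function(stack, row_band = NULL, channel = 1L) {
  stopifnot(inherits(stack, "calibrated_stack"))
  H <- dim(stack$data)[1L]
  if (is.null(row_band)) row_band <- c(1L, H)
  row_band <- as.integer(row_band)
  if (row_band[1L] > row_band[2L] || row_band[1L] < 1L || row_band[2L] > H)
    stop("empty or out-of-range row band")
  ci <- resolve_channel(stack, channel)
  nf <- n_frames(stack)
  W <- dim(stack$data)[2L]
  K <- matrix(NA_real_, nf, W)
  band <- row_band[1L]:row_band[2L]
  for (f in seq_len(nf)) {
    fr <- stack$data[band, , ci, f, drop = FALSE]
    dim(fr) <- c(length(band), W)
    K[f, ] <- do.call(pmax, c(asplit(fr, 1L), list(na.rm = FALSE)))
  }
  kymograph(K, stack$pixel_size, stack$frame_interval, row_band)
}

#' @rdname build_kymograph
#' @param data kymograph matrix (rows = time, columns = space).
#' @param pixel_size micrometres per pixel along the space axis.
#' @param frame_interval seconds per row.
#' @export
kymograph <- function(data, pixel_size, frame_interval, row_band = NULL) {
  stopifnot(is.matrix(data), pixel_size > 0, frame_interval > 0)
  structure(data, pixel_size = pixel_size, frame_interval = frame_interval,
            row_band = row_band, class = c("kymograph", "matrix", "array"))
}

#' @export
print.kymograph <- function(x, ...) {
  cat(sprintf("<kymograph> %d time rows x %d space columns\n",
              nrow(x), ncol(x)))
  cat(sprintf("  %.4g um/px (space), %.4g s/row (time)\n",
              attr(x, "pixel_size"), attr(x, "frame_interval")))
  invisible(x)
}

#' Display a kymograph
#'
#' @param x a `kymograph`.
#' @param ... passed to [graphics::image()].
#' @export
plot.kymograph <- function(x, ...) {
  px <- attr(x, "pixel_size"); dt <- attr(x, "frame_interval")
  graphics::image(x = (seq_len(ncol(x)) - 1) * px,
                  y = (seq_len(nrow(x)) - 1) * dt,
                  z = t(x)[, rev(seq_len(nrow(x))), drop = FALSE],
                  col = grDevices::gray.colors(256, 0, 1),
                  xlab = "position (um)", ylab = "time (s)",
                  useRaster = TRUE, ...)
  invisible(x)
}

#' Remove horizontal interference stripes by Fourier notch filtering
#'
#' Horizontal stripes (rows of constant offset, e.g. interference
#' patterns or sudden changes of the cell's z-position) carry all their
#' energy at zero spatial frequency along the space axis. The filter
#' takes the 2D FFT of the kymograph, zeroes a `mask_width`-pixel-wide
#' vertical strip of the centred spectrum (zero spatial frequency, all
#' temporal frequencies) while preserving the DC coefficient so the mean
#' intensity is unchanged, and returns the real part of the inverse
#' transform. The strip grows outward from the zero-frequency column
#' (`{0}`, `{0, -1}`, `{0, -1, +1}`, ...) and is always applied together
#' with its conjugate mirror, as editing the (conjugate-symmetric)
#' spectrum of a real image implies; the filtered image is therefore
#' exactly real and carries exactly zero energy at the masked
#' frequencies.
#'
#' @param kymo a [kymograph()].
#' @param mask_width width of the notch strip in frequency pixels.
#' @return the filtered `kymograph` (same dimensions and calibration).
#' @export
fourier_stripe_filter <- function(kymo, mask_width = 2L) {
  stopifnot(inherits(kymo, "kymograph"))
  mask_width <- as.integer(mask_width)
  if (mask_width < 1L) stop("`mask_width` must be >= 1")
  W <- ncol(kymo)
  if (mask_width >= W) stop("`mask_width` must be smaller than the width")
  K <- unclass(kymo)
  attributes(K) <- list(dim = dim(kymo))
  F <- stats::fft(K)
  offs <- stripe_mask_offsets(mask_width)
  offs <- union(offs, -offs)          # conjugate-symmetric closure
  cols <- unique((offs %% W) + 1L)
  dc <- F[1L, 1L]
  F[, cols] <- 0
  F[1L, 1L] <- dc
  out <- Re(stats::fft(F, inverse = TRUE)) / length(F)
  kymograph(out, attr(kymo, "pixel_size"), attr(kymo, "frame_interval"),
            attr(kymo, "row_band"))
}

# centred-spectrum column offsets covered by a notch of width m:
# 0, -1, +1, -2, +2, ... (even widths end on the negative side)
stripe_mask_offsets <- function(m) {
  offs <- integer(m)
  for (k in seq_len(m)) {
    offs[k] <- if (k == 1L) 0L
    else if (k %% 2L == 0L) -(k %/% 2L)
    else k %/% 2L
  }
  offs
}
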