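#' Select the reference frame for cell-frame registration
#'
#' Among frames with a valid pose, picks the frame in which the cell is
#' most nearly horizontal and closest to the centre of the field of view:
#' the frame minimising
#' `|angle| / 90 + dist(centre, FOV centre) / (diagonal / 2)`,
#' with ties broken by the earliest frame.
#'
#' @param pose a [compute_cell_pose()] result.
#' @param fov `(H, W)` of the field of view in pixels.
#' @return list of class `reference_frame`: `frame`, `center`
#'   (`c(x_px, y_px)`), `angle_deg`, `score`.
#' @export
select_reference_frame <- function(pose, fov) {
  stopifnot(inherits(pose, "cell_pose"), length(fov) == 2L)
  if (!any(pose$valid)) stop("no valid pose frames")
  H <- fov[1L]; W <- fov[2L]
  fc <- c((W - 1) / 2, (H - 1) / 2)
  half_diag <- sqrt((H - 1)^2 + (W - 1)^2) / 2
  score <- abs(pose$angle_deg) / 90 +
    sqrt((pose$cx_px - fc[1L])^2 + (pose$cy_px - fc[2L])^2) / half_diag
  score[!pose$valid] <- Inf
  best <- which.min(score)          # which.min returns the earliest minimum
  structure(list(frame = pose$frame[best],
                 center = c(pose$cx_px[best], pose$cy_px[best]),
                 angle_deg = pose$angle_deg[best],
                 score = score[best]),
            class = "reference_frame")
}

# bilinear sampling of `img` at 0-based pixel coordinates (x, y); points
# outside the image return `fill`
bilinear_sample <- function(img, x, y, fill = 0) {
  h <- nrow(img); w <- ncol(img)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  inside <- x0 >= -1 & x0 <= w - 1 & y0 >= -1 & y0 <= h - 1
  gather <- function(ix, iy) {
    ok <- inside & ix >= 0 & ix <= w - 1 & iy >= 0 & iy <= h - 1
    v <- numeric(length(ix))
    v[ok] <- img[cbind(iy[ok] + 1L, ix[ok] + 1L)]
    v
  }
  v00 <- gather(x0, y0)
  v01 <- gather(x0 + 1, y0)
  v10 <- gather(x0, y0 + 1)
  v11 <- gather(x0 + 1, y0 + 1)
  out <- (1 - fy) * ((1 - fx) * v00 + fx * v01) +
         fy * ((1 - fx) * v10 + fx * v11)
  out[!inside] <- fill
  matrix(out, nrow(x), ncol(x))
}

#' Register a stack into the cell's reference frame
#'
#' Every frame is rigidly transformed so that the tracked cell pose maps
#' onto the reference pose: the frame's cell centre is translated to the
#' reference centre and the frame is then rotated about the reference
#' centre by the pose-angle difference. Resampling is bilinear
#' (inverse mapping); pixels falling outside the source canvas are set to
#' 0. Frames with an invalid pose are emitted all-zero and flagged in the
#' `registered_valid` attribute of the result.
#'
#' @param stack a [calibrated_stack()].
#' @param pose a [compute_cell_pose()] covering every frame of `stack`.
#' @param ref a [select_reference_frame()] result.
#' @param channels channel labels or indices to register (default: all).
#' @return a `calibrated_stack` of the registered channels, with
#'   attribute `registered_valid` (logical per frame).
#' @export
register_stack <- function(stack, pose, ref, channels = NULL) {
  stopifnot(inherits(stack, "calibrated_stack"),
            inherits(pose, "cell_pose"),
            inherits(ref, "reference_frame"))
  nf <- n_frames(stack)
  if (nrow(pose) < nf) stop("pose must cover all frames of the stack")
  d <- dim(stack$data)
  H <- d[1L]; W <- d[2L]
  ch_idx <- if (is.null(channels)) seq_len(d[3L]) else
    vapply(channels, function(ch) resolve_channel(stack, ch), integer(1))
  nc <- length(ch_idx)
  xs <- (seq_len(W) - 1)
  ys <- (seq_len(H) - 1)
  Xo <- matrix(xs, H, W, byrow = TRUE)
  Yo <- matrix(ys, H, W)
  out <- array(0, c(H, W, nc, nf))
  valid <- logical(nf)
  for (f in seq_len(nf)) {
    if (!pose$valid[f]) next
    valid[f] <- TRUE
    # forward map: p_out = M(phi) (p_in - c_frame) + c_ref with
    # phi = angle_frame - angle_ref (pixel coords, y down); sample by the
    # inverse map
    phi <- (pose$angle_deg[f] - ref$angle_deg) * pi / 180
    cph <- cos(-phi); sph <- sin(-phi)
    dx <- Xo - ref$center[1L]
    dy <- Yo - ref$center[2L]
    Xi <- cph * dx - sph * dy + pose$cx_px[f]
    Yi <- sph * dx + cph * dy + pose$cy_px[f]
    for (c in seq_len(nc))
      out[, , c, f] <- bilinear_sample(stack$data[, , ch_idx[c], f], Xi, Yi)
  }
  res <- calibrated_stack(out, stack$pixel_size, stack$frame_interval,
                          stack$channels[ch_idx])
  attr(res, "registered_valid") <- valid
  attr(res, "reference_frame") <- ref
  res
}
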