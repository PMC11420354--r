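# 2D convolution, 'same' output, zero padding, via FFT; kernel dims odd
fft_convolve_same <- function(img, kernel, kernel_fft = NULL,
                              pad = NULL) {
  h <- nrow(img); w <- ncol(img)
  kh <- nrow(kernel); kw <- ncol(kernel)
  if (is.null(pad)) pad <- conv_pad_dims(dim(img), dim(kernel))
  H <- pad[1L]; W <- pad[2L]
  A <- matrix(0, H, W); A[1:h, 1:w] <- img
  if (is.null(kernel_fft)) kernel_fft <- conv_kernel_fft(kernel, pad)
  C <- Re(stats::fft(stats::fft(A) * kernel_fft, inverse = TRUE)) / (H * W)
  r0 <- (kh + 1L) %/% 2L; c0 <- (kw + 1L) %/% 2L
  C[r0:(r0 + h - 1L), c0:(c0 + w - 1L)]
}

conv_pad_dims <- function(dim_img, dim_kernel) {
  c(stats::nextn(dim_img[1L] + dim_kernel[1L] - 1L, 2L),
    stats::nextn(dim_img[2L] + dim_kernel[2L] - 1L, 2L))
}

conv_kernel_fft <- function(kernel, pad) {
  B <- matrix(0, pad[1L], pad[2L])
  B[seq_len(nrow(kernel)), seq_len(ncol(kernel))] <- kernel
  stats::fft(B)
}

# scale-normalised Laplacian-of-Gaussian kernel, sign-flipped so bright
# blobs of sd ~ sigma give a positive peak; zero-sum (flat input -> 0)
log_kernel <- function(sigma) {
  r <- ceiling(3.5 * sigma)
  x <- -r:r
  X <- matrix(x, 2L * r + 1L, 2L * r + 1L, byrow = TRUE)
  Y <- matrix(x, 2L * r + 1L, 2L * r + 1L)
  r2 <- X^2 + Y^2
  k <- -(r2 - 2 * sigma^2) / sigma^2 * exp(-r2 / (2 * sigma^2))
  k - mean(k)
}

# logical matrix of 8-neighbourhood local maxima (border excluded); ties
# on flat plateaus are broken in raster order: strictly greater than the
# neighbours already scanned (W, NW, N, NE), at least equal to the rest
local_maxima <- function(m) {
  h <- nrow(m); w <- ncol(m)
  if (h < 3L || w < 3L) return(matrix(FALSE, h, w))
  ctr <- m[2:(h - 1), 2:(w - 1)]
  ok <- ctr >  m[2:(h - 1), 1:(w - 2)] & ctr >  m[1:(h - 2), 1:(w - 2)] &
        ctr >  m[1:(h - 2), 2:(w - 1)] & ctr >  m[1:(h - 2), 3:w] &
        ctr >= m[2:(h - 1), 3:w]       & ctr >= m[3:h, 1:(w - 2)] &
        ctr >= m[3:h, 2:(w - 1)]       & ctr >= m[3:h, 3:w]
  out <- matrix(FALSE, h, w)
  out[2:(h - 1), 2:(w - 1)] <- ok
  out
}

# intensity-weighted centroid within the bounding circle, iterated to a
# fixed point; the circle is Gaussian-apodised (sigma = radius/2) so the
# discrete window edge cannot bias the sub-pixel estimate
refine_centroid <- function(img, bg, x0, y0, radius, iters = 15L,
                            tol = 1e-4) {
  h <- nrow(img); w <- ncol(img)
  x <- x0; y <- y0
  tot <- 0
  sw2 <- (radius / 2)^2
  for (it in seq_len(iters)) {
    i0 <- max(1L, floor(y + 1 - radius)); i1 <- min(h, ceiling(y + 1 + radius))
    j0 <- max(1L, floor(x + 1 - radius)); j1 <- min(w, ceiling(x + 1 + radius))
    sub <- img[i0:i1, j0:j1, drop = FALSE] - bg
    sub[sub < 0] <- 0
    xs <- (j0:j1) - 1; ys <- (i0:i1) - 1
    X <- matrix(xs, nrow(sub), ncol(sub), byrow = TRUE)
    Y <- matrix(ys, nrow(sub), ncol(sub))
    r2 <- (X - x)^2 + (Y - y)^2
    wgt <- sub * exp(-r2 / (2 * sw2)) * (r2 <= radius^2)
    tot <- sum(wgt)
    if (tot <= 0) break
    xn <- sum(wgt * X) / tot
    yn <- sum(wgt * Y) / tot
    done <- abs(xn - x) < tol && abs(yn - y) < tol
    x <- xn; y <- yn
    if (done) break
  }
  list(x = x, y = y, intensity = tot)
}

#' Detect the two chloroplast landmarks in every frame
#'
#' Fixed-scale blob detection in the autofluorescence channel: each frame
#' is convolved with a scale-normalised Laplacian-of-Gaussian kernel
#' matched to `spot_diameter`, the two strongest non-overlapping local
#' maxima are kept, and their centres are refined to sub-pixel accuracy by
#' iterated intensity-weighted centroids within the bounding circle.
#'
#' Frames with fewer than two accepted detections simply contribute fewer
#' rows (downstream linking flags them as gaps); an error is raised only
#' if no frame yields any detection.
#'
#' @param stack a [calibrated_stack()] containing the autofluorescence
#'   channel.
#' @param spot_diameter fixed bounding-circle diameter in micrometres
#'   (must lie in `[4, 8]`, bracketing the 4.5--6.0 um chloroplasts).
#' @param channel channel label or index to detect in.
#' @param n_spots number of spots to keep per frame.
#' @param response_k acceptance threshold in units of the robust (MAD)
#'   scale of the blob response; rejects noise peaks in blank frames.
#' @return data frame (`frame`, `x_px`, `y_px`, `diameter_px`,
#'   `intensity`) with 0-based pixel coordinates (`x` = column, `y` = row)
#'   and an `n_frames` attribute.
#' @export
detect_chloroplasts <- function(stack, spot_diameter = 5.6,
                                channel = "chloroplast", n_spots = 2L,
                                response_k = 6) {
  stopifnot(inherits(stack, "calibrated_stack"))
  if (spot_diameter < 4 || spot_diameter > 8)
    stop("`spot_diameter` must be within [4, 8] um")
  d_px <- spot_diameter / stack$pixel_size
  sigma <- d_px / 2.354820045
  kernel <- log_kernel(sigma)
  nf <- n_frames(stack)
  pad <- conv_pad_dims(dim(stack$data)[1:2], dim(kernel))
  kfft <- conv_kernel_fft(kernel, pad)

  rows <- vector("list", nf)
  for (f in seq_len(nf)) {
    img <- get_frame(stack, f, channel)
    bg <- stats::median(img)
    resp <- fft_convolve_same(img - bg, kernel, kernel_fft = kfft, pad = pad)
    thr <- response_k * stats::mad(resp)
    lm <- local_maxima(resp) & resp > thr
    idx <- which(lm)
    if (!length(idx)) next
    ord <- idx[order(resp[idx], decreasing = TRUE)]
    py <- (ord - 1L) %% nrow(resp)          # 0-based row
    px <- (ord - 1L) %/% nrow(resp)         # 0-based col
    keep_x <- numeric(0); keep_y <- numeric(0)
    for (k in seq_along(ord)) {
      if (length(keep_x) >= n_spots) break
      if (length(keep_x) == 0L ||
          all((keep_x - px[k])^2 + (keep_y - py[k])^2 >= d_px^2)) {
        keep_x <- c(keep_x, px[k]); keep_y <- c(keep_y, py[k])
      }
    }
    det <- lapply(seq_along(keep_x), function(k) {
      ref <- refine_centroid(img, bg, keep_x[k], keep_y[k], d_px / 2)
      data.frame(frame = f, x_px = ref$x, y_px = ref$y,
                 diameter_px = d_px, intensity = ref$intensity)
    })
    rows[[f]] <- do.call(rbind, det)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out) || nrow(out) == 0L)
    stop("no chloroplast detections in any frame")
  attr(out, "n_frames") <- nf
  out
}

#' Link per-frame detections into the two chloroplast tracks
#'
#' Nearest-neighbour assignment of each frame's detections to the two
#' tracks (minimal total displacement over the two possible pairings),
#' with gap closing by linear interpolation. Identities are protected: an
#' assignment whose two pairings cost the same within `tie_tol` raises an
#' error naming the frame. After linking, the track whose mean projection
#' onto the cell's net displacement is larger is labelled `leading`; if
#' the net displacement is below one pixel the rightmost (larger mean x)
#' track is labelled `leading` as a deterministic fallback.
#'
#' @param detections output of [detect_chloroplasts()].
#' @param max_gap maximum tolerated run of consecutive gap frames per
#'   track; longer runs raise an error.
#' @param tie_tol ambiguity tolerance (px) for identity assignment.
#' @return list with elements `leading` and `trailing`, each a data frame
#'   (`frame`, `x_px`, `y_px`, `gap`) covering every frame.
#' @export
link_tracks <- function(detections, max_gap = 5L, tie_tol = 1e-6) {
  nf <- attr(detections, "n_frames")
  if (is.null(nf)) nf <- max(detections$frame)
  per <- split(detections, factor(detections$frame, levels = seq_len(nf)))
  n_two <- sum(vapply(per, nrow, integer(1)) >= 2L)
  if (nf > 1L && n_two < nf / 2)
    stop("need two detections in at least half the frames")

  first <- which(vapply(per, nrow, integer(1)) >= 2L)[1L]
  if (is.na(first)) stop("no frame with two detections")
  ax <- rep(NA_real_, nf); ay <- rep(NA_real_, nf)
  bx <- rep(NA_real_, nf); by <- rep(NA_real_, nf)
  d0 <- per[[first]][order(per[[first]]$x_px, per[[first]]$y_px), ]
  ax[first] <- d0$x_px[1L]; ay[first] <- d0$y_px[1L]
  bx[first] <- d0$x_px[2L]; by[first] <- d0$y_px[2L]
  pa <- c(ax[first], ay[first]); pb <- c(bx[first], by[first])

  if (nf > first) for (f in (first + 1L):nf) {
    det <- per[[f]]
    nd <- if (is.null(det)) 0L else min(nrow(det), 2L)
    if (nd == 2L) {
      det <- det[order(-det$intensity), ][1:2, ]
      p1 <- c(det$x_px[1L], det$y_px[1L]); p2 <- c(det$x_px[2L], det$y_px[2L])
      c1 <- sqrt(sum((pa - p1)^2)) + sqrt(sum((pb - p2)^2))
      c2 <- sqrt(sum((pa - p2)^2)) + sqrt(sum((pb - p1)^2))
      if (abs(c1 - c2) < tie_tol)
        stop(sprintf("ambiguous track assignment at frame %d", f))
      if (c2 < c1) { tmp <- p1; p1 <- p2; p2 <- tmp }
      ax[f] <- p1[1L]; ay[f] <- p1[2L]; bx[f] <- p2[1L]; by[f] <- p2[2L]
      pa <- p1; pb <- p2
    } else if (nd == 1L) {
      p1 <- c(det$x_px[1L], det$y_px[1L])
      da <- sqrt(sum((pa - p1)^2)); db <- sqrt(sum((pb - p1)^2))
      if (abs(da - db) < tie_tol)
        stop(sprintf("ambiguous track assignment at frame %d", f))
      if (da < db) { ax[f] <- p1[1L]; ay[f] <- p1[2L]; pa <- p1 }
      else         { bx[f] <- p1[1L]; by[f] <- p1[2L]; pb <- p1 }
    }
  }

  fill <- function(x) {
    gap <- is.na(x)
    if (any(gap)) {
      runs <- rle(gap)
      if (max(runs$lengths[runs$values]) > max_gap)
        stop(sprintf("gap longer than max_gap (%d frames)", max_gap))
      x <- stats::approx(which(!gap), x[!gap], xout = seq_along(x),
                         rule = 2)$y
    }
    list(x = x, gap = gap)
  }
  fa_x <- fill(ax); fa_y <- fill(ay)
  fb_x <- fill(bx); fb_y <- fill(by)
  gap_a <- fa_x$gap | fa_y$gap
  gap_b <- fb_x$gap | fb_y$gap
  tr_a <- data.frame(frame = seq_len(nf), x_px = fa_x$x, y_px = fa_y$x,
                     gap = gap_a)
  tr_b <- data.frame(frame = seq_len(nf), x_px = fb_x$x, y_px = fb_y$x,
                     gap = gap_b)

  mx <- (tr_a$x_px + tr_b$x_px) / 2
  my <- (tr_a$y_px + tr_b$y_px) / 2
  net <- c(mx[nf] - mx[1L], my[nf] - my[1L])
  if (sqrt(sum(net^2)) >= 1) {
    u <- net / sqrt(sum(net^2))
    proj_a <- mean(tr_a$x_px * u[1L] + tr_a$y_px * u[2L])
    proj_b <- mean(tr_b$x_px * u[1L] + tr_b$y_px * u[2L])
    a_leads <- proj_a > proj_b
  } else {
    a_leads <- mean(tr_a$x_px) > mean(tr_b$x_px)
  }
  if (a_leads) list(leading = tr_a, trailing = tr_b)
  else list(leading = tr_b, trailing = tr_a)
}

#' Derive the per-frame cell pose from the two chloroplast tracks
#'
#' The cell centre is the coordinate midpoint of the two landmark centres
#' and the long-axis angle is the angle of the vector connecting them,
#' reported counter-clockwise positive in the mathematical (y-up) sense
#' and wrapped to `(-90, 90]` degrees. Frames where either track was
#' gap-filled carry `valid = FALSE`.
#'
#' @param track_a,track_b frame-aligned track data frames as produced by
#'   [link_tracks()] (order irrelevant).
#' @return data frame of class `cell_pose`: `frame`, `cx_px`, `cy_px`,
#'   `angle_deg`, `valid`.
#' @export
compute_cell_pose <- function(track_a, track_b) {
  stopifnot(nrow(track_a) == nrow(track_b),
            all(track_a$frame == track_b$frame))
  dx <- track_b$x_px - track_a$x_px
  dy <- track_b$y_px - track_a$y_px
  angle <- wrap_axis_angle(atan2(-dy, dx) * 180 / pi)
  out <- data.frame(frame = track_a$frame,
                    cx_px = (track_a$x_px + track_b$x_px) / 2,
                    cy_px = (track_a$y_px + track_b$y_px) / 2,
                    angle_deg = angle,
                    valid = !(track_a$gap | track_b$gap))
  class(out) <- c("cell_pose", class(out))
  out
}

#' Centered moving average with symmetric shrinking end windows
#'
#' The smoothing rule of the MATLAB `smooth` function: an even `window` is
#' reduced by one, and near the ends the window shrinks symmetrically so
#' that the average at index `i` always uses `x[(i-k):(i+k)]` with
#' `k = min(h, i-1, n-i)`.
#'
#' @param x numeric vector.
#' @param window nominal window length in samples (>= 1, <= `length(x)`).
#' @return smoothed vector, same length as `x`.
#' @export
moving_average <- function(x, window) {
  n <- length(x)
  if (window < 1) stop("`window` must be >= 1")
  if (window > n) stop("`window` exceeds the trace length")
  w <- as.integer(window)
  if (w %% 2L == 0L) w <- w - 1L
  h <- (w - 1L) %/% 2L
  if (h == 0L) return(x)
  cs <- cumsum(c(0, x))
  k <- pmin(h, seq_len(n) - 1L, n - seq_len(n))
  i <- seq_len(n)
  (cs[i + k + 1L] - cs[i - k]) / (2L * k + 1L)
}

#' Compute the cell's instantaneous and smoothed speed trace
#'
#' Instantaneous speed at frame `i` is the frame-to-frame displacement of
#' the cell centre divided by the frame interval,
#' `||c[i+1] - c[i]|| * pixel_size / frame_interval`; the final value is
#' repeated so the trace has one entry per frame. The smoothed trace is
#' the centered moving average of [moving_average()] (default window of
#' 20 samples).
#'
#' @param pose a [compute_cell_pose()] result.
#' @param pixel_size micrometres per pixel.
#' @param frame_interval seconds per frame.
#' @param window moving-average window, samples.
#' @return data frame of class `velocity_trace`: `frame`, `t_s`,
#'   `v_um_s`, `v_smooth_um_s`; attributes `frame_interval`, `window`.
#' @export
compute_velocity_trace <- function(pose, pixel_size, frame_interval,
                                   window = 20L) {
  stopifnot(inherits(pose, "cell_pose"))
  if (sum(pose$valid) < 2L) stop("need at least two valid pose frames")
  n <- nrow(pose)
  if (window > n) stop("`window` exceeds the trace length")
  v <- sqrt(diff(pose$cx_px)^2 + diff(pose$cy_px)^2) *
    pixel_size / frame_interval
  v <- c(v, v[length(v)])
  out <- data.frame(frame = pose$frame,
                    t_s = (pose$frame - 1L) * frame_interval,
                    v_um_s = v,
                    v_smooth_um_s = moving_average(v, window))
  attr(out, "frame_interval") <- frame_interval
  attr(out, "pixel_size") <- pixel_size
  attr(out, "window") <- window
  class(out) <- c("velocity_trace", class(out))
  out
}
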