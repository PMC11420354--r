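#' Fourier-components orientation histogram of a kymograph region
#'
#' Measures the distribution of structure orientations in a 2D intensity
#' region the way the classic Fourier-components directionality analysis
#' does: the mean-subtracted region is windowed with a 2D Hann window,
#' zero-padded to a square power of two, and the power spectrum is
#' integrated over an annulus (0.1--0.9 of the Nyquist radius by default)
#' into angular bins. Frequency-space orientations are rotated by 90
#' degrees to structure orientations, so a bundle of parallel traces of
#' orientation `alpha` produces a histogram peak at `alpha`. Orientation
#' is measured in degrees from the space (horizontal) axis toward
#' increasing row (time) and lies in `[0, 180)`: vertical (stationary)
#' traces score 90 degrees.
#'
#' A Gaussian-with-baseline model is fitted to the circularly unwrapped
#' histogram around the peak (or around `fit_center` if given); the fit
#' and its goodness (`r_squared`) drive the tier choice in
#' [estimate_batch_velocity()].
#'
#' @param roi numeric matrix, at least 16 x 16 (rows = time, columns =
#'   space).
#' @param n_bins number of orientation bins over 180 degrees (default 90,
#'   i.e. 2-degree bins).
#' @param annulus inner and outer radius of the integration annulus as
#'   fractions of the Nyquist radius.
#' @param fit_center optional bin-centre angle (deg) around which to fit
#'   the Gaussian; default is the histogram maximum.
#' @return object of class `orientation_histogram`: list with `centers`
#'   (deg), `weights` (sum 1), `bin_width`, and `fit` (`mu`, `sigma`,
#'   `amplitude`, `baseline`, `r_squared`; `r_squared` is `NA` if the fit
#'   failed to converge).
#' @export
orientation_histogram <- function(roi, n_bins = 90L,
                                  annulus = c(0.1, 0.9),
                                  fit_center = NULL) {
  roi <- as.matrix(roi)
  if (nrow(roi) < 16L || ncol(roi) < 16L)
    stop("ROI must be at least 16 x 16 px")
  if (stats::sd(roi) == 0) stop("no signal in ROI")
  hann <- function(n) 0.5 * (1 - cos(2 * pi * (0:(n - 1)) / (n - 1)))
  x <- (roi - mean(roi)) * outer(hann(nrow(roi)), hann(ncol(roi)))
  N <- 2^ceiling(log2(max(dim(roi))))
  pad <- matrix(0, N, N)
  pad[seq_len(nrow(roi)), seq_len(ncol(roi))] <- x
  P <- Mod(stats::fft(pad))^2
  f <- c(0:(N / 2 - 1), -(N / 2):-1)           # unshifted frequency index
  FX <- matrix(f, N, N, byrow = TRUE)
  FY <- matrix(f, N, N)
  r <- sqrt(FX^2 + FY^2)
  keep <- r >= annulus[1L] * N / 2 & r <= annulus[2L] * N / 2
  alpha <- (atan2(FY[keep], FX[keep]) * 180 / pi + 90) %% 180
  bw <- 180 / n_bins
  bin <- pmin(floor(alpha / bw), n_bins - 1L) + 1L
  wts <- vapply(seq_len(n_bins),
                function(b) sum(P[keep][bin == b]), numeric(1))
  if (sum(wts) == 0) stop("no signal in ROI")
  wts <- wts / sum(wts)
  centers <- (seq_len(n_bins) - 0.5) * bw

  c0 <- if (is.null(fit_center)) centers[which.max(wts)] else fit_center
  th <- c0 + ((centers - c0 + 90) %% 180) - 90   # unwrap around c0
  ord <- order(th)
  fit <- fit_gaussian_baseline(th[ord], wts[ord], c0)
  structure(list(centers = centers, weights = wts, bin_width = bw,
                 fit = fit),
            class = "orientation_histogram")
}

# least-squares Gaussian + constant baseline on (theta, w); returns a list
# with NA r_squared on failure
fit_gaussian_baseline <- function(theta, w, mu0) {
  df <- data.frame(theta = theta, w = w)
  start <- list(b = stats::median(w), A = max(w) - stats::median(w),
                mu = mu0, s = 6)
  fit <- tryCatch(
    minpack.lm::nlsLM(w ~ b + A * exp(-(theta - mu)^2 / (2 * s^2)),
                      data = df, start = start,
                      lower = c(b = 0, A = 0, mu = mu0 - 90, s = 0.5),
                      upper = c(b = Inf, A = Inf, mu = mu0 + 90, s = 90),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit))
    return(list(mu = NA_real_, sigma = NA_real_, amplitude = NA_real_,
                baseline = NA_real_, r_squared = NA_real_))
  cf <- stats::coef(fit)
  res <- stats::resid(fit)
  ss_tot <- sum((w - mean(w))^2)
  r2 <- if (ss_tot > 0) 1 - sum(res^2) / ss_tot else NA_real_
  list(mu = unname(cf["mu"]) %% 180, sigma = unname(cf["s"]),
       amplitude = unname(cf["A"]), baseline = unname(cf["b"]),
       r_squared = r2)
}

#' @export
print.orientation_histogram <- function(x, ...) {
  cat(sprintf("<orientation_histogram> %d bins of %.3g deg\n",
              length(x$weights), x$bin_width))
  if (!is.na(x$fit$r_squared))
    cat(sprintf("  Gaussian fit: mu = %.2f deg, sigma = %.2f deg, R^2 = %.3f\n",
                x$fit$mu, x$fit$sigma, x$fit$r_squared))
  invisible(x)
}

#' Convert a kymograph trace orientation to a velocity
#'
#' With orientation `alpha` measured in degrees from the space
#' (horizontal) axis, a trace advancing `cot(alpha)` space pixels per
#' time row corresponds to
#' `v = (pixel_size / frame_interval) * cot(alpha)`.
#' Vertical traces (`alpha = 90`) are stationary; `alpha < 90` means
#' motion toward +x as time advances.
#'
#' @param alpha orientation in degrees, strictly inside `(0, 180)`;
#'   orientations within 2 degrees of 0 or 180 are rejected as too fast
#'   to resolve.
#' @param pixel_size micrometres per pixel.
#' @param frame_interval seconds per row.
#' @return velocity in micrometres per second (signed).
#' @export
orientation_to_velocity <- function(alpha, pixel_size, frame_interval) {
  if (any(alpha <= 0 | alpha >= 180))
    stop("`alpha` must lie strictly inside (0, 180) degrees")
  if (any(alpha < 2 | alpha > 178))
    stop("trace too fast to resolve (orientation within 2 deg of the space axis)")
  ifelse(alpha == 90, 0,
         pixel_size / frame_interval / tan(alpha * pi / 180))
}

#' Specify a rectangular kymograph region of interest
#'
#' @param t_range `(t0, t1)` seconds; batch measurements require a 5--15 s
#'   duration (enforced by [estimate_batch_velocity()]).
#' @param col_range `(x0, x1)` 1-based inclusive column range.
#' @param half which cell half the ROI covers, `"leading"` or
#'   `"trailing"`.
#' @return list of class `roi_spec`.
#' @export
roi_spec <- function(t_range, col_range, half = c("leading", "trailing")) {
  half <- match.arg(half)
  stopifnot(length(t_range) == 2L, length(col_range) == 2L)
  if (t_range[2L] <= t_range[1L]) stop("t_range must have t1 > t0")
  if (col_range[2L] < col_range[1L]) stop("col_range must be increasing")
  structure(list(t_range = as.numeric(t_range),
                 col_range = as.integer(col_range), half = half),
            class = "roi_spec")
}

#' Estimate the batch myosin velocity in a kymograph ROI
#'
#' Applies the three-tier estimation hierarchy to the orientation
#' histogram of the ROI: (I) the peak of the Gaussian fit to the
#' orientation histogram, if its goodness of fit reaches
#' `r2_threshold` (`method = "gaussian-peak"`); (II) otherwise the local
#' maximum of the histogram nearest the strongest off-vertical mode
#' (`method = "local-max"`); tier (III), manually measured segments, is
#' exposed separately as [measure_segment()]. Vertical structure within
#' `vertical_exclusion_deg` of 90 degrees (stationary background) is
#' excluded when searching for the moving-trace mode; if no off-vertical
#' bin exceeds `mode_threshold` times the uniform level the ROI contains
#' no moving traces and an error is raised.
#'
#' @param kymo a [kymograph()] (already stripe-filtered if needed).
#' @param roi a [roi_spec()]; its time span must be 5--15 s.
#' @param r2_threshold goodness-of-fit threshold for tier (I).
#' @param n_bins orientation bins over 180 degrees.
#' @param vertical_exclusion_deg half-width of the stationary-structure
#'   exclusion zone around 90 degrees.
#' @param mode_threshold multiple of the uniform histogram level an
#'   off-vertical bin must exceed to count as a moving-trace mode.
#' @return list of class `velocity_measurement`: `roi`, `method`,
#'   `myosin_v_um_s` (signed, positive toward +x), `alpha_deg`,
#'   `histogram`, `n` (= `"batch"`).
#' @export
estimate_batch_velocity <- function(kymo, roi, r2_threshold = 0.5,
                                    n_bins = 90L,
                                    vertical_exclusion_deg = 5,
                                    mode_threshold = 1.5) {
  stopifnot(inherits(kymo, "kymograph"), inherits(roi, "roi_spec"))
  dt <- attr(kymo, "frame_interval")
  px <- attr(kymo, "pixel_size")
  dur <- diff(roi$t_range)
  if (dur < 5 || dur > 15)
    stop("batch ROI duration must be between 5 and 15 s")
  r0 <- floor(roi$t_range[1L] / dt) + 1L
  r1 <- min(nrow(kymo), ceiling(roi$t_range[2L] / dt))
  c0 <- roi$col_range[1L]; c1 <- roi$col_range[2L]
  if (r0 < 1L || r1 > nrow(kymo) || c0 < 1L || c1 > ncol(kymo))
    stop("ROI outside the kymograph")
  sub <- unclass(kymo)[r0:r1, c0:c1]

  hist0 <- orientation_histogram(sub, n_bins = n_bins)
  off <- abs(hist0$centers - 90) > vertical_exclusion_deg
  uniform <- 1 / n_bins
  cand <- off & hist0$weights > mode_threshold * uniform
  if (!any(cand))
    stop("no moving traces (no off-vertical orientation mode above threshold)")
  mode_center <- hist0$centers[which(cand)[which.max(hist0$weights[cand])]]

  hist1 <- orientation_histogram(sub, n_bins = n_bins,
                                 fit_center = mode_center)
  fit <- hist1$fit
  use_fit <- !is.na(fit$r_squared) && fit$r_squared >= r2_threshold &&
    abs(fit$mu - 90) > vertical_exclusion_deg &&
    fit$mu > 2 && fit$mu < 178
  if (use_fit) {
    alpha <- fit$mu
    method <- "gaussian-peak"
  } else {
    alpha <- mode_center
    method <- "local-max"
  }
  v <- orientation_to_velocity(alpha, px, dt)
  structure(list(roi = roi, method = method, myosin_v_um_s = v,
                 alpha_deg = alpha, histogram = hist1, n = "batch"),
            class = "velocity_measurement")
}

#' Measure the velocity of one manually identified straight segment
#'
#' Tier (III) of the estimation hierarchy: the velocity of a straight
#' kymograph segment drawn from `p0` to `p1` is
#' `pixel_size * (col1 - col0) / (frame_interval * (row1 - row0))`.
#'
#' @param kymo a [kymograph()].
#' @param p0,p1 segment endpoints `c(col, row)` (pixel units; only the
#'   differences matter).
#' @return list of class `velocity_measurement` with
#'   `method = "manual-segment"` and `n = 1`.
#' @export
measure_segment <- function(kymo, p0, p1) {
  stopifnot(inherits(kymo, "kymograph"),
            length(p0) == 2L, length(p1) == 2L)
  drow <- p1[2L] - p0[2L]
  if (drow == 0) stop("segment endpoints on the same row: infinite velocity")
  v <- attr(kymo, "pixel_size") * (p1[1L] - p0[1L]) /
    (attr(kymo, "frame_interval") * drow)
  alpha <- (atan2(drow, p1[1L] - p0[1L]) * 180 / pi) %% 180
  structure(list(roi = NULL, method = "manual-segment", myosin_v_um_s = v,
                 alpha_deg = alpha, histogram = NULL, n = 1L),
            class = "velocity_measurement")
}

#' @export
print.velocity_measurement <- function(x, ...) {
  cat(sprintf("<velocity_measurement> %s: %.3f um/s (orientation %.2f deg)\n",
              x$method, x$myosin_v_um_s, x$alpha_deg))
  invisible(x)
}

#' Find windows of smooth, sustained gliding
#'
#' Maximal runs in which the smoothed cell speed exceeds `v_min` for at
#' least `t_min` seconds; these windows anchor the rectangular ROIs of
#' the batch velocity measurements.
#'
#' @param trace a [compute_velocity_trace()] result.
#' @param v_min speed threshold (um/s), exceeded strictly.
#' @param t_min minimum window duration (s).
#' @return data frame (`t0_s`, `t1_s`, `frame0`, `frame1`); zero rows if
#'   the cell never glides.
#' @export
select_gliding_windows <- function(trace, v_min = 0.5, t_min = 5) {
  stopifnot(inherits(trace, "velocity_trace"))
  if (nrow(trace) == 0L) stop("empty velocity trace")
  dt <- attr(trace, "frame_interval")
  above <- trace$v_smooth_um_s > v_min
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths * dt >= t_min
  data.frame(t0_s = (starts[keep] - 1L) * dt,
             t1_s = ends[keep] * dt,
             frame0 = starts[keep], frame1 = ends[keep])
}

#' Pair myosin velocity measurements with the cell's velocity
#'
#' For every measurement made in a time window of the kymograph, reports
#' the myosin speed in the cell frame together with the mean smoothed
#' cell speed over the same window and their ratio, one row per
#' measurement. The mean +/- SD summary across measurements is attached
#' as the `"summary"` attribute.
#'
#' @param measurements list of `velocity_measurement` objects (batch
#'   measurements carry their ROI window; manual segments may be given a
#'   window via the `t_range` of an attached `roi`).
#' @param trace the cell's [compute_velocity_trace()].
#' @return data frame (`t0_s`, `t1_s`, `half`, `method`,
#'   `myosin_v_um_s`, `myosin_speed_um_s`, `cell_speed_um_s`, `ratio`
#'   = cell speed / myosin speed) with a `"summary"` attribute
#'   (`mean_myosin`, `sd_myosin`, `mean_cell`, `sd_cell`, `n`).
#' @export
pair_with_cell_velocity <- function(measurements, trace) {
  stopifnot(inherits(trace, "velocity_trace"))
  if (inherits(measurements, "velocity_measurement"))
    measurements <- list(measurements)
  rows <- lapply(measurements, function(m) {
    stopifnot(inherits(m, "velocity_measurement"))
    if (is.null(m$roi))
      stop("measurement carries no ROI window; cannot pair with the trace")
    tr <- m$roi$t_range
    if (tr[1L] < min(trace$t_s) - 1e-9 || tr[2L] > max(trace$t_s) + 1e-9)
      stop("measurement window outside the velocity trace span")
    inwin <- trace$t_s >= tr[1L] & trace$t_s <= tr[2L]
    cell <- mean(abs(trace$v_smooth_um_s[inwin]))
    data.frame(t0_s = tr[1L], t1_s = tr[2L], half = m$roi$half,
               method = m$method,
               myosin_v_um_s = m$myosin_v_um_s,
               myosin_speed_um_s = abs(m$myosin_v_um_s),
               cell_speed_um_s = cell,
               ratio = cell / abs(m$myosin_v_um_s))
  })
  out <- do.call(rbind, rows)
  attr(out, "summary") <- data.frame(
    mean_myosin = mean(out$myosin_speed_um_s),
    sd_myosin = stats::sd(out$myosin_speed_um_s),
    mean_cell = mean(out$cell_speed_um_s),
    sd_cell = stats::sd(out$cell_speed_um_s),
    n = nrow(out))
  out
}
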