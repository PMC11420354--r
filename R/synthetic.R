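#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed`, then restores the
#' previous RNG state, so generators are deterministic without disturbing
#' the caller's random stream.
#' @noRd
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

#' Describe a synthetic gliding-cell TIRF scenario
#'
#' Bundles every parameter of a ground-truthed dual-channel movie of an
#' elongated diatom gliding along its long axis: the trajectory
#' (piecewise-constant velocity segments), the two chloroplast landmarks
#' rendered in the autofluorescence channel, a raphe-line GFP ridge with
#' translocating myosin spots, additive noise and optional full-width
#' horizontal interference stripes.
#'
#' Headings and axis angles are degrees counter-clockwise from the image
#' +x axis in the mathematical (y-up) sense; image rows increase downward.
#'
#' @param duration movie length in seconds.
#' @param frame_interval seconds between frames (default 0.1 s, i.e. 10 fps).
#' @param pixel_size micrometres per pixel (default 0.13, the 1x tube-lens
#'   TIRF calibration).
#' @param fov `(height_px, width_px)` of the field of view.
#' @param cell_length,cell_width cell dimensions in micrometres.
#' @param trajectory data frame with columns `t0`, `t1` (s), `v` (um/s) and
#'   `heading` (deg): piecewise-constant-velocity segments. Outside the
#'   covered time span the cell is stationary at its last pose.
#' @param chloroplast_diameters two blob diameters (FWHM) in micrometres,
#'   by default within the 4.5--6.0 um range typical of the landmarks.
#' @param chloroplast_offsets signed positions of the two blobs along the
#'   cell axis, micrometres from the cell centre.
#' @param myosin_spots data frame with columns `position_um` (start position
#'   along the axis), `v_um_s` (cell-frame velocity, |v| <= 12 by default
#'   convention), `intensity`, `t_on_s`, `t_off_s`; or `NULL` for none.
#' @param noise_sd standard deviation of additive Gaussian noise
#'   (intensity counts); ignored when `noise_model = "poisson"`.
#' @param noise_model `"gaussian"` (additive, default) or `"poisson"`
#'   (shot noise with the clean image as expectation).
#' @param stripe_events list of `list(frames = c(f0, f1), rows = c(r0, r1),
#'   amplitude = a)` entries (1-based inclusive ranges); each adds a
#'   constant offset to whole rows of the GFP channel.
#' @param start_center `(x_um, y_um)` of the cell centre at `t = 0` in
#'   image coordinates, or `NULL` to centre the whole path in the FOV.
#' @param background constant background offset (counts), both channels.
#' @param chloroplast_amplitude peak amplitude of each chloroplast blob.
#' @param ridge_amplitude peak amplitude of the GFP cell-body ridge.
#' @param ridge_sigma_perp transverse sigma of the ridge in micrometres.
#' @param spot_fwhm FWHM of rendered myosin spots in micrometres
#'   (diffraction-limited by default).
#' @param rng_seed integer seed controlling all randomness.
#'
#' @return a list of class `gliding_scenario`.
#' @seealso [generate_gliding_movie()], [myosin_spot_train()]
#' @export
gliding_scenario <- function(duration = 25,
                             frame_interval = 0.1,
                             pixel_size = 0.13,
                             fov = c(120L, 800L),
                             cell_length = 40,
                             cell_width = 8,
                             trajectory = data.frame(t0 = 0, t1 = duration,
                                                     v = 2, heading = 0),
                             chloroplast_diameters = c(4.8, 5.6),
                             chloroplast_offsets = c(-10, 10),
                             myosin_spots = NULL,
                             noise_sd = 10,
                             noise_model = c("gaussian", "poisson"),
                             stripe_events = list(),
                             start_center = NULL,
                             background = 100,
                             chloroplast_amplitude = 600,
                             ridge_amplitude = 80,
                             ridge_sigma_perp = 0.5,
                             spot_fwhm = 0.4,
                             rng_seed = 1L) {
  noise_model <- match.arg(noise_model)
  if (duration <= 0) stop("`duration` must be > 0")
  if (frame_interval <= 0) stop("`frame_interval` must be > 0")
  if (pixel_size <= 0) stop("`pixel_size` must be > 0")
  fov <- as.integer(fov)
  if (length(fov) != 2L || any(fov < 8L)) stop("`fov` must be (H, W) >= 8 px")
  if (cell_length <= 0 || cell_width <= 0) stop("cell dimensions must be > 0")
  stopifnot(is.data.frame(trajectory),
            all(c("t0", "t1", "v", "heading") %in% names(trajectory)))
  trajectory <- trajectory[order(trajectory$t0), , drop = FALSE]
  if (any(trajectory$t1 <= trajectory$t0))
    stop("trajectory segments need t1 > t0")
  if (nrow(trajectory) > 1L &&
      any(trajectory$t0[-1L] < trajectory$t1[-nrow(trajectory)] - 1e-12))
    stop("trajectory segments must not overlap")
  if (length(chloroplast_diameters) != 2L || any(chloroplast_diameters <= 0))
    stop("`chloroplast_diameters` must be two positive values")
  if (length(chloroplast_offsets) != 2L)
    stop("`chloroplast_offsets` must have two entries")
  if (!is.null(myosin_spots)) {
    stopifnot(is.data.frame(myosin_spots),
              all(c("position_um", "v_um_s", "intensity",
                    "t_on_s", "t_off_s") %in% names(myosin_spots)))
  }
  if (noise_sd < 0) stop("`noise_sd` must be >= 0")
  structure(list(duration = duration, frame_interval = frame_interval,
                 pixel_size = pixel_size, fov = fov,
                 cell_length = cell_length, cell_width = cell_width,
                 trajectory = trajectory,
                 chloroplast_diameters = chloroplast_diameters,
                 chloroplast_offsets = chloroplast_offsets,
                 myosin_spots = myosin_spots,
                 noise_sd = noise_sd, noise_model = noise_model,
                 stripe_events = stripe_events,
                 start_center = start_center, background = background,
                 chloroplast_amplitude = chloroplast_amplitude,
                 ridge_amplitude = ridge_amplitude,
                 ridge_sigma_perp = ridge_sigma_perp,
                 spot_fwhm = spot_fwhm,
                 rng_seed = as.integer(rng_seed)),
            class = "gliding_scenario")
}

#' Build a train of myosin spots running pole-to-pole
#'
#' Convenience constructor for the `myosin_spots` field of
#' [gliding_scenario()]: `n` spots launched at regular intervals from one
#' cell pole, each translocating at the same cell-frame velocity until it
#' reaches the opposite pole.
#'
#' @param n number of spots.
#' @param v_um_s cell-frame velocity (um/s, signed along the axis).
#' @param cell_length cell length (um); spots run between `+/- cell_length/2`.
#' @param interval_s launch interval between consecutive spots (s).
#' @param t_start_s launch time of the first spot (s).
#' @param intensity peak intensity of each spot.
#' @return data frame suitable for `gliding_scenario(myosin_spots = ...)`.
#' @export
myosin_spot_train <- function(n, v_um_s, cell_length = 40, interval_s = 2,
                              t_start_s = 0, intensity = 150) {
  if (v_um_s == 0) stop("use a nonzero cell-frame velocity")
  start <- if (v_um_s < 0) cell_length / 2 else -cell_length / 2
  t_on <- t_start_s + interval_s * (seq_len(n) - 1L)
  data.frame(position_um = rep(start, n),
             v_um_s = rep(v_um_s, n),
             intensity = rep(intensity, n),
             t_on_s = t_on,
             t_off_s = t_on + cell_length / abs(v_um_s))
}

# closed-form trajectory integration: positions/heading/speed at times t
integrate_trajectory <- function(trajectory, t) {
  nt <- length(t)
  dx <- numeric(nt); dy <- numeric(nt)
  heading <- numeric(nt); speed <- numeric(nt)
  seg_head <- trajectory$heading
  # displacement: sum over segments of v * overlap(t0, min(t, t1))
  for (k in seq_len(nrow(trajectory))) {
    dt <- pmax(0, pmin(t, trajectory$t1[k]) - trajectory$t0[k])
    h <- seg_head[k] * pi / 180
    dx <- dx + trajectory$v[k] * dt * cos(h)
    dy <- dy - trajectory$v[k] * dt * sin(h)   # image y increases downward
  }
  # heading/speed at each time: active segment, else hold last heading, v = 0
  idx <- rep(NA_integer_, nt)
  for (k in seq_len(nrow(trajectory)))
    idx[t >= trajectory$t0[k] - 1e-12 & t < trajectory$t1[k] - 1e-12] <- k
  last_before <- vapply(t, function(ti) {
    w <- which(trajectory$t1 <= ti + 1e-12)
    if (length(w)) max(w) else 1L
  }, integer(1))
  use <- ifelse(is.na(idx), last_before, idx)
  heading <- seg_head[use]
  speed <- ifelse(is.na(idx), 0, trajectory$v[use])
  list(dx = dx, dy = dy, heading = heading, speed = speed)
}

wrap_axis_angle <- function(a) {
  a <- a %% 180
  ifelse(a > 90, a - 180, a)
}

# add an isotropic Gaussian blob (amplitude `amp`, sd `sigma_px`) to `img`
# at pixel-coordinate centre (cx, cy); evaluated analytically at pixel
# centres over a +/-4.5 sigma window
add_blob <- function(img, cx, cy, sigma_px, amp) {
  h <- nrow(img); w <- ncol(img)
  r <- ceiling(4.5 * sigma_px)
  i0 <- max(1L, floor(cy + 1 - r)); i1 <- min(h, ceiling(cy + 1 + r))
  j0 <- max(1L, floor(cx + 1 - r)); j1 <- min(w, ceiling(cx + 1 + r))
  if (i0 > i1 || j0 > j1) return(img)
  gy <- exp(-((i0:i1) - 1 - cy)^2 / (2 * sigma_px^2))
  gx <- exp(-((j0:j1) - 1 - cx)^2 / (2 * sigma_px^2))
  img[i0:i1, j0:j1] <- img[i0:i1, j0:j1] + amp * outer(gy, gx)
  img
}

# add an anisotropic Gaussian ridge centred at (cx, cy) with long axis at
# `angle_deg` (math CCW, y-up), sigmas in px
add_ridge <- function(img, cx, cy, angle_deg, sigma_long, sigma_perp, amp) {
  h <- nrow(img); w <- ncol(img)
  a <- angle_deg * pi / 180
  ux <- cos(a); uy <- -sin(a)            # axis direction in image coords
  rx <- 3.5 * (sigma_long * abs(ux) + sigma_perp * abs(uy))
  ry <- 3.5 * (sigma_long * abs(uy) + sigma_perp * abs(ux))
  i0 <- max(1L, floor(cy + 1 - ry)); i1 <- min(h, ceiling(cy + 1 + ry))
  j0 <- max(1L, floor(cx + 1 - rx)); j1 <- min(w, ceiling(cx + 1 + rx))
  if (i0 > i1 || j0 > j1) return(img)
  xs <- (j0:j1) - 1 - cx
  ys <- (i0:i1) - 1 - cy
  X <- matrix(xs, i1 - i0 + 1L, j1 - j0 + 1L, byrow = TRUE)
  Y <- matrix(ys, i1 - i0 + 1L, j1 - j0 + 1L)
  dpar <- X * ux + Y * uy
  dperp <- -X * uy + Y * ux
  img[i0:i1, j0:j1] <- img[i0:i1, j0:j1] +
    amp * exp(-dpar^2 / (2 * sigma_long^2) - dperp^2 / (2 * sigma_perp^2))
  img
}

#' Generate a ground-truthed dual-channel gliding-cell movie
#'
#' Renders the scenario into a two-channel [calibrated_stack()] (channel 1
#' `"GFP"`: cell-body ridge plus translocating myosin spots; channel 2
#' `"chloroplast"`: the two Gaussian landmark blobs) and returns exact
#' per-frame ground truth for the cell pose, cell velocity, spot positions
#' and trajectory events. Identical scenarios (including seed) produce
#' bit-identical pixel data.
#'
#' @param scenario a [gliding_scenario()].
#' @return list with elements `stack` (a `calibrated_stack`) and `truth`,
#'   where `truth` is a list of data frames: `cells` (`frame`, `t_s`,
#'   `cx_um`, `cy_um`, `cx_px`, `cy_px`, `angle_deg`, `v_um_s`), `spots`
#'   (`frame`, `t_s`, `spot`, `s_um`, `v_um_s`; `NA` while a spot is
#'   inactive) and `events` (`t_s`, `v_before`, `v_after`, `type`).
#' @examples
#' sc <- gliding_scenario(duration = 2, fov = c(64L, 256L),
#'                        cell_length = 20, chloroplast_offsets = c(-6, 6),
#'                        noise_sd = 0)
#' mv <- generate_gliding_movie(sc)
#' mv$stack
#' @export
generate_gliding_movie <- function(scenario) {
  stopifnot(inherits(scenario, "gliding_scenario"))
  s <- scenario
  px <- s$pixel_size
  nf <- max(1L, as.integer(round(s$duration / s$frame_interval)))
  t <- (seq_len(nf) - 1L) * s$frame_interval
  traj <- integrate_trajectory(s$trajectory, t)

  H <- s$fov[1L]; W <- s$fov[2L]
  fov_cx <- (W - 1) / 2 * px
  fov_cy <- (H - 1) / 2 * px
  if (is.null(s$start_center)) {
    start <- c(fov_cx - (min(traj$dx) + max(traj$dx)) / 2,
               fov_cy - (min(traj$dy) + max(traj$dy)) / 2)
  } else start <- s$start_center
  cx <- start[1L] + traj$dx
  cy <- start[2L] + traj$dy
  angle <- wrap_axis_angle(traj$heading)
  # signed speed along the reported axis direction
  v_signed <- traj$speed * cos((traj$heading - angle) * pi / 180)
  v_signed <- ifelse(abs(v_signed) < 1e-12, 0, v_signed)

  # in-FOV check: cell rectangle must intersect the FOV every frame
  a <- angle * pi / 180
  ux <- cos(a); uy <- -sin(a)
  hx <- abs(ux) * s$cell_length / 2 + abs(uy) * s$cell_width / 2
  hy <- abs(uy) * s$cell_length / 2 + abs(ux) * s$cell_width / 2
  out <- (cx + hx < -px / 2) | (cx - hx > (W - 0.5) * px) |
         (cy + hy < -px / 2) | (cy - hy > (H - 0.5) * px)
  if (any(out))
    stop(sprintf("cell fully outside the field of view at frame %d",
                 which(out)[1L]))

  sig_ch <- s$chloroplast_diameters / 2.354820045 / px   # FWHM -> sd, px
  sig_spot <- s$spot_fwhm / 2.354820045 / px
  sig_long <- s$cell_length / 4 / px
  sig_perp <- s$ridge_sigma_perp / px

  spots <- s$myosin_spots
  nspot <- if (is.null(spots)) 0L else nrow(spots)

  data <- array(s$background, c(H, W, 2L, nf))
  spot_rows <- vector("list", nf)
  for (f in seq_len(nf)) {
    uxf <- ux[f]; uyf <- uy[f]
    cxp <- cx[f] / px; cyp <- cy[f] / px
    # chloroplast channel
    ch2 <- data[, , 2L, f]
    for (b in 1:2) {
      bx <- cxp + s$chloroplast_offsets[b] / px * uxf
      by <- cyp + s$chloroplast_offsets[b] / px * uyf
      ch2 <- add_blob(ch2, bx, by, sig_ch[b], s$chloroplast_amplitude)
    }
    data[, , 2L, f] <- ch2
    # GFP channel: ridge + active spots
    ch1 <- data[, , 1L, f]
    ch1 <- add_ridge(ch1, cxp, cyp, angle[f], sig_long, sig_perp,
                     s$ridge_amplitude)
    if (nspot) {
      s_um <- spots$position_um + spots$v_um_s * (t[f] - spots$t_on_s)
      active <- t[f] >= spots$t_on_s & t[f] <= spots$t_off_s &
        abs(s_um) <= s$cell_length / 2
      for (k in which(active)) {
        ch1 <- add_blob(ch1, cxp + s_um[k] / px * uxf,
                        cyp + s_um[k] / px * uyf,
                        sig_spot, spots$intensity[k])
      }
      spot_rows[[f]] <- data.frame(
        frame = f, t_s = t[f], spot = seq_len(nspot),
        s_um = ifelse(active, s_um, NA_real_),
        v_um_s = ifelse(active, spots$v_um_s, NA_real_))
    }
    data[, , 1L, f] <- ch1
  }

  # stripes (GFP channel): constant offsets over whole rows
  for (ev in s$stripe_events) {
    fr <- ev$frames; rw <- ev$rows
    fr <- max(1L, fr[1L]):min(nf, fr[2L])
    rw <- max(1L, rw[1L]):min(H, rw[2L])
    data[rw, , 1L, fr] <- data[rw, , 1L, fr] + ev$amplitude
  }

  # noise, drawn in a fixed frame/channel order for determinism
  if (s$noise_model == "poisson" || s$noise_sd > 0) {
    data <- with_seed(s$rng_seed, {
      for (f in seq_len(nf)) for (c in 1:2) {
        fr <- data[, , c, f]
        data[, , c, f] <- if (s$noise_model == "poisson")
          array(stats::rpois(length(fr), pmax(fr, 0)), dim(fr))
        else fr + stats::rnorm(length(fr), sd = s$noise_sd)
      }
      data
    })
  }

  events <- trajectory_events(s$trajectory)
  truth <- list(
    cells = data.frame(frame = seq_len(nf), t_s = t,
                       cx_um = cx, cy_um = cy,
                       cx_px = cx / px, cy_px = cy / px,
                       angle_deg = angle, v_um_s = v_signed),
    spots = if (nspot) do.call(rbind, spot_rows) else NULL,
    events = events)
  list(stack = calibrated_stack(data, px, s$frame_interval,
                                c("GFP", "chloroplast")),
       truth = truth)
}

# segment boundaries where the (signed, along-axis) velocity changes
trajectory_events <- function(trajectory) {
  if (nrow(trajectory) < 2L)
    return(data.frame(t_s = numeric(0), v_before = numeric(0),
                      v_after = numeric(0), type = character(0)))
  ax <- wrap_axis_angle(trajectory$heading)
  vs <- trajectory$v * cos((trajectory$heading - ax) * pi / 180)
  vs <- ifelse(abs(vs) < 1e-12, 0, vs)
  out <- data.frame(t_s = numeric(0), v_before = numeric(0),
                    v_after = numeric(0), type = character(0))
  for (k in seq_len(nrow(trajectory) - 1L)) {
    vb <- vs[k]; va <- vs[k + 1L]
    if (vb == va) next
    type <- if (vb == 0) "start" else if (va == 0) "stop" else
      if (sign(vb) != sign(va)) "reversal" else "speed_change"
    out <- rbind(out, data.frame(t_s = trajectory$t1[k], v_before = vb,
                                 v_after = va, type = type))
  }
  out
}

#' Generate a ground-truthed low-magnification population motility movie
#'
#' Renders `n_cells` dark elongated cells on a bright background, each
#' gliding at its assigned constant speed along a gently curving path that
#' reverses direction at the field margins (raphid diatoms frequently
#' reverse their gliding direction, and reversal keeps every path inside
#' the field). Default calibration matches the population assay:
#' 0.91 um/px at 1 frame per second.
#'
#' @param n_cells number of cells (>= 1).
#' @param duration movie length, seconds.
#' @param speeds per-cell gliding speeds (um/s); recycled to `n_cells`;
#'   `NULL` draws log-normal speeds (median ~4 um/s).
#' @param pixel_size micrometres per pixel.
#' @param frame_interval seconds per frame.
#' @param rng_seed integer seed.
#' @param fov `(H, W)` in pixels.
#' @param cell_length,cell_width cell dimensions, micrometres.
#' @param background background intensity (counts).
#' @param depth peak darkening of a cell body below background (counts).
#' @param noise_sd additive Gaussian noise sd (counts).
#' @param curvature_deg_s heading drift rate magnitude (deg/s).
#' @return list with `stack` (single-channel `calibrated_stack`) and
#'   `truth`: `positions` (`cell`, `frame`, `t_s`, `x_um`, `y_um`) and
#'   `cells` (`cell`, `speed_um_s`, `mean_v_um_s`, `path_um`, `duration_s`).
#' @export
generate_population_movie <- function(n_cells, duration = 300, speeds = NULL,
                                      pixel_size = 0.91, frame_interval = 1,
                                      rng_seed = 1L, fov = c(512L, 512L),
                                      cell_length = 50, cell_width = 9,
                                      background = 800, depth = 350,
                                      noise_sd = 4, curvature_deg_s = 0.05) {
  if (n_cells < 1L) stop("`n_cells` must be >= 1")
  if (duration <= 0 || frame_interval <= 0 || pixel_size <= 0)
    stop("duration, frame_interval and pixel_size must be > 0")
  fov <- as.integer(fov)
  nf <- max(2L, as.integer(round(duration / frame_interval)) + 1L)
  t <- (seq_len(nf) - 1L) * frame_interval

  with_seed(rng_seed, {
    if (is.null(speeds)) speeds <- stats::rlnorm(n_cells, log(4), 0.5)
    speeds <- rep_len(speeds, n_cells)
    H <- fov[1L]; W <- fov[2L]
    margin <- cell_length / 2 + 2
    xmax <- (W - 1) * pixel_size - margin
    ymax <- (H - 1) * pixel_size - margin
    if (xmax <= margin || ymax <= margin)
      stop("field of view too small for the cell size")

    starts <- matrix(NA_real_, n_cells, 2L)
    headings0 <- numeric(n_cells)
    for (i in seq_len(n_cells)) {
      ok <- FALSE
      for (att in seq_len(100L)) {
        p <- c(stats::runif(1, margin, xmax), stats::runif(1, margin, ymax))
        if (i == 1L ||
            all(sqrt(colSums((t(starts[seq_len(i - 1L), , drop = FALSE]) -
                              p)^2)) > cell_length)) {
          starts[i, ] <- p; ok <- TRUE; break
        }
      }
      if (!ok)
        stop("overlapping initial placements after 100 attempts")
      headings0[i] <- stats::runif(1, 0, 360)
    }
    curv <- sample(c(-1, 1), n_cells, replace = TRUE) * curvature_deg_s

    xs <- matrix(NA_real_, nf, n_cells)
    ys <- matrix(NA_real_, nf, n_cells)
    hs <- matrix(NA_real_, nf, n_cells)
    for (i in seq_len(n_cells)) {
      x <- starts[i, 1L]; y <- starts[i, 2L]; h <- headings0[i]
      dirn <- 1
      for (f in seq_len(nf)) {
        xs[f, i] <- x; ys[f, i] <- y; hs[f, i] <- h
        if (f == nf) break
        hr <- h * pi / 180
        adv <- function(d) c(x + speeds[i] * frame_interval * d * cos(hr),
                             y - speeds[i] * frame_interval * d * sin(hr))
        p <- adv(dirn)
        if (p[1L] < margin || p[1L] > xmax || p[2L] < margin ||
            p[2L] > ymax) {
          dirn <- -dirn                     # reversal at the margin
          p <- adv(dirn)
        }
        x <- p[1L]; y <- p[2L]
        h <- h + curv[i] * frame_interval
      }
    }

    sig_long <- cell_length / 4 / pixel_size
    sig_perp <- cell_width / 4 / pixel_size
    data <- array(background, c(H, W, 1L, nf))
    for (f in seq_len(nf)) {
      img <- data[, , 1L, f]
      for (i in seq_len(n_cells))
        img <- add_ridge(img, xs[f, i] / pixel_size, ys[f, i] / pixel_size,
                         hs[f, i], sig_long, sig_perp, -depth)
      if (noise_sd > 0)
        img <- img + stats::rnorm(length(img), sd = noise_sd)
      data[, , 1L, f] <- pmax(img, 0)
    }

    path <- colSums(sqrt(diff(xs)^2 + diff(ys)^2))
    truth <- list(
      positions = data.frame(cell = rep(seq_len(n_cells), each = nf),
                             frame = rep(seq_len(nf), n_cells),
                             t_s = rep(t, n_cells),
                             x_um = as.vector(xs), y_um = as.vector(ys)),
      cells = data.frame(cell = seq_len(n_cells), speed_um_s = speeds,
                         mean_v_um_s = path / (t[nf] - t[1L]),
                         path_um = path, duration_s = t[nf] - t[1L]))
    list(stack = calibrated_stack(data, pixel_size, frame_interval,
                                  "brightfield"),
         truth = truth)
  })
}
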