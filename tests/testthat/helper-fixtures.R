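# Shared fixtures, all generated in code.

# small noise-free gliding movie used by tracking/registration tests
tiny_scenario <- function(noise_sd = 0, v = 1.5, duration = 6, ...) {
  gliding_scenario(
    duration = duration, frame_interval = 0.1, pixel_size = 0.13,
    fov = c(80L, 360L), cell_length = 24, cell_width = 6,
    chloroplast_offsets = c(-7, 7),
    trajectory = data.frame(t0 = 0, t1 = duration, v = v, heading = 0),
    noise_sd = noise_sd, rng_seed = 42L, ...)
}

# ground-truth chloroplast blob centres (px) for a gliding-movie truth table
truth_blob_centers <- function(truth, offsets, pixel_size) {
  a <- truth$cells$angle_deg * pi / 180
  ux <- cos(a); uy <- -sin(a)
  lapply(seq_along(offsets), function(b) {
    data.frame(frame = truth$cells$frame,
               x_px = truth$cells$cx_px + offsets[b] / pixel_size * ux,
               y_px = truth$cells$cy_px + offsets[b] / pixel_size * uy)
  })
}

# kymograph fixture: parallel Gaussian-profile traces advancing v_px
# columns per row, optionally with additive noise
draw_trace_kymograph <- function(v_px, n_t = 100L, n_x = 256L, sigma = 1.3,
                                 spacing = 24, amp = 100, noise_sd = 0,
                                 seed = 1L) {
  K <- matrix(0, n_t, n_x)
  xs <- seq_len(n_x) - 1
  offsets <- seq(-n_x - abs(v_px) * n_t, 2 * n_x, by = spacing)
  for (t in seq_len(n_t)) {
    mu <- offsets + v_px * (t - 1)
    for (m in mu[mu > -8 & mu < n_x + 8])
      K[t, ] <- K[t, ] + amp * exp(-(xs - m)^2 / (2 * sigma^2))
  }
  if (noise_sd > 0) {
    set.seed(seed)
    K <- K + rnorm(length(K), sd = noise_sd)
  }
  K
}

# sinusoidal grating whose structures are oriented at `alpha` degrees
# (measured from the x axis toward increasing row)
grating <- function(alpha_deg, n = 128L, wavelength = 8) {
  phi <- (alpha_deg + 90) * pi / 180        # wavevector direction
  xs <- seq_len(n) - 1
  X <- matrix(xs, n, n, byrow = TRUE)
  Y <- matrix(xs, n, n)
  sin(2 * pi * (X * cos(phi) + Y * sin(phi)) / wavelength)
}

# drop kymograph attributes for plain-matrix comparisons
strip <- function(K) matrix(as.numeric(K), nrow(K), ncol(K))

# distance between two axis orientations, modulo 180 degrees
angle_dist <- function(a, b) {
  d <- (a - b) %% 180
  pmin(d, 180 - d)
}

# fabricate a velocity_trace object from a raw speed vector
fake_trace <- function(v, frame_interval = 0.1, window = 5L) {
  out <- data.frame(frame = seq_along(v),
                    t_s = (seq_along(v) - 1) * frame_interval,
                    v_um_s = v,
                    v_smooth_um_s = moving_average(v, window))
  attr(out, "frame_interval") <- frame_interval
  attr(out, "window") <- window
  class(out) <- c("velocity_trace", class(out))
  out
}

# fabricate a cell_pose data frame directly
fake_pose <- function(cx, cy, angle = 0, valid = TRUE) {
  out <- data.frame(frame = seq_along(cx), cx_px = cx, cy_px = cy,
                    angle_deg = rep_len(angle, length(cx)),
                    valid = rep_len(valid, length(cx)))
  class(out) <- c("cell_pose", class(out))
  out
}

# straight-line motility trace of given speed/duration (1 s sampling)
straight_trace <- function(speed, duration, cell = 1L, heading = 0) {
  t <- seq(0, duration, by = 1)
  motility_trace(t, speed * t * cos(heading), speed * t * sin(heading),
                 cell = cell)
}
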