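test_that("vertical structures peak at 90 degrees", {
  # vertical Gaussian stripes: constant along time
  xs <- seq_len(64L) - 1
  prof <- rowSums(vapply(seq(4, 60, by = 12),
                         function(m) exp(-(xs - m)^2 / 4), numeric(64L)))
  K <- matrix(prof, 64L, 64L, byrow = TRUE)
  h <- orientation_histogram(K)
  expect_equal(sum(h$weights), 1, tolerance = 1e-9)
  peak <- h$centers[which.max(h$weights)]
  expect_lte(angle_dist(peak, 90), h$bin_width)
})

test_that("rotating the texture shifts the orientation peak by the same angle", {
  for (a0 in c(35, 120)) {
    h1 <- orientation_histogram(grating(a0))
    h2 <- orientation_histogram(grating(a0 + 20))
    p1 <- h1$centers[which.max(h1$weights)]
    p2 <- h2$centers[which.max(h2$weights)]
    expect_lte(angle_dist(p1, a0), h1$bin_width)
    expect_lte(angle_dist(p2 - p1, 20), h1$bin_width)
  }
})

test_that("isotropic noise has no dominant orientation and a poor fit", {
  set.seed(31)
  h <- orientation_histogram(matrix(rnorm(128 * 128), 128, 128))
  expect_lt(max(h$weights), 3 / length(h$weights))
  expect_true(is.na(h$fit$r_squared) || h$fit$r_squared < 0.5)
  expect_error(orientation_histogram(matrix(0, 32, 32)), "no signal")
  expect_error(orientation_histogram(matrix(rnorm(100), 10, 10)), "16 x 16")
})

test_that("orientation converts to velocity via cot(alpha)", {
  expect_equal(orientation_to_velocity(90, 0.13, 0.1), 0)
  expect_equal(orientation_to_velocity(45, 0.13, 0.1), 1.3,
               tolerance = 1e-12)
  expect_equal(orientation_to_velocity(135, 0.13, 0.1), -1.3,
               tolerance = 1e-12)
  expect_error(orientation_to_velocity(1, 0.13, 0.1), "too fast")
  expect_error(orientation_to_velocity(179.5, 0.13, 0.1), "too fast")
  expect_error(orientation_to_velocity(0, 0.13, 0.1), "strictly inside")
  expect_error(orientation_to_velocity(180, 0.13, 0.1), "strictly inside")
})

test_that("manual segments measure displacement over rows", {
  K <- kymograph(matrix(0, 40, 40), 0.13, 0.1)
  m <- measure_segment(K, c(0, 0), c(10, 10))
  expect_equal(m$myosin_v_um_s, 1.3, tolerance = 1e-12)
  expect_equal(m$method, "manual-segment")
  expect_equal(measure_segment(K, c(5, 0), c(5, 20))$myosin_v_um_s, 0)
  expect_error(measure_segment(K, c(0, 3), c(9, 3)), "same row")
  K2 <- kymograph(matrix(0, 40, 40), 0.086, 0.1)
  expect_equal(measure_segment(K2, c(0, 0), c(10, 10))$myosin_v_um_s, 0.86,
               tolerance = 1e-12)
})

test_that("segment and orientation routes give identical velocities", {
  K <- kymograph(matrix(0, 64, 64), 0.13, 0.1)
  set.seed(17)
  for (i in 1:20) {
    p0 <- c(runif(1, 0, 60), runif(1, 0, 30))
    p1 <- p0 + c(runif(1, -25, 25), runif(1, 3, 30))
    alpha <- (atan2(p1[2] - p0[2], p1[1] - p0[1]) * 180 / pi) %% 180
    if (alpha < 2 || alpha > 178) next
    v_seg <- measure_segment(K, p0, p1)$myosin_v_um_s
    v_ang <- orientation_to_velocity(alpha, 0.13, 0.1)
    expect_equal(v_ang, v_seg, tolerance = 1e-9)
  }
})

test_that("batch estimation recovers trace velocities across the speed range", {
  px <- 0.13; dt <- 0.1
  for (v in c(0.5, 1, 2, 4, 8, 12)) {
    K <- kymograph(draw_trace_kymograph(v_px = v * dt / px, noise_sd = 20),
                   px, dt)                     # SNR = 5
    m <- estimate_batch_velocity(K, roi_spec(c(0, 10), c(1, 256), "leading"))
    expect_lt(abs(m$myosin_v_um_s - v) / v, 0.1)
    alpha_true <- (atan2(1, v * dt / px) * 180 / pi) %% 180
    expect_lte(angle_dist(m$alpha_deg, alpha_true), 2)
    # negative velocities mirror to the other side of 90 degrees
    Kn <- kymograph(draw_trace_kymograph(v_px = -v * dt / px, noise_sd = 20),
                    px, dt)
    mn <- estimate_batch_velocity(Kn, roi_spec(c(0, 10), c(1, 256), "leading"))
    expect_lt(abs(mn$myosin_v_um_s + v) / v, 0.1)
  }
})

test_that("batch estimation enforces the ROI duration and signal contracts", {
  K <- kymograph(draw_trace_kymograph(v_px = 2), 0.13, 0.1)
  expect_error(estimate_batch_velocity(K, roi_spec(c(0, 4), c(1, 256),
                                                   "leading")), "5 and 15")
  expect_error(estimate_batch_velocity(K, roi_spec(c(0, 16), c(1, 256),
                                                   "leading")), "5 and 15")
  # stationary traces only: no off-vertical mode
  Kv <- kymograph(draw_trace_kymograph(v_px = 0), 0.13, 0.1)
  expect_error(estimate_batch_velocity(Kv, roi_spec(c(0, 10), c(1, 256),
                                                    "leading")),
               "no moving traces")
})

test_that("gliding windows match a brute-force threshold scan", {
  dt <- 0.1
  tr <- fake_trace(rep(2, 250), frame_interval = dt)   # 25 s at 2 um/s
  w <- select_gliding_windows(tr)
  expect_equal(nrow(w), 1L)
  expect_equal(c(w$t0_s, w$t1_s), c(0, 25))

  expect_equal(nrow(select_gliding_windows(fake_trace(rep(0.3, 100)))), 0L)

  set.seed(41)
  v <- rep(rbinom(12, 1, 0.5) * 2, each = 25) + 0.05
  tr2 <- fake_trace(v, frame_interval = dt, window = 1L)
  w2 <- select_gliding_windows(tr2, v_min = 0.5, t_min = 5)
  # run-length oracle
  above <- tr2$v_smooth_um_s > 0.5
  r <- rle(above)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths * dt >= 5
  expect_equal(w2$frame0, starts[keep])
  expect_equal(w2$frame1, ends[keep])
})

test_that("pairing reports cell-to-myosin speed ratios and summaries", {
  tr <- fake_trace(rep(3, 200), frame_interval = 0.1)
  K <- kymograph(matrix(0, 40, 40), 0.13, 0.1)
  m <- measure_segment(K, c(0, 0), c(10, 10))
  m$roi <- roi_spec(c(2, 12), c(1, 40), "leading")
  m$myosin_v_um_s <- 6
  tab <- pair_with_cell_velocity(list(m), tr)
  expect_equal(tab$ratio, 0.5)                  # cell 3 / myosin 6
  expect_equal(tab$cell_speed_um_s, 3)
  s <- attr(tab, "summary")
  expect_equal(s$n, 1L)
  expect_equal(s$mean_myosin, 6)
  # a window outside the trace span is rejected
  m2 <- m; m2$roi <- roi_spec(c(15, 25), c(1, 40), "leading")
  expect_error(pair_with_cell_velocity(list(m2), tr), "outside")
})
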