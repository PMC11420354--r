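# noise-free movie shared across this file
mv <- generate_gliding_movie(tiny_scenario())
truth <- mv$truth
blobs <- truth_blob_centers(truth, c(-7, 7), 0.13)

test_that("chloroplast detection recovers blob centres to sub-pixel", {
  det <- detect_chloroplasts(mv$stack, 5.6)
  expect_equal(nrow(det), 2L * n_frames(mv$stack))
  for (f in c(1L, 17L, n_frames(mv$stack))) {
    d <- det[det$frame == f, ]
    for (b in 1:2) {
      tb <- blobs[[b]]
      err <- min(sqrt((d$x_px - tb$x_px[f])^2 + (d$y_px - tb$y_px[f])^2))
      expect_lt(err, 0.25)
    }
  }
})

test_that("spot diameter accepts the chloroplast range and rejects others", {
  expect_no_error(detect_chloroplasts(mv$stack, 4.5))
  expect_no_error(detect_chloroplasts(mv$stack, 6.0))
  expect_error(detect_chloroplasts(mv$stack, 3.9), "4, 8")
  expect_error(detect_chloroplasts(mv$stack, 8.1), "4, 8")
})

test_that("blank frames yield gaps that linking closes by interpolation", {
  st <- mv$stack
  st$data[, , 2L, 4:6] <- st$data[1L, 1L, 2L, 1L] * 0 + 100  # blank 3 frames
  det <- detect_chloroplasts(st, 5.6)
  expect_false(any(det$frame %in% 4:6))
  tr <- link_tracks(det, max_gap = 5L)
  expect_true(all(tr$leading$gap[4:6]))
  expect_true(all(!tr$leading$gap[-(4:6)]))
  # interpolated positions are exact for linear motion
  for (b in 1:2) {
    tb <- blobs[[b]]
    errs <- vapply(4:6, function(f) {
      min(sqrt((c(tr$leading$x_px[f], tr$trailing$x_px[f]) - tb$x_px[f])^2 +
               (c(tr$leading$y_px[f], tr$trailing$y_px[f]) - tb$y_px[f])^2))
    }, numeric(1))
    expect_lt(max(errs), 0.5)
  }
  # a gap longer than max_gap is an error
  st2 <- mv$stack
  st2$data[, , 2L, 4:10] <- 100
  expect_error(link_tracks(detect_chloroplasts(st2, 5.6), max_gap = 5L),
               "max_gap")
})

test_that("rigidly moving blobs stay on parallel tracks without swaps", {
  det <- detect_chloroplasts(mv$stack, 5.6)
  tr <- link_tracks(det)
  sep <- sqrt((tr$leading$x_px - tr$trailing$x_px)^2 +
              (tr$leading$y_px - tr$trailing$y_px)^2)
  expect_lt(diff(range(sep)), 0.5)
  # the cell moves toward +x, so the leading blob is always ahead
  expect_true(all(tr$leading$x_px > tr$trailing$x_px))
})

test_that("a single frame gives two one-point tracks via the fallback rule", {
  one <- calibrated_stack(mv$stack$data[, , , 1L, drop = FALSE],
                          0.13, 0.1, mv$stack$channels)
  det <- detect_chloroplasts(one, 5.6)
  tr <- link_tracks(det)
  expect_equal(nrow(tr$leading), 1L)
  expect_equal(nrow(tr$trailing), 1L)
  expect_gt(tr$leading$x_px, tr$trailing$x_px)   # fallback: rightmost leads
})

test_that("cell pose midpoint and angle follow the landmark geometry", {
  mk <- function(x, y) data.frame(frame = 1L, x_px = x, y_px = y, gap = FALSE)
  p1 <- compute_cell_pose(mk(10, 10), mk(30, 10))
  expect_equal(c(p1$cx_px, p1$cy_px, p1$angle_deg), c(20, 10, 0))
  p2 <- compute_cell_pose(mk(0, 0), mk(10, 10))
  expect_equal(c(p2$cx_px, p2$cy_px), c(5, 5))
  expect_equal(p2$angle_deg, -45)       # y increases downward
  # wrapping: a vector pointing up-left maps into (-90, 90]
  p3 <- compute_cell_pose(mk(10, 10), mk(0, 11))
  expect_true(p3$angle_deg > -90 && p3$angle_deg <= 90)
})

test_that("full-movie pose recovery is sub-pixel and sub-degree", {
  det <- detect_chloroplasts(mv$stack, 5.6)
  tr <- link_tracks(det)
  pose <- compute_cell_pose(tr$leading, tr$trailing)
  err_c <- sqrt((pose$cx_px - truth$cells$cx_px)^2 +
                (pose$cy_px - truth$cells$cy_px)^2)
  expect_lt(max(err_c), 0.5)
  expect_lt(max(angle_dist(pose$angle_deg, truth$cells$angle_deg)), 1)
})

test_that("rotating the stack by 90 degrees rotates recovered angles", {
  pose_of <- function(stack) {
    tr <- link_tracks(detect_chloroplasts(stack, 5.6))
    compute_cell_pose(tr$leading, tr$trailing)
  }
  sub <- calibrated_stack(mv$stack$data[, , , 1:10, drop = FALSE],
                          0.13, 0.1, mv$stack$channels)
  d <- dim(sub$data)
  rot <- array(0, c(d[2L], d[1L], d[3L], d[4L]))
  for (f in 1:d[4L]) for (c in 1:d[3L])
    rot[, , c, f] <- t(sub$data[, , c, f])[d[2L]:1, ]
  rot <- calibrated_stack(rot, 0.13, 0.1, sub$channels)
  a1 <- pose_of(sub)$angle_deg
  a2 <- pose_of(rot)$angle_deg
  expect_lt(max(angle_dist(a2, a1 + 90)), 1)
})

test_that("velocity trace equals displacement over time at constant speed", {
  # centres advancing 0.2 um per 0.1 s frame -> 2 um/s everywhere
  step_px <- 0.2 / 0.13
  pose <- fake_pose(cx = 10 + step_px * (0:29), cy = rep(5, 30))
  vt <- compute_velocity_trace(pose, 0.13, 0.1, window = 5L)
  expect_equal(vt$v_um_s, rep(2, 30), tolerance = 1e-9)
  expect_equal(vt$v_smooth_um_s, rep(2, 30), tolerance = 1e-9)
  expect_error(compute_velocity_trace(pose, 0.13, 0.1, window = 31L),
               "exceeds")
})

test_that("moving average matches the brute-force windowed-mean oracle", {
  set.seed(11)
  x <- rnorm(57)
  oracle <- function(x, h) {
    n <- length(x)
    vapply(seq_len(n), function(i) {
      k <- min(h, i - 1L, n - i)
      mean(x[(i - k):(i + k)])
    }, numeric(1))
  }
  for (w in c(1L, 3L, 5L, 20L, 21L)) {
    h <- (w - 1L - (1L - w %% 2L)) %/% 2L
    expect_equal(moving_average(x, w), oracle(x, h), tolerance = 1e-12)
  }
  expect_error(moving_average(x, 58L), "exceeds")
})

test_that("smoothing conserves the mean for traces constant near the ends", {
  # with symmetric shrinking windows the mean is conserved exactly when
  # the trace is constant within 2h points of each end
  x <- c(rep(1, 10), 3, 7, 2, 5, rep(4, 10))
  y <- moving_average(x, 5L)
  expect_lt(abs(mean(y) - mean(x)) / abs(mean(x)), 1e-9)
})

test_that("a stationary cell's speed sits at the noise floor, monotone in noise", {
  mean_speed <- function(noise_sd) {
    m <- generate_gliding_movie(tiny_scenario(v = 0, duration = 2,
                                              noise_sd = noise_sd))
    tr <- link_tracks(detect_chloroplasts(m$stack, 5.6))
    pose <- compute_cell_pose(tr$leading, tr$trailing)
    mean(compute_velocity_trace(pose, 0.13, 0.1, window = 5L)$v_um_s)
  }
  v0 <- mean_speed(0)
  v5 <- mean_speed(5)
  v20 <- mean_speed(20)
  expect_lt(v0, 0.02)
  expect_lt(v0, v5)
  expect_lt(v5, v20)
})
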