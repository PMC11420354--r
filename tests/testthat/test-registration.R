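test_that("reference-frame selection matches exhaustive score minimisation", {
  # wandering, rotating pose
  set.seed(21)
  n <- 40L
  pose <- fake_pose(cx = 60 + cumsum(rnorm(n)), cy = 40 + cumsum(rnorm(n)),
                    angle = seq(-30, 50, length.out = n))
  pose$valid[c(3, 9)] <- FALSE
  fov <- c(80L, 120L)
  ref <- select_reference_frame(pose, fov)
  fc <- c((fov[2L] - 1) / 2, (fov[1L] - 1) / 2)
  half_diag <- sqrt((fov[1L] - 1)^2 + (fov[2L] - 1)^2) / 2
  score <- abs(pose$angle_deg) / 90 +
    sqrt((pose$cx_px - fc[1])^2 + (pose$cy_px - fc[2])^2) / half_diag
  score[!pose$valid] <- Inf
  expect_equal(ref$frame, which.min(score))

  # all frames identical -> earliest wins
  pose2 <- fake_pose(cx = rep(10, 5), cy = rep(10, 5), angle = 12)
  expect_equal(select_reference_frame(pose2, fov)$frame, 1L)
  expect_error(select_reference_frame(
    fake_pose(1, 1, valid = FALSE), fov), "no valid")
})

test_that("registering a stationary centred cell is the identity", {
  mv <- generate_gliding_movie(tiny_scenario(v = 0, duration = 1))
  tr <- link_tracks(detect_chloroplasts(mv$stack, 5.6))
  pose <- compute_cell_pose(tr$leading, tr$trailing)
  ref <- select_reference_frame(pose, dim(mv$stack$data)[1:2])
  reg <- register_stack(mv$stack, pose, ref)
  rng <- diff(range(mv$stack$data))
  expect_lt(mean(abs(reg$data - mv$stack$data)), 1e-6 * rng)
})

test_that("a pure translation is undone to sub-pixel accuracy", {
  mv <- generate_gliding_movie(tiny_scenario(v = 0, duration = 0.2))
  img <- mv$stack$data[, , , 1L, drop = TRUE]        # H x W x C
  d <- dim(img)
  shifted <- array(100, d)
  shifted[, 6:d[2L], ] <- img[, 1:(d[2L] - 5L), ]    # shift +5 px in x
  two <- array(c(img, shifted), c(d[1L], d[2L], d[3L], 2L))
  st <- calibrated_stack(two, 0.13, 0.1, mv$stack$channels)
  c0 <- c(mv$truth$cells$cx_px[1L], mv$truth$cells$cy_px[1L])
  pose <- fake_pose(cx = c(c0[1L], c0[1L] + 5), cy = rep(c0[2L], 2))
  ref <- select_reference_frame(pose, d[1:2])
  reg <- register_stack(st, pose, ref)
  det <- detect_chloroplasts(reg, 5.6)
  for (b in split(det, det$frame == 1L)) expect_equal(nrow(b), 2L)
  d1 <- det[det$frame == 1L, ]; d2 <- det[det$frame == 2L, ]
  d1 <- d1[order(d1$x_px), ]; d2 <- d2[order(d2$x_px), ]
  expect_lt(max(sqrt((d1$x_px - d2$x_px)^2 + (d1$y_px - d2$y_px)^2)), 0.25)
})

test_that("a rotated cell is brought back to the reference orientation", {
  base <- list(duration = 0.1, frame_interval = 0.1, pixel_size = 0.13,
               fov = c(160L, 240L), cell_length = 16, cell_width = 5,
               chloroplast_offsets = c(-5, 5), noise_sd = 0)
  mk <- function(heading) {
    sc <- do.call(gliding_scenario, c(base, list(
      trajectory = data.frame(t0 = 0, t1 = 0.1, v = 0, heading = heading))))
    generate_gliding_movie(sc)
  }
  a <- mk(0); b <- mk(30)
  two <- array(c(a$stack$data, b$stack$data), c(160L, 240L, 2L, 2L))
  st <- calibrated_stack(two, 0.13, 0.1, a$stack$channels)
  pose <- fake_pose(cx = c(a$truth$cells$cx_px, b$truth$cells$cx_px),
                    cy = c(a$truth$cells$cy_px, b$truth$cells$cy_px),
                    angle = c(0, 30))
  ref <- select_reference_frame(pose, c(160L, 240L))
  expect_equal(ref$frame, 1L)
  reg <- register_stack(st, pose, ref)
  tr <- link_tracks(detect_chloroplasts(reg, 5.6))
  p2 <- compute_cell_pose(tr$leading, tr$trailing)
  expect_lt(max(angle_dist(p2$angle_deg, 0)), 1)
})

test_that("registration cancels the motion of a gliding cell", {
  mv <- generate_gliding_movie(tiny_scenario())
  tr <- link_tracks(detect_chloroplasts(mv$stack, 5.6))
  pose <- compute_cell_pose(tr$leading, tr$trailing)
  ref <- select_reference_frame(pose, dim(mv$stack$data)[1:2])
  reg <- register_stack(mv$stack, pose, ref)
  tr2 <- link_tracks(detect_chloroplasts(reg, 5.6))
  p2 <- compute_cell_pose(tr2$leading, tr2$trailing)
  expect_lt(diff(range(p2$cx_px)), 0.5)
  expect_lt(diff(range(p2$cy_px)), 0.5)
})

test_that("invalid-pose frames come out all-zero and flagged", {
  mv <- generate_gliding_movie(tiny_scenario(duration = 1))
  tr <- link_tracks(detect_chloroplasts(mv$stack, 5.6))
  pose <- compute_cell_pose(tr$leading, tr$trailing)
  pose$valid[3L] <- FALSE
  ref <- select_reference_frame(pose, dim(mv$stack$data)[1:2])
  reg <- register_stack(mv$stack, pose, ref)
  expect_true(all(reg$data[, , , 3L] == 0))
  expect_false(attr(reg, "registered_valid")[3L])
  expect_true(attr(reg, "registered_valid")[1L])
})
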