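test_that("identity pair gives exactly zero flow under block matching", {
  set.seed(4)
  img <- matrix(stats::runif(96 * 96), 96, 96)
  fl <- dense_flow(img, img, backend = "block", block_radius = 3)
  expect_true(all(fl$u == 0) && all(fl$v == 0))
})

test_that("integer translations are recovered by both backends", {
  sc3 <- generate_scene(fx_small_scene(
    seed = 21, motion = list(type = "translation", dv = 0, du = 3)))
  m <- sc3$truth$colony_masks[[1]]
  fb <- dense_flow(sc3$frames[[1]], sc3$frames[[2]], backend = "block")
  expect_equal(stats::median(fb$u[m]), 3)
  expect_equal(stats::median(fb$v[m]), 0)
  fl <- dense_flow(sc3$frames[[1]], sc3$frames[[2]], backend = "lk")
  expect_lt(abs(stats::median(fl$u[m]) - 3), 0.5)
  expect_lt(abs(stats::median(fl$v[m]) - 0), 0.5)

  sc21 <- generate_scene(fx_small_scene(
    seed = 22, motion = list(type = "translation", dv = -2, du = 1)))
  m2 <- sc21$truth$colony_masks[[1]]
  fb2 <- dense_flow(sc21$frames[[1]], sc21$frames[[2]], backend = "block")
  expect_equal(stats::median(fb2$v[m2]), -2)
  expect_equal(stats::median(fb2$u[m2]), 1)
})

test_that("untextured input yields zero flow with a warning", {
  flat <- matrix(0.5, 64, 64)
  expect_warning(fl <- dense_flow(flat, flat, backend = "lk"), "untextured")
  expect_true(all(fl$u == 0))
})

test_that("colony speed has the closed-form unit conversion", {
  m <- matrix(c(TRUE, FALSE), 10, 10)
  fl <- flow <- structure(list(u = matrix(2, 10, 10), v = matrix(0, 10, 10),
                               frame_pair = c(1L, 2L)), class = "flow_field")
  cs <- colony_speed(fl, m, pixel_size_um = 0.65, interval_min = 5)
  expect_equal(cs$mean_speed, 0.26)
  expect_equal(cs$n_pixels, sum(m))

  z <- structure(list(u = matrix(0, 10, 10), v = matrix(0, 10, 10),
                      frame_pair = c(1L, 2L)), class = "flow_field")
  expect_equal(colony_speed(z, m, 0.65, 5)$mean_speed, 0)

  # half the mask at |d| = 1, half at |d| = 3: arithmetic mean (1+3)/2/5
  half <- matrix(FALSE, 10, 10); half[1:5, 1] <- TRUE; half[6:10, 1] <- TRUE
  u <- matrix(0, 10, 10); u[1:5, 1] <- 1; u[6:10, 1] <- 3
  mix <- structure(list(u = u, v = matrix(0, 10, 10), frame_pair = c(1L, 2L)),
                   class = "flow_field")
  expect_equal(colony_speed(mix, half, 1, 5)$mean_speed, 0.4)

  expect_error(colony_speed(z, matrix(FALSE, 10, 10), 1, 5), "empty")

  # exact scale equivariance in pixel size and frame interval
  set.seed(2)
  ru <- matrix(stats::runif(100), 10, 10); rv <- matrix(stats::runif(100), 10, 10)
  rf <- structure(list(u = ru, v = rv, frame_pair = c(1L, 2L)),
                  class = "flow_field")
  base <- colony_speed(rf, m, 0.5, 5)$mean_speed
  expect_identical(colony_speed(rf, m, 1.0, 5)$mean_speed, 2 * base)
  expect_identical(colony_speed(rf, m, 0.5, 10)$mean_speed, base / 2)
})

test_that("speed timecourse is consistent for stationary-statistics motion", {
  spec <- fx_small_scene(seed = 30, shape = c(128L, 128L), colony_radius = 46,
                         n_cells = 7,
                         motion = list(type = "translation", dv = 0.7, du = 0.7),
                         n_frames = 37L)
  sc <- generate_scene(spec)
  masks <- lapply(seq_along(sc$frames), function(t)
    colonyflow:::colony_mask(sc$truth$colony_masks[[1]], t))
  out <- speed_timecourse(sc$frames, masks, pipeline_config())
  expect_length(out$per_pair_means, 36L)
  expect_lt(out$sd_speed / out$mean_speed, 0.2)   # CV < 0.2 over 36 pairs
  expect_equal(out$mean_speed, mean(out$per_pair_means))
  expect_identical(out$unit, "px/frame")

  # 2 frames: one per-pair mean, SD reported as absent
  out2 <- speed_timecourse(sc$frames[1:2], masks[1:2], pipeline_config())
  expect_length(out2$per_pair_means, 1L)
  expect_true(is.na(out2$sd_speed))

  expect_error(speed_timecourse(sc$frames[1], masks[1], pipeline_config()),
               "at least 2 frames")
})

test_that("variational and block-matching backends agree on translations", {
  set.seed(99)
  moves <- cbind(sample(c(-3, -2, 2, 3), 10, TRUE), sample(-3:3, 10, TRUE))
  for (i in 1:10) {
    sc <- generate_scene(fx_small_scene(
      seed = 40 + i, shape = c(128L, 128L), colony_radius = 46, n_cells = 7,
      motion = list(type = "translation", dv = moves[i, 1], du = moves[i, 2])))
    m <- sc$truth$colony_masks[[1]]
    lk <- dense_flow(sc$frames[[1]], sc$frames[[2]], backend = "lk")
    bk <- dense_flow(sc$frames[[1]], sc$frames[[2]], backend = "block")
    s_lk <- mean(sqrt(lk$u[m]^2 + lk$v[m]^2))
    s_bk <- mean(sqrt(bk$u[m]^2 + bk$v[m]^2))
    expect_lt(abs(s_lk - s_bk) / s_bk, 0.15)
  }
})
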