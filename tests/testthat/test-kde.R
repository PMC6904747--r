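test_that("landmark pooling is additive and keeps cross-kind duplicates", {
  shp <- c(64L, 64L)
  nuc <- point_set(cbind(10:19, 10:19), "nucleolus", shp)
  bp <- point_set(cbind(30:54, 5:29), "branch_point", shp)
  pooled <- pool_landmarks(nuc, bp)
  expect_equal(nrow(pooled$points), 35L)

  both <- pool_landmarks(point_set(cbind(7, 7), "nucleolus", shp),
                         point_set(cbind(7, 7), "branch_point", shp))
  expect_equal(nrow(both$points), 2L)   # same pixel counts twice

  e <- point_set(matrix(integer(), 0, 2), "nucleolus", shp)
  expect_equal(nrow(pool_landmarks(e, e)$points), 0L)

  expect_error(pool_landmarks(nuc, point_set(cbind(1, 1), "branch_point",
                                             c(32L, 32L))), "shapes")
})

test_that("KDE has the closed-form single-point solution", {
  h <- 8
  ps <- point_set(cbind(33, 33), "nucleolus", c(65L, 65L))
  d <- kde_density(ps, bandwidth = h)
  expect_equal(d$values[33, 33], 1 / (2 * pi * h^2))
  expect_equal(which.max(d$values), (33 - 1) * 65 + 33)
  # radial symmetry: equal values at equal offsets
  expect_equal(d$values[33, 43], d$values[43, 33])
  expect_equal(d$values[23, 33], d$values[33, 23])
  # the global maximum lies within h of a sample point
  mx <- which(d$values == max(d$values), arr.ind = TRUE)[1, ]
  expect_lte(sqrt(sum((mx - c(33, 33))^2)), h)
})

test_that("two nearby points put the density maximum at their midpoint", {
  ps <- point_set(rbind(c(32, 28), c(32, 36)), "nucleolus", c(64L, 64L))
  d <- kde_density(ps, bandwidth = 10)   # d = 8 << h would be ideal; h > d/2 suffices
  idx <- which(d$values == max(d$values), arr.ind = TRUE)
  expect_true(any(idx[, 1] == 32 & idx[, 2] == 32))
  # direct evaluation along the connecting line confirms the interior maximum
  line <- d$values[32, 28:36]
  expect_equal(which.max(line), 5L)
})

test_that("convolution evaluation matches the direct sum", {
  set.seed(20)
  pts <- cbind(sample(64, 10, TRUE), sample(64, 10, TRUE))
  pts <- pts[!duplicated(pts), , drop = FALSE]
  ps <- point_set(pts, "nucleolus", c(64L, 64L))
  dc <- kde_density(ps, bandwidth = 5, method = "convolution")
  dd <- kde_density(ps, bandwidth = 5, method = "direct")
  expect_lt(max(abs(dc$values - dd$values)) / max(dd$values), 1e-6)
})

test_that("KDE mass and monotonicity behave as densities should", {
  # centered point on a frame of side 10h: nearly all kernel mass inside
  h <- 3
  ps <- point_set(cbind(16, 16), "nucleolus", c(31L, 31L))
  d <- kde_density(ps, bandwidth = h)
  expect_equal(sum(d$values), 1, tolerance = 1e-3)

  # un-normalized sum is pointwise non-decreasing under landmark addition
  ps2 <- point_set(rbind(c(16, 16), c(8, 24)), "nucleolus", c(31L, 31L))
  d2 <- kde_density(ps2, bandwidth = h)
  expect_true(all(2 * d2$values - 1 * d$values >= -1e-12))

  # empty point set: all-zero map, flagged
  e <- point_set(matrix(integer(), 0, 2), "nucleolus", c(31L, 31L))
  de <- kde_density(e, bandwidth = h)
  expect_true(all(de$values == 0))
  expect_true(isTRUE(attr(de, "empty")))
})

test_that("colony extraction keeps the largest super-threshold region", {
  # two Gaussian blobs of different support
  ps <- point_set(rbind(c(20, 20), c(21, 20), c(20, 21), c(60, 70)),
                  "nucleolus", c(80L, 90L))
  d <- kde_density(ps, bandwidth = 6)
  cm <- extract_colony(d, threshold_frac = 0.2)
  expect_s3_class(cm, "colony_mask")
  expect_equal(nrow(label_components(cm$pixels, 8)$region_table), 1L)
  expect_equal(cm$area_px, sum(cm$pixels))
  # the kept region is the 3-point blob, not the single far point
  expect_true(cm$pixels[20, 20])
  expect_false(cm$pixels[60, 70])

  zero <- kde_density(point_set(matrix(integer(), 0, 2), "nucleolus",
                                c(40L, 40L)), bandwidth = 6)
  expect_warning(cm0 <- extract_colony(zero, 0.5), "all-zero")
  expect_equal(cm0$area_px, 0L)
  expect_true(isTRUE(attr(cm0, "empty")))
  expect_error(extract_colony(d, 1.5), "threshold_frac")
})

test_that("per-frame extraction tracks a translating colony", {
  spec <- fx_small_scene(seed = 9, shape = c(224L, 224L), colony_radius = 72,
                         n_cells = 15,
                         motion = list(type = "translation", dv = 0, du = 2),
                         n_frames = 3L)
  sc <- generate_scene(spec)
  # bandwidth matched to the miniature scene scale (h = 151 is the operating
  # point for full camera frames and over-smooths a 224 px field)
  masks <- extract_colony_timeseries(sc$frames,
                                     pipeline_config(kde_bandwidth = 30))
  expect_length(masks, 3L)
  cents <- t(vapply(masks, function(m) fx_mask_centroid(m$pixels), numeric(2)))
  # cumulative drift over 2 steps: ~4 px in col, ~0 in row (the mask outline
  # jitters by a px or two per frame as discrete landmarks enter and leave)
  expect_lt(abs((cents[3, 2] - cents[1, 2]) - 4), 2)
  expect_lt(abs(cents[3, 1] - cents[1, 1]), 2.5)

  # feeder-only scenes produce empty masks with a warning
  bg <- generate_scene(scene_spec(shape = c(224L, 224L), n_cells = 0,
                                  n_feeder = 6, n_decoys = 0, n_frames = 2L,
                                  colony_radius = 60, seed = 3))
  expect_warning(extract_colony_timeseries(bg$frames[1], pipeline_config()),
                 "no landmarks")
  m0 <- suppressWarnings(extract_colony_timeseries(bg$frames, pipeline_config()))
  expect_true(all(vapply(m0, function(m) m$area_px == 0L, logical(1))))

  one <- extract_colony_timeseries(sc$frames[1], pipeline_config())
  expect_length(one, 1L)
})
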