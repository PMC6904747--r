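test_that("boundary extraction keeps a wide bright grid, drops small blobs", {
  # bright 3-px grid lines on dark background (one big connected mesh)
  img <- matrix(0.3, 128, 128)
  for (g in seq(10, 120, by = 22)) {
    img[g:(g + 2), 5:124] <- 0.8
    img[5:124, g:(g + 2)] <- 0.8
  }
  cfg <- pipeline_config()
  bm <- extract_boundary_mask(img, cfg)
  expect_gt(sum(bm), 3000)
  expect_equal(nrow(label_components(bm, 8)$region_table), 1L)

  # isolated bright blob of exactly 250 px is removed; 251 px retained.
  # rectangles survive a 3x3 opening/closing unchanged, so the boundary-case
  # areas are exact after morphology.
  blob250 <- matrix(0.3, 64, 64)
  blob250[20:44, 20:29] <- 0.8              # 25 x 10 = 250 px
  expect_equal(sum(extract_boundary_mask(blob250, cfg)), 0L)
  blob252 <- matrix(0.3, 64, 64)
  blob252[20:33, 20:37] <- 0.8              # 14 x 18 = 252 px
  expect_equal(sum(extract_boundary_mask(blob252, cfg)), 252L)

  # the raw size rule, independent of morphology, at the exact boundary
  m250 <- matrix(FALSE, 64, 64); m250[1:25, 1:10] <- TRUE
  expect_equal(sum(remove_small_regions(m250, 250)), 0L)
  m251 <- m250; m251[26, 1] <- TRUE
  expect_equal(sum(remove_small_regions(m251, 250)), 251L)
})

test_that("Zhang-Suen thinning is idempotent on thin input and shrinks bars", {
  line <- matrix(FALSE, 20, 20)
  line[10, 3:17] <- TRUE
  expect_identical(unclass(zhang_suen_thin(line)), line)

  empty <- matrix(FALSE, 10, 10)
  expect_identical(unclass(zhang_suen_thin(empty)), empty)

  # filled 9x3 horizontal bar collapses to a centered line; the genuine
  # two-subiteration algorithm erodes up to ~1.5 px per end (an independent
  # textbook implementation yields exactly 6 px for this input)
  bar <- matrix(FALSE, 11, 15)
  bar[5:7, 4:12] <- TRUE
  sk <- zhang_suen_thin(bar)
  expect_true(all(bar[sk]))                      # skeleton is a subset
  len <- diff(range(which(apply(sk, 2, any)))) + 1
  expect_gte(len, 6); expect_lte(len, 9)
  expect_true(all(which(apply(sk, 1, any)) == 6))  # centered on the middle row
})

test_that("thinning preserves 8-connectivity and leaves no 2x2 block", {
  for (seed in 1:20) {
    m <- fx_blob_mask(c(64L, 64L), n_discs = 6L, seed = seed)
    sk <- zhang_suen_thin(m)
    expect_equal(nrow(label_components(sk, 8)$region_table),
                 nrow(label_components(m, 8)$region_table))
    two_by_two <- sk[-nrow(sk), -ncol(sk)] & sk[-1, -ncol(sk)] &
      sk[-nrow(sk), -1] & sk[-1, -1]
    expect_false(any(two_by_two))
  }
})

test_that("crossing number matches its definition on canonical junctions", {
  # straight-line interior: CN 2
  line <- matrix(FALSE, 5, 5); line[3, 1:5] <- TRUE
  expect_identical(crossing_number(line, c(3, 3)), 2L)
  # endpoint: CN 1
  expect_identical(crossing_number(line, c(3, 1)), 1L)
  # T-junction center: CN 3, and it is the only branch point
  tj <- matrix(FALSE, 7, 7)
  tj[4, 1:7] <- TRUE; tj[5:7, 4] <- TRUE
  expect_identical(crossing_number(tj, c(4, 4)), 3L)
  bp <- detect_branch_points(tj)
  expect_identical(unname(bp$points), cbind(4L, 4L))
  expect_identical(bp$kind, "branch_point")
  # plus-sign center: CN 4 -> not a branch point by default, included on demand
  plus <- matrix(FALSE, 7, 7)
  plus[4, 1:7] <- TRUE; plus[1:7, 4] <- TRUE
  expect_identical(crossing_number(plus, c(4, 4)), 4L)
  expect_identical(nrow(detect_branch_points(plus)$points), 0L)
  expect_identical(unname(detect_branch_points(plus, TRUE)$points), cbind(4L, 4L))
  # isolated pixel: CN 0; background pixel: domain error
  dot <- matrix(FALSE, 3, 3); dot[2, 2] <- TRUE
  expect_identical(crossing_number(dot, c(2, 2)), 0L)
  expect_error(crossing_number(dot, c(1, 1)), "foreground")
})

test_that("crossing number is bounded, even-transitioned and symmetric", {
  # parity/bounds over all 256 neighborhoods via the independent oracle
  for (code in 0:255) {
    neigh <- as.integer(intToBits(code))[1:8]
    m <- fx_embed_neigh(neigh)
    cn <- crossing_number(m, c(2, 2))
    expect_gte(cn, 0L); expect_lte(cn, 4L)
    expect_identical(cn, as.integer(fx_cn_oracle(neigh)))
  }
  # branch points commute with transposition (coordinate swap)
  for (seed in 1:5) {
    sk <- zhang_suen_thin(fx_blob_mask(c(48L, 48L), 5L, seed = seed))
    a <- detect_branch_points(sk)$points
    b <- detect_branch_points(t(unclass(sk)))$points
    expect_identical(a[order(a[, 1], a[, 2]), , drop = FALSE],
                     b[order(b[, 2], b[, 1]), c(2, 1), drop = FALSE],
                     ignore_attr = TRUE)
  }
})
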