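test_that("pixel confusion matches its definitions on enumerable cases", {
  m <- fx_blob_mask(c(20L, 20L), 3, seed = 2)
  id <- pixel_confusion(m, m)
  expect_equal(id$fp, 0L); expect_equal(id$fn, 0L)
  expect_equal(id$accurate_frac, 1)

  # empty prediction vs 30% manual coverage on 100 px
  manual <- matrix(FALSE, 10, 10); manual[1:3, ] <- TRUE
  ec <- pixel_confusion(matrix(FALSE, 10, 10), manual)
  expect_equal(ec$fn, 30L); expect_equal(ec$tn, 70L)
  expect_equal(ec$undetected_frac, 0.30)

  # manual = left half, predicted = top half: enumerate all 100 pixels
  pred <- matrix(FALSE, 10, 10); pred[1:5, ] <- TRUE
  man <- matrix(FALSE, 10, 10); man[, 1:5] <- TRUE
  counts <- c(tp = 0L, fp = 0L, fn = 0L, tn = 0L)
  for (r in 1:10) for (c in 1:10) {
    counts <- counts + c(tp = pred[r, c] && man[r, c],
                         fp = pred[r, c] && !man[r, c],
                         fn = !pred[r, c] && man[r, c],
                         tn = !pred[r, c] && !man[r, c])
  }
  pc <- pixel_confusion(pred, man)
  expect_equal(unlist(pc[c("tp", "fp", "fn", "tn")]), counts)
  expect_equal(pc$accurate_frac, 0.5)

  expect_error(pixel_confusion(pred, matrix(FALSE, 5, 5)), "shapes")
})

test_that("the three confusion ratios always sum to one exactly", {
  for (seed in 1:25) {
    p <- fx_blob_mask(c(16L, 16L), 3, seed = seed)
    m <- fx_blob_mask(c(16L, 16L), 3, seed = seed + 100)
    pc <- pixel_confusion(p, m)
    expect_identical(pc$undetected_frac + pc$overdetected_frac +
                       pc$accurate_frac, 1)
    expect_identical(pc$tp + pc$fp + pc$fn + pc$tn, 256L)
  }
})

test_that("Mann-Whitney p-values match exact enumeration for separation", {
  # 5 vs 5 complete separation: exact two-tailed p = 2 / choose(10, 5)
  ctrl <- c(2.1, 2.2, 2.3, 2.25, 2.15)
  treat <- c(0.4, 0.5, 0.45, 0.55, 0.35)
  gc <- compare_two_groups(ctrl, treat)
  expect_equal(gc$p_value, 2 / choose(10, 5))
  expect_equal(round(gc$p_value, 4), 0.0079)
  expect_true(gc$exact)

  # 4 vs 4: oracle enumerates every rank assignment of group A
  oracle_p <- local({
    ranks <- utils::combn(8, 4)
    u_obs <- 0  # complete separation: treated group has all the low ranks
    u_all <- apply(ranks, 2, function(ix) sum(ix) - 4 * 5 / 2)
    u_min <- pmin(u_all, 16 - u_all)
    mean(u_min <= min(u_obs, 16 - u_obs)) # two-tailed by doubling via symmetry
  })
  gc4 <- compare_two_groups(c(5, 6, 7, 8), c(1, 2, 3, 4))
  expect_equal(gc4$p_value, 2 / choose(8, 4))
  expect_equal(gc4$p_value, oracle_p)

  # identical groups: p = 1, tie note recorded
  same <- c(1, 2, 3, 4, 5)
  gid <- compare_two_groups(same, same)
  expect_equal(gid$p_value, 1)
  expect_match(gid$note, "ties")

  # label swap symmetry
  expect_equal(compare_two_groups(treat, ctrl)$p_value, gc$p_value)
  expect_error(compare_two_groups(1:2, 1:5), "at least 3")
})

test_that("Kruskal-Wallis screen holds its type-I error and detects shifts", {
  set.seed(123)
  reject <- logical(1000)
  for (i in seq_along(reject)) {
    g <- list(a = stats::rnorm(8), b = stats::rnorm(8), c = stats::rnorm(8))
    reject[i] <- compare_multi_groups(g)$p_value < 0.05
  }
  expect_gte(mean(reject), 0.03)
  expect_lte(mean(reject), 0.07)

  shifted <- list(a = stats::rnorm(8), b = stats::rnorm(8),
                  c = stats::rnorm(8) + 10)
  expect_lt(compare_multi_groups(shifted)$p_value, 0.001)

  # all-constant groups: H = 0, p = 1 under the tie-corrected convention
  const <- list(a = rep(1, 4), b = rep(1, 4), c = rep(1, 4))
  gc <- compare_multi_groups(const)
  expect_equal(gc$statistic, 0)
  expect_equal(gc$p_value, 1)
})

test_that("Dunn post-hoc is control-anchored and never de-adjusts", {
  set.seed(5)
  g <- list(control = stats::rnorm(6, 1), d1 = stats::rnorm(6, 0.5),
            d2 = stats::rnorm(6, 3), d3 = stats::rnorm(6, 1))
  gc <- compare_multi_groups(g, control = "control")
  ph <- gc$posthoc_table
  expect_equal(nrow(ph), 3L)
  expect_true(all(ph$p_adjusted >= ph$p_unadjusted - 1e-15))
  expect_true(all(ph$p_adjusted <= 1))
  expect_identical(ph$adjustment, rep("bonferroni", 3))
  expect_match(ph$comparison, "^control vs ")
  expect_error(compare_multi_groups(g[1:2]), "compare_two_groups")
})
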