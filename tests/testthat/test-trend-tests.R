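test_that("Z1 is zero when f01 = f12 and signed toward the leaning model", {
  z0 <- z1_statistic(group_by_genotype(1:6, c(0, 1, 2, 0, 1, 2)))
  expect_equal(z0$statistic, 0)
  expect_equal(z0$p_value, 1)

  # f01 = 1 > f12 = 0: dominant-leaning, positive
  zpos <- z1_statistic(group_by_genotype(c(1, 2, 5, 6, 3, 4),
                                         c(0, 0, 1, 1, 2, 2)))
  expect_gt(zpos$statistic, 0)
  expect_equal(zpos$reference, "standard-normal")
})

test_that("complete separation drives every trend test positive with f = 1", {
  gt <- group_by_genotype(c(1:10, 101:110, 201:210), rep(0:2, each = 10))
  e <- win_prob_estimates(gt)
  expect_equal(c(e$f01, e$f12, e$f02), c(1, 1, 1))
  for (m in c("REC", "ADD", "DOM")) {
    r <- npt_statistic(gt, m)
    expect_gt(r$statistic, 0)
    expect_lt(r$p_value, 0.05)
  }
})

test_that("additive weights are normalized for every input", {
  set.seed(31)
  for (r in 1:10) {
    gr <- null_groups(150, runif(1, 0.2, 0.5))
    w <- npt_statistic(gr$gt, "ADD")$weights
    expect_equal(unname(w[["w1"]] + w[["w2"]]), 1)
    expect_true(all(w > 0))
  }
})

test_that("Kruskal-Wallis reproduces the hand-computed H and guards ties", {
  gt <- group_by_genotype(1:6, rep(0:2, each = 2))
  # rank sums 3, 7, 11: H = 12/(6*7) * (9/2 + 49/2 + 121/2) - 3*7 = 32/7
  expect_equal(kruskal_wallis(gt)$statistic, 32 / 7)
  expect_equal(kruskal_wallis(gt)$reference, "chi-squared")
  expect_equal(kruskal_wallis(gt)$df, 2)
  expect_error(kruskal_wallis(group_by_genotype(rep(1, 6), rep(0:2, 2))),
               "tied")
})

test_that("every statistic is exactly rank invariant", {
  set.seed(13)
  y <- rnorm(120)
  g <- sample(0:2, 120, replace = TRUE)
  for (f in list(function(x) exp(x), function(x) x^3,
                 function(x) qgamma(pnorm(x), shape = 2))) {
    expect_identical(all_z(y, g), all_z(f(y), g))
    expect_identical(kruskal_wallis(group_by_genotype(y, g))$statistic,
                     kruskal_wallis(group_by_genotype(f(y), g))$statistic)
    expect_identical(max3_test(group_by_genotype(y, g))$statistic,
                     max3_test(group_by_genotype(f(y), g))$statistic)
  }
})

test_that("MAX3 takes the largest absolute trend statistic", {
  set.seed(17)
  gr <- null_groups(240, 0.35)
  z <- all_z(gr$y, gr$g)
  m <- max3_test(gr$gt)
  expect_equal(m$statistic, max(abs(z[c("zR", "zA", "zD")])))
  expect_equal(m$label, "MAX3")
  expect_true(m$p_value >= 0 && m$p_value <= 1)
  # delta-method correlation matrix is a valid correlation matrix
  R <- m$correlations
  expect_equal(diag(R), c(REC = 1, ADD = 1, DOM = 1))
  expect_true(all(abs(R) <= 1 + 1e-12))
})

test_that("trivariate-normal and permutation MAX3 p-values agree", {
  set.seed(29)
  for (r in 1:3) {
    gr <- null_groups(120, 0.4)
    pn <- max3_test(gr$gt)$p_value
    pp <- max3_test(gr$gt, "permutation", draws = 1500, seed = 100 + r)$p_value
    mc <- 3 * sqrt(pn * (1 - pn) / 1500)
    expect_lt(abs(pn - pp), mc + 0.02)
  }
})

test_that("degenerate inputs raise errors instead of returning NaN", {
  expect_error(kruskal_wallis(group_by_genotype(rep(5, 12),
                                                rep(0:2, each = 4))), "tied")
  # this arrangement makes the additive combination variance exactly zero
  y <- 1:6; g <- c(1, 2, 0, 2, 0, 1)
  expect_error(npt_statistic(group_by_genotype(y, g), "ADD"), "degenerate")
  # distinct group 0 against tied groups 1/2 is still well-defined
  expect_no_error(z1_statistic(group_by_genotype(c(1, 2, rep(5, 8)),
                                                 c(0, 0, rep(1:2, 4)))))
})
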