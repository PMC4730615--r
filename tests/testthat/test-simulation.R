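test_that("truncated Gumbel draws respect the truncation region and CDF", {
  law <- error_law("tgev", scale = 5)
  x <- sample_error(law, 50000, seed = 1)
  expect_true(all(x >= 0))
  # untruncated Gumbel mass below 0 is exp(-1)
  expect_equal(tppassoc:::pgev(0, 0, 0, 5), exp(-1))
  # empirical CDF vs (F(x) - F(0)) / (1 - F(0))
  qs <- quantile(x, c(0.1, 0.25, 0.5, 0.75, 0.9))
  Ft <- function(q) (tppassoc:::pgev(q, 0, 0, 5) - exp(-1)) / (1 - exp(-1))
  expect_lt(max(abs(Ft(qs) - c(0.1, 0.25, 0.5, 0.75, 0.9))), 0.01)

  xr <- sample_error(error_law("tgev", scale = 5, side = "right"), 2000,
                     seed = 2)
  expect_true(all(xr <= 0))
  expect_error(sample_error(error_law("tgev", scale = 1, truncation = 1e6),
                            10), "empty truncation region")
})

test_that("error law streams are reproducible and families distinct", {
  law <- error_law("tgev", scale = 5)
  expect_identical(sample_error(law, 100, seed = 7),
                   sample_error(law, 100, seed = 7))
  g1 <- sample_error(error_law("gev", shape = 0.2, scale = 2), 20000,
                     seed = 3)
  # GEV median equals its closed-form quantile
  expect_lt(abs(median(g1) - tppassoc:::qgev(0.5, 0.2, 0, 2)), 0.05)
  t1 <- sample_error(error_law("t", df = 5, scale = 2), 20000, seed = 4)
  expect_lt(abs(median(t1)), 0.06)
  expect_error(error_law("t"), "degrees of freedom")
})

test_that("genotypes follow Hardy-Weinberg at the requested MAF", {
  g <- simulate_genotypes(1e5, 0.5, seed = 5)
  counts <- tabulate(g + 1L, 3L)
  # goodness-of-fit against the Hardy-Weinberg trinomial
  expect_gt(chisq.test(counts, p = c(0.25, 0.5, 0.25))$p.value, 1e-3)
  expect_lt(max(abs(counts / 1e5 - c(0.25, 0.5, 0.25))), 0.01)

  g2 <- simulate_genotypes(1500, 0.05, seed = 6)
  expect_lt(sum(g2 == 2L), 15)  # E[n2] = 3.75
  expect_identical(simulate_genotypes(50, 0.3, seed = 8),
                   simulate_genotypes(50, 0.3, seed = 8))
})

test_that("the trait model applies the genotype scores of each model", {
  g <- c(0L, 1L, 2L)
  tiny <- error_law("tgev", scale = 1e-13)
  expect_equal(simulate_trait(g, "ADD", 0.5, 0.5, tiny, seed = 1),
               c(0.5, 1.0, 1.5), tolerance = 1e-9)
  expect_equal(simulate_trait(g, "REC", 0.5, 0.5, tiny, seed = 1),
               c(0.5, 0.5, 1.5), tolerance = 1e-9)
  expect_equal(simulate_trait(g, "DOM", 0.5, 0.5, tiny, seed = 1),
               c(0.5, 1.5, 1.5), tolerance = 1e-9)
  # null model ignores genotype
  y <- simulate_trait(rep(g, 200), "NULL", 0.5, 0.5, seed = 9)
  expect_equal(length(y), 600)

  # under REC, genotypes 0 and 1 are exchangeable
  set.seed(10)
  gg <- simulate_genotypes(4000, 0.4)
  yy <- simulate_trait(gg, "REC")
  expect_lt(abs(win_prob(yy[gg == 0], yy[gg == 1]) - 0.5), 0.03)
})

test_that("selection-rate experiment rows account for every replicate", {
  tab <- experiment_tsr(mafs = c(0.3, 0.5), models = c("REC", "ADD"),
                        replicates = 60, seed = 42)
  expect_equal(nrow(tab), 4L)
  expect_equal(tab$rate_REC + tab$rate_ADD + tab$rate_DOM + tab$fallback_rate,
               rep(1, 4))
  tab2 <- experiment_tsr(mafs = c(0.3, 0.5), models = c("REC", "ADD"),
                         replicates = 60, seed = 42)
  expect_identical(tab, tab2)
  # REC truth at common MAF concentrates on REC even at this size
  expect_gt(tab$rate_REC[tab$model == "REC" & tab$maf == 0.5], 0.5)
})

test_that("type-1 and power drivers return calibrated tidy tables", {
  t1 <- experiment_type1(mafs = 0.3, alpha = 0.2, tests = c("KW", "TPP"),
                         n = 300, replicates = 60, seed = 7)
  expect_setequal(t1$test, c("KW", "TPP"))
  expect_true(all(t1$size >= 0 & t1$size <= 1))
  expect_identical(t1, experiment_type1(mafs = 0.3, alpha = 0.2,
                                        tests = c("KW", "TPP"), n = 300,
                                        replicates = 60, seed = 7))

  pw <- experiment_power(mafs = 0.4, models = "DOM", alpha = 0.05,
                         tests = c("ZA", "TPP"), n = 400, beta1 = 1,
                         replicates = 60, seed = 11)
  expect_true(all(pw$power > 0.3))  # strong effect, easy cell
  expect_named(min_power(pw), c("TPP", "ZA"))
})

test_that("power increases with effect size", {
  pows <- vapply(c(0.25, 0.75, 2), function(b1) {
    pw <- experiment_power(mafs = 0.35, models = "ADD", tests = "TPP",
                           n = 250, beta1 = b1, replicates = 80, seed = 13)
    pw$power
  }, numeric(1))
  # allow Monte Carlo slack on the middle point
  expect_gte(pows[2], pows[1] - 0.1)
  expect_gte(pows[3], pows[2] - 0.1)
  expect_gt(pows[3], pows[1])
})
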