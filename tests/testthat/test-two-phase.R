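test_that("model selection follows the threshold rule with ADD boundary", {
  xi <- qnorm(0.9)
  expect_equal(select_model(2.0, xi), "DOM")
  expect_equal(select_model(-2.0, xi), "REC")
  expect_equal(select_model(0, xi), "ADD")
  expect_equal(select_model(xi, xi), "ADD")     # boundary goes to additive
  expect_equal(select_model(-xi, xi), "ADD")
  expect_error(select_model(Inf, xi))
})

test_that("estimated correlations are valid and track the sampling truth", {
  set.seed(41)
  gr <- null_groups(600, 0.3)
  r <- estimate_rho(gr$gt)
  expect_s3_class(r, "rho_estimates")
  expect_true(all(abs(c(r$rho_R, r$rho_A, r$rho_D)) <= 1))

  # Monte Carlo oracle at reduced scale: the delta-method estimate should
  # approximate the empirical correlation of (Z1, Zx) across replicates
  reps <- 400
  zs <- matrix(NA_real_, reps, 4)
  rh <- matrix(NA_real_, reps, 3)
  for (i in seq_len(reps)) {
    gr <- null_groups(900, 0.3)
    zs[i, ] <- all_z(gr$y, gr$g)
    e <- tppassoc:::compute_estimates(gr$gt$values0, gr$gt$values1,
                                      gr$gt$values2)
    rh[i, ] <- tppassoc:::rho_from_estimates(e)
  }
  emp <- c(cor(zs[, 1], zs[, 2]), cor(zs[, 1], zs[, 3]),
           cor(zs[, 1], zs[, 4]))
  expect_lt(max(abs(colMeans(rh) - emp)), 0.08)
  expect_lt(max(apply(rh, 2, sd)), 0.08)
})

test_that("the size equation recovers alpha in both degenerate limits", {
  for (a in c(0.05, 0.001)) {
    expect_lt(abs(adjusted_alpha(a, rho = c(0, 0, 0)) - a), 1e-8)
    expect_lt(abs(adjusted_alpha(a, rho = c(1, 1, 1)) - a), 1e-8)
    expect_lt(abs(adjusted_alpha(a, rho = c(-1, -1, -1)) - a), 1e-8)
  }
})

test_that("adjusted level is below nominal for estimated correlations and
           increases with alpha", {
  set.seed(43)
  for (maf in c(0.15, 0.3, 0.45)) {
    gr <- null_groups(800, maf)
    r <- estimate_rho(gr$gt)
    a1 <- adjusted_alpha(0.05, rho = r)
    a2 <- adjusted_alpha(0.10, rho = r)
    expect_gt(a1, 0); expect_lt(a1, 0.05)
    expect_gt(a2, a1)
  }
})

test_that("the two-phase test rejects under complete separation and is
           deterministic", {
  y <- c(rnorm(60, 0), rnorm(60, 40), rnorm(60, 80))
  g <- rep(0:2, each = 60)
  r1 <- tpp_test(y, g)
  expect_true(r1$reject)
  expect_lt(r1$alpha_star, r1$alpha_nominal)
  expect_equal(r1$selected_model,
               select_model(r1$z1, r1$xi))
  r2 <- tpp_test(y, g)
  expect_identical(r1, r2)
})

test_that("decision is exactly |Z| > z(1 - alpha*/2)", {
  set.seed(47)
  gr <- null_groups(400, 0.3)
  r <- tpp_test(gr$y, gr$g)
  expect_identical(r$reject,
                   abs(r$phase2$statistic) > qnorm(1 - r$alpha_star / 2))
})

test_that("adjusted threshold is reported for a user-supplied nominal level", {
  set.seed(53)
  gr <- null_groups(500, 0.25)
  r <- tpp_test(gr$y, gr$g, nominal_threshold = 5e-5)
  expect_lt(r$adjusted_threshold, 5e-5)
  expect_gt(r$adjusted_threshold, 0)
})

test_that("degenerate rare-homozygote group falls back to the two-group test", {
  set.seed(59)
  g <- c(rep(0L, 90), rep(1L, 25), 2L)
  y <- 0.5 + sample_error(error_law("tgev", scale = 5), length(g))
  expect_warning(r <- tpp_test(y, g), "falling back")
  expect_true(r$fallback)
  expect_identical(r$alpha_star, r$alpha_nominal)
  expect_identical(r$selected_model, "ADD")
  # two-group statistic built from groups 0 and 1 only
  f <- win_prob(y[g == 0L], y[g == 1L])
  v <- win_prob_variance(y[g == 0L], y[g == 1L])
  expect_equal(r$phase2$statistic, (f - 0.5) / sqrt(v))

  expect_error(tpp_test(y[1:91], g[1:91]), "fewer than two genotype groups")
  expect_error(tpp_test(c(y[1:90], 1, 2, 3), c(rep(0L, 90), 1L, 2L, 2L)),
               "heterozygote")
})

test_that("residualization has OLS properties and flags collinearity", {
  y <- c(3, 1, 4, 1, 5, 9)
  expect_equal(residualize(y), y - mean(y))
  x <- cbind(a = c(1, 2, 3, 4, 5, 6))
  expect_equal(residualize(2 + 3 * x[, 1], x), rep(0, 6))
  set.seed(61)
  X <- cbind(a = rnorm(40), b = rnorm(40))
  r <- residualize(rnorm(40), X)
  expect_lt(max(abs(crossprod(X, r))), 1e-8 * max(abs(r)) * 40)
  expect_lt(abs(sum(r)), 1e-8)
  Xbad <- cbind(X, c = X[, "a"] * 2)
  expect_error(residualize(rnorm(40), Xbad), "collinear column")
  expect_error(residualize(1:5, X), "rows")
})
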