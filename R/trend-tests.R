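#' @title Single-phase rank tests: Z1, the model-specific trend tests, KW
#'   and MAX3
#'
#' @description
#' All statistics are built from the win-probability estimates of
#' [win_prob_estimates()] and are therefore invariant under any strictly
#' increasing transform of the trait.
#'
#' * `z1_statistic()` contrasts \eqn{\hat f_{01}} and \eqn{\hat f_{12}}:
#'   positive values lean dominant, negative lean recessive; asymptotically
#'   standard normal under the null.
#' * `npt_statistic()` is the nonparametric trend test optimal under a given
#'   genetic model (`"REC"`, `"ADD"`, `"DOM"`), each a studentized weighted
#'   combination of win probabilities, standard normal under the null.
#' * `kruskal_wallis()` is the classical Kruskal-Wallis comparator (midrank
#'   H with tie correction, chi-squared reference).
#' * `max3_test()` is \eqn{\max(|Z_R|, |Z_A|, |Z_D|)} with its null law
#'   either from a trivariate normal with delta-method correlations or from
#'   permutation of genotype labels.
#'
#' @param g A [group_by_genotype()] object.
#' @param ties Tie handling, see [win_prob()].
#' @return An object of class `test_result` with elements `statistic`,
#'   `p_value`, `reference` (one of `"standard-normal"`,
#'   `"chi-squared"`, `"max3-null"`), `label` and method details.
#' @name trend_tests
NULL

new_test_result <- function(statistic, p_value, reference, label, ...) {
  structure(list(statistic = statistic, p_value = p_value,
                 reference = reference, label = label, ...),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s = %.4f  (%s)  two-sided p = %.4g\n",
              x$label, x$statistic, x$reference, x$p_value))
  invisible(x)
}

# minimum denominator treated as non-degenerate
.DENOM_EPS <- 1e-12

check_denom <- function(v, what) {
  if (!is.finite(v) || v < .DENOM_EPS) {
    stop("degenerate variance in ", what,
         " (pathological ties or tiny groups)")
  }
  invisible(v)
}

# all four Z statistics and the ADD weights from a compute_estimates() list.
# safe = TRUE (permutation null on tiny groups): a zero combination variance
# scores 0 when the numerator is also zero, +-Inf otherwise, instead of
# raising the degenerate-variance error.
z_statistics <- function(e, safe = FALSE) {
  n0 <- e$n0; n1 <- e$n1; n2 <- e$n2; n <- n0 + n1 + n2
  zdiv <- if (safe) {
    function(num, den, what) {
      if (!is.finite(den) || den < .DENOM_EPS) {
        if (abs(num) < .DENOM_EPS) 0 else sign(num) * Inf
      } else num / sqrt(den)
    }
  } else {
    function(num, den, what) num / sqrt(check_denom(den, what))
  }
  z1 <- zdiv(e$f01 - e$f12, e$var01 - 2 * e$cov01_12 + e$var12, "Z1")
  fR <- (n0 * e$f02 + n1 * e$f12) / (n0 + n1)
  vR <- (n0^2 * e$var02 + 2 * n0 * n1 * e$cov02_12 + n1^2 * e$var12) /
    (n0 + n1)^2
  # var01, var12 are >= 1/(4 na nb) > 0, so the weights are always defined
  w1s <- sqrt((n0 + n1) / ((n + n1) * check_denom(e$var01, "w1")))
  w2s <- sqrt((n1 + n2) / ((n + n1) * check_denom(e$var12, "w2")))
  w1 <- w1s / (w1s + w2s); w2 <- w2s / (w1s + w2s)
  fA <- w1 * e$f01 + w2 * e$f12
  vA <- w1^2 * e$var01 + 2 * w1 * w2 * e$cov01_12 + w2^2 * e$var12
  fD <- (n1 * e$f01 + n2 * e$f02) / (n1 + n2)
  vD <- (n1^2 * e$var01 + 2 * n1 * n2 * e$cov01_02 + n2^2 * e$var02) /
    (n1 + n2)^2
  list(z1 = z1,
       zR = zdiv(fR - 0.5, vR, "ZR"),
       zA = zdiv(fA - 0.5, vA, "ZA"),
       zD = zdiv(fD - 0.5, vD, "ZD"),
       w1 = w1, w2 = w2)
}

two_sided_p <- function(z) 2 * stats::pnorm(-abs(z))

#' @rdname trend_tests
#' @export
z1_statistic <- function(g, ties = c("strict", "midrank")) {
  e <- win_prob_estimates(g, ties)
  z <- z_statistics(e)
  new_test_result(z$z1, two_sided_p(z$z1), "standard-normal", "Z1")
}

#' @rdname trend_tests
#' @param model Genetic model: `"REC"`, `"ADD"` or `"DOM"`.
#' @export
npt_statistic <- function(g, model = c("REC", "ADD", "DOM"),
                          ties = c("strict", "midrank")) {
  model <- match.arg(model)
  e <- win_prob_estimates(g, ties)
  z <- z_statistics(e)
  stat <- switch(model, REC = z$zR, ADD = z$zA, DOM = z$zD)
  label <- switch(model, REC = "ZR", ADD = "ZA", DOM = "ZD")
  new_test_result(stat, two_sided_p(stat), "standard-normal", label,
                  model = model, weights = c(w1 = z$w1, w2 = z$w2))
}

#' @rdname trend_tests
#' @export
kruskal_wallis <- function(g) {
  g <- as_grouped_trait(g)
  y <- c(g$values0, g$values1, g$values2)
  grp <- factor(rep.int(c(0L, 1L, 2L), c(g$n0, g$n1, g$n2)))
  grp <- droplevels(grp)
  if (nlevels(grp) < 2L) stop("need at least two nonempty genotype groups")
  if (length(unique(y)) == 1L) stop("all observations tied")
  kt <- stats::kruskal.test(y, grp)
  new_test_result(unname(kt$statistic), kt$p.value, "chi-squared", "KW",
                  df = unname(kt$parameter))
}

# delta-method correlation matrix of (ZR, ZA, ZD) from the plug-in covariance
npt_correlations <- function(e, z = NULL) {
  if (is.null(z)) z <- z_statistics(e)
  S <- estimates_cov_matrix(e)
  n0 <- e$n0; n1 <- e$n1; n2 <- e$n2
  B <- cbind(REC = c(0, n1 / (n0 + n1), n0 / (n0 + n1)),
             ADD = c(z$w1, z$w2, 0),
             DOM = c(n1 / (n1 + n2), 0, n2 / (n1 + n2)))
  V <- t(B) %*% S %*% B
  d <- sqrt(diag(V))
  if (any(d < sqrt(.DENOM_EPS))) stop("degenerate covariance")
  stats::cov2cor(V)
}

#' @rdname trend_tests
#' @param null_method How the MAX3 p-value is computed:
#'   `"trivariate-normal"` (default; correlations of the three trend tests
#'   estimated by the delta method from the plug-in covariances) or
#'   `"permutation"` (genotype labels permuted `draws` times).
#' @param draws Number of permutations for `null_method = "permutation"`.
#' @param seed Optional integer seed used only for the permutation null.
#' @export
max3_test <- function(g, null_method = c("trivariate-normal", "permutation"),
                      draws = 10000L, seed = NULL,
                      ties = c("strict", "midrank")) {
  null_method <- match.arg(null_method)
  ties <- match.arg(ties)
  e <- win_prob_estimates(g, ties)
  z <- z_statistics(e)
  m <- max(abs(z$zR), abs(z$zA), abs(z$zD))
  if (null_method == "trivariate-normal") {
    R <- npt_correlations(e, z)
    p <- 1 - pmax3_normal(m, R)
    p <- min(max(p, 0), 1)
    new_test_result(m, p, "max3-null", "MAX3",
                    null_method = null_method, correlations = R)
  } else {
    g <- as_grouped_trait(g)
    y <- c(g$values0, g$values1, g$values2)
    lab <- rep.int(c(0L, 1L, 2L), c(g$n0, g$n1, g$n2))
    if (!is.null(seed)) {
      old <- get_rng_state(); on.exit(set_rng_state(old))
      set.seed(seed)
    }
    hits <- 0L
    for (b in seq_len(draws)) {
      lp <- sample(lab)
      ep <- compute_estimates(y[lp == 0L], y[lp == 1L], y[lp == 2L], ties)
      zp <- z_statistics(ep, safe = TRUE)
      if (max(abs(zp$zR), abs(zp$zA), abs(zp$zD)) >= m) hits <- hits + 1L
    }
    p <- (1 + hits) / (1 + draws)
    new_test_result(m, p, "max3-null", "MAX3",
                    null_method = null_method, draws = draws)
  }
}
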