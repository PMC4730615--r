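#' @title The two-phase procedure: model selection, size adjustment and the
#'   end-to-end test
#'
#' @description
#' Phase 1 classifies the genetic model with the selection statistic
#' \eqn{Z_1}: dominant if \eqn{Z_1 > \xi}, recessive if \eqn{Z_1 < -\xi},
#' additive otherwise (the boundary goes to additive). Phase 2 applies the
#' trend test matched to the selected model, but at an adjusted level
#' \eqn{\alpha^*} rather than the nominal \eqn{\alpha}: because
#' \eqn{(Z_1, Z_x)} is asymptotically bivariate normal with correlation
#' \eqn{\rho_x}, testing naively at \eqn{\alpha} after selection would
#' distort the overall size. \eqn{\alpha^*} solves
#' \deqn{\alpha = \sum_{x} \int_{\Omega_x}
#'   \left\{\Phi\!\left(\frac{-z_{1-\alpha^*/2} - \rho_x u}
#'   {\sqrt{1-\rho_x^2}}\right) +
#'   \Phi\!\left(\frac{-z_{1-\alpha^*/2} + \rho_x u}
#'   {\sqrt{1-\rho_x^2}}\right)\right\} d\Phi(u)}
#' over the selection regions \eqn{\Omega_R = \{u < -\xi\}},
#' \eqn{\Omega_A = \{-\xi \le u \le \xi\}}, \eqn{\Omega_D = \{u > \xi\}}.
#'
#' @param xi Positive selection threshold; default the 90% standard-normal
#'   quantile, `qnorm(0.9)`.
#' @name two_phase
NULL

#' @rdname two_phase
#' @param z1 Value of the selection statistic.
#' @return `select_model()`: one of `"REC"`, `"ADD"`, `"DOM"`.
#' @export
select_model <- function(z1, xi = stats::qnorm(0.9)) {
  stopifnot(is.finite(z1), xi > 0)
  if (z1 > xi) "DOM" else if (z1 < -xi) "REC" else "ADD"
}

#' @rdname two_phase
#' @param g A [group_by_genotype()] object, every group of size >= 2.
#' @param ties Tie handling, see [win_prob()].
#' @return `estimate_rho()`: an object of class `rho_estimates` with
#'   `rho_R`, `rho_A`, `rho_D` in \eqn{[-1, 1]} — the delta-method
#'   correlations between \eqn{Z_1} and each phase-2 statistic, treating
#'   both as linear forms in \eqn{(\hat f_{01}, \hat f_{12}, \hat f_{02})}
#'   with the plug-in covariance matrix.
#' @export
estimate_rho <- function(g, ties = c("strict", "midrank")) {
  e <- win_prob_estimates(g, ties)
  r <- rho_from_estimates(e)
  structure(list(rho_R = r[[1L]], rho_A = r[[2L]], rho_D = r[[3L]]),
            class = "rho_estimates")
}

# fast path: numeric (rho_R, rho_A, rho_D) from a compute_estimates() list
rho_from_estimates <- function(e, z = NULL) {
  if (is.null(z)) z <- z_statistics(e)
  S <- estimates_cov_matrix(e)
  n0 <- e$n0; n1 <- e$n1; n2 <- e$n2
  a <- c(1, -1, 0)                       # Z1 numerator weights
  B <- cbind(c(0, n1 / (n0 + n1), n0 / (n0 + n1)),   # REC
             c(z$w1, z$w2, 0),                       # ADD
             c(n1 / (n1 + n2), 0, n2 / (n1 + n2)))   # DOM
  Sa <- S %*% a
  qa <- drop(crossprod(a, Sa))
  qb <- colSums(B * (S %*% B))
  if (qa < .DENOM_EPS || any(qb < .DENOM_EPS)) stop("degenerate covariance")
  r <- drop(crossprod(B, Sa)) / sqrt(qa * qb)
  pmin(1, pmax(-1, r))
}

#' @export
print.rho_estimates <- function(x, ...) {
  cat(sprintf("Joint null correlations: rho_R = %.3f, rho_A = %.3f, rho_D = %.3f\n",
              x$rho_R, x$rho_A, x$rho_D))
  invisible(x)
}

as_rho_vector <- function(rho) {
  if (inherits(rho, "rho_estimates")) {
    c(rho$rho_R, rho$rho_A, rho$rho_D)
  } else if (is.numeric(rho) && length(rho) == 3L) {
    as.numeric(rho)
  } else {
    stop("rho must be a 'rho_estimates' object or a numeric vector ",
         "(rho_R, rho_A, rho_D)")
  }
}

# right-hand side of the size equation at phase-2 level `astar`
size_equation_rhs <- function(astar, xi, rho, nodes = 200L, lim = 8) {
  cq <- stats::qnorm(1 - astar / 2)
  segs <- list(gl_nodes(nodes, -lim, -xi),
               gl_nodes(nodes, -xi, xi),
               gl_nodes(nodes, xi, lim))
  bounds <- list(c(-Inf, -xi), c(-xi, xi), c(xi, Inf))
  tot <- 0
  for (s in 1:3) {
    r <- rho[s]
    if (abs(r) >= 1 - 1e-10) {
      # degenerate limit Z_x = sign(r) Z_1: Phi-measure of {|u| > cq} on
      # the selection region, in closed form (quadrature cannot integrate
      # the indicator accurately)
      lo <- bounds[[s]][1L]; hi <- bounds[[s]][2L]
      msr <- function(a, b) max(0, stats::pnorm(b) - stats::pnorm(a))
      tot <- tot + msr(max(lo, cq), hi) + msr(lo, min(hi, -cq))
    } else {
      u <- segs[[s]]$x; w <- segs[[s]]$w
      sdc <- sqrt(1 - r^2)
      inner <- stats::pnorm((-cq - r * u) / sdc) +
               stats::pnorm((-cq + r * u) / sdc)
      tot <- tot + sum(w * stats::dnorm(u) * inner)
    }
  }
  tot
}

#' @rdname two_phase
#' @param alpha Nominal overall significance level in (0, 1).
#' @param rho A `rho_estimates` object or numeric `(rho_R, rho_A, rho_D)`.
#' @param nodes Gauss-Legendre nodes per integration segment.
#' @param tol Absolute bisection tolerance on \eqn{\alpha^*}.
#' @return `adjusted_alpha()`: the phase-2 level \eqn{\alpha^*} solving the
#'   size equation. Equals `alpha` exactly when all correlations are 0 or
#'   in the degenerate limit \eqn{|\rho_x| = 1}; strictly increasing in
#'   `alpha`.
#' @export
adjusted_alpha <- function(alpha, xi = stats::qnorm(0.9), rho,
                           nodes = 200L, tol = 1e-10) {
  stopifnot(alpha > 0, alpha < 1, xi > 0)
  rho <- as_rho_vector(rho)
  stopifnot(all(abs(rho) <= 1))
  lo <- 1e-12; hi <- 1 - 1e-12
  # the RHS is strictly increasing in alpha*: bisection has a unique root
  if (size_equation_rhs(hi, xi, rho, nodes) < alpha ||
      size_equation_rhs(lo, xi, rho, nodes) > alpha) {
    stop("no sign change in the size-equation bracket")  # cannot occur
  }
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (size_equation_rhs(mid, xi, rho, nodes) < alpha) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' @rdname two_phase
#' @param traits,genotypes Per-subject trait values and genotype counts
#'   (0/1/2), equal length, complete cases only.
#' @param nominal_threshold Optional extra nominal level (e.g. a genome-wide
#'   `5e-5`) for which the adjusted per-test threshold is also reported.
#' @return `tpp_test()`: an object of class `tpp_result` with the selection
#'   statistic `z1`, `selected_model`, the phase-2 `test_result`,
#'   `alpha_nominal`, `alpha_star`, the `reject` decision
#'   (\eqn{|Z_x| > z_{1-\alpha^*/2}}), the `rho` estimates, and a
#'   `fallback` flag. If the rare homozygote group has fewer than 2
#'   subjects the procedure cannot select a model; it then applies the
#'   two-group trend test on the remaining well-populated groups (the
#'   zero-weight limit of the additive test) at the unadjusted level and
#'   warns.
#' @export
tpp_test <- function(traits, genotypes, alpha = 0.05,
                     xi = stats::qnorm(0.9),
                     ties = c("strict", "midrank"),
                     nominal_threshold = NULL) {
  ties <- match.arg(ties)
  g <- group_by_genotype(traits, genotypes)
  deficient <- c(g$n0, g$n1, g$n2) < 2L
  if (sum(deficient) >= 2L) {
    stop("fewer than two genotype groups with >= 2 subjects; ",
         "no trend test is defined")
  }
  if (deficient[2L]) {
    stop("heterozygote group has < 2 subjects; no trend test is defined")
  }
  if (any(deficient)) {
    # degenerate minor-homozygote (or major-homozygote) group: two-group
    # fallback at the unadjusted level
    if (deficient[3L]) {
      warning("genotype-2 group has < 2 subjects; falling back to the ",
              "two-group trend test on genotypes 0 vs 1 at the unadjusted level")
      a <- g$values0; b <- g$values1
    } else {
      warning("genotype-0 group has < 2 subjects; falling back to the ",
              "two-group trend test on genotypes 1 vs 2 at the unadjusted level")
      a <- g$values1; b <- g$values2
    }
    f <- win_prob(a, b, ties)
    v <- check_denom(win_prob_variance(a, b, ties), "fallback ZA")
    z <- (f - 0.5) / sqrt(v)
    phase2 <- new_test_result(z, two_sided_p(z), "standard-normal", "ZA",
                              model = "ADD")
    out <- structure(
      list(z1 = NA_real_, selected_model = "ADD", phase2 = phase2,
           alpha_nominal = alpha, alpha_star = alpha,
           reject = abs(z) > stats::qnorm(1 - alpha / 2),
           rho = NULL, fallback = TRUE, xi = xi,
           n = c(n0 = g$n0, n1 = g$n1, n2 = g$n2)),
      class = "tpp_result")
    if (!is.null(nominal_threshold)) {
      out$nominal_threshold <- nominal_threshold
      out$adjusted_threshold <- nominal_threshold
    }
    return(out)
  }
  e <- win_prob_estimates(g, ties)
  z <- z_statistics(e)
  model <- select_model(z$z1, xi)
  rho <- rho_from_estimates(e, z)
  astar <- adjusted_alpha(alpha, xi, rho)
  stat <- switch(model, REC = z$zR, ADD = z$zA, DOM = z$zD)
  label <- switch(model, REC = "ZR", ADD = "ZA", DOM = "ZD")
  phase2 <- new_test_result(stat, two_sided_p(stat), "standard-normal",
                            label, model = model)
  out <- structure(
    list(z1 = z$z1, selected_model = model, phase2 = phase2,
         alpha_nominal = alpha, alpha_star = astar,
         reject = abs(stat) > stats::qnorm(1 - astar / 2),
         rho = structure(list(rho_R = rho[1L], rho_A = rho[2L],
                              rho_D = rho[3L]), class = "rho_estimates"),
         fallback = FALSE, xi = xi,
         n = c(n0 = g$n0, n1 = g$n1, n2 = g$n2)),
    class = "tpp_result")
  if (!is.null(nominal_threshold)) {
    out$nominal_threshold <- nominal_threshold
    out$adjusted_threshold <- adjusted_alpha(nominal_threshold, xi, rho)
  }
  out
}

#' @export
print.tpp_result <- function(x, ...) {
  cat("Two-phase nonparametric association test\n")
  cat(sprintf("  groups: n0 = %d, n1 = %d, n2 = %d\n",
              x$n["n0"], x$n["n1"], x$n["n2"]))
  if (x$fallback) {
    cat("  [degenerate group: two-group fallback, no model selection]\n")
  } else {
    cat(sprintf("  phase 1: Z1 = %.4f (xi = %.4f) -> %s model\n",
                x$z1, x$xi, x$selected_model))
  }
  cat(sprintf("  phase 2: %s = %.4f, two-sided p = %.4g\n",
              x$phase2$label, x$phase2$statistic, x$phase2$p_value))
  cat(sprintf("  nominal alpha = %g, adjusted alpha* = %.4g -> %s\n",
              x$alpha_nominal, x$alpha_star,
              if (x$reject) "reject H0" else "do not reject H0"))
  if (!is.null(x$nominal_threshold)) {
    cat(sprintf("  adjusted threshold for nominal %g: %.4g\n",
                x$nominal_threshold, x$adjusted_threshold))
  }
  invisible(x)
}

#' Residualize a trait on covariates
#'
#' Ordinary-least-squares residuals of the trait on an intercept plus the
#' given covariates, for covariate adjustment before the rank tests (regress
#' first, then test the residuals).
#'
#' @param traits Numeric trait vector.
#' @param covariates Optional numeric matrix or data frame, one row per
#'   subject. `NULL` or zero columns mean intercept only (centering).
#' @return Numeric vector of residuals, orthogonal to every covariate
#'   column.
#' @export
residualize <- function(traits, covariates = NULL) {
  traits <- as.numeric(traits)
  if (is.null(covariates) || NCOL(covariates) == 0L ||
      (is.matrix(covariates) && ncol(covariates) == 0L)) {
    return(traits - mean(traits))
  }
  X <- as.matrix(covariates)
  if (nrow(X) != length(traits)) {
    stop("covariate rows (", nrow(X), ") != trait length (", length(traits), ")")
  }
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  M <- cbind(`(Intercept)` = 1, X)
  qrM <- qr(M)
  if (qrM$rank < ncol(M)) {
    dropped <- colnames(M)[qrM$pivot[(qrM$rank + 1L):ncol(M)]]
    stop("covariate matrix is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  unname(qr.resid(qrM, traits))
}
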