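#' @title Win-probability estimators and their plug-in (co)variances
#'
#' @description
#' The building block of every test in this package is the pairwise win
#' probability \eqn{f_{ab} = \Pr(Y_a < Y_b)} between two genotype groups,
#' estimated by the fraction of cross-group pairs in which the first group's
#' value is strictly below the second's (the Mann-Whitney functional). Under
#' no association every \eqn{f_{ab} = 1/2}.
#'
#' `win_prob()` returns the point estimate; `win_prob_variance()` the
#' three-term plug-in variance estimator (two sums of squared centered
#' per-observation means plus the constant \eqn{1/(4 n_a n_b)});
#' `win_prob_cov()` the plug-in covariance between two win probabilities that
#' share one group.
#'
#' @param a,b Numeric vectors: trait values of the two groups ("a beats b"
#'   means `a < b` contributes).
#' @param ties Tie handling: `"strict"` scores ties 0 (the default,
#'   matching the strict indicator \eqn{I(y_i < y_j)}); `"midrank"` scores
#'   ties 1/2, for traits with point masses.
#' @name win_prob
NULL

# per-observation means of the pairwise indicator score(a_i < b_j):
#   row[i] = mean_j score(a_i, b_j),  col[j] = mean_i score(a_i, b_j)
# O((na+nb) log(na+nb)) via sorted counts.
rowcol_means <- function(a, b, ties = c("strict", "midrank")) {
  ties <- match.arg(ties)
  na <- length(a); nb <- length(b)
  as_ <- sort(a); bs <- sort(b)
  if (ties == "strict") {
    row <- (nb - findInterval(a, bs)) / nb              # #{b > a_i}
    col <- findInterval(b, as_, left.open = TRUE) / na  # #{a < b_j}
  } else {
    le <- findInterval(a, bs)                       # #{b <= a_i}
    lt <- findInterval(a, bs, left.open = TRUE)     # #{b <  a_i}
    row <- (nb - le + 0.5 * (le - lt)) / nb
    lt2 <- findInterval(b, as_, left.open = TRUE)
    le2 <- findInterval(b, as_)
    col <- (lt2 + 0.5 * (le2 - lt2)) / na
  }
  list(row = row, col = col)
}

check_group <- function(x, min_size, what) {
  if (length(x) == 0L) stop("empty genotype group (", what, ")")
  if (length(x) < min_size) {
    stop("variance undefined for group of size < 2 (", what, ")")
  }
  invisible(TRUE)
}

#' @rdname win_prob
#' @return `win_prob()`: the estimate in \eqn{[0, 1]}.
#' @examples
#' win_prob(c(1, 4), c(2, 3, 5))  # 4 of the 6 pairs have a < b
#' @export
win_prob <- function(a, b, ties = c("strict", "midrank")) {
  if (length(a) == 0L || length(b) == 0L) stop("empty genotype group")
  mean(rowcol_means(a, b, ties)$row)
}

#' @rdname win_prob
#' @return `win_prob_variance()`: the plug-in variance, strictly positive.
#' @export
win_prob_variance <- function(a, b, ties = c("strict", "midrank")) {
  check_group(a, 2L, "first"); check_group(b, 2L, "second")
  rc <- rowcol_means(a, b, ties)
  na <- length(a); nb <- length(b)
  (nb - 1) / (na^2 * nb) * sum((rc$row - 0.5)^2) +
    (na - 1) / (na * nb^2) * sum((rc$col - 0.5)^2) +
    1 / (4 * na * nb)
}

#' @rdname win_prob
#' @param left,shared,right Numeric vectors: the shared group appears in both
#'   win probabilities; `left` and `right` are the non-shared groups, in the
#'   order of the two pairs.
#' @param topology Which group is shared between the two win probabilities:
#'   `"shared-middle-01-12"` for cov(f(left, shared), f(shared, right)),
#'   `"shared-right-02-12"` for cov(f(left, shared), f(right, shared)),
#'   `"shared-left-01-02"` for cov(f(shared, left), f(shared, right)).
#' @return `win_prob_cov()`: the plug-in covariance (sign unrestricted).
#' @export
win_prob_cov <- function(left, shared, right,
                         topology = c("shared-middle-01-12",
                                      "shared-right-02-12",
                                      "shared-left-01-02"),
                         ties = c("strict", "midrank")) {
  topology <- match.arg(topology)
  if (length(left) == 0L || length(shared) == 0L || length(right) == 0L) {
    stop("empty genotype group")
  }
  ns <- length(shared)
  switch(topology,
    "shared-middle-01-12" = {
      u <- rowcol_means(left, shared, ties)$col    # mean_i I(left_i < s_j)
      v <- rowcol_means(shared, right, ties)$row   # mean_k I(s_j < right_k)
      sum((u - 0.5) * (v - 0.5)) / ns^2
    },
    "shared-right-02-12" = {
      u <- rowcol_means(left, shared, ties)$col    # mean_i I(left_i < s_k)
      v <- rowcol_means(right, shared, ties)$col   # mean_j I(right_j < s_k)
      sum((u - 0.5) * (v - 0.5)) / ns^2
    },
    "shared-left-01-02" = {
      u <- rowcol_means(shared, left, ties)$row    # mean_j I(s_i < left_j)
      v <- rowcol_means(shared, right, ties)$row   # mean_k I(s_i < right_k)
      sum((u - 0.5) * (v - 0.5)) / ns^2
    })
}

# all win probabilities and plug-ins for one grouped trait, plain list
# (fast path used by the experiment drivers; win_prob_estimates() wraps it)
compute_estimates <- function(y0, y1, y2, ties = "strict") {
  n0 <- length(y0); n1 <- length(y1); n2 <- length(y2)
  rc01 <- rowcol_means(y0, y1, ties)
  rc12 <- rowcol_means(y1, y2, ties)
  rc02 <- rowcol_means(y0, y2, ties)
  list(
    n0 = n0, n1 = n1, n2 = n2,
    f01 = mean(rc01$row), f12 = mean(rc12$row), f02 = mean(rc02$row),
    var01 = (n1 - 1) / (n0^2 * n1) * sum((rc01$row - 0.5)^2) +
            (n0 - 1) / (n0 * n1^2) * sum((rc01$col - 0.5)^2) +
            1 / (4 * n0 * n1),
    var12 = (n2 - 1) / (n1^2 * n2) * sum((rc12$row - 0.5)^2) +
            (n1 - 1) / (n1 * n2^2) * sum((rc12$col - 0.5)^2) +
            1 / (4 * n1 * n2),
    var02 = (n2 - 1) / (n0^2 * n2) * sum((rc02$row - 0.5)^2) +
            (n0 - 1) / (n0 * n2^2) * sum((rc02$col - 0.5)^2) +
            1 / (4 * n0 * n2),
    cov01_12 = sum((rc01$col - 0.5) * (rc12$row - 0.5)) / n1^2,
    cov02_12 = sum((rc02$col - 0.5) * (rc12$col - 0.5)) / n2^2,
    cov01_02 = sum((rc01$row - 0.5) * (rc02$row - 0.5)) / n0^2)
}

#' All win probabilities and plug-in (co)variances for one SNP
#'
#' Computes \eqn{\hat f_{01}, \hat f_{12}, \hat f_{02}}, their three plug-in
#' variances and the three pairwise plug-in covariances in one pass.
#'
#' @param g A [group_by_genotype()] object with every group of size at
#'   least 2.
#' @inheritParams win_prob
#' @return An object of class `win_prob_estimates`: a list with `f01`,
#'   `f12`, `f02`, `var01`, `var12`, `var02`, `cov01_12`, `cov02_12`,
#'   `cov01_02` and the group sizes.
#' @export
win_prob_estimates <- function(g, ties = c("strict", "midrank")) {
  g <- as_grouped_trait(g)
  ties <- match.arg(ties)
  check_group(g$values0, 2L, "genotype 0")
  check_group(g$values1, 2L, "genotype 1")
  check_group(g$values2, 2L, "genotype 2")
  structure(compute_estimates(g$values0, g$values1, g$values2, ties),
            ties = ties, class = "win_prob_estimates")
}

#' @export
print.win_prob_estimates <- function(x, ...) {
  cat("Win-probability estimates\n")
  cat(sprintf("  f01 = %.4f  f12 = %.4f  f02 = %.4f\n", x$f01, x$f12, x$f02))
  cat(sprintf("  var01 = %.3e  var12 = %.3e  var02 = %.3e\n",
              x$var01, x$var12, x$var02))
  cat(sprintf("  cov01,12 = %.3e  cov02,12 = %.3e  cov01,02 = %.3e\n",
              x$cov01_12, x$cov02_12, x$cov01_02))
  invisible(x)
}

# 3x3 plug-in covariance matrix of (f01, f12, f02)
estimates_cov_matrix <- function(e) {
  matrix(c(e$var01,    e$cov01_12, e$cov01_02,
           e$cov01_12, e$var12,    e$cov02_12,
           e$cov01_02, e$cov02_12, e$var02), 3L, 3L)
}
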