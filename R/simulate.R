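#' Simulate genotypes, traits and full cohorts
#'
#' The generator reproduces the study conditions of the Monte Carlo
#' experiments: Hardy-Weinberg genotypes at a given minor allele frequency,
#' and a linear trait model \eqn{Y = \beta_0 + s(G)\,\beta_1 + \varepsilon}
#' where the genotype score \eqn{s(\cdot)} encodes the genetic model —
#' recessive (0,0,2), additive (0,1,2), dominant (0,2,2) — so the contrast
#' between the two homozygote groups equals \eqn{2\beta_1} under every
#' model, and \eqn{\varepsilon} follows an [error_law()] (default: Gumbel
#' scale 5, left-truncated at 0).
#'
#' @param n Number of subjects.
#' @param maf Minor allele frequency in (0, 0.5].
#' @param seed Optional integer seed.
#' @return `simulate_genotypes()`: integer vector of minor-allele counts
#'   with Hardy-Weinberg frequencies \eqn{(1-p)^2, 2p(1-p), p^2}.
#' @name simulate
NULL

#' @rdname simulate
#' @export
simulate_genotypes <- function(n, maf, seed = NULL) {
  stopifnot(n >= 1, maf > 0, maf <= 0.5)
  p <- c((1 - maf)^2, 2 * maf * (1 - maf), maf^2)
  with_seed(seed, sample(0:2, n, replace = TRUE, prob = p))
}

genotype_score <- function(genotypes, model) {
  scores <- switch(model,
                   REC = c(0, 0, 2), ADD = c(0, 1, 2), DOM = c(0, 2, 2),
                   `NULL` = c(0, 0, 0),
                   stop("unknown genetic model: ", model))
  scores[genotypes + 1L]
}

#' @rdname simulate
#' @param genotypes Integer vector of 0/1/2 counts.
#' @param model Generating genetic model: `"REC"`, `"ADD"`, `"DOM"`, or
#'   `"NULL"` (no genetic effect; `beta1` ignored).
#' @param beta0,beta1 Intercept and genetic effect of the linear trait
#'   model; study-condition defaults 0.5 and 0.5.
#' @param error An [error_law()]; default `error_law("tgev", scale = 5)`.
#' @return `simulate_trait()`: numeric trait vector.
#' @export
simulate_trait <- function(genotypes, model = c("ADD", "REC", "DOM", "NULL"),
                           beta0 = 0.5, beta1 = 0.5,
                           error = error_law("tgev", scale = 5),
                           seed = NULL) {
  model <- match.arg(model)
  stopifnot(all(genotypes %in% 0:2))
  eff <- if (model == "NULL") 0 else genotype_score(genotypes, model) * beta1
  beta0 + eff + sample_error(error, length(genotypes), seed = seed)
}

#' @rdname simulate
#' @return `simulate_cohort()`: a data frame with columns `id`, `trait`,
#'   `genotype`.
#' @export
simulate_cohort <- function(n = 1500, maf, model = c("ADD", "REC", "DOM", "NULL"),
                            beta0 = 0.5, beta1 = 0.5,
                            error = error_law("tgev", scale = 5),
                            seed = NULL) {
  model <- match.arg(model)
  with_seed(seed, {
    g <- simulate_genotypes(n, maf)
    y <- simulate_trait(g, model, beta0, beta1, error)
    data.frame(id = sprintf("S%04d", seq_len(n)), trait = y, genotype = g,
               stringsAsFactors = FALSE)
  })
}
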