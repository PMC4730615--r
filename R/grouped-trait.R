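#' Partition trait values by genotype
#'
#' Splits a quantitative trait vector into the three genotype groups of a
#' biallelic SNP coded as minor-allele counts 0, 1 and 2. Every downstream
#' statistic operates on this partition; within-group order is irrelevant.
#'
#' @param traits Numeric vector of trait values (no missing values; remove
#'   incomplete subjects before calling).
#' @param genotypes Integer-like vector of the same length with values in
#'   `{0, 1, 2}`.
#'
#' @return An object of class `grouped_trait`: a list with components
#'   `values0`, `values1`, `values2` (numeric vectors) and the counts
#'   `n0`, `n1`, `n2`.
#'
#' @examples
#' g <- group_by_genotype(c(5, 6, 7), c(0, 1, 2))
#' g$n1
#' @export
group_by_genotype <- function(traits, genotypes) {
  if (length(traits) != length(genotypes)) {
    stop("length mismatch: ", length(traits), " traits vs ",
         length(genotypes), " genotypes")
  }
  if (anyNA(traits) || anyNA(genotypes)) {
    stop("missing values must be removed before grouping")
  }
  bad <- which(!(genotypes %in% c(0, 1, 2)))
  if (length(bad) > 0L) {
    stop("genotype outside {0,1,2} at index ", bad[1L],
         " (value ", genotypes[bad[1L]], ")")
  }
  traits <- as.numeric(traits)
  g <- as.integer(genotypes)
  out <- structure(
    list(values0 = traits[g == 0L],
         values1 = traits[g == 1L],
         values2 = traits[g == 2L],
         n0 = sum(g == 0L), n1 = sum(g == 1L), n2 = sum(g == 2L)),
    class = "grouped_trait")
  if (out$n0 + out$n1 + out$n2 < 3L) {
    stop("need at least 3 subjects in total")
  }
  out
}

#' @export
print.grouped_trait <- function(x, ...) {
  cat("Trait values grouped by genotype\n")
  cat(sprintf("  n0 = %d, n1 = %d, n2 = %d (n = %d)\n",
              x$n0, x$n1, x$n2, x$n0 + x$n1 + x$n2))
  invisible(x)
}

# accepts either a grouped_trait or raw (traits, genotypes)
as_grouped_trait <- function(x) {
  if (inherits(x, "grouped_trait")) return(x)
  stop("expected a 'grouped_trait' object; see group_by_genotype()")
}
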