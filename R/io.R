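#' Read a cohort: phenotype table plus genotypes
#'
#' Loads per-subject trait (and optional covariate) values from a delimited
#' table and genotypes either from a second delimited table or from a VCF.
#' Genotypes are oriented as counts of the MINOR allele, recomputed from the
#' observed allele frequencies (a frequency tie at 0.5 keeps the coded/ALT
#' allele). Per-SNP missingness is recorded and SNPs above the missingness
#' threshold are flagged as excluded (the association scan skips them).
#'
#' @param phenotype_path Delimited file (comma or tab, auto-detected from
#'   the header line) with a header row: subject id in the first column, the
#'   trait in column `trait_col`, any remaining numeric columns treated as
#'   covariates.
#' @param genotype_path Delimited file (id column then one 0/1/2 column per
#'   SNP; blanks/NA = missing) or a VCF, per `format`.
#' @param format `"delimited"` or `"vcf"`.
#' @param trait_col Name of the trait column (default `"trait"`).
#' @param max_missing Per-SNP missing-genotype fraction above which the SNP
#'   is flagged excluded (default 0.15).
#' @return An object of class `cohort_table`: list with `subjects`,
#'   `trait`, `genotypes` (n x SNP integer matrix with NAs),
#'   `covariates` (matrix or NULL), `missing_frac`, `excluded` (logical
#'   per SNP) and `flipped` (SNPs re-oriented to the minor allele).
#' @export
read_cohort <- function(phenotype_path, genotype_path,
                        format = c("delimited", "vcf"),
                        trait_col = "trait", max_missing = 0.15) {
  format <- match.arg(format)
  pheno <- read_delimited(phenotype_path)
  if (!trait_col %in% names(pheno)) {
    stop("phenotype file has no '", trait_col, "' column")
  }
  subjects <- as.character(pheno[[1L]])
  trait <- as.numeric(pheno[[trait_col]])
  covar_cols <- setdiff(names(pheno), c(names(pheno)[1L], trait_col))
  covariates <- if (length(covar_cols)) {
    as.matrix(pheno[covar_cols])
  } else NULL

  gt <- switch(format,
               delimited = read_genotypes_delimited(genotype_path, subjects),
               vcf = read_genotypes_vcf(genotype_path, subjects))

  # orient to the minor allele
  freq <- colMeans(gt, na.rm = TRUE) / 2
  flip <- !is.na(freq) & freq > 0.5
  gt[, flip] <- 2L - gt[, flip]
  missing_frac <- colMeans(is.na(gt))
  excluded <- missing_frac > max_missing
  if (any(excluded)) {
    message(sum(excluded), " SNP(s) exceed ", max_missing * 100,
            "% missing genotypes and are flagged excluded")
  }
  structure(list(subjects = subjects, trait = trait, genotypes = gt,
                 covariates = covariates, missing_frac = missing_frac,
                 excluded = excluded, flipped = colnames(gt)[flip],
                 max_missing = max_missing),
            class = "cohort_table")
}

#' @export
print.cohort_table <- function(x, ...) {
  cat("Cohort:", length(x$subjects), "subjects,",
      ncol(x$genotypes), "SNP(s)\n")
  if (!is.null(x$covariates)) {
    cat("  covariates:", paste(colnames(x$covariates), collapse = ", "), "\n")
  }
  if (any(x$excluded)) {
    cat("  excluded (>", x$max_missing * 100, "% missing):",
        paste(colnames(x$genotypes)[x$excluded], collapse = ", "), "\n")
  }
  invisible(x)
}

detect_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header, fixed = TRUE)) "\t" else ","
}

read_delimited <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- detect_sep(path)
  out <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep,
                      stringsAsFactors = FALSE, check.names = FALSE),
    error = function(e) stop("malformed delimited file '", path, "': ",
                             conditionMessage(e)))
  if (ncol(out) < 2L) stop("file '", path, "' needs at least two columns")
  out
}

read_genotypes_delimited <- function(path, subjects) {
  tab <- read_delimited(path)
  ids <- as.character(tab[[1L]])
  idx <- match(subjects, ids)
  if (anyNA(idx)) {
    stop("genotype file is missing subject(s): ",
         paste(utils::head(subjects[is.na(idx)], 5L), collapse = ", "))
  }
  snps <- names(tab)[-1L]
  gt <- matrix(NA_integer_, length(subjects), length(snps),
               dimnames = list(subjects, snps))
  for (j in seq_along(snps)) {
    v <- tab[[j + 1L]][idx]
    v <- suppressWarnings(as.integer(v))
    bad <- !is.na(v) & !(v %in% 0:2)
    if (any(bad)) {
      stop("genotype outside {0,1,2} in SNP '", snps[j], "', line ",
           idx[which(bad)[1L]] + 1L)
    }
    gt[, j] <- v
  }
  gt
}

# ALT-allele dosages from a (plain-text) VCF via vcfR; half calls and
# missing genotypes -> NA; multi-allelic and non-diploid records skipped
read_genotypes_vcf <- function(path, subjects) {
  if (!file.exists(path)) stop("file not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt_raw <- vcfR::extract.gt(v, element = "GT")
  alt <- vcfR::getALT(v)
  ids <- vcfR::getID(v)
  ids[is.na(ids) | ids == "."] <- paste0("snp", which(is.na(ids) | ids == "."))
  rownames(gt_raw) <- ids
  multi <- grepl(",", alt, fixed = TRUE)
  if (any(multi)) {
    warning("skipping ", sum(multi), " multi-allelic VCF record(s): ",
            paste(utils::head(ids[multi], 5L), collapse = ", "))
  }
  keep <- !multi
  gt_raw <- gt_raw[keep, , drop = FALSE]
  parse_gt <- function(x) {
    # "0/1", "0|1" -> dosage; "./1", ".", "./." -> NA
    al <- strsplit(x, "[/|]")
    vapply(al, function(a) {
      if (length(a) != 2L) return(NA_integer_)   # non-diploid
      if (any(a == "." | a == "")) return(NA_integer_)
      sum(as.integer(a) > 0L)
    }, integer(1))
  }
  nondip <- apply(gt_raw, 1L, function(row) {
    row <- row[!is.na(row) & row != "."]
    any(lengths(strsplit(row, "[/|]")) != 2L)
  })
  if (any(nondip)) {
    warning("skipping ", sum(nondip), " non-diploid VCF record(s): ",
            paste(utils::head(rownames(gt_raw)[nondip], 5L), collapse = ", "))
    gt_raw <- gt_raw[!nondip, , drop = FALSE]
  }
  gt <- t(apply(gt_raw, 1L, parse_gt))
  colnames(gt) <- colnames(gt_raw)
  idx <- match(subjects, colnames(gt))
  if (anyNA(idx)) {
    stop("VCF is missing subject(s): ",
         paste(utils::head(subjects[is.na(idx)], 5L), collapse = ", "))
  }
  out <- t(gt[, idx, drop = FALSE])
  rownames(out) <- subjects
  storage.mode(out) <- "integer"
  out
}

#' Write a cohort back to delimited files
#'
#' Full-precision (17 significant digits) CSV output so that
#' `read_cohort()` round-trips losslessly.
#'
#' @param cohort A `cohort_table`.
#' @param phenotype_path,genotype_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_cohort <- function(cohort, phenotype_path, genotype_path) {
  stopifnot(inherits(cohort, "cohort_table"))
  pheno <- data.frame(id = cohort$subjects,
                      trait = format_full(cohort$trait),
                      stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(cohort$covariates)) {
    for (cn in colnames(cohort$covariates)) {
      pheno[[cn]] <- format_full(cohort$covariates[, cn])
    }
  }
  utils::write.table(pheno, phenotype_path, sep = ",", quote = FALSE,
                     row.names = FALSE)
  geno <- data.frame(id = cohort$subjects, cohort$genotypes,
                     stringsAsFactors = FALSE, check.names = FALSE)
  utils::write.table(geno, genotype_path, sep = ",", quote = FALSE,
                     row.names = FALSE)
  invisible(c(phenotype_path, genotype_path))
}

format_full <- function(x) {
  formatC(x, digits = 17, format = "g")
}

#' Per-SNP association scan with the two-phase procedure
#'
#' Runs [tpp_test()] (and optional comparators) on every non-excluded SNP
#' of a cohort, with per-SNP complete-case handling of missing genotypes
#' and optional covariate residualization of the trait.
#'
#' @param cohort A [read_cohort()] object.
#' @param alpha Nominal level for the decision column.
#' @param xi Phase-1 threshold.
#' @param tests Character subset of `c("TPP", "KW", "ZA", "MAX3")`;
#'   comparators add p-value columns.
#' @param use_covariates If `TRUE` (default) and the cohort has covariate
#'   columns, the trait is residualized on them first.
#' @param nominal_threshold Optional nominal level for which a per-SNP
#'   adjusted threshold column `alpha_star_nominal` is added.
#' @param ties Tie handling, see [win_prob()]. Imputed or heavily rounded
#'   traits usually warrant `"midrank"`.
#' @return Data frame, one row per SNP.
#' @export
tpp_scan <- function(cohort, alpha = 0.05, xi = stats::qnorm(0.9),
                     tests = "TPP", use_covariates = TRUE,
                     nominal_threshold = NULL,
                     ties = c("strict", "midrank")) {
  stopifnot(inherits(cohort, "cohort_table"))
  ties <- match.arg(ties)
  tests <- match.arg(tests, c("TPP", "KW", "ZA", "MAX3"), several.ok = TRUE)
  trait <- cohort$trait
  keep_tr <- !is.na(trait)
  snps <- colnames(cohort$genotypes)
  rows <- vector("list", length(snps))
  for (j in seq_along(snps)) {
    gvec <- cohort$genotypes[, j]
    keep <- keep_tr & !is.na(gvec)
    row <- data.frame(snp = snps[j], n_used = sum(keep),
                      n_missing = sum(!keep),
                      excluded = cohort$excluded[j])
    if (cohort$excluded[j]) {
      rows[[j]] <- row
      next
    }
    y <- trait[keep]
    if (use_covariates && !is.null(cohort$covariates)) {
      y <- residualize(y, cohort$covariates[keep, , drop = FALSE])
    }
    g <- gvec[keep]
    res <- tryCatch(
      tpp_test(y, g, alpha = alpha, xi = xi, ties = ties,
               nominal_threshold = nominal_threshold),
      error = function(e) e)
    if (inherits(res, "error")) {
      row$error <- conditionMessage(res)
      rows[[j]] <- row
      next
    }
    row$z1 <- res$z1
    row$model <- res$selected_model
    row$statistic <- res$phase2$statistic
    row$p_value <- res$phase2$p_value
    row$alpha_star <- res$alpha_star
    row$reject <- res$reject
    row$fallback <- res$fallback
    if (!is.null(nominal_threshold)) {
      row$alpha_star_nominal <- res$adjusted_threshold
    }
    gt <- group_by_genotype(y, g)
    if ("KW" %in% tests) row$p_KW <- kruskal_wallis(gt)$p_value
    if ("ZA" %in% tests) row$p_ZA <- npt_statistic(gt, "ADD", ties)$p_value
    if ("MAX3" %in% tests) row$p_MAX3 <- max3_test(gt, ties = ties)$p_value
    rows[[j]] <- row
  }
  merge_ragged(rows)
}

# rbind data frames with possibly different columns
merge_ragged <- function(rows) {
  cols <- unique(unlist(lapply(rows, names)))
  filled <- lapply(rows, function(r) {
    for (cn in setdiff(cols, names(r))) r[[cn]] <- NA
    r[cols]
  })
  do.call(rbind, filled)
}
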