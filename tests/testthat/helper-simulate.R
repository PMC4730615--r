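# shared test helpers: brute-force oracles and small simulated datasets

# O(na*nb) enumeration oracle for the win probability
brute_win_prob <- function(a, b, ties = "strict") {
  s <- outer(a, b, function(x, y) (x < y) + if (ties == "midrank") 0.5 * (x == y) else 0)
  mean(s)
}

# one null cohort split into genotype groups
null_groups <- function(n, maf, d = 5) {
  g <- simulate_genotypes(n, maf)
  y <- 0.5 + sample_error(error_law("tgev", scale = d), n)
  list(y = y, g = g,
       gt = group_by_genotype(y, g))
}

# all four Z statistics for raw data, as a named vector
all_z <- function(y, g, ties = "strict") {
  gt <- group_by_genotype(y, g)
  e <- win_prob_estimates(gt, ties)
  z <- tppassoc:::z_statistics(e)
  c(z1 = z$z1, zR = z$zR, zA = z$zA, zD = z$zD)
}
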