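# Gauss-Legendre machinery shared by the size-adjustment equation and the
# MAX3 trivariate-normal null. Nodes are cached per (n, a, b).

.quad_cache <- new.env(parent = emptyenv())

gl_nodes <- function(n, a, b) {
  key <- sprintf("%d_%.17g_%.17g", n, a, b)
  got <- .quad_cache[[key]]
  if (!is.null(got)) return(got)
  gl <- pracma::gaussLegendre(n, a, b)
  out <- list(x = gl$x, w = gl$w)
  .quad_cache[[key]] <- out
  out
}

# P(all |Z_i| <= m) for a trivariate normal with unit variances and
# correlation matrix R, by conditioning on Z1 and nesting two fixed
# Gauss-Legendre grids on [-m, m]. Correlations are clamped slightly inside
# (-1, 1); accuracy ~1e-6 for |rho| <= 0.999.
pmax3_normal <- function(m, R, nodes = 64L) {
  if (m <= 0) return(0)
  clamp <- function(r) max(-0.999, min(0.999, r))
  r12 <- clamp(R[1, 2]); r13 <- clamp(R[1, 3]); r23 <- clamp(R[2, 3])
  g <- gl_nodes(nodes, -m, m)
  u <- g$x; wu <- g$w        # outer: Z1
  v <- g$x; wv <- g$w        # inner: Z2
  s2 <- sqrt(1 - r12^2); s3 <- sqrt(1 - r13^2)
  rc <- (r23 - r12 * r13) / (s2 * s3)
  rc <- clamp(rc)
  s3c <- s3 * sqrt(1 - rc^2)
  # grids: rows = outer u, cols = inner v
  mu2 <- r12 * u; mu3 <- r13 * u
  dv <- outer(-mu2, v, "+")                  # v - mu2
  dens2 <- stats::dnorm(dv / s2) / s2
  mu3c <- matrix(mu3, length(u), length(v)) + rc * s3 / s2 * dv
  inner <- stats::pnorm((m - mu3c) / s3c) - stats::pnorm((-m - mu3c) / s3c)
  bi <- drop((dens2 * inner) %*% wv)
  sum(wu * stats::dnorm(u) * bi)
}
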