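#' Error distributions for the synthetic cohort generator
#'
#' The study conditions use a heavy-tailed, left-truncated error: a
#' generalized extreme value (GEV) law with shape 0 (Gumbel), location 0 and
#' scale \eqn{d}, conditioned to exceed a truncation point of 0 — the shape
#' of, e.g., survival-time traits. Untruncated GEV and centered Student-t
#' variants are provided for sensitivity work.
#'
#' @param family `"tgev"` (truncated GEV, the default study condition),
#'   `"gev"` (untruncated) or `"t"` (Student t with `df` degrees of
#'   freedom, centered at `location`, scaled by `scale`).
#' @param shape,location,scale GEV parameters (shape 0 is Gumbel);
#'   `scale > 0`.
#' @param truncation Truncation point (tGEV only; default 0).
#' @param side Truncation side, `"left"` keeps draws above the truncation
#'   point (the default), `"right"` keeps draws below it.
#' @param df Degrees of freedom (t family only).
#' @return An object of class `error_law`.
#' @examples
#' law <- error_law("tgev", scale = 5)
#' summary(sample_error(law, 1000, seed = 1))
#' @export
error_law <- function(family = c("tgev", "gev", "t"),
                      shape = 0, location = 0, scale = 1,
                      truncation = 0, side = c("left", "right"),
                      df = NULL) {
  family <- match.arg(family)
  side <- match.arg(side)
  stopifnot(scale > 0)
  if (family == "t" && (is.null(df) || df <= 0)) {
    stop("the t family needs positive degrees of freedom 'df'")
  }
  structure(list(family = family, shape = shape, location = location,
                 scale = scale, truncation = truncation, side = side,
                 df = df),
            class = "error_law")
}

#' @export
print.error_law <- function(x, ...) {
  desc <- switch(x$family,
    tgev = sprintf("tGEV(shape %g, loc %g, scale %g, %s-truncated at %g)",
                   x$shape, x$location, x$scale, x$side, x$truncation),
    gev = sprintf("GEV(shape %g, loc %g, scale %g)",
                  x$shape, x$location, x$scale),
    t = sprintf("centered t(df %g, loc %g, scale %g)",
                x$df, x$location, x$scale))
  cat("Error law:", desc, "\n")
  invisible(x)
}

# GEV distribution function and quantile function (shape 0 = Gumbel)
pgev <- function(q, shape = 0, location = 0, scale = 1) {
  z <- (q - location) / scale
  if (abs(shape) < 1e-12) {
    exp(-exp(-z))
  } else {
    t <- 1 + shape * z
    ifelse(t <= 0, if (shape > 0) 0 else 1, exp(-t^(-1 / shape)))
  }
}

qgev <- function(p, shape = 0, location = 0, scale = 1) {
  if (abs(shape) < 1e-12) {
    location - scale * log(-log(p))
  } else {
    location + scale * ((-log(p))^(-shape) - 1) / shape
  }
}

#' Draw from an error law
#'
#' Inverse-CDF sampling; for the truncated GEV the uniform variate is
#' restricted to the truncation region, so all draws fall on the kept side
#' of the truncation point.
#'
#' @param law An [error_law()] object.
#' @param n Number of draws.
#' @param seed Optional integer seed (the caller's RNG state is preserved).
#' @return Numeric vector of length `n`.
#' @export
sample_error <- function(law, n, seed = NULL) {
  stopifnot(inherits(law, "error_law"), n >= 1)
  with_seed(seed, {
    switch(law$family,
      tgev = {
        Ft <- pgev(law$truncation, law$shape, law$location, law$scale)
        if (law$side == "left") {
          if (1 - Ft < 1e-12) stop("empty truncation region")
          u <- stats::runif(n, Ft, 1)
        } else {
          if (Ft < 1e-12) stop("empty truncation region")
          u <- stats::runif(n, 0, Ft)
        }
        qgev(u, law$shape, law$location, law$scale)
      },
      gev = qgev(stats::runif(n), law$shape, law$location, law$scale),
      t = law$location + law$scale * stats::rt(n, df = law$df))
  })
}

#' @rdname sample_error
#' @param shape,location,scale,truncation,side GEV parameters, see
#'   [error_law()].
#' @export
sample_truncated_gev <- function(n, shape = 0, location = 0, scale = 1,
                                 truncation = 0, side = c("left", "right"),
                                 seed = NULL) {
  sample_error(error_law("tgev", shape = shape, location = location,
                         scale = scale, truncation = truncation,
                         side = match.arg(side)),
               n, seed = seed)
}
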