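# seed hygiene: run code under a given seed without disturbing the caller's
# RNG stream; seed = NULL means "use the current stream"
get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  } else NULL
}

set_rng_state <- function(state) {
  if (!is.null(state)) {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- get_rng_state()
  on.exit(set_rng_state(old))
  set.seed(seed)
  expr
}

# deterministic sub-seed for experiment cell `index` under a master seed;
# kept strictly below 2^31 - 1
cell_seed <- function(master, index) {
  v <- (as.double(master) %% 2147483647) * 48271 + 99991 * as.double(index)
  as.integer(v %% 2147483629) + 1L
}
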