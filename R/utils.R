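# RNG bookkeeping: generators save/restore the caller's RNG state so that
# seeded generation never perturbs the session stream
get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

set_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", state, envir = globalenv())
}

# deterministic derived seeds, kept inside 32-bit integer range
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1009 + as.numeric(k)) %% 2147483647)
}

with_seed <- function(seed, expr) {
  rs <- get_rng_state()
  on.exit(set_rng_state(rs), add = TRUE)
  set.seed(as.integer(seed))
  expr
}
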