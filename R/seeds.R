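#' Derive reproducible sub-seeds from a master seed
#'
#' Every stochastic stage of a simulation (input-set assembly, population
#' initialisation, per-replicate evolution, null-model draws) consumes its own
#' integer seed derived deterministically from one master seed. The derivation
#' seeds R's RNG with the master seed and draws `n` integers uniformly from
#' \code{1:(2^31 - 2)}, so a replicate is exactly reproducible from
#' `(master_seed, index)` alone and sub-streams are effectively independent.
#'
#' @param master_seed Integer master seed.
#' @param n Number of sub-seeds to derive.
#' @return Integer vector of length `n`.
#' @examples
#' derive_seeds(1, 3)
#' @export
derive_seeds <- function(master_seed, n) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1L, n >= 1)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(master_seed) %% .Machine$integer.max)
  sample.int(.Machine$integer.max - 1L, n, replace = FALSE)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

# Evaluate `expr` under a local RNG seeded with `seed`, restoring the caller's
# RNG state afterwards. All internal randomness goes through this.
with_seed <- function(seed, expr) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed) %% .Machine$integer.max)
  expr
}
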