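#' Derive a deterministic stream of child seeds from a master seed
#'
#' A splittable counter scheme: the master seed initialises R's RNG once and
#' the stream is drawn in a single call, so the i-th child seed does not
#' depend on how many workers consume the stream or in which order.
#'
#' @param master_seed Single integer master seed.
#' @param n Number of child seeds to derive.
#' @return Integer vector of length `n`, each in `[1, 2^31 - 2]`.
#' @export
derive_seeds <- function(master_seed, n) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1, n >= 1)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(master_seed))
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

# Run code under a local RNG seed, restoring the caller's RNG state after.
with_seed <- function(seed, code) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  force(code)
}

first_col_ids <- function(df, what) {
  ids <- df[[1]]
  if (anyDuplicated(ids)) {
    abort(sprintf("duplicate subject IDs in %s", what))
  }
  as.character(ids)
}
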