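# Internal helpers shared across modules.

#' Evaluate code under a temporary RNG seed
#'
#' Sets the seed, runs `code`, and restores the caller's RNG state so that
#' seeded draws inside the package never perturb user-level randomness.
#' @noRd
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

#' Derive a child seed for one simulation replicate
#'
#' Replicate streams are derived deterministically from (seed, n, replicate)
#' so batches are order-independent: replicate r of a run gives the same
#' sample whether replicates run forward, backward or in parallel. All
#' arithmetic stays exact in doubles (< 2^53) and the result is < 2^31.
#' @noRd
child_seed <- function(seed, n, r) {
  s <- as.double(seed) %% 2147483647
  as.integer((s * 69069 + as.double(n) * 104729 + as.double(r) * 30011 + 1) %%
               2147483647)
}

is_whole <- function(x, tol = 1e-8) {
  is.finite(x) & abs(x - round(x)) < tol
}

`%||%` <- function(a, b) if (is.null(a)) b else a
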