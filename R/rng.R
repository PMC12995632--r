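# Seed plumbing: every stochastic operation takes an integer seed and leaves
# the caller's RNG state untouched. Sub-streams are derived deterministically
# so one study seed fans out to per-animal / per-section seeds without reuse.

#' Evaluate code under a temporary RNG seed
#'
#' Sets the seed, runs `code`, and restores the previous global RNG state, so
#' package functions never perturb user-level randomness.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  code
}

#' Derive a child seed from a parent seed
#'
#' Deterministic splitting of one integer seed into independent sub-stream
#' seeds (parent seed plus a stream index). Results stay in `[1, 2^31 - 2]`.
#'
#' @param seed Parent integer seed.
#' @param k Stream index (non-negative integer; vectors allowed).
#' @return Integer seed(s).
#' @export
derive_seed <- function(seed, k) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.numeric(k))
  m <- 2147483647 # 2^31 - 1, prime
  s <- (abs(as.numeric(seed)) %% m)
  # two rounds of a multiplicative hash, kept in double-precision-exact range
  x <- (s * 48271 + as.numeric(k) * 16807 + 11) %% m
  x <- (x * 69621 + 7919) %% m
  as.integer(x %% (m - 2) + 1)
}
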