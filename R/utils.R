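# Internal RNG plumbing.
#
# All stochastic entry points take an explicit `seed`; NULL means "use the
# session RNG stream as-is". A non-NULL seed is applied locally: the caller's
# .Random.seed is saved and restored, so package calls never perturb user
# code that relies on its own RNG state.

local_seed <- function(seed, expr) {
  if (is.null(seed)) {
    return(expr)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic substream derivation: replicate (or stage) i of an ensemble
# seeded with `seed` gets its own derived seed, so enlarging an ensemble
# never perturbs earlier replicates and independent stages of a pipeline do
# not share streams. Mixing uses a Lehmer step plus a Knuth multiplicative
# hash of the index, kept exactly representable in doubles and < 2^31.
derive_seed <- function(seed, i) {
  s <- as.double(seed) %% 2147483647
  s <- (s * 16807) %% 2147483647
  s <- (s + (as.double(i) * 2654435.0) %% 2147483647) %% 2147483647
  as.integer(s) + 1L
}

check_rate <- function(p) {
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1) {
    stop("sampling rate must be a single probability in [0, 1]", call. = FALSE)
  }
  as.double(p)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
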