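#' Sampling configuration
#'
#' Bundles the parameters of the partial-observation process: the sampling
#' rate `p` (the per-event probability that an event is observed), an
#' optional seed, and the ensemble size for replicate draws.
#'
#' @param rate probability in `[0, 1]` that an individual event is observed.
#' @param seed integer seed, or `NULL` to use the session RNG stream.
#' @param n_reps positive integer; number of replicate sampled series in an
#'   ensemble.
#' @return An object of class `sampling_config`.
#' @seealso [binomial_sample()], [sample_ensemble()]
#' @export
sampling_config <- function(rate, seed = NULL, n_reps = 1L) {
  rate <- check_rate(rate)
  if (!is.null(seed)) {
    seed <- as.integer(seed)[1L]
  }
  n_reps <- as.integer(n_reps)[1L]
  if (is.na(n_reps) || n_reps < 1L) {
    stop("n_reps must be a positive integer", call. = FALSE)
  }
  structure(list(rate = rate, seed = seed, n_reps = n_reps),
            class = "sampling_config")
}

as_sampling_config <- function(config, seed = NULL, n_reps = 1L) {
  if (inherits(config, "sampling_config")) {
    return(config)
  }
  sampling_config(rate = config, seed = seed, n_reps = n_reps)
}

#' Binomial thinning of a count series
#'
#' Implements the partial-observation model: each of the `X_t` events at
#' time `t` is independently observed with probability `p`, so the observed
#' count is `Y_t ~ Binomial(X_t, p)`. The observed series is elementwise
#' dominated by the ground truth (`Y_t <= X_t`) and has mean `p * E[X_t]`.
#'
#' Rates of exactly 0 or 1 bypass the RNG and return the deterministic limit
#' (all zeros, resp. a copy of `x`), so the trivial cases are bit-exact and
#' consume no random numbers.
#'
#' @param x a [count_series()] (or numeric vector of counts): the ground
#'   truth signal.
#' @param config a [sampling_config()], or a bare rate in `[0, 1]`.
#' @param seed convenience override when `config` is a bare rate.
#' @return A `count_series` of the same length: the observed signal.
#' @examples
#' x <- count_series(c(5, 8, 2, 0, 11))
#' binomial_sample(x, sampling_config(rate = 0.5, seed = 1))
#' @export
binomial_sample <- function(x, config, seed = NULL) {
  config <- as_sampling_config(config, seed = seed)
  if (!inherits(x, "count_series")) {
    x <- count_series(x)
  }
  v <- x$values
  p <- config$rate
  out_label <- sprintf("%s[p=%g]", x$label, p)
  if (p == 1) {
    y <- v
  } else if (p == 0) {
    y <- rep(0, length(v))
  } else {
    y <- local_seed(config$seed, stats::rbinom(length(v), size = v, prob = p))
  }
  count_series(y, start_index = x$start_index, label = out_label)
}

#' Ensemble of independently thinned series
#'
#' Draws `n_reps` independent binomially sampled versions of `x` at the same
#' rate. Replicate `r` uses a seed deterministically derived from the
#' ensemble seed, so replicate streams are independent but jointly
#' reproducible, and enlarging the ensemble never changes earlier
#' replicates.
#'
#' @inheritParams binomial_sample
#' @param n_reps convenience override when `config` is a bare rate.
#' @return A list of `count_series` of length `n_reps`.
#' @export
sample_ensemble <- function(x, config, seed = NULL, n_reps = NULL) {
  config <- as_sampling_config(config, seed = seed,
                               n_reps = n_reps %||% 1L)
  lapply(seq_len(config$n_reps), function(r) {
    rep_seed <- if (is.null(config$seed)) NULL else derive_seed(config$seed, r)
    binomial_sample(x, sampling_config(config$rate, seed = rep_seed))
  })
}
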