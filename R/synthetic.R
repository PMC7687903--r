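#' Poisson-INAR(1) count process
#'
#' Integer-valued autoregressive process built from binomial thinning plus
#' Poisson innovations,
#' `X_t = alpha o X_{t-1} + eps_t`, `eps_t ~ Poisson(lam)`,
#' where `alpha o n` is a `Binomial(n, alpha)` draw (each event of the
#' previous interval independently survives with probability `alpha`).
#' The stationary law is Poisson with mean `mu = lam / (1 - alpha)`, so
#' `Var(X) = E[X] = mu`, and the lag-k autocorrelation is `alpha^k` — a
#' count-valued autoregressive test bed with closed-form moments.
#'
#' The chain is started from a `Poisson(mu)` draw (the stationary marginal)
#' and a burn-in prefix is discarded to shed any residual transient.
#'
#' @param alpha survival coefficient in `[0, 1)`.
#' @param lam innovation rate, > 0.
#' @param n length of the returned series.
#' @param burn_in number of initial steps discarded (default 1000).
#' @param seed integer seed, or `NULL`.
#' @return A [count_series()] of length `n`.
#' @examples
#' x <- generate_inar(alpha = 0.6, lam = 4, n = 2000, seed = 1)
#' mean(x$values)  # ~ 4 / (1 - 0.6) = 10
#' @export
generate_inar <- function(alpha, lam, n, burn_in = 1000L, seed = NULL) {
  if (!is.numeric(alpha) || alpha < 0 || alpha >= 1) {
    stop("alpha must lie in [0, 1)", call. = FALSE)
  }
  if (!is.numeric(lam) || lam <= 0) stop("lam must be > 0", call. = FALSE)
  n <- as.integer(n)[1L]
  burn_in <- as.integer(burn_in)[1L]
  if (is.na(n) || n < 1L) stop("n must be >= 1", call. = FALSE)
  if (is.na(burn_in) || burn_in < 0L) stop("burn_in must be >= 0", call. = FALSE)
  mu <- lam / (1 - alpha)
  total <- n + burn_in
  v <- local_seed(seed, {
    innov <- stats::rpois(total, lam)
    x <- numeric(total)
    prev <- stats::rpois(1L, mu)
    if (alpha == 0) {
      x <- innov  # thinning term vanishes: iid Poisson(lam)
    } else {
      for (t in seq_len(total)) {
        prev <- stats::rbinom(1L, size = prev, prob = alpha) + innov[t]
        x[t] <- prev
      }
    }
    x
  })
  count_series(v[seq.int(burn_in + 1L, total)],
               label = sprintf("inar(alpha=%g,lam=%g)", alpha, lam))
}

#' Independent Poisson counts
#'
#' iid `Poisson(lam)` series: the memoryless baseline process
#' (equidispersed, zero autocorrelation at every lag).
#'
#' @param lam rate, > 0.
#' @param n length.
#' @param seed integer seed, or `NULL`.
#' @return A [count_series()].
#' @export
generate_poisson <- function(lam, n, seed = NULL) {
  if (!is.numeric(lam) || lam <= 0) stop("lam must be > 0", call. = FALSE)
  n <- as.integer(n)[1L]
  if (is.na(n) || n < 1L) stop("n must be >= 1", call. = FALSE)
  v <- local_seed(seed, stats::rpois(n, lam))
  count_series(v, label = sprintf("poisson(lam=%g)", lam))
}

#' External signal with controlled correlation
#'
#' Generates `S_t = a * X_t + eps_t` with `eps_t ~ Normal(0, noise_sd^2)`:
#' an auxiliary real-valued signal whose population covariance with the
#' ground truth is `a * Var(X)` and whose correlation is
#' `a * sigma_X / sqrt(a^2 sigma_X^2 + noise_sd^2)`. Use
#' [external_noise_sd()] to pick `noise_sd` for a target correlation.
#'
#' @param x ground-truth [count_series()].
#' @param gain linear coupling `a`.
#' @param noise_sd standard deviation of the additive Gaussian noise, >= 0.
#' @param seed integer seed, or `NULL`.
#' @return A [real_series()] of the same length as `x`.
#' @export
generate_external <- function(x, gain = 1, noise_sd = 0, seed = NULL) {
  v <- series_values(x)
  if (!is.numeric(noise_sd) || noise_sd < 0) {
    stop("noise_sd must be >= 0", call. = FALSE)
  }
  if (gain != 0 && noise_sd == 0 && stats::sd(v) == 0) {
    stop("degenerate external signal: constant x with gain != 0 and no noise",
         call. = FALSE)
  }
  eps <- if (noise_sd > 0) {
    local_seed(seed, stats::rnorm(length(v), 0, noise_sd))
  } else {
    numeric(length(v))
  }
  real_series(gain * v + eps,
              label = sprintf("external(a=%g,sd=%g)", gain, noise_sd))
}

#' @rdname generate_external
#' @param sigma_x standard deviation of the ground-truth series.
#' @param rho target correlation in (0, 1].
#' @return `external_noise_sd` returns the noise standard deviation giving
#'   population correlation `rho` between `S = gain * X + eps` and `X`.
#' @export
external_noise_sd <- function(sigma_x, gain = 1, rho = 0.8) {
  if (!is.numeric(rho) || rho <= 0 || rho > 1) {
    stop("rho must lie in (0, 1]", call. = FALSE)
  }
  abs(gain) * sigma_x * sqrt(1 / rho^2 - 1)
}

#' Burst-inflated (overdispersed) counts
#'
#' Multiplies every count by an integer `k`, as if events arrived in bursts
#' of `k`: the mean scales by `k` and the variance by `k^2`, so the
#' variance-to-mean ratio is inflated k-fold while the series stays integer
#' valued. Used to realise the `Var(X) >> E[X]` regime in which sampling
#' leaves the correlation with an external signal essentially intact.
#'
#' @param x_base a [count_series()].
#' @param k positive integer burst size.
#' @return A [count_series()].
#' @export
generate_high_dispersion <- function(x_base, k) {
  k <- as.integer(k)[1L]
  if (is.na(k) || k < 1L) stop("k must be a positive integer", call. = FALSE)
  v <- series_values(x_base)
  lab <- if (inherits(x_base, "count_series")) x_base$label else ""
  count_series(v * k, label = sprintf("%s*k%d", lab, k))
}
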