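#' Random fixed-length windows of a series
#'
#' Draws `n_windows` windows of length `window_len` with uniformly random
#' start positions, sampled with replacement. Windowing lets a long series
#' (e.g. years of weekly surveillance counts) contribute many quasi-
#' independent segments to the replicate distribution of a metric.
#'
#' @param x a [count_series()].
#' @param window_len window length, `<= length(x)`.
#' @param n_windows number of windows.
#' @param seed integer seed, or `NULL`.
#' @return A list of `count_series`, each of length `window_len`, with
#'   `start_index` recording the window's offset into `x`.
#' @export
random_windows <- function(x, window_len, n_windows, seed = NULL) {
  v <- series_values(x)
  window_len <- as.integer(window_len)[1L]
  n_windows <- as.integer(n_windows)[1L]
  if (is.na(window_len) || window_len < 1L) {
    stop("window_len must be >= 1", call. = FALSE)
  }
  if (window_len > length(v)) {
    stop("window longer than the series", call. = FALSE)
  }
  if (is.na(n_windows) || n_windows < 1L) {
    stop("n_windows must be >= 1", call. = FALSE)
  }
  n_starts <- length(v) - window_len + 1L
  starts <- local_seed(seed, sample.int(n_starts, n_windows, replace = TRUE))
  lab <- if (inherits(x, "count_series")) x$label else ""
  lapply(starts, function(s) {
    count_series(v[seq.int(s, length.out = window_len)],
                 start_index = s,
                 label = sprintf("%s[win@%d]", lab, s))
  })
}

quartile_row <- function(vals) {
  q <- stats::quantile(vals, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  c(q25 = q[1], median = q[2], q75 = q[3])
}

#' Sampling-rate sweep of a relative predictability metric
#'
#' The core degradation experiment: for each sampling rate `p` on a grid,
#' draw replicate windows of the ground truth, thin each at rate `p`,
#' compute a predictability metric on the thinned window, and divide by
#' the same metric on the unthinned window. The relative metric isolates
#' the effect of sampling from the base predictability of the process; at
#' `p = 1` it is exactly 1 for every replicate. Per-`p` distributions are
#' summarised by the median and interquartile range.
#'
#' Metric parameters are frozen once on the full ground-truth series —
#' `(d, tau)` by [pe_grid_search()] for `metric = "pe"` (weighted PE,
#' normalised by `log2(d!)`), the lag by [best_lag()] for
#' `metric = "acf"` — and reused unchanged at every rate, so parameter
#' drift cannot masquerade as predictability change.
#'
#' Replicates whose metric is undefined after thinning (e.g. an all-zero
#' window at a very low rate) are dropped and counted in `n_dropped`; if
#' every replicate at some rate drops, the sweep aborts.
#'
#' @param x ground-truth [count_series()].
#' @param rate_grid numeric vector of sampling rates in `(0, 1]`.
#' @param metric `"acf"` or `"pe"`.
#' @param n_reps replicate windows per rate.
#' @param window_len window length, or `NULL` to use the full series as a
#'   single window per replicate.
#' @param seed integer seed, or `NULL`.
#' @param max_lag search range for [best_lag()] (metric `"acf"`).
#' @param d_range,tau_range search grid for [pe_grid_search()] (metric
#'   `"pe"`).
#' @return A data frame of class `sweep_result` with columns `p`, `q25`,
#'   `median`, `q75`, `n_used`, `n_dropped`; the frozen parameters are in
#'   `attr(., "params")`.
#' @export
sampling_sweep <- function(x, rate_grid, metric = c("acf", "pe"),
                           n_reps = 100L, window_len = NULL, seed = NULL,
                           max_lag = 52L, d_range = 2:5, tau_range = 1:7) {
  metric <- match.arg(metric)
  stopifnot(inherits(x, "count_series"))
  rate_grid <- sort(unique(as.double(rate_grid)))
  if (any(rate_grid <= 0 | rate_grid > 1)) {
    stop("rate_grid values must lie in (0, 1]", call. = FALSE)
  }
  n_reps <- as.integer(n_reps)[1L]

  if (metric == "acf") {
    lag <- best_lag(x, min(max_lag, length(x) - 2L))
    params <- list(lag = lag)
    metric_fun <- function(v) autocorrelation(v, lag)
  } else {
    gs <- pe_grid_search(x, d_range, tau_range)
    params <- list(d = gs$d, tau = gs$tau)
    cfg <- pe_config(gs$d, gs$tau, weighted = TRUE,
                     normalization = "possible_permutations")
    metric_fun <- function(v) permutation_entropy(v, cfg)
  }

  windows <- if (is.null(window_len)) {
    rep(list(x), n_reps)
  } else {
    random_windows(x, window_len, n_reps,
                   seed = if (is.null(seed)) NULL else derive_seed(seed, 0L))
  }
  base_vals <- vapply(windows, function(w) {
    tryCatch(metric_fun(w$values), error = function(e) NA_real_)
  }, numeric(1))

  rows <- lapply(seq_along(rate_grid), function(pi) {
    p <- rate_grid[pi]
    rel <- rep(NA_real_, n_reps)
    for (r in seq_len(n_reps)) {
      if (is.na(base_vals[r])) next
      rep_seed <- if (is.null(seed)) NULL else derive_seed(seed, pi * 100003L + r)
      y <- binomial_sample(windows[[r]], sampling_config(p, seed = rep_seed))
      val <- tryCatch(metric_fun(y$values), error = function(e) NA_real_)
      if (!is.na(val)) rel[r] <- val / base_vals[r]
    }
    ok <- rel[!is.na(rel)]
    if (!length(ok)) {
      stop("all replicates degenerate at p = ", p, call. = FALSE)
    }
    n_dropped <- n_reps - length(ok)
    if (n_dropped > 0L) {
      message(sprintf("sampling_sweep: dropped %d/%d replicates at p = %g",
                      n_dropped, n_reps, p))
    }
    c(p = p, quartile_row(ok), n_used = length(ok), n_dropped = n_dropped)
  })
  out <- as.data.frame(do.call(rbind, rows))
  attr(out, "metric") <- metric
  attr(out, "params") <- params
  class(out) <- c("sweep_result", class(out))
  out
}

#' Predicted versus empirical autocorrelation of the thinned series
#'
#' For each rate on the grid, compares the closed-form autocorrelation of
#' the thinned series (from the moments of `x`) with the median empirical
#' lagged Pearson autocorrelation over replicate thinnings of `x`.
#'
#' @param x ground-truth [count_series()].
#' @param rate_grid sampling rates in `(0, 1]`.
#' @param lag autocorrelation lag.
#' @param n_reps replicates per rate.
#' @param seed integer seed, or `NULL`.
#' @return A data frame with columns `p`, `predicted`, `empirical`,
#'   `difference`, sorted by `p`.
#' @export
theory_vs_empirical <- function(x, rate_grid, lag = 1L, n_reps = 100L,
                                seed = NULL) {
  stopifnot(inherits(x, "count_series"))
  rate_grid <- sort(unique(as.double(rate_grid)))
  m <- estimate_moments(x, max_lag = lag)
  rows <- lapply(seq_along(rate_grid), function(pi) {
    p <- rate_grid[pi]
    pred <- predicted_autocorrelation(m, lag, p)
    emp <- vapply(seq_len(n_reps), function(r) {
      rep_seed <- if (is.null(seed)) NULL else derive_seed(seed, pi * 100003L + r)
      y <- binomial_sample(x, sampling_config(p, seed = rep_seed))
      tryCatch(autocorrelation(y$values, lag), error = function(e) NA_real_)
    }, numeric(1))
    emp <- stats::median(emp, na.rm = TRUE)
    c(p = p, predicted = pred, empirical = emp, difference = emp - pred)
  })
  as.data.frame(do.call(rbind, rows))
}

#' External-signal degradation sweep
#'
#' Quantifies how much of an external signal's information survives
#' thinning: for each rate `p`, the median over replicates of the
#' covariance ratio `Cov(Y,S) / Cov(X,S)` (theoretical line: `p`), of the
#' Pearson correlation `rho(Y,S)`, and of the plug-in mutual information
#' `MI(Y,S)`.
#'
#' If `Cov(X,S) = 0` the covariance ratio is undefined and reported as
#' `NA` with a warning; correlation and MI are still reported.
#'
#' @param x ground-truth [count_series()].
#' @param s external [real_series()] of the same length.
#' @param rate_grid sampling rates in `(0, 1]`.
#' @param n_reps replicates per rate.
#' @param seed integer seed, or `NULL`.
#' @param bins MI discretisation, passed to [mutual_information()].
#' @return A data frame with columns `p`, `cov_ratio`, `theory_ratio`,
#'   `correlation`, `mi`.
#' @export
external_sweep <- function(x, s, rate_grid, n_reps = 100L, seed = NULL,
                           bins = "auto") {
  stopifnot(inherits(x, "count_series"))
  vs <- series_values(s)
  vx <- series_values(x)
  if (length(vx) != length(vs)) {
    stop("x and s must have equal length", call. = FALSE)
  }
  cov_xs <- stats::cov(vx, vs)
  if (cov_xs == 0) {
    warning("Cov(X, S) = 0: covariance ratio undefined, reported as NA")
  }
  sd_s <- stats::sd(vs)
  rate_grid <- sort(unique(as.double(rate_grid)))
  rows <- lapply(seq_along(rate_grid), function(pi) {
    p <- rate_grid[pi]
    reps <- vapply(seq_len(n_reps), function(r) {
      rep_seed <- if (is.null(seed)) NULL else derive_seed(seed, pi * 100003L + r)
      y <- binomial_sample(x, sampling_config(p, seed = rep_seed))$values
      c(cov = stats::cov(y, vs),
        cor = if (sd_s > 0 && stats::sd(y) > 0) stats::cor(y, vs) else NA_real_,
        mi = mutual_information(y, vs, bins = bins))
    }, numeric(3))
    c(p = p,
      cov_ratio = if (cov_xs == 0) NA_real_ else
        stats::median(reps["cov", ]) / cov_xs,
      theory_ratio = p,
      correlation = stats::median(reps["cor", ], na.rm = TRUE),
      mi = stats::median(reps["mi", ]))
  })
  as.data.frame(do.call(rbind, rows))
}

# Method-of-moments AR(1) one-step predictor fitted on a training segment:
# slope = lag-1 autocorrelation, intercept from the mean. Returns NULL when
# the fit is undefined (constant training segment).
fit_ar1 <- function(train) {
  rho1 <- tryCatch(autocorrelation(train, 1L), error = function(e) NULL)
  if (is.null(rho1)) return(NULL)
  list(mean = mean(train), slope = rho1)
}

predict_ar1 <- function(fit, prev) {
  fit$mean + fit$slope * (prev - fit$mean)
}

#' Forecast-skill degradation under sampling
#'
#' The forecasting consequence of thinning: for each rate `p` and
#' replicate, thin the series, fit an order-1 autoregressive predictor on
#' the training prefix (method of moments: slope = lag-1 autocorrelation,
#' intercept from the training mean) and score one-step-ahead RMSE on the
#' test suffix; a Poisson-style baseline that assumes independent events
#' predicts the training mean everywhere. Both RMSEs are normalised by the
#' test-segment standard deviation, so the `p`-dependent scale of the
#' thinned series (`E[Y] = p E[X]`) does not masquerade as skill change.
#'
#' As `p` falls, the sampled lag-1 autocorrelation shrinks towards zero
#' and the autoregressive forecast converges to the baseline: at low rates
#' the autoregressive model is no more accurate than one that ignores the
#' temporal structure entirely.
#'
#' Replicates with a constant training or test segment are dropped and
#' counted.
#'
#' @param x ground-truth [count_series()].
#' @param rate_grid sampling rates in `(0, 1]`.
#' @param n_reps replicates per rate.
#' @param train_frac fraction of the series used for fitting, in (0, 1).
#' @param seed integer seed, or `NULL`.
#' @return A data frame of class `forecast_result` with columns `p`,
#'   `ar_rmse`, `poisson_rmse` (per-`p` medians of normalised RMSE),
#'   `n_used`, `n_dropped`.
#' @export
forecast_experiment <- function(x, rate_grid, n_reps = 100L,
                                train_frac = 0.8, seed = NULL) {
  stopifnot(inherits(x, "count_series"))
  if (!is.numeric(train_frac) || train_frac <= 0 || train_frac >= 1) {
    stop("train_frac must lie in (0, 1)", call. = FALSE)
  }
  v <- x$values
  n <- length(v)
  nt <- floor(train_frac * n)
  if (nt < 3L || n - nt < 3L) {
    stop("series too short for the requested train/test split", call. = FALSE)
  }
  rate_grid <- sort(unique(as.double(rate_grid)))
  rows <- lapply(seq_along(rate_grid), function(pi) {
    p <- rate_grid[pi]
    ar <- base <- rep(NA_real_, n_reps)
    for (r in seq_len(n_reps)) {
      rep_seed <- if (is.null(seed)) NULL else derive_seed(seed, pi * 100003L + r)
      y <- binomial_sample(x, sampling_config(p, seed = rep_seed))$values
      train <- y[seq_len(nt)]
      test <- y[seq.int(nt + 1L, n)]
      fit <- fit_ar1(train)
      sd_test <- stats::sd(test)
      if (is.null(fit) || sd_test == 0) next
      prev <- y[seq.int(nt, n - 1L)]  # last train value seeds the first forecast
      pred <- predict_ar1(fit, prev)
      ar[r] <- sqrt(mean((test - pred)^2)) / sd_test
      base[r] <- sqrt(mean((test - fit$mean)^2)) / sd_test
    }
    ok <- !is.na(ar)
    if (!any(ok)) stop("all replicates degenerate at p = ", p, call. = FALSE)
    if (any(!ok)) {
      message(sprintf("forecast_experiment: dropped %d/%d replicates at p = %g",
                      sum(!ok), n_reps, p))
    }
    c(p = p, ar_rmse = stats::median(ar[ok]),
      poisson_rmse = stats::median(base[ok]),
      n_used = sum(ok), n_dropped = sum(!ok))
  })
  out <- as.data.frame(do.call(rbind, rows))
  attr(out, "train_frac") <- train_frac
  class(out) <- c("forecast_result", class(out))
  out
}

#' Conditional variance of the thinned counts given the ground truth
#'
#' Thinning makes the observed series heteroskedastic even when the ground
#' truth is not: conditional on `X_t = x`, `Var(Y_t) = p(1-p) x`, so the
#' observation noise tracks the signal level. This helper measures it
#' empirically: it draws `n_reps` thinned replicates, computes the
#' across-replicate variance of `Y_t` at each `t`, groups time points by
#' their ground-truth count, and regresses the mean conditional variance
#' on the count (through the origin). The fitted slope estimates
#' `p(1 - p)`.
#'
#' @param x ground-truth [count_series()].
#' @param p sampling rate.
#' @param n_reps replicates.
#' @param seed integer seed, or `NULL`.
#' @return A list with `slope` (regression slope of conditional variance on
#'   `X_t`), `expected_slope` (`p(1-p)`), and the per-level table `levels`
#'   (`x`, mean conditional variance, number of time points).
#' @export
conditional_variance_profile <- function(x, p, n_reps = 200L, seed = NULL) {
  stopifnot(inherits(x, "count_series"))
  p <- check_rate(p)
  v <- x$values
  ys <- sample_ensemble(x, sampling_config(p, seed = seed, n_reps = n_reps))
  Y <- vapply(ys, function(y) y$values, numeric(length(v)))
  cond_var <- apply(Y, 1L, stats::var)
  lv <- split(cond_var, v)
  levels <- data.frame(
    x = as.double(names(lv)),
    var = vapply(lv, mean, numeric(1)),
    n = vapply(lv, length, numeric(1)),
    row.names = NULL
  )
  fit <- stats::lm(var ~ 0 + x, data = levels, weights = levels$n)
  list(slope = unname(stats::coef(fit)[1L]),
       expected_slope = p * (1 - p),
       levels = levels)
}
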