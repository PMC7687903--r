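#' Permutation-entropy configuration
#'
#' Parameters of the ordinal-pattern (Bandt-Pompe) analysis: embedding
#' dimension `d`, temporal delay `tau`, amplitude weighting, and the
#' normalisation of the entropy.
#'
#' Normalisation modes:
#' * `"possible_permutations"` — divide by `log2(d!)`; the result lies in
#'   `[0, 1]` and is the headline normalised PE.
#' * `"observed_permutations"` — divide by `log2(#distinct observed
#'   patterns)`; used during the `(d, tau)` grid search, where the
#'   `log2(d!)` normalisation would make the score decrease in `d`
#'   mechanically.
#' * `"none"` — raw entropy in bits.
#'
#' @param d embedding dimension (motif length), integer >= 2.
#' @param tau temporal delay between motif elements, integer >= 1.
#' @param weighted if `TRUE`, each motif contributes proportionally to the
#'   population variance of its values, emphasising ordinal changes of
#'   large amplitude.
#' @param normalization one of `"possible_permutations"`,
#'   `"observed_permutations"`, `"none"`.
#' @return An object of class `pe_config`.
#' @export
pe_config <- function(d = 3L, tau = 1L, weighted = TRUE,
                      normalization = c("possible_permutations",
                                        "observed_permutations", "none")) {
  d <- as.integer(d)[1L]
  tau <- as.integer(tau)[1L]
  if (is.na(d) || d < 2L) stop("order d must be an integer >= 2", call. = FALSE)
  if (is.na(tau) || tau < 1L) stop("delay tau must be an integer >= 1", call. = FALSE)
  structure(list(d = d, tau = tau, weighted = isTRUE(weighted),
                 normalization = match.arg(normalization)),
            class = "pe_config")
}

# Extract all T - (d-1)*tau motifs (one row per motif) and encode each
# row's ordinal pattern as a single base-d integer. Element j's rank within
# its motif is the number of elements below it, with ties broken stably so
# the earlier position wins — the standard convention for integer-valued
# data, where ties are common and materially affect the pattern
# distribution. The rank vector is the inverse of the sorting permutation,
# so the code identifies the pattern uniquely; pairwise column comparisons
# keep the whole encoding vectorised.
ordinal_patterns <- function(v, d, tau) {
  n_motif <- length(v) - (d - 1L) * tau
  if (n_motif < 1L) {
    stop("series too short: need length >= (d-1)*tau + 1", call. = FALSE)
  }
  M <- matrix(0, n_motif, d)
  for (j in seq_len(d)) {
    M[, j] <- v[seq.int((j - 1L) * tau + 1L, length.out = n_motif)]
  }
  code <- numeric(n_motif)
  base <- 1
  for (j in seq_len(d)) {
    r <- numeric(n_motif)
    for (k in seq_len(d)) {
      if (k < j) {
        r <- r + (M[, k] <= M[, j])  # equal value, earlier index: ranks below
      } else if (k > j) {
        r <- r + (M[, k] < M[, j])
      }
    }
    code <- code + r * base
    base <- base * d
  }
  list(patterns = code, motifs = M)
}

#' Permutation entropy of a time series
#'
#' Shannon entropy, in bits, of the distribution of ordinal patterns of
#' length `d` at delay `tau`: each motif
#' `[x_t, x_{t+tau}, ..., x_{t+(d-1)tau}]` is mapped to the permutation that
#' sorts it, `H = -sum P(pi) log2 P(pi)` over the observed patterns, with
#' `0 log 0 = 0`. Low PE means few, dominant motifs — a more predictable
#' series; PE near its maximum means pattern-uniform, noise-like dynamics.
#'
#' Unweighted, `P(pi)` is the relative frequency of the pattern. Weighted,
#' each motif counts proportionally to the population variance (denominator
#' `d`) of its values, so large-amplitude ordinal changes dominate and
#' small-amplitude noise motifs are discounted. A series whose motifs are
#' all constant has zero total weight and no weighted PE; this degenerate
#' input raises an error rather than returning a silent 0/0.
#'
#' @param x a [count_series()], [real_series()] or numeric vector.
#' @param cfg a [pe_config()].
#' @return A single non-negative number; in `[0, 1]` under
#'   `"possible_permutations"` normalisation.
#' @examples
#' permutation_entropy(1:50, pe_config(d = 3, tau = 1))       # 0: one motif
#' permutation_entropy(c(1, 3, 2, 4), pe_config(d = 2, weighted = TRUE))
#' @export
permutation_entropy <- function(x, cfg = pe_config()) {
  stopifnot(inherits(cfg, "pe_config"))
  v <- series_values(x)
  op <- ordinal_patterns(v, cfg$d, cfg$tau)
  if (cfg$weighted) {
    w <- rowMeans((op$motifs - rowMeans(op$motifs))^2)
    total <- sum(w)
    if (total <= 0) {
      stop("degenerate input: all motifs constant, total weight is zero, ",
           "weighted permutation entropy undefined", call. = FALSE)
    }
    P <- tapply(w, op$patterns, sum) / total
  } else {
    P <- table(op$patterns) / length(op$patterns)
  }
  P <- as.numeric(P)
  P <- P[P > 0]
  H <- -sum(P * log2(P))
  switch(cfg$normalization,
         possible_permutations = H / log2(factorial(cfg$d)),
         observed_permutations = if (length(P) == 1L) 0 else H / log2(length(P)),
         none = H)
}

# Grid-search score: weighted PE normalised by the number of *observed*
# patterns. A grid point with exactly one observed pattern scores 0 (its
# unnormalised entropy is already 0), even when its total motif weight is
# zero and the weighted entropy proper would be undefined.
pe_search_score <- function(v, d, tau) {
  op <- ordinal_patterns(v, d, tau)
  if (length(unique(op$patterns)) == 1L) {
    return(0)
  }
  permutation_entropy(v, pe_config(d, tau, weighted = TRUE,
                                   normalization = "observed_permutations"))
}

#' Grid search for permutation-entropy parameters
#'
#' Scans embedding dimensions `d` and delays `tau` for the pair minimising
#' the weighted permutation entropy normalised by the number of distinct
#' observed patterns (the `log2(d!)` normalisation would mechanically
#' favour large `d`). The winning parameters are meant to be chosen once on
#' the ground-truth series and then held fixed for every sampled version of
#' it, so that parameter drift never masquerades as a predictability
#' change.
#'
#' Grid points the series is too short for (`length < (d-1)*tau + 1`) are
#' skipped with a message. Ties are broken towards the smallest `d`, then
#' the smallest `tau` — the shortest-memory explanation, and deterministic.
#'
#' @param x series to tune on (normally the ground truth).
#' @param d_range integer vector of candidate orders (default `2:5`).
#' @param tau_range integer vector of candidate delays (default `1:7`).
#' @return A list with elements `d`, `tau` and `score` (the winning
#'   search-normalised weighted PE).
#' @export
pe_grid_search <- function(x, d_range = 2:5, tau_range = 1:7) {
  v <- series_values(x)
  best <- NULL
  n_skipped <- 0L
  for (d in sort(unique(as.integer(d_range)))) {
    for (tau in sort(unique(as.integer(tau_range)))) {
      if (length(v) < (d - 1L) * tau + 1L) {
        n_skipped <- n_skipped + 1L
        next
      }
      score <- pe_search_score(v, d, tau)
      if (is.null(best) || score < best$score) {
        best <- list(d = d, tau = tau, score = score)
      }
    }
  }
  if (n_skipped > 0L) {
    message("pe_grid_search: skipped ", n_skipped,
            " infeasible grid point(s) (series too short)")
  }
  if (is.null(best)) {
    stop("entire (d, tau) grid infeasible for a series of length ",
         length(v), call. = FALSE)
  }
  best
}

#' Lagged Pearson autocorrelation
#'
#' Pearson correlation between the series and its lag-shifted self: the
#' first `T - lag` values against the last `T - lag`, each segment centred
#' on its own mean. A constant segment has no defined correlation and
#' raises an error.
#'
#' @param x a series or numeric vector; length must exceed `lag + 1`.
#' @param lag positive integer lag.
#' @return A number in `[-1, 1]`.
#' @export
autocorrelation <- function(x, lag = 1L) {
  v <- series_values(x)
  lag <- as.integer(lag)[1L]
  if (is.na(lag) || lag < 1L) stop("lag must be a positive integer", call. = FALSE)
  n <- length(v)
  if (n < lag + 2L) stop("series too short for lag ", lag, call. = FALSE)
  a <- v[seq_len(n - lag)]
  b <- v[seq.int(lag + 1L, n)]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("zero variance in a segment: autocorrelation undefined", call. = FALSE)
  }
  stats::cor(a, b)
}

#' Most significant autocorrelation lag
#'
#' The lag in `1..max_lag` with the largest `|autocorrelation|`; intended
#' to be found on the ground-truth series and then reused unchanged for all
#' of its sampled versions. Lags at which the autocorrelation is undefined
#' (constant segment) are skipped; ties go to the smallest lag.
#'
#' @param x a series or numeric vector.
#' @param max_lag largest lag considered; `length(x)` must exceed
#'   `max_lag + 1`.
#' @return A positive integer lag.
#' @export
best_lag <- function(x, max_lag) {
  v <- series_values(x)
  max_lag <- as.integer(max_lag)[1L]
  if (is.na(max_lag) || max_lag < 1L) stop("max_lag must be >= 1", call. = FALSE)
  if (length(v) < max_lag + 2L) {
    stop("series too short for max_lag ", max_lag, call. = FALSE)
  }
  abs_rho <- rep(NA_real_, max_lag)
  for (k in seq_len(max_lag)) {
    abs_rho[k] <- tryCatch(abs(autocorrelation(v, k)), error = function(e) NA_real_)
  }
  if (all(is.na(abs_rho))) {
    stop("autocorrelation undefined at every lag", call. = FALSE)
  }
  # ties (within floating-point noise of the max) resolve to the smallest lag
  top <- max(abs_rho, na.rm = TRUE)
  which(!is.na(abs_rho) & abs_rho >= top - 1e-10)[1L]
}

# Map a series to discrete symbols for the plug-in entropy estimators.
# Integer-valued series are used as-is; real-valued series are discretised
# into equal-frequency (quantile) bins, by default ceiling(sqrt(T)) of
# them, which keeps the plug-in estimator stable at moderate lengths.
discretize_series <- function(v, bins) {
  if (identical(bins, "none")) {
    return(as.character(v))
  }
  if (identical(bins, "auto")) {
    if (all(v == trunc(v))) {
      return(as.character(v))
    }
    bins <- ceiling(sqrt(length(v)))
  }
  bins <- as.integer(bins)[1L]
  if (is.na(bins) || bins < 1L) {
    stop("bins must be a positive integer, \"auto\" or \"none\"", call. = FALSE)
  }
  breaks <- unique(stats::quantile(v, probs = seq(0, 1, length.out = bins + 1L),
                                   names = FALSE, type = 7))
  if (length(breaks) < 2L) {
    return(rep("1", length(v)))  # constant series: single symbol
  }
  as.character(cut(v, breaks = breaks, include.lowest = TRUE, labels = FALSE))
}

plugin_entropy <- function(symbols) {
  P <- table(symbols) / length(symbols)
  P <- as.numeric(P)
  P <- P[P > 0]
  -sum(P * log2(P))
}

#' Plug-in mutual information between two series
#'
#' `I(X; Y) = H(X) + H(Y) - H(X, Y)` in bits, from the empirical joint
#' distribution of (discretised) value pairs at lag 0. Captures nonlinear
#' dependence that covariance misses; `I = 0` iff the empirical joint
#' factorises.
#'
#' Integer count series are treated as discrete symbols directly
#' (`bins = "auto"` or `"none"`); real-valued series are discretised into
#' equal-frequency quantile bins, `ceiling(sqrt(T))` by default. The
#' plug-in estimator is biased upward on independent data at small `T`;
#' the bias shrinks as `T` grows relative to the number of occupied cells.
#'
#' @param x,y series or numeric vectors of equal length >= 2.
#' @param bins `"auto"` (default), `"none"`, or a positive integer number
#'   of quantile bins applied to both series.
#' @return A single non-negative number (bits).
#' @export
mutual_information <- function(x, y, bins = "auto") {
  vx <- series_values(x)
  vy <- series_values(y)
  if (length(vx) != length(vy)) {
    stop("series must have equal length", call. = FALSE)
  }
  if (length(vx) < 2L) stop("need at least two observations", call. = FALSE)
  sx <- discretize_series(vx, bins)
  sy <- discretize_series(vy, bins)
  mi <- plugin_entropy(sx) + plugin_entropy(sy) -
    plugin_entropy(paste(sx, sy, sep = "\r"))
  max(mi, 0)  # clip tiny negative rounding residue
}
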