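# Independent brute-force oracles used to freeze expected values. These
# deliberately share no code with the package: patterns come from explicit
# selection sort, entropies from direct summation over enumerated motifs.

# Ordinal pattern of one motif by repeated first-minimum extraction
# (stable: the earlier position wins on ties).
oracle_pattern <- function(m) {
  d <- length(m)
  idx <- integer(d)
  remaining <- seq_len(d)
  for (i in seq_len(d)) {
    j <- remaining[which.min(m[remaining])]
    idx[i] <- j
    remaining <- remaining[remaining != j]
  }
  paste(idx, collapse = "-")
}

oracle_pe <- function(v, d, tau, weighted = FALSE,
                      norm = c("possible", "observed", "none")) {
  norm <- match.arg(norm)
  n_motif <- length(v) - (d - 1) * tau
  stopifnot(n_motif >= 1)
  pats <- character(n_motif)
  wts <- numeric(n_motif)
  for (i in seq_len(n_motif)) {
    m <- v[i + (0:(d - 1)) * tau]
    pats[i] <- oracle_pattern(m)
    wts[i] <- sum((m - mean(m))^2) / d
  }
  if (weighted) {
    stopifnot(sum(wts) > 0)
    P <- tapply(wts, pats, sum) / sum(wts)
  } else {
    P <- table(pats) / n_motif
  }
  P <- as.numeric(P)
  P <- P[P > 0]
  H <- -sum(P * log2(P))
  switch(norm,
         possible = H / log2(factorial(d)),
         observed = if (length(P) == 1) 0 else H / log2(length(P)),
         none = H)
}

# Brute-force most-significant lag: max |Pearson rho| over 1..max_lag,
# smallest lag on ties.
oracle_best_lag <- function(v, max_lag) {
  n <- length(v)
  rho <- vapply(seq_len(max_lag), function(k) {
    abs(cor(v[1:(n - k)], v[(k + 1):n]))
  }, numeric(1))
  which.max(rho)
}

# Plug-in MI on discrete symbol vectors, direct from the joint table.
oracle_mi <- function(sx, sy) {
  joint <- table(sx, sy) / length(sx)
  px <- rowSums(joint)
  py <- colSums(joint)
  mi <- 0
  for (i in seq_along(px)) {
    for (j in seq_along(py)) {
      if (joint[i, j] > 0) {
        mi <- mi + joint[i, j] * log2(joint[i, j] / (px[i] * py[j]))
      }
    }
  }
  unname(mi)
}

# Stationary INAR(1) targets.
inar_mean <- function(alpha, lam) lam / (1 - alpha)
inar_acf <- function(alpha, k) alpha^k
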