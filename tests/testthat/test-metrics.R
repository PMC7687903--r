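test_that("autocorrelation matches the Pearson definition and its anchors", {
  expect_equal(autocorrelation(c(1, 2, 3, 4, 5), 1), 1)
  expect_equal(autocorrelation(c(1, 2, 1, 2, 1, 2), 1), -1)
  expect_error(autocorrelation(c(5, 5, 5, 5), 1), "zero variance")
  expect_error(autocorrelation(c(1, 2, 3), 5), "too short")
  # bounded, and time reversal preserves the lag-1 value
  set.seed(9)
  v <- rpois(300, 6)
  r <- autocorrelation(v, 1)
  expect_true(r >= -1 && r <= 1)
  expect_equal(autocorrelation(rev(v), 1), r, tolerance = 1e-12)
})

test_that("best lag finds the dominant period and breaks ties low", {
  t <- 1:280
  per7 <- sin(2 * pi * t / 7)
  expect_equal(best_lag(per7, 10), 7)
  expect_equal(best_lag(per7, 10), oracle_best_lag(per7, 10))
  # monotone ramp: every lag has rho = 1, tie resolves to lag 1
  expect_equal(best_lag(1:50, 10), 1)
  # white noise: deterministic argmax of the realized |rho|
  set.seed(41)
  w <- rnorm(2000)
  expect_equal(best_lag(w, 20), oracle_best_lag(w, 20))
  expect_error(best_lag(rep(2, 50), 5), "every lag")
})

test_that("permutation entropy matches brute-force enumeration", {
  # single motif type: zero entropy at every feasible (d, tau)
  for (d in 2:4) {
    for (tau in 1:3) {
      expect_equal(permutation_entropy(1:30, pe_config(d, tau, weighted = FALSE)), 0)
      expect_equal(permutation_entropy(1:30, pe_config(d, tau, weighted = TRUE)), 0)
    }
  }
  # alternating series, d=2 tau=1, unweighted: 3 up / 2 down motifs
  v <- c(1, 2, 1, 2, 1, 2)
  expected <- -(0.6 * log2(0.6) + 0.4 * log2(0.4))  # 0.9709506
  expect_equal(
    permutation_entropy(v, pe_config(2, 1, weighted = FALSE)), expected)
  expect_equal(expected, oracle_pe(v, 2, 1, weighted = FALSE, norm = "possible"))

  # weighted worked example: motif variances 1, 0.25, 1 -> P = (8/9, 1/9)
  w <- c(1, 3, 2, 4)
  expected_w <- -((8 / 9) * log2(8 / 9) + (1 / 9) * log2(1 / 9))  # 0.5032583
  expect_equal(permutation_entropy(w, pe_config(2, 1, weighted = TRUE)),
               expected_w, tolerance = 1e-12)
  expect_equal(expected_w, oracle_pe(w, 2, 1, weighted = TRUE, norm = "possible"),
               tolerance = 1e-12)

  # randomized agreement with the independent oracle across the grid
  set.seed(73)
  r <- rpois(120, 5)
  for (d in 2:4) {
    for (tau in c(1, 3)) {
      for (wt in c(TRUE, FALSE)) {
        expect_equal(
          permutation_entropy(r, pe_config(d, tau, weighted = wt)),
          oracle_pe(r, d, tau, weighted = wt, norm = "possible"),
          tolerance = 1e-12,
          info = sprintf("d=%d tau=%d weighted=%s", d, tau, wt))
      }
    }
  }
})

test_that("permutation entropy degenerate and boundary handling", {
  expect_error(permutation_entropy(c(1, 2), pe_config(3, 1)), "too short")
  expect_error(permutation_entropy(rep(4, 20), pe_config(2, 1, weighted = TRUE)),
               "degenerate")
  # unweighted PE of a constant series is 0 (single flat pattern)
  expect_equal(permutation_entropy(rep(4, 20), pe_config(2, 1, weighted = FALSE)), 0)
})

test_that("normalized PE lies in [0,1] and hits its extremes", {
  set.seed(11)
  for (i in 1:20) {
    v <- rpois(80, 8)
    h <- permutation_entropy(v, pe_config(3, 1, weighted = TRUE))
    expect_true(h >= 0 && h <= 1)
  }
  # pattern-uniform input approaches 1
  u <- runif(50000)
  expect_gte(permutation_entropy(u, pe_config(3, 1, weighted = FALSE)), 0.999)
})

test_that("unweighted PE is invariant under strictly monotone transforms; weighted under affine", {
  set.seed(57)
  v <- rpois(200, 10)
  cfg_u <- pe_config(3, 2, weighted = FALSE)
  expect_equal(permutation_entropy(exp(v / 5), cfg_u),
               permutation_entropy(v, cfg_u))
  cfg_w <- pe_config(3, 2, weighted = TRUE)
  expect_equal(permutation_entropy(3.7 * v + 11, cfg_w),
               permutation_entropy(v, cfg_w), tolerance = 1e-12)
})

test_that("tie handling follows the stable earlier-position-wins convention", {
  # motif (2, 2): tied values keep input order -> pattern "up"
  v <- c(2, 2, 1)
  # motifs: (2,2) -> up (stable), (2,1) -> down; unweighted P = (1/2, 1/2)
  expect_equal(permutation_entropy(v, pe_config(2, 1, weighted = FALSE)), 1)
  expect_equal(oracle_pe(v, 2, 1, weighted = FALSE, norm = "possible"), 1)
})

test_that("grid search minimizes search-normalized weighted PE with low-(d,tau) ties", {
  gs <- pe_grid_search(1:200)
  expect_equal(gs$d, 2L)
  expect_equal(gs$tau, 1L)
  expect_equal(gs$score, 0)

  # winner matches an exhaustive independent re-scan
  set.seed(91)
  v <- rpois(400, 6)
  gs2 <- pe_grid_search(v)
  scores <- expand.grid(d = 2:5, tau = 1:7)
  scores$h <- mapply(function(d, tau) oracle_pe(v, d, tau, weighted = TRUE,
                                                norm = "observed"),
                     scores$d, scores$tau)
  best <- scores[order(scores$h, scores$d, scores$tau), ][1, ]
  expect_equal(gs2$d, best$d)
  expect_equal(gs2$tau, best$tau)
  expect_equal(gs2$score, best$h, tolerance = 1e-12)
})

test_that("grid search skips infeasible points and fails on an infeasible grid", {
  v <- rpois(8, 5) + seq(0, 7)   # length 8: (d-1)*tau+1 > 8 points skipped
  expect_message(gs <- pe_grid_search(v), "skipped")
  expect_true((gs$d - 1) * gs$tau + 1 <= 8)
  expect_error(suppressMessages(pe_grid_search(c(1, 2), d_range = 4:5)),
               "infeasible")
})

test_that("mutual information matches hand-computable anchors", {
  x <- rep(c(0, 1), 50)
  expect_equal(mutual_information(x, x), 1)            # I(X;X) = H(X) = 1 bit
  expect_equal(mutual_information(c(0, 0, 1, 1), c(0, 1, 0, 1)), 0)
  expect_error(mutual_information(1:4, 1:5), "equal length")
  # symbol relabeling leaves MI unchanged
  set.seed(13)
  a <- rpois(500, 3)
  b <- rpois(500, 3) + a
  expect_equal(mutual_information(a, b), mutual_information(10 - a, b),
               tolerance = 1e-12)
  # agreement with the brute-force joint-table oracle
  expect_equal(mutual_information(a, b),
               oracle_mi(as.character(a), as.character(b)),
               tolerance = 1e-12)
})

test_that("plug-in MI is near zero for independent series and non-negative", {
  set.seed(29)
  x <- sample(0:9, 20000, replace = TRUE)
  y <- sample(0:9, 20000, replace = TRUE)
  mi <- mutual_information(x, y)
  expect_gte(mi, 0)
  expect_lt(mi, 0.05)
  # real-valued signals go through quantile binning; with an explicit
  # coarse grid the plug-in bias on independent data stays small, while
  # the default sqrt(T) grid still ranks dependence far above independence
  s1 <- rnorm(5000)
  s2 <- rnorm(5000)
  expect_lt(mutual_information(s1, s2, bins = 10), 0.05)
  # default grid: near-deterministic coupling recovers several bits, the
  # independent pair only the small-sample bias (< 1 bit at this T)
  expect_gt(mutual_information(s1, s1 + 0.01 * s2), 3)
  expect_lt(mutual_information(s1, s2), 1)
})
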