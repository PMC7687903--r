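# partialobs

Quantifying how random temporal sampling degrades the predictability of
event-count time series.

Many count series are observed only partially: disease surveillance sees a
fraction of true infections, public social-media APIs return a sample of
posts, repository telemetry misses events. `partialobs` models this as
independent binomial thinning — each of the `X_t` events at time `t` is
observed with probability `p`, so the observed count is

    Y_t ~ Binomial(X_t, p)

— and provides the closed-form consequences for predictability, the
model-free metrics to measure it, and the simulation machinery to validate
both.

## The model

For a stationary ground-truth process `X` with mean `E[X]`, variance
`Var(X)` and lagged autocovariance `Cov(X_i, X_{i+k})`, thinning at rate
`p` gives:

* **Variance** — `Var(Y) = p² Var(X) + p(1−p) E[X]` (thinning adds
  binomial observation noise proportional to the mean);
* **Lagged autocovariance** — `Cov(Y_i, Y_{i+k}) = p² Cov(X_i, X_{i+k})`
  (the noise is serially independent, so off-diagonal terms only shrink);
* **Autocorrelation** —
  `ρ_Y(k) = p² Cov(X_i, X_{i+k}) / (p² Var(X) + p(1−p) E[X])`,
  whose magnitude increases monotonically in `p` and recovers `ρ_X(k)` at
  `p = 1`;
* **External signal** — for any auxiliary series `S`,
  `Cov(Y, S) = p · Cov(X, S)`. The correlation
  `ρ_{Y,S} = p Cov(X,S) / (σ_Y σ_S)` is nearly invariant to sampling when
  `Var(X) ≫ E[X]` (since then `σ_Y ≈ p σ_X`), but decays for Poisson-like
  processes.

Alongside the closed forms, the package measures predictability
model-free: lagged Pearson autocorrelation, weighted permutation entropy
(ordinal-pattern entropy with amplitude weighting, `(d, τ)` chosen by grid
search on the ground truth and frozen), and plug-in mutual information.
A Poisson-INAR(1) generator (`X_t = α∘X_{t−1} + Poisson(λ)`, stationary
mean `λ/(1−α)`, lag-k autocorrelation `α^k`) provides a count-valued
autoregressive test bed in which every prediction has a closed form — in
particular the thinned lag-1 autocorrelation is exactly `p·α`.

## Worked example

```r
library(partialobs)

# count-valued AR(1) ground truth: mean 10, lag-1 autocorrelation 0.6
x <- generate_inar(alpha = 0.6, lam = 4, n = 20000, seed = 1)
autocorrelation(x, 1)
#> [1] 0.5956534

# observe only 50% of events
y <- binomial_sample(x, sampling_config(rate = 0.5, seed = 2))
autocorrelation(y, 1)
#> [1] 0.2948693

# the closed form predicts the loss: p * alpha = 0.30
m <- estimate_moments(x, max_lag = 1)
predicted_autocorrelation(m, lag = 1, p = 0.5)
#> [1] 0.2966082
```

Half the events gone halves the autocorrelation — the observed series is
genuinely less predictable, and the decay matches the theory. The same
loss appears in forecasting skill:

```r
forecast_experiment(x, rate_grid = c(0.02, 0.5, 1), n_reps = 60, seed = 3)
#>      p   ar_rmse poisson_rmse n_used n_dropped
#> 1 0.02 0.9999409    0.9999461     60         0
#> 2 0.50 0.9519316    0.9999250     60         0
#> 3 1.00 0.7926984    0.9998930     60         0
```

At full observation the AR(1) forecaster beats the
predict-the-mean Poisson baseline by the theoretical factor
`√(1−α²) = 0.8`; at `p = 0.02` its advantage is gone ("no more accurate
than a model that assumes independent events").

A thin CLI over the same functions is installed at
`system.file("cli", "partialobs.R", package = "partialobs")` with
subcommands `simulate`, `sample`, `external`, `theory`, `pe`, `acf`, `mi`,
`sweep`, `external-sweep`, `forecast`.

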