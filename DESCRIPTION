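Package: partialobs
Title: Predictability Loss in Partially Observed Count Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for quantifying how random temporal sampling (partial
    observation) degrades the predictability of event-count time series.
    Implements the binomial observation model Y_t ~ Binomial(X_t, p),
    closed-form predictions for the variance, lagged autocovariance,
    autocorrelation and external-signal covariance of the thinned series,
    model-free predictability metrics (weighted permutation entropy with
    ordinal-pattern grid search, lagged Pearson autocorrelation, plug-in
    mutual information), Poisson-INAR(1) synthetic generators with known
    stationary moments, and an experiment harness for sampling-rate sweeps,
    theory-versus-empirical comparison and autoregressive-versus-Poisson
    forecast degradation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
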