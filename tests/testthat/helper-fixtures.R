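# Shared fixtures: all simulated in code, nothing on disk.

# Well-conditioned truths (time scale near 1 cycle) for parameter-recovery
# checks; at n = 5000 the sampling error of every parameter is well inside
# the 5% band for these values.
recovery_truths <- function() {
  list(
    exponential = parsurv("exponential", c(rate = 0.5)),
    weibull     = parsurv("weibull", c(rate = 0.5, shape = 1.3)),
    loglogistic = parsurv("loglogistic", c(scale = 2.0, shape = 2.15)),
    lognormal   = parsurv("lognormal", c(meanlog = 0.8, sdlog = 0.83)),
    gompertz    = parsurv("gompertz", c(shape = 0.3, rate = 0.4)),
    gengamma    = parsurv("gengamma", c(mu = 0.9, sigma = 0.6, Q = 1.0))
  )
}

# Uncensored draw from a model by inverse-CDF sampling.
draw_uncensored <- function(model, n, seed) {
  set.seed(seed)
  data.frame(time = surv_inverse(model, stats::runif(n)), event = 1L)
}

# Right-censored draw: administrative cutoff plus uniform censoring.
draw_censored <- function(model, n, seed, cutoff = 20) {
  set.seed(seed)
  tev <- surv_inverse(model, stats::runif(n))
  cens <- pmin(stats::runif(n, 0, 2 * cutoff), cutoff)
  data.frame(time = pmax(pmin(tev, cens), 1e-9),
             event = as.integer(tev <= cens))
}

# Survival-curve step function evaluator (right-continuous).
km_stepfun <- function(curve) stats::stepfun(curve$time[-1], curve$surv)

# Independent log-density oracle: central-difference derivative of S.
numderiv_logdens <- function(model, t, h = 1e-6) {
  log((surv_prob(model, t - h) - surv_prob(model, t + h)) / (2 * h))
}

# A tiny two-parameter grid of models per family for property sweeps.
property_models <- function() {
  list(
    parsurv("exponential", c(rate = 0.05)),
    parsurv("exponential", c(rate = 0.6)),
    parsurv("weibull", c(rate = 0.02, shape = 1.32)),
    parsurv("weibull", c(rate = 0.3, shape = 0.7)),
    parsurv("loglogistic", c(scale = 9.06, shape = 2.15)),
    parsurv("loglogistic", c(scale = 16.12, shape = 2.0)),
    parsurv("lognormal", c(meanlog = 1.8, sdlog = 0.72)),
    parsurv("gompertz", c(shape = 0.1, rate = 0.05)),
    parsurv("gompertz", c(shape = -0.05, rate = 0.08)),
    parsurv("gengamma", c(mu = 2.0, sigma = 0.7, Q = 0.5)),
    parsurv("gengamma", c(mu = 2.0, sigma = 0.7, Q = -0.8))
  )
}
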