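test_that("every family starts at 1, decreases and stays within [0,1]", {
  grid <- seq(0, 80, by = 0.5)
  for (m in property_models()) {
    s <- surv_prob(m, grid)
    expect_equal(s[1], 1, info = m$family)
    expect_true(all(diff(s) <= 1e-12), info = m$family)
    expect_true(all(s >= 0 & s <= 1), info = m$family)
  }
})

test_that("closed-form survival values and medians are exact", {
  ll <- parsurv("loglogistic", c(scale = 9.06, shape = 2.15))
  expect_identical(surv_prob(ll, 0), 1)
  expect_equal(surv_prob(ll, 9.06), 0.5)     # log-logistic scale = median
  expect_equal(surv_prob(parsurv("exponential", c(rate = 0.1)), 10), exp(-1))
  ln <- parsurv("lognormal", c(meanlog = 1.80, sdlog = 0.72))
  expect_equal(surv_prob(ln, exp(1.80)), 0.5)  # lognormal median = e^mu
})

test_that("nested parameterizations collapse onto each other", {
  t <- c(0.5, 2, 7, 20)
  wb1 <- parsurv("weibull", c(rate = 0.09, shape = 1))
  ex <- parsurv("exponential", c(rate = 0.09))
  expect_equal(surv_prob(wb1, t), surv_prob(ex, t))
  # gengamma Q = 0 is the lognormal
  gg0 <- parsurv("gengamma", c(mu = 1.4, sigma = 0.6, Q = 0))
  ln <- parsurv("lognormal", c(meanlog = 1.4, sdlog = 0.6))
  expect_equal(surv_prob(gg0, t), surv_prob(ln, t), tolerance = 1e-12)
  # gengamma Q = 1 is the Weibull with rate e^(-mu/sigma), shape 1/sigma
  gg1 <- parsurv("gengamma", c(mu = 1.4, sigma = 0.5, Q = 1))
  wb <- parsurv("weibull", c(rate = exp(-1.4 / 0.5), shape = 2))
  expect_equal(surv_prob(gg1, t), surv_prob(wb, t), tolerance = 1e-10)
  # Gompertz shape -> 0 limit is the exponential
  gzo <- parsurv("gompertz", c(shape = 1e-10, rate = 0.07))
  expect_equal(surv_prob(gzo, t), surv_prob(parsurv("exponential", c(rate = 0.07)), t),
               tolerance = 1e-8)
})

test_that("log-densities agree with numerical differentiation of S", {
  t <- c(0.8, 3, 11, 30)
  for (m in property_models()) {
    expect_equal(surv_logdens(m, t), numderiv_logdens(m, t),
                 tolerance = 1e-5, info = m$family)
  }
})

test_that("log-densities agree with the flexsurv reference distributions", {
  t <- c(0.8, 3, 11, 30)
  gz <- parsurv("gompertz", c(shape = 0.1, rate = 0.05))
  expect_equal(surv_logdens(gz, t),
               flexsurv::dgompertz(t, shape = 0.1, rate = 0.05, log = TRUE))
  gg <- parsurv("gengamma", c(mu = 2.0, sigma = 0.7, Q = -0.8))
  expect_equal(surv_logdens(gg, t),
               flexsurv::dgengamma(t, mu = 2.0, sigma = 0.7, Q = -0.8, log = TRUE))
  expect_equal(surv_prob(gg, t),
               1 - flexsurv::pgengamma(t, mu = 2.0, sigma = 0.7, Q = -0.8))
  ll <- parsurv("loglogistic", c(scale = 9.06, shape = 2.15))
  expect_equal(surv_logdens(ll, t),
               flexsurv::dllogis(t, shape = 2.15, scale = 9.06, log = TRUE))
})

test_that("the inverse survival function inverts S for every family", {
  u <- c(0.95, 0.7, 0.5, 0.2, 0.04)
  for (m in property_models()) {
    tt <- surv_inverse(m, u)
    # a negative-shape Gompertz plateaus: probabilities below the plateau
    # are never reached and invert to Inf
    ok <- is.finite(tt)
    expect_true(any(ok), info = m$family)
    expect_equal(surv_prob(m, tt[ok]), u[ok], tolerance = 1e-9, info = m$family)
  }
})

test_that("invalid parameters and domains are rejected", {
  expect_error(parsurv("loglogistic", c(scale = -1, shape = 2)), "must be > 0")
  expect_error(parsurv("weibull", c(rate = 0.1)), "needs 2 parameters")
  expect_error(parsurv("nosuch", c(1)))
  m <- parsurv("exponential", c(rate = 0.1))
  expect_error(surv_prob(m, -1), ">= 0")
  expect_error(surv_inverse(m, 0), "in \\(0, 1\\]")
})

test_that("restricted mean survival matches closed forms", {
  ex <- parsurv("exponential", c(rate = 0.05))
  expect_equal(restricted_mean_survival(ex, 174, step = 0.1),
               (1 - exp(-0.05 * 174)) / 0.05, tolerance = 1e-3 / 20)
  # log-logistic with shape 2: integral of 1/(1+(t/theta)^2) = theta*atan(t/theta)
  ll2 <- parsurv("loglogistic", c(scale = 16.12, shape = 2.0))
  expect_equal(restricted_mean_survival(ll2, 174, step = 0.1),
               16.12 * atan(174 / 16.12), tolerance = 1e-3 / 20)
  expect_identical(restricted_mean_survival(ll2, 0), 0)
  expect_error(restricted_mean_survival(ll2, 10, step = 0), "> 0")
})
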