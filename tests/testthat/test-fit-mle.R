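test_that("censored log-likelihood has its closed forms", {
  ipd <- data.frame(time = c(2, 3), event = c(1L, 0L))
  for (lam in c(0.05, 0.2, 1)) {
    m <- parsurv("exponential", c(rate = lam))
    expect_equal(log_likelihood(m, ipd), log(lam) - 5 * lam)
  }
  expect_identical(log_likelihood(m, data.frame(time = numeric(0), event = integer(0))), 0)
})

test_that("log-likelihood equals independent per-record summation", {
  m <- parsurv("loglogistic", c(scale = 9.06, shape = 2.15))
  ipd <- draw_censored(m, 200, seed = 11, cutoff = 18)
  ev <- ipd$event == 1
  oracle <- sum(numderiv_logdens(m, ipd$time[ev])) +
    sum(log(surv_prob(m, ipd$time[!ev])))
  expect_equal(log_likelihood(m, ipd), oracle, tolerance = 1e-6)
})

test_that("exponential MLE matches the closed form to 1e-6 relative", {
  for (seed in c(1, 7, 23)) {
    ipd <- draw_censored(parsurv("exponential", c(rate = 0.15)), 150, seed)
    lam_hat <- fit_mle(ipd, "exponential")$model$params[["rate"]]
    expect_equal(lam_hat, sum(ipd$event) / sum(ipd$time), tolerance = 1e-6)
  }
})

test_that("Weibull with shape fixed at 1 reduces to the exponential fit", {
  ipd <- draw_censored(parsurv("exponential", c(rate = 0.12)), 120, seed = 5)
  wb <- fit_mle(ipd, "weibull", fixed = list(shape = 1))
  ex <- fit_mle(ipd, "exponential")
  expect_equal(wb$model$params[["rate"]], ex$model$params[["rate"]], tolerance = 1e-6)
  expect_equal(wb$n_params, 1L)
})

test_that("fitting recovers generating parameters within 5% at n=5000", {
  truths <- recovery_truths()
  for (nm in names(truths)) {
    ipd <- draw_uncensored(truths[[nm]], 5000, seed = 1)
    fit <- fit_mle(ipd, nm)
    expect_true(fit$converged, info = nm)
    expect_equal(unname(fit$model$params), unname(truths[[nm]]$params),
                 tolerance = 0.05, info = nm)
  }
})

test_that("the fitter agrees with flexsurvreg on the same likelihood", {
  ipd <- draw_censored(parsurv("loglogistic", c(scale = 9.06, shape = 2.15)),
                       400, seed = 2, cutoff = 20)
  ours <- fit_mle(ipd, "loglogistic")
  ref <- flexsurv::flexsurvreg(survival::Surv(time, event) ~ 1, data = ipd,
                               dist = "llogis")
  expect_equal(ours$loglik, ref$loglik, tolerance = 1e-6)
  expect_equal(unname(ours$model$params[c("shape", "scale")]),
               unname(ref$res[c("shape", "scale"), "est"]), tolerance = 1e-4)
})

test_that("AIC/BIC identities hold exactly", {
  ipd <- draw_censored(parsurv("weibull", c(rate = 0.05, shape = 1.3)), 90, seed = 9)
  for (fam in c("exponential", "weibull", "lognormal")) {
    f <- fit_mle(ipd, fam)
    expect_identical(f$aic, 2 * f$n_params - 2 * f$loglik)
    expect_identical(f$bic, f$n_params * log(f$n) - 2 * f$loglik)
  }
})

test_that("model selection ranks by parsimony and fit", {
  # data truly exponential: the 1-parameter family beats gengamma on BIC
  ipd <- draw_uncensored(parsurv("exponential", c(rate = 0.3)), 1500, seed = 4)
  fits <- select_best(ipd, c("gengamma", "exponential"))
  bics <- vapply(fits, `[[`, numeric(1), "bic")
  expect_lt(bics[[which(vapply(fits, `[[`, character(1), "family") == "exponential")]],
            bics[[which(vapply(fits, `[[`, character(1), "family") == "gengamma")]])
  # strong log-logistic shape is detected by AIC against all six families
  ipd2 <- draw_uncensored(parsurv("loglogistic", c(scale = 5, shape = 2.5)),
                          2000, seed = 6)
  ranked <- select_best(ipd2)
  expect_identical(ranked[[1]]$family, "loglogistic")
  # single-family input returns that family
  single <- select_best(ipd, "weibull")
  expect_length(single, 1)
  expect_identical(single[[1]]$family, "weibull")
})

test_that("fitted models serialize to JSON with their criteria", {
  ipd <- draw_censored(parsurv("exponential", c(rate = 0.2)), 60, seed = 8)
  f <- fit_mle(ipd, "exponential")
  path <- tempfile(fileext = ".json")
  write_fits_json(f, path)
  back <- jsonlite::read_json(path)
  expect_identical(back[[1]]$family, "exponential")
  expect_equal(back[[1]]$params$rate, f$model$params[["rate"]])
  expect_equal(back[[1]]$aic, f$aic)
})

test_that("degenerate inputs fail loudly, not silently", {
  expect_error(fit_mle(data.frame(time = c(1, 2, 3), event = c(0L, 0L, 1L)),
                       "weibull"), "at least 2 events")
  expect_error(fit_mle(data.frame(time = c(-1, 2), event = c(1L, 1L)),
                       "exponential"), "> 0")
  expect_error(check_ipd(data.frame(t = 1)), "columns 'time' and 'event'")
})
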