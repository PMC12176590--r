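#' Supported parametric survival families
#'
#' Six families used for extrapolating trial progression-free and overall
#' survival beyond follow-up. All time is measured in model cycles
#' (1 cycle = 21 days).
#'
#' @format Character vector of family names.
#' @export
psm_families <- c("exponential", "weibull", "loglogistic", "lognormal",
                  "gompertz", "gengamma")

# Parameter names and positivity constraints per family. Weibull is in
# proportional-hazards form S(t) = exp(-rate * t^shape); gengamma is the
# Prentice (mu, sigma, Q) parameterization so lognormal (Q = 0) and Weibull
# (Q = 1) sit inside it.
.psm_par_info <- list(
  exponential = list(names = "rate",                       positive = TRUE),
  weibull     = list(names = c("rate", "shape"),           positive = c(TRUE, TRUE)),
  loglogistic = list(names = c("scale", "shape"),          positive = c(TRUE, TRUE)),
  lognormal   = list(names = c("meanlog", "sdlog"),        positive = c(FALSE, TRUE)),
  gompertz    = list(names = c("shape", "rate"),           positive = c(FALSE, TRUE)),
  gengamma    = list(names = c("mu", "sigma", "Q"),        positive = c(FALSE, TRUE, FALSE))
)

#' Construct a parametric survival model
#'
#' @param family One of [psm_families].
#' @param params Numeric vector of parameters, either named with the
#'   family's parameter names or positional in the order documented below.
#'
#' @details Parameterizations (time `t` in cycles):
#' * `exponential(rate)`: \eqn{S(t) = e^{-\lambda t}}
#' * `weibull(rate, shape)`: \eqn{S(t) = e^{-\lambda t^{\gamma}}}
#' * `loglogistic(scale, shape)`: \eqn{S(t) = [1 + (t/\theta)^k]^{-1}};
#'   the scale equals the median survival time.
#' * `lognormal(meanlog, sdlog)`: \eqn{S(t) = 1 - \Phi((\ln t - \mu)/\sigma)}
#' * `gompertz(shape, rate)`: \eqn{S(t) = e^{-(b/a)(e^{at} - 1)}}, with the
#'   shape `a` unrestricted and the exponential as its \eqn{a \to 0} limit.
#' * `gengamma(mu, sigma, Q)`: Prentice form; `Q = 0` collapses to the
#'   lognormal and `Q = 1` to the Weibull.
#'
#' @return An object of class `parsurv`.
#' @examples
#' m <- parsurv("loglogistic", c(scale = 9.06, shape = 2.15))
#' surv_prob(m, c(0, 9.06))
#' @export
parsurv <- function(family, params) {
  family <- match.arg(family, psm_families)
  info <- .psm_par_info[[family]]
  params <- unlist(params)
  if (length(params) != length(info$names))
    stop(sprintf("family '%s' needs %d parameters (%s), got %d",
                 family, length(info$names),
                 paste(info$names, collapse = ", "), length(params)))
  if (!is.null(names(params)) && all(nzchar(names(params)))) {
    if (!setequal(names(params), info$names))
      stop(sprintf("parameter names for '%s' must be: %s",
                   family, paste(info$names, collapse = ", ")))
    params <- params[info$names]
  } else {
    names(params) <- info$names
  }
  if (any(!is.finite(params)))
    stop("all parameters must be finite")
  bad <- info$positive & params <= 0
  if (any(bad))
    stop(sprintf("parameter(s) %s of family '%s' must be > 0",
                 paste(info$names[bad], collapse = ", "), family))
  structure(list(family = family, params = params), class = "parsurv")
}

#' @export
print.parsurv <- function(x, ...) {
  cat("<parsurv>", x$family, "\n")
  print(round(x$params, 6))
  invisible(x)
}

.check_t <- function(t) {
  if (any(!is.finite(t)) || any(t < 0))
    stop("t must be finite and >= 0")
  t
}

# Gompertz cumulative hazard, stable as shape -> 0:
# H(t) = (b/a)(e^{at}-1) = b t * (e^{at}-1)/(at)
.gompertz_cumhaz <- function(t, a, b) {
  x <- a * t
  ratio <- ifelse(abs(x) < 1e-8, 1 + x / 2 + x^2 / 6, expm1(x) / x)
  ratio[t == 0] <- 1
  b * t * ratio
}

#' Survival probability S(t)
#'
#' Vectorized over `t` (model cycles).
#'
#' @param model A [parsurv] object.
#' @param t Nonnegative times in cycles.
#' @return Survival probabilities in `[0, 1]`.
#' @export
surv_prob <- function(model, t) {
  stopifnot(inherits(model, "parsurv"))
  t <- .check_t(t)
  p <- model$params
  out <- switch(model$family,
    exponential = exp(-p[["rate"]] * t),
    weibull     = exp(-p[["rate"]] * t^p[["shape"]]),
    loglogistic = 1 / (1 + (t / p[["scale"]])^p[["shape"]]),
    lognormal   = stats::plnorm(t, p[["meanlog"]], p[["sdlog"]], lower.tail = FALSE),
    gompertz    = exp(-.gompertz_cumhaz(t, p[["shape"]], p[["rate"]])),
    gengamma    = .gengamma_surv(t, p[["mu"]], p[["sigma"]], p[["Q"]])
  )
  unname(pmin(pmax(out, 0), 1))
}

.gengamma_surv <- function(t, mu, sigma, Q) {
  if (abs(Q) < 1e-12)
    return(stats::plnorm(t, mu, sigma, lower.tail = FALSE))
  out <- numeric(length(t))
  pos <- t > 0
  w <- (log(t[pos]) - mu) / sigma
  a <- Q^-2
  u <- a * exp(Q * w)
  out[pos] <- if (Q > 0) stats::pgamma(u, a, lower.tail = FALSE)
              else       stats::pgamma(u, a, lower.tail = TRUE)
  out[!pos] <- 1
  out
}

#' Log density implied by the survival function
#'
#' @inheritParams surv_prob
#' @return `log f(t)`; `-Inf` where the density is zero.
#' @export
surv_logdens <- function(model, t) {
  stopifnot(inherits(model, "parsurv"))
  t <- .check_t(t)
  p <- model$params
  out <- switch(model$family,
    exponential = log(p[["rate"]]) - p[["rate"]] * t,
    weibull     = log(p[["rate"]]) + log(p[["shape"]]) +
                  (p[["shape"]] - 1) * log(t) - p[["rate"]] * t^p[["shape"]],
    loglogistic = {
      k <- p[["shape"]]; th <- p[["scale"]]
      log(k) - log(th) + (k - 1) * (log(t) - log(th)) -
        2 * log1p((t / th)^k)
    },
    lognormal   = stats::dlnorm(t, p[["meanlog"]], p[["sdlog"]], log = TRUE),
    gompertz    = log(p[["rate"]]) + p[["shape"]] * t -
                  .gompertz_cumhaz(t, p[["shape"]], p[["rate"]]),
    gengamma    = .gengamma_logdens(t, p[["mu"]], p[["sigma"]], p[["Q"]])
  )
  unname(out)
}

.gengamma_logdens <- function(t, mu, sigma, Q) {
  if (abs(Q) < 1e-12)
    return(stats::dlnorm(t, mu, sigma, log = TRUE))
  w <- (log(t) - mu) / sigma
  a <- Q^-2
  logu <- log(a) + Q * w
  # f(t) = dgamma(u; a) * u * |Q| / (sigma * t)
  stats::dgamma(exp(logu), a, rate = 1, log = TRUE) +
    logu + log(abs(Q)) - log(sigma) - log(t)
}

#' Inverse survival function (quantile on the survival scale)
#'
#' Returns the time `t` with `S(t) = s`. Used by the trial simulator for
#' inverse-CDF sampling.
#'
#' @param model A [parsurv] object.
#' @param s Survival probabilities in `(0, 1]`.
#' @return Times in cycles.
#' @export
surv_inverse <- function(model, s) {
  stopifnot(inherits(model, "parsurv"))
  if (any(s <= 0 | s > 1)) stop("s must be in (0, 1]")
  p <- model$params
  out <- switch(model$family,
    exponential = -log(s) / p[["rate"]],
    weibull     = (-log(s) / p[["rate"]])^(1 / p[["shape"]]),
    loglogistic = p[["scale"]] * ((1 - s) / s)^(1 / p[["shape"]]),
    lognormal   = stats::qlnorm(s, p[["meanlog"]], p[["sdlog"]], lower.tail = FALSE),
    gompertz    = {
      a <- p[["shape"]]; b <- p[["rate"]]
      if (abs(a) < 1e-12) -log(s) / b
      else {
        arg <- 1 - (a / b) * log(s)
        # negative-shape Gompertz plateaus at exp(b/a); beyond it no solution
        out <- rep(Inf, length(arg))
        out[arg > 0] <- log(arg[arg > 0]) / a
        out
      }
    },
    gengamma    = {
      mu <- p[["mu"]]; sigma <- p[["sigma"]]; Q <- p[["Q"]]
      if (abs(Q) < 1e-12) stats::qlnorm(s, mu, sigma, lower.tail = FALSE)
      else {
        a <- Q^-2
        u <- if (Q > 0) stats::qgamma(s, a, lower.tail = FALSE)
             else       stats::qgamma(s, a, lower.tail = TRUE)
        exp(mu + sigma * log(u / a) / Q)
      }
    }
  )
  unname(out)
}

#' Restricted mean survival time
#'
#' Trapezoid integral of `S(t)` over `[0, horizon]`.
#'
#' @param model A [parsurv] object.
#' @param horizon Upper limit in cycles (> 0, or 0 for a zero integral).
#' @param step Grid resolution in cycles.
#' @return RMST in cycles.
#' @export
restricted_mean_survival <- function(model, horizon, step = 0.1) {
  stopifnot(inherits(model, "parsurv"))
  if (!is.finite(horizon) || horizon < 0) stop("horizon must be >= 0")
  if (step <= 0) stop("step must be > 0")
  if (horizon == 0) return(0)
  n <- max(1L, ceiling(horizon / step))
  t <- seq(0, horizon, length.out = n + 1L)
  s <- surv_prob(model, t)
  h <- horizon / n
  sum((s[-1] + s[-length(s)]) / 2) * h
}
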