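#' Right-censored log-likelihood
#'
#' \eqn{\sum_i \delta_i \ln f(t_i) + (1 - \delta_i) \ln S(t_i)} over the
#' individual patient data, where \eqn{\delta} is the event flag.
#'
#' @param model A [parsurv] object.
#' @param ipd Data frame with columns `time` (> 0, cycles) and `event`
#'   (1 = event, 0 = censored).
#' @return The log-likelihood; `-Inf` when any record has zero density or
#'   survival under the model (treated by the fitter as a failed candidate,
#'   never an error).
#' @export
log_likelihood <- function(model, ipd) {
  ipd <- check_ipd(ipd, allow_empty = TRUE)
  if (nrow(ipd) == 0) return(0)
  ev <- ipd$event == 1
  ll <- 0
  if (any(ev))  ll <- ll + sum(surv_logdens(model, ipd$time[ev]))
  if (any(!ev)) ll <- ll + sum(log(surv_prob(model, ipd$time[!ev])))
  if (!is.finite(ll)) return(-Inf)
  ll
}

#' Validate an IPD table
#'
#' @param ipd Data frame with at least `time` and `event`.
#' @param allow_empty Accept zero rows.
#' @return The validated data frame (invisibly usable).
#' @keywords internal
check_ipd <- function(ipd, allow_empty = FALSE) {
  if (!is.data.frame(ipd) || !all(c("time", "event") %in% names(ipd)))
    stop("ipd must be a data frame with columns 'time' and 'event'")
  if (nrow(ipd) == 0) {
    if (allow_empty) return(ipd)
    stop("ipd has no records")
  }
  if (any(!is.finite(ipd$time)) || any(ipd$time <= 0))
    stop("all times must be finite and > 0")
  if (!all(ipd$event %in% c(0, 1)))
    stop("event must be coded 0 (censored) / 1 (event)")
  ipd
}

# Optimization-scale transforms: positive parameters are log-transformed,
# unconstrained ones passed through.
.to_opt <- function(family, params) {
  pos <- .psm_par_info[[family]]$positive
  out <- params
  out[pos] <- log(params[pos])
  out
}
.from_opt <- function(family, theta) {
  pos <- .psm_par_info[[family]]$positive
  out <- theta
  out[pos] <- exp(theta[pos])
  names(out) <- .psm_par_info[[family]]$names
  out
}

# Deterministic moment-based starting values: location/spread of log event
# times seed every family, plus fixed perturbations for multi-start.
.start_values <- function(family, ipd) {
  tev <- ipd$time[ipd$event == 1]
  if (length(tev) < 2) tev <- ipd$time
  mlog <- mean(log(tev))
  slog <- max(stats::sd(log(tev)), 0.2)
  med <- exp(mlog)
  rate_naive <- sum(ipd$event) / sum(ipd$time)
  starts <- switch(family,
    exponential = list(c(rate = rate_naive)),
    weibull = {
      sh <- pmin(pmax(1.2 / slog, 0.3), 5)
      lapply(c(1, 0.5, 2), function(f) {
        g <- sh * f
        c(rate = log(2) / med^g, shape = g)
      })
    },
    loglogistic = {
      k <- pmin(pmax(pi / (sqrt(3) * slog), 0.3), 8)
      lapply(c(1, 0.5, 2), function(f) c(scale = med, shape = k * f))
    },
    lognormal = list(c(meanlog = mlog, sdlog = slog),
                     c(meanlog = mlog, sdlog = 2 * slog)),
    gompertz = list(c(shape = 1e-3, rate = rate_naive),
                    c(shape = 0.05, rate = rate_naive),
                    c(shape = -0.05, rate = rate_naive)),
    gengamma = list(c(mu = mlog, sigma = slog, Q = 1e-3),
                    c(mu = mlog, sigma = slog, Q = 1),
                    c(mu = mlog, sigma = slog, Q = -0.5))
  )
  starts
}

#' Fit a parametric survival model by maximum likelihood
#'
#' Multi-start quasi-Newton (BFGS) optimization of the right-censored
#' log-likelihood on transformed parameters (log scale for positive ones),
#' with deterministic moment-based starting heuristics.
#'
#' @param ipd IPD data frame (`time`, `event`); at least 2 events required.
#' @param family One of [psm_families].
#' @param fixed Optional named list of parameters held fixed (e.g.
#'   `list(shape = 1)` nests the exponential inside the Weibull).
#' @return A `parsurv_fit` object: `model`, `loglik`, `aic`, `bic`, `n`,
#'   `n_params` (estimated parameters), `converged`, `message`.
#'   Non-convergence is flagged, never silent.
#' @export
fit_mle <- function(ipd, family, fixed = NULL) {
  family <- match.arg(family, psm_families)
  ipd <- check_ipd(ipd)
  if (sum(ipd$event) < 2) stop("at least 2 events are required for fitting")
  pnames <- .psm_par_info[[family]]$names
  if (!is.null(fixed)) {
    fixed <- unlist(fixed)
    if (!all(names(fixed) %in% pnames))
      stop("fixed parameter names must be among: ", paste(pnames, collapse = ", "))
  }
  free <- setdiff(pnames, names(fixed))
  assemble <- function(nat_free) {
    full <- numeric(length(pnames)); names(full) <- pnames
    full[free] <- nat_free
    if (length(fixed)) full[names(fixed)] <- fixed
    full
  }
  negll <- function(theta_opt) {
    nat <- .from_opt_free(family, theta_opt, free)
    full <- assemble(nat)
    m <- tryCatch(parsurv(family, full), error = function(e) NULL)
    if (is.null(m)) return(1e10)
    ll <- log_likelihood(m, ipd)
    if (!is.finite(ll)) return(1e10)
    -ll
  }
  best <- NULL
  for (st in .start_values(family, ipd)) {
    if (length(fixed)) st[names(fixed)] <- fixed
    theta0 <- .to_opt_free(family, st[free], free)
    fit <- tryCatch(
      stats::optim(theta0, negll, method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$value) || fit$value >= 1e10) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  n <- nrow(ipd)
  k <- length(free)
  if (is.null(best)) {
    return(structure(list(model = NULL, loglik = -Inf, aic = Inf, bic = Inf,
                          n = n, n_params = k, converged = FALSE,
                          family = family,
                          message = "all starts failed or likelihood degenerate"),
                     class = "parsurv_fit"))
  }
  params <- assemble(.from_opt_free(family, best$par, free))
  ll <- -best$value
  structure(list(model = parsurv(family, params), loglik = ll,
                 aic = 2 * k - 2 * ll, bic = k * log(n) - 2 * ll,
                 n = n, n_params = k, converged = best$convergence == 0,
                 family = family,
                 message = if (best$convergence == 0) "ok" else
                   sprintf("optim convergence code %d", best$convergence)),
            class = "parsurv_fit")
}

.to_opt_free <- function(family, params_free, free) {
  pos <- stats::setNames(.psm_par_info[[family]]$positive,
                         .psm_par_info[[family]]$names)[free]
  out <- params_free
  out[pos] <- log(params_free[pos])
  out
}
.from_opt_free <- function(family, theta_free, free) {
  pos <- stats::setNames(.psm_par_info[[family]]$positive,
                         .psm_par_info[[family]]$names)[free]
  out <- theta_free
  out[pos] <- exp(theta_free[pos])
  names(out) <- free
  out
}

#' @export
print.parsurv_fit <- function(x, ...) {
  cat(sprintf("<parsurv_fit> %s  loglik=%.3f AIC=%.2f BIC=%.2f (n=%d, k=%d, %s)\n",
              x$family, x$loglik, x$aic, x$bic, x$n, x$n_params,
              if (x$converged) "converged" else paste("NOT converged:", x$message)))
  if (!is.null(x$model)) print(round(x$model$params, 5))
  invisible(x)
}

#' Fit several families and rank by information criteria
#'
#' @param ipd IPD data frame.
#' @param families Character vector of families (default: all six).
#' @return List of `parsurv_fit` objects sorted ascending by AIC, ties
#'   broken by BIC, then by fewer parameters. Families that fail to
#'   converge are dropped; if none converge an error lists per-family
#'   diagnostics.
#' @export
select_best <- function(ipd, families = psm_families) {
  if (length(families) == 0) stop("no families supplied")
  fits <- lapply(families, function(f)
    tryCatch(fit_mle(ipd, f), error = function(e)
      structure(list(model = NULL, loglik = -Inf, aic = Inf, bic = Inf,
                     n = NA_integer_, n_params = NA_integer_,
                     converged = FALSE, family = f, message = conditionMessage(e)),
                class = "parsurv_fit")))
  ok <- vapply(fits, function(f) isTRUE(f$converged), logical(1))
  if (!any(ok)) {
    msgs <- vapply(fits, function(f) paste0(f$family, ": ", f$message), character(1))
    stop("no family converged:\n", paste(msgs, collapse = "\n"))
  }
  kept <- fits[ok]
  ord <- order(vapply(kept, `[[`, numeric(1), "aic"),
               vapply(kept, `[[`, numeric(1), "bic"),
               vapply(kept, `[[`, numeric(1), "n_params"))
  kept[ord]
}

#' Serialize fitted models to JSON
#'
#' @param fits A `parsurv_fit` or list of them.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fits_json <- function(fits, path) {
  if (inherits(fits, "parsurv_fit")) fits <- list(fits)
  out <- lapply(fits, function(f) list(
    family = f$family, params = as.list(f$model$params),
    loglik = f$loglik, aic = f$aic, bic = f$bic))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
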