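#' Product-limit (Kaplan-Meier) estimate
#'
#' At each distinct event time the survivor function is multiplied by
#' `(1 - d/n)`; censored observations leave the risk set without a step.
#'
#' @param ipd IPD data frame with `time` (> 0) and `event` (0/1).
#' @return A `km_curve`: data frame with `time`, `n_risk`, `n_event`,
#'   `n_censor`, `surv`, starting at the row `(0, n, 0, 0, 1)`.
#' @export
km_estimate <- function(ipd) {
  ipd <- check_ipd(ipd)
  n0 <- nrow(ipd)
  tt <- sort(unique(ipd$time))
  d <- vapply(tt, function(x) sum(ipd$time == x & ipd$event == 1), numeric(1))
  cns <- vapply(tt, function(x) sum(ipd$time == x & ipd$event == 0), numeric(1))
  at_risk <- n0 - c(0, cumsum(d + cns))[seq_along(tt)]
  surv <- cumprod(1 - d / at_risk)
  out <- data.frame(time = c(0, tt), n_risk = c(n0, at_risk),
                    n_event = c(0, d), n_censor = c(0, cns),
                    surv = c(1, surv))
  class(out) <- c("km_curve", "data.frame")
  out
}

#' Assemble a digitized KM curve
#'
#' Wraps extracted curve coordinates (as read off a published plot) in the
#' container the reconstruction routine expects, validating monotonicity.
#'
#' @param time Ascending times in cycles, starting at 0.
#' @param surv Survival probabilities, starting at 1, nonincreasing.
#' @return A `km_curve` data frame (`time`, `surv`).
#' @export
km_curve <- function(time, surv) {
  if (length(time) != length(surv) || length(time) < 1)
    stop("time and surv must be equal-length, nonempty")
  if (time[1] != 0 || surv[1] != 1) {
    time <- c(0, time); surv <- c(1, surv)
  }
  if (is.unsorted(time, strictly = TRUE)) stop("times must be strictly ascending")
  if (any(diff(surv) > 1e-12)) stop("surv must be nonincreasing")
  if (any(surv < 0 | surv > 1)) stop("surv must lie in [0, 1]")
  out <- data.frame(time = time, surv = surv)
  class(out) <- c("km_curve", "data.frame")
  out
}

#' Sample a KM curve on a grid (digitization stand-in)
#'
#' Evaluates the right-continuous step function at `times`, optionally
#' adding truncated noise to mimic manual curve extraction; output is
#' re-monotonized so it remains a valid curve.
#'
#' @param curve A `km_curve` (from [km_estimate] or [km_curve]).
#' @param times Grid of times (ascending, starting at or above 0).
#' @param jitter_sd Standard deviation of additive digitization noise
#'   (default 0 = exact readout).
#' @return A `km_curve` on the grid.
#' @export
digitize_km <- function(curve, times, jitter_sd = 0) {
  stopifnot(inherits(curve, "km_curve"))
  if (is.unsorted(times)) stop("grid times must be ascending")
  s <- stats::stepfun(curve$time[-1], curve$surv)(times)
  if (jitter_sd > 0) {
    s <- s + stats::rnorm(length(s), 0, jitter_sd)
    s <- cummin(pmin(pmax(s, 0), 1))
  }
  if (times[1] > 0) { times <- c(0, times); s <- c(1, s) }
  s[1] <- 1
  km_curve(times, s)
}

#' Numbers at risk from IPD
#'
#' `n_at_risk(t)` counts records still under observation at `t`
#' (i.e. with `time >= t`).
#'
#' @param ipd IPD data frame.
#' @param times Ascending evaluation times.
#' @return Data frame `time`, `n_at_risk`.
#' @export
risk_table_at <- function(ipd, times) {
  if (length(times) == 0)
    return(data.frame(time = numeric(0), n_at_risk = integer(0)))
  if (is.unsorted(times)) stop("times must be ascending")
  ipd <- check_ipd(ipd)
  data.frame(time = times,
             n_at_risk = vapply(times, function(x) sum(ipd$time >= x), integer(1)))
}

#' Reconstruct pseudo-IPD from a digitized curve and numbers at risk
#'
#' Interval-wise inversion of the product-limit estimator (Guyot-type):
#' within each risk-table interval, integer censoring counts are adjusted
#' until the running risk set matches the published number at risk at the
#' next interval start, with event counts recovered from the curve steps.
#' Censoring within an interval is assumed uniform.
#'
#' @param curve `km_curve` of digitized coordinates.
#' @param risk Data frame `time`, `n_at_risk` (ascending times,
#'   nonincreasing counts, first count > 0).
#' @param total_events Optional known total number of events; when given,
#'   censoring in the final interval is adjusted so the reconstructed
#'   event count matches.
#' @param arm,endpoint,subgroup Labels copied onto the output records.
#' @return IPD data frame (`time`, `event`, `arm`, `endpoint`, `subgroup`)
#'   with `nrow == risk$n_at_risk[1]`.
#' @export
reconstruct_ipd <- function(curve, risk, total_events = NULL,
                            arm = "arm", endpoint = "OS", subgroup = "all") {
  stopifnot(inherits(curve, "km_curve"))
  if (!all(c("time", "n_at_risk") %in% names(risk)))
    stop("risk must have columns 'time' and 'n_at_risk'")
  if (is.unsorted(risk$time)) stop("risk times must be ascending")
  if (any(diff(risk$n_at_risk) > 0)) stop("n_at_risk must be nonincreasing")
  if (risk$n_at_risk[1] <= 0) stop("initial number at risk must be > 0")
  if (any(diff(curve$surv) > 1e-12)) stop("surv must be nonincreasing")

  tS <- curve$time; S <- curve$surv
  K <- length(tS)
  tR <- risk$time; nR <- risk$n_at_risk
  I <- length(tR)
  # first digitized index in each risk interval
  lower <- vapply(tR, function(x) which(tS >= x - 1e-12)[1], integer(1))
  if (any(is.na(lower))) stop("risk table extends beyond the digitized curve")
  upper <- c(lower[-1] - 1L, K)

  n_hat <- numeric(K + 1); n_hat[] <- NA_real_
  d <- integer(K); cen <- integer(K)
  cen_times <- vector("list", K)
  KM_hat <- numeric(K)
  last <- 1L
  n_cen_int <- integer(I)

  process_interval <- function(i, ncen_i, n_start, last, KM_last) {
    # distribute ncen_i censor times uniformly across the interval
    lo <- lower[i]; hi <- upper[i]
    t_end <- if (i < I) tS[lower[i + 1]] else tS[K]
    ct <- if (ncen_i > 0)
      tS[lo] + (seq_len(ncen_i)) * (t_end - tS[lo]) / (ncen_i + 1)
    else numeric(0)
    d_l <- integer(K); cen_l <- integer(K); ctimes <- vector("list", K)
    KM_l <- numeric(K)
    n <- n_start
    for (k in lo:hi) {
      if (k == 1) {
        d_l[k] <- 0L; KM_l[k] <- 1; KM_last <- 1; last <- 1L
      } else {
        dk <- round(n * (1 - S[k] / KM_last))
        dk <- max(0L, min(as.integer(dk), as.integer(n)))
        d_l[k] <- dk
        KM_l[k] <- if (n > 0) KM_last * (1 - dk / n) else KM_last
        if (dk > 0) { KM_last <- KM_l[k]; last <- k }
      }
      brk_lo <- tS[k]
      brk_hi <- if (k < K) tS[k + 1] else Inf
      in_k <- ct >= brk_lo & ct < brk_hi
      cen_l[k] <- sum(in_k)
      ctimes[[k]] <- ct[in_k]
      n <- n - d_l[k] - cen_l[k]
    }
    list(d = d_l, cen = cen_l, ctimes = ctimes, n_end = n,
         last = last, KM_last = KM_last, KM = KM_l)
  }

  for (i in seq_len(I)) {
    n_start <- if (i == 1) nR[1] else n_hat[lower[i]]
    KM_last <- if (i == 1) 1 else KM_hat[last]
    if (i < I) {
      # initial censoring guess from the survival drop vs. risk-set drop
      guess <- round(n_start * S[lower[i + 1]] / max(S[lower[i]], 1e-12)) - nR[i + 1]
      guess <- max(0L, as.integer(guess))
      res <- NULL
      for (iter in 1:60) {
        res <- process_interval(i, guess, n_start, last, KM_last)
        gap <- res$n_end - nR[i + 1]
        if (gap == 0) break
        newguess <- max(0L, guess + as.integer(gap))
        if (newguess == guess) break
        guess <- newguess
      }
      if (res$n_end != nR[i + 1] && res$n_end < 0)
        stop(sprintf("infeasible allocation in risk interval %d [%g, %g)",
                     i, tR[i], tR[i + 1]))
      n_cen_int[i] <- guess
    } else {
      # final interval: censoring fixed by total_events when known, else 0
      guess <- 0L
      if (!is.null(total_events)) {
        ev_so_far <- sum(d[seq_len(lower[I] - 1)])
        res0 <- process_interval(I, 0L, n_start, last, KM_last)
        ev_last <- sum(res0$d)
        excess <- (ev_so_far + ev_last) - (total_events - 0)
        # censor records to absorb excess events beyond the known total
        guess <- max(0L, as.integer(excess))
      }
      res <- process_interval(i, guess, n_start, last, KM_last)
      n_cen_int[i] <- guess
    }
    rng <- lower[i]:upper[i]
    d[rng] <- res$d[rng]; cen[rng] <- res$cen[rng]
    cen_times[rng] <- res$ctimes[rng]
    KM_hat[rng] <- res$KM[rng]
    last <- res$last
    n_hat[lower[i]] <- n_start
    for (k in rng) n_hat[k + 1] <- n_hat[k] - d[k] - cen[k]
  }

  if (!is.null(total_events)) {
    # trim event count down to the known total if rounding overshot
    excess <- sum(d) - total_events
    k <- K
    while (excess > 0 && k >= 1) {
      take <- min(d[k], excess)
      d[k] <- d[k] - take
      cen[k] <- cen[k] + take
      cen_times[[k]] <- c(cen_times[[k]], rep(tS[k], take))
      excess <- excess - take
      k <- k - 1
    }
  }

  times <- c(rep(tS, d), unlist(cen_times))
  events <- c(rep(1L, sum(d)), rep(0L, length(unlist(cen_times))))
  n_left <- nR[1] - length(times)
  if (n_left < 0) stop("reconstruction produced more records than the initial risk set")
  if (n_left > 0) {
    times <- c(times, rep(tS[K], n_left))
    events <- c(events, rep(0L, n_left))
  }
  times <- pmax(times, 1e-9)
  ord <- order(times, -events)
  data.frame(time = times[ord], event = events[ord],
             arm = arm, endpoint = endpoint, subgroup = subgroup,
             stringsAsFactors = FALSE)
}
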