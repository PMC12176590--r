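#' Economic settings of the cycle model
#'
#' @param discount_rate Annual discount rate (default 0.05).
#' @param cycle_days Cycle length in days (default 21, the q3w dosing
#'   interval).
#' @param horizon_years Time horizon in years (default 10; the number of
#'   cycles is rounded up, giving 174).
#' @param wtp Willingness-to-pay threshold in USD/QALY (default 23,901.90,
#'   1.94 times 2024 per-capita GDP).
#' @return An `econ_params` list with derived fields `n_cycles` and
#'   `cycle_years`.
#' @export
econ_params <- function(discount_rate = 0.05, cycle_days = 21,
                        horizon_years = 10, wtp = 23901.90) {
  if (discount_rate < 0) stop("discount_rate must be >= 0")
  if (cycle_days <= 0 || horizon_years <= 0) stop("cycle length and horizon must be > 0")
  structure(list(discount_rate = discount_rate, cycle_days = cycle_days,
                 horizon_years = horizon_years, wtp = wtp,
                 cycle_years = cycle_days / 365.25,
                 n_cycles = as.integer(ceiling(horizon_years * 365.25 / cycle_days))),
            class = "econ_params")
}

#' Health-state utilities
#'
#' @param pfs Utility while progression free (default 0.75).
#' @param pd Utility after progression (default 0.60). Death is 0.
#'
#' @details The base-case configuration is validated to keep `pd <= pfs`
#'   ([validate_config]); the container itself only requires both weights
#'   in `[0, 1]`, because independently resampled utilities in the
#'   probabilistic analysis may momentarily cross, which the accumulation
#'   arithmetic tolerates.
#' @return A `utility_set` list.
#' @export
utility_set <- function(pfs = 0.75, pd = 0.60) {
  if (!(pd >= 0 && pd <= 1 && pfs >= 0 && pfs <= 1))
    stop("utilities must lie in [0, 1]")
  structure(list(pfs = pfs, pd = pd, death = 0), class = "utility_set")
}

#' State occupancy from the two survival curves
#'
#' Partitioned-survival rule at every cycle boundary `j` (time `j` cycles):
#' `p_pfs = min(S_PFS, S_OS)`, `p_pd = max(0, S_OS - S_PFS)`,
#' `p_death = 1 - S_OS`. Boundaries where the extrapolated PFS curve
#' crosses above OS are clamped and counted.
#'
#' @param pfs_model,os_model [parsurv] models for the two endpoints.
#' @param econ An [econ_params].
#' @return A `psm_trace` data frame with one row per boundary `0..n_cycles`
#'   (`cycle`, `p_pfs`, `p_pd`, `p_death`) and attribute `clamp_count`.
#' @export
occupancy_trace <- function(pfs_model, os_model, econ = econ_params()) {
  stopifnot(inherits(pfs_model, "parsurv"), inherits(os_model, "parsurv"),
            inherits(econ, "econ_params"))
  j <- 0:econ$n_cycles
  s_pfs <- surv_prob(pfs_model, j)
  s_os <- surv_prob(os_model, j)
  clamp <- s_pfs > s_os
  out <- data.frame(cycle = j,
                    p_pfs = pmin(s_pfs, s_os),
                    p_pd = pmax(0, s_os - s_pfs),
                    p_death = 1 - s_os)
  attr(out, "clamp_count") <- sum(clamp)
  class(out) <- c("psm_trace", "data.frame")
  out
}

#' Discount factor at a cycle boundary
#'
#' `(1 + r)^(-j * cycle_days / 365.25)` — annual compounding evaluated in
#' continuous cycle time.
#'
#' @param j Cycle boundary (>= 0, vectorized).
#' @param econ An [econ_params].
#' @export
discount_factor <- function(j, econ = econ_params()) {
  if (any(j < 0)) stop("j must be >= 0")
  (1 + econ$discount_rate)^(-j * econ$cycle_years)
}

# Per-cycle accounting weights shared by QALY and cost accumulation: the
# model books each cycle at its opening boundary, so cycle m (m = 1..N)
# carries the occupancy of boundary m-1 and the discount factor of that
# same boundary. This start-of-cycle convention is what reproduces the
# published base case; see the methods vignette.
.cycle_weights <- function(trace, econ) {
  n <- econ$n_cycles
  idx <- seq_len(n)            # rows 1..N of the trace = boundaries 0..N-1
  list(idx = idx, disc = discount_factor(trace$cycle[idx], econ))
}

#' Discounted quality-adjusted life years
#'
#' Utility-weighted occupancy accumulated cycle by cycle (start-of-cycle
#' convention) and converted to years.
#'
#' @param trace A `psm_trace` from [occupancy_trace].
#' @param utilities A [utility_set].
#' @param econ An [econ_params].
#' @return QALYs (scalar).
#' @export
discounted_qalys <- function(trace, utilities = utility_set(),
                             econ = econ_params()) {
  stopifnot(inherits(trace, "psm_trace"), inherits(utilities, "utility_set"))
  w <- .cycle_weights(trace, econ)
  u <- utilities$pfs * trace$p_pfs[w$idx] + utilities$pd * trace$p_pd[w$idx]
  sum(u * w$disc) * econ$cycle_years
}

#' Discounted life years
#'
#' [discounted_qalys] with both alive-state utilities set to 1.
#'
#' @inheritParams discounted_qalys
#' @export
discounted_life_years <- function(trace, econ = econ_params()) {
  stopifnot(inherits(trace, "psm_trace"))
  w <- .cycle_weights(trace, econ)
  alive <- trace$p_pfs[w$idx] + trace$p_pd[w$idx]
  sum(alive * w$disc) * econ$cycle_years
}

#' Export a trace with its discount column
#'
#' @param trace A `psm_trace`.
#' @param econ An [econ_params].
#' @param path Optional CSV path; when `NULL` the data frame is returned.
#' @export
trace_table <- function(trace, econ = econ_params(), path = NULL) {
  out <- cbind(trace, discount = discount_factor(trace$cycle, econ))
  if (!is.null(path)) {
    utils::write.csv(out, path, row.names = FALSE)
    return(invisible(path))
  }
  out
}
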