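#' Table of uncertain parameters
#'
#' Collects the sensitivity block of the config into one table, resolving
#' each parameter's base value from its config path.
#'
#' @param config A `psmcea_config`.
#' @return Data frame `path`, `base`, `low`, `high`, `family`, `role`.
#' @export
param_table <- function(config) {
  ps <- config$sensitivity$parameters
  if (is.null(ps) || length(ps) == 0)
    return(data.frame(path = character(0), base = numeric(0), low = numeric(0),
                      high = numeric(0), family = character(0), role = character(0)))
  do.call(rbind, lapply(ps, function(p) data.frame(
    path = p$path, base = config_get(config, p$path),
    low = p$low, high = p$high, family = p$family, role = p$role,
    stringsAsFactors = FALSE)))
}

#' One-way sensitivity analysis (tornado)
#'
#' Each parameter is set in turn to its lower and upper bound (all others
#' at base) and the scenario ICER recomputed. Parameters without a stated
#' range default to +-20% around base.
#'
#' @param config A `psmcea_config`.
#' @param scenario Scenario name.
#' @param params Parameter table (default [param_table] of the config).
#' @return Data frame sorted by descending span: `path`, `icer_low`,
#'   `icer_high`, `span`; an empty parameter table yields an empty tornado.
#' @export
owsa <- function(config, scenario = "whole", params = param_table(config)) {
  base <- run_scenario(config, scenario)
  if (base$cea$label != "icer")
    stop("base case has no finite ICER; tornado undefined")
  if (nrow(params) == 0)
    return(data.frame(path = character(0), icer_low = numeric(0),
                      icer_high = numeric(0), span = numeric(0)))
  rng <- config$sensitivity$default_range
  if (is.null(rng)) rng <- 0.20
  rows <- lapply(seq_len(nrow(params)), function(i) {
    p <- params[i, ]
    lo <- if (is.na(p$low)) p$base * (1 - rng) else p$low
    hi <- if (is.na(p$high)) p$base * (1 + rng) else p$high
    il <- run_scenario(config_set(config, p$path, lo), scenario)$cea$icer
    ih <- run_scenario(config_set(config, p$path, hi), scenario)$cea$icer
    data.frame(path = p$path, icer_low = il, icer_high = ih,
               span = abs(ih - il), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(-out$span), , drop = FALSE]
}

#' Draw from an uncertain parameter
#'
#' Method-of-moments sampling: the standard error is taken as
#' `(high - low) / 3.92` (the range read as a 95% interval). Costs use a
#' gamma with `shape = base^2/SE^2`, `scale = SE^2/base`; probabilities,
#' utilities and the discount rate use a beta matched to the same mean
#' and variance. A zero-width range returns the base value.
#'
#' @param base,low,high Base value and range.
#' @param family `"gamma"` or `"beta"`.
#' @param n Number of draws.
#' @return Numeric vector of `n` draws (uses the current RNG state).
#' @export
sample_param <- function(base, low, high, family = c("gamma", "beta"), n = 1) {
  family <- match.arg(family)
  se <- (high - low) / 3.92
  if (se == 0) return(rep(base, n))
  if (family == "gamma") {
    if (base <= 0) stop("gamma sampling needs base > 0")
    stats::rgamma(n, shape = base^2 / se^2, scale = se^2 / base)
  } else {
    if (base <= 0 || base >= 1)
      stop(sprintf("beta sampling needs base in (0,1); got %g", base))
    v <- se^2
    if (v >= base * (1 - base))
      stop(sprintf("beta moments infeasible for base=%g, SE=%g", base, se))
    k <- base * (1 - base) / v - 1
    stats::rbeta(n, base * k, (1 - base) * k)
  }
}

#' Probabilistic sensitivity analysis
#'
#' Monte-Carlo rerun of both arms with all uncertain parameters jointly
#' resampled per draw. Survival-curve parameters are not resampled (no
#' published ranges exist for them); the switch `resample_survival` is a
#' placeholder that errors if enabled without ranges.
#'
#' @param config A `psmcea_config`.
#' @param scenario Scenario name.
#' @param n Number of draws (default 1000).
#' @param seed Integer seed; same seed, same result.
#' @param resample_survival Not supported; must stay `FALSE`.
#' @return A `psa_result`: data frame `draws` (`inc_cost`, `inc_qalys`),
#'   the per-draw parameter matrix, `n`, `seed`, and a count of failed
#'   draws (excluded with a warning).
#' @export
run_psa <- function(config, scenario = "whole", n = 1000, seed = 1L,
                    resample_survival = FALSE) {
  if (resample_survival)
    stop("survival parameters carry no uncertainty ranges; resampling unsupported")
  if (n < 1) stop("n must be >= 1")
  params <- param_table(config)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  draws_mat <- matrix(NA_real_, nrow = n, ncol = nrow(params),
                      dimnames = list(NULL, params$path))
  for (j in seq_len(nrow(params)))
    draws_mat[, j] <- sample_param(params$base[j], params$low[j],
                                   params$high[j], params$family[j], n)
  inc_cost <- numeric(n); inc_q <- numeric(n); failed <- 0L
  for (i in seq_len(n)) {
    cfg_i <- config
    for (j in seq_len(ncol(draws_mat)))
      cfg_i <- config_set(cfg_i, params$path[j], draws_mat[i, j])
    r <- tryCatch(run_scenario(cfg_i, scenario), error = function(e) NULL)
    if (is.null(r)) {
      failed <- failed + 1L
      inc_cost[i] <- NA_real_; inc_q[i] <- NA_real_
    } else {
      inc_cost[i] <- r$cea$inc_cost; inc_q[i] <- r$cea$inc_qalys
    }
  }
  if (failed > 0)
    warning(failed, " PSA draw(s) failed and were excluded")
  keep <- !is.na(inc_cost)
  structure(list(draws = data.frame(inc_cost = inc_cost[keep],
                                    inc_qalys = inc_q[keep]),
                 params = draws_mat, n = n, seed = as.integer(seed),
                 n_failed = failed, scenario = scenario,
                 wtp = config$econ$wtp),
            class = "psa_result")
}

#' Cost-effectiveness acceptability curve
#'
#' Probability that the intervention is cost-effective,
#' `P(wtp * dQALY - dCost > 0)`, along a willingness-to-pay grid.
#'
#' @param psa A `psa_result`.
#' @param wtp_grid Numeric vector of thresholds.
#' @return Data frame `wtp`, `prob_cost_effective`.
#' @export
ceac <- function(psa, wtp_grid) {
  stopifnot(inherits(psa, "psa_result"))
  if (nrow(psa$draws) == 0) stop("PSA has no successful draws")
  prob <- vapply(wtp_grid, function(w)
    mean(w * psa$draws$inc_qalys - psa$draws$inc_cost > 0), numeric(1))
  data.frame(wtp = wtp_grid, prob_cost_effective = prob)
}
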