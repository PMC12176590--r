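#' Run one arm of a scenario
#'
#' Chains survival extrapolation, state occupancy, QALY accumulation and
#' cost accounting for one treatment arm of a named scenario.
#'
#' @param config A `psmcea_config` (see [load_config]).
#' @param scenario Scenario name from `config$scenarios` (e.g. `"whole"`,
#'   `"cps_ge10"`, `"pap"`).
#' @param arm Arm name from `config$arms`.
#' @return An `arm_result` list: `cost` (USD), `qalys`, `life_years`,
#'   `clamp_count`, plus labels.
#' @export
run_arm <- function(config, scenario, arm) {
  stopifnot(inherits(config, "psmcea_config"))
  if (is.null(config$scenarios[[scenario]]))
    stop("unknown scenario: ", scenario)
  if (is.null(config$arms[[arm]])) stop("unknown arm: ", arm)
  econ <- .config_econ(config)
  models <- .config_models(config, scenario, arm)
  trace <- occupancy_trace(models$pfs, models$os, econ)
  pap <- if (isTRUE(config$scenarios[[scenario]]$pap)) .config_pap(config) else NULL
  res <- list(
    scenario = scenario, arm = arm,
    cost = arm_discounted_cost(trace, .config_regimen(config, arm),
                               .config_cost_inputs(config, arm), econ,
                               .config_profile(config), pap = pap),
    qalys = discounted_qalys(trace, .config_utilities(config), econ),
    life_years = discounted_life_years(trace, econ),
    clamp_count = attr(trace, "clamp_count"))
  class(res) <- "arm_result"
  res
}

#' Incremental cost-effectiveness ratio
#'
#' @param exp,ctrl `arm_result`s (or lists with `cost` and `qalys`) for
#'   the experimental and control strategies.
#' @return A `cea_result`: `inc_cost`, `inc_qalys`, `icer` (finite number,
#'   or `NA` with a `label` of `"dominant"`, `"dominated"` or
#'   `"no_difference"`). Dominance is a label, never an error.
#' @export
icer <- function(exp, ctrl) {
  dc <- exp$cost - ctrl$cost
  dq <- exp$qalys - ctrl$qalys
  label <- "icer"
  val <- NA_real_
  if (dq == 0) {
    label <- "no_difference"
  } else if (dq > 0 && dc < 0) {
    label <- "dominant"
  } else if (dq < 0 && dc >= 0) {
    label <- "dominated"
  } else {
    val <- dc / dq
  }
  structure(list(inc_cost = dc, inc_qalys = dq, icer = val, label = label),
            class = "cea_result")
}

#' @export
print.cea_result <- function(x, ...) {
  cat(sprintf("<cea_result> dCost=%.2f dQALY=%.4f %s\n", x$inc_cost,
              x$inc_qalys,
              if (x$label == "icer") sprintf("ICER=%.2f/QALY", x$icer) else x$label))
  invisible(x)
}

#' Net monetary benefit
#'
#' `wtp * dQALY - dCost`; zero exactly when the ICER equals the threshold.
#'
#' @param result A `cea_result` (or anything with `inc_cost`/`inc_qalys`).
#' @param wtp Willingness to pay, USD/QALY.
#' @return USD.
#' @export
nmb <- function(result, wtp) {
  wtp * result$inc_qalys - result$inc_cost
}

#' Compare both arms of one scenario
#'
#' @inheritParams run_arm
#' @return List with both `arm_result`s and the `cea_result`.
#' @export
run_scenario <- function(config, scenario) {
  exp_arm <- run_arm(config, scenario, "sugemalimab_chemo")
  ctrl_arm <- run_arm(config, scenario, "chemo")
  list(exp = exp_arm, ctrl = ctrl_arm, cea = icer(exp_arm, ctrl_arm))
}

#' Base-case comparison table across scenarios
#'
#' @param config A `psmcea_config`.
#' @param scenarios Character vector of scenario names (default: all in
#'   the config); an empty vector returns an empty table.
#' @return Data frame with one row per scenario: arm costs and QALYs,
#'   increments, ICER (the comparison-table shape of the base case).
#' @export
run_all <- function(config, scenarios = names(config$scenarios)) {
  cols <- c("scenario", "cost_exp", "qalys_exp", "cost_ctrl", "qalys_ctrl",
            "inc_cost", "inc_qalys", "icer")
  if (length(scenarios) == 0) {
    out <- as.data.frame(stats::setNames(rep(list(numeric(0)), length(cols)), cols))
    out$scenario <- character(0)
    return(out)
  }
  rows <- lapply(scenarios, function(sc) {
    r <- run_scenario(config, sc)
    data.frame(scenario = sc,
               cost_exp = r$exp$cost, qalys_exp = r$exp$qalys,
               cost_ctrl = r$ctrl$cost, qalys_ctrl = r$ctrl$qalys,
               inc_cost = r$cea$inc_cost, inc_qalys = r$cea$inc_qalys,
               icer = if (r$cea$label == "icer") r$cea$icer else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Price at which a scenario becomes cost-effective
#'
#' Bisection on the sugemalimab package price (efficacy, and hence the
#' QALY increment, held fixed) until the ICER meets the willingness-to-pay
#' threshold.
#'
#' @param config A `psmcea_config`.
#' @param scenario Scenario name (the assistance schedule stays active in
#'   the `"pap"` scenario).
#' @param wtp Threshold (default: the config's).
#' @param bounds Price search interval, USD per package (default `[0,
#'   current price]`).
#' @param tol Price tolerance of the bisection, USD (default 0.01).
#' @param price_path Config path of the price being varied.
#' @param max_iter Bisection iteration cap.
#' @return List: `price`, `pct_reduction` (from the current price),
#'   `icer` at the returned price, `status` (`"ok"`,
#'   `"already_cost_effective"` or `"not_achievable"`), `wtp`.
#' @export
price_threshold <- function(config, scenario = "whole", wtp = NULL,
                            bounds = NULL, tol = 0.01,
                            price_path = "drugs.sugemalimab.vial_price",
                            max_iter = 60) {
  stopifnot(inherits(config, "psmcea_config"))
  base_price <- config_get(config, price_path)
  if (is.null(wtp)) wtp <- config$econ$wtp
  if (is.null(bounds)) bounds <- c(0, base_price)
  icer_at <- function(price) {
    r <- run_scenario(config_set(config, price_path, price), scenario)
    r$cea$icer
  }
  at_hi <- icer_at(bounds[2])
  if (is.na(at_hi) || at_hi <= wtp)
    return(list(price = bounds[2], pct_reduction = 100 * (1 - bounds[2] / base_price),
                icer = at_hi, status = "already_cost_effective", wtp = wtp))
  at_lo <- icer_at(bounds[1])
  if (!is.na(at_lo) && at_lo > wtp)
    return(list(price = bounds[1], pct_reduction = 100 * (1 - bounds[1] / base_price),
                icer = at_lo, status = "not_achievable", wtp = wtp))
  lo <- bounds[1]; hi <- bounds[2]
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    if (icer_at(mid) > wtp) hi <- mid else lo <- mid
    if (hi - lo < tol) break
  }
  price <- (lo + hi) / 2
  list(price = price, pct_reduction = 100 * (1 - price / base_price),
       icer = icer_at(price), status = "ok", wtp = wtp)
}
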