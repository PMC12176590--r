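#' Load and validate a model configuration
#'
#' Reads the YAML configuration holding every model input (economic
#' settings, utilities, dosing and prices, adverse events, assistance
#' tiers, survival parameters, sensitivity ranges) and validates it.
#'
#' @param path YAML file; `NULL` loads the package default, which encodes
#'   the published base case.
#' @return A validated `psmcea_config` list.
#' @export
load_config <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "default_config.yaml", package = "psmcea")
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg) || !is.list(cfg)) stop("config file is empty or not a mapping")
  validate_config(cfg)
}

#' @rdname load_config
#' @param config A configuration list to validate.
#' @export
validate_config <- function(config) {
  need <- function(field, type = "numeric") {
    v <- config_get(config, field)
    if (is.null(v))
      stop(sprintf("config field '%s' is missing (expected %s)", field, type))
    if (type == "numeric" && !is.numeric(v))
      stop(sprintf("config field '%s' must be numeric", field))
    v
  }
  for (f in c("econ.discount_rate", "econ.cycle_days", "econ.horizon_years",
              "econ.wtp", "patient.weight_kg", "patient.bsa_m2",
              "utilities.pfs", "utilities.pd",
              "costs.post_progression_per_cycle",
              "costs.hospitalization_per_cycle"))
    need(f)
  if (config$utilities$pd > config$utilities$pfs)
    stop("config field 'utilities.pd' must not exceed 'utilities.pfs'")
  if (config$utilities$pfs > 1 || config$utilities$pd < 0)
    stop("utilities must lie in [0, 1]")
  if (is.null(config$drugs) || is.null(config$arms) || is.null(config$survival) ||
      is.null(config$scenarios))
    stop("config must define 'drugs', 'arms', 'survival' and 'scenarios'")
  for (d in names(config$drugs)) {
    dr <- config$drugs[[d]]
    for (f in c("dose", "vial_mg", "vial_price", "admins_per_cycle"))
      if (is.null(dr[[f]]) || !is.numeric(dr[[f]]))
        stop(sprintf("config field 'drugs.%s.%s' missing or non-numeric (mg/USD)", d, f))
  }
  for (arm in names(config$arms))
    for (d in config$arms[[arm]])
      if (is.null(config$drugs[[d]]))
        stop(sprintf("arm '%s' references undefined drug '%s'", arm, d))
  for (arm in names(config$adverse_events$risks)) {
    r <- unlist(config$adverse_events$risks[[arm]])
    if (any(r < 0 | r > 1))
      stop(sprintf("adverse event risks for arm '%s' must be in [0, 1]", arm))
  }
  for (set in names(config$survival))
    for (arm in names(config$survival[[set]]))
      for (ep in c("pfs", "os")) {
        s <- config$survival[[set]][[arm]][[ep]]
        if (is.null(s$family))
          stop(sprintf("survival.%s.%s.%s needs a 'family'", set, arm, ep))
        .config_parsurv(s)  # constructor enforces the positivity constraints
      }
  for (sc in names(config$scenarios)) {
    surv <- config$scenarios[[sc]]$survival
    if (is.null(config$survival[[surv]]))
      stop(sprintf("scenario '%s' references undefined survival set '%s'", sc, surv))
  }
  if (!is.null(config$sensitivity$parameters))
    for (p in config$sensitivity$parameters) {
      base <- config_get(config, p$path)
      if (is.null(base))
        stop(sprintf("sensitivity parameter path '%s' not found in config", p$path))
      if (!(p$low <= base + 1e-9 && base <= p$high + 1e-9))
        stop(sprintf("sensitivity range for '%s' must satisfy low <= base <= high", p$path))
      if (!p$family %in% c("gamma", "beta"))
        stop(sprintf("sensitivity family for '%s' must be gamma or beta", p$path))
    }
  structure(config, class = c("psmcea_config", "list"))
}

#' Get or set a config value by dotted path
#'
#' @param config A config list.
#' @param path Dotted path, e.g. `"drugs.sugemalimab.vial_price"`.
#' @return `config_get`: the value (or `NULL`); `config_set`: the
#'   modified config.
#' @export
config_get <- function(config, path) {
  cur <- config
  for (k in strsplit(path, ".", fixed = TRUE)[[1]]) {
    if (is.null(cur[[k]])) return(NULL)
    cur <- cur[[k]]
  }
  cur
}

#' @rdname config_get
#' @param value Replacement value.
#' @export
config_set <- function(config, path, value) {
  keys <- strsplit(path, ".", fixed = TRUE)[[1]]
  rec <- function(x, ks) {
    if (length(ks) == 1) { x[[ks]] <- value; return(x) }
    x[[ks[1]]] <- rec(x[[ks[1]]], ks[-1])
    x
  }
  rec(config, keys)
}

#' Serialize a config back to YAML
#'
#' `load_config(dump_config(cfg, f))` is the identity.
#'
#' @param config A `psmcea_config`.
#' @param path Output YAML file.
#' @export
dump_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 12)
  invisible(path)
}

# -- builders from config sections ------------------------------------------

.config_parsurv <- function(spec) {
  params <- unlist(spec[setdiff(names(spec), "family")])
  parsurv(spec$family, params)
}

.config_econ <- function(config) {
  econ_params(discount_rate = config$econ$discount_rate,
              cycle_days = config$econ$cycle_days,
              horizon_years = config$econ$horizon_years,
              wtp = config$econ$wtp)
}

.config_utilities <- function(config) {
  utility_set(pfs = config$utilities$pfs, pd = config$utilities$pd)
}

.config_profile <- function(config) {
  patient_profile(weight_kg = config$patient$weight_kg,
                  bsa_m2 = config$patient$bsa_m2)
}

.config_regimen <- function(config, arm) {
  lapply(config$arms[[arm]], function(d) {
    dr <- config$drugs[[d]]
    regimen_component(name = d, dose = dr$dose, basis = dr$basis,
                      admins_per_cycle = dr$admins_per_cycle,
                      vial_mg = dr$vial_mg, vial_price = dr$vial_price,
                      max_cycles = if (is.null(dr$max_cycles)) Inf else dr$max_cycles,
                      pap_gated = isTRUE(dr$pap_gated))
  })
}

.config_cost_inputs <- function(config, arm) {
  risks <- config$adverse_events$risks[[arm]]
  ae <- if (is.null(risks)) NULL else data.frame(
    name = names(risks),
    incidence = unlist(risks, use.names = FALSE),
    cost = unlist(config$adverse_events$unit_costs[names(risks)], use.names = FALSE))
  cost_inputs(post_progression_per_cycle = config$costs$post_progression_per_cycle,
              hospitalization_per_cycle = config$costs$hospitalization_per_cycle,
              ae = ae)
}

.config_pap <- function(config) {
  pap_schedule(tiers = lapply(config$pap$tiers, as.integer),
               after = if (is.null(config$pap$after)) "free" else config$pap$after)
}

.config_models <- function(config, scenario, arm) {
  surv_set <- config$scenarios[[scenario]]$survival
  list(pfs = .config_parsurv(config$survival[[surv_set]][[arm]]$pfs),
       os  = .config_parsurv(config$survival[[surv_set]][[arm]]$os))
}
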