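#' Specify a simulated two-arm trial
#'
#' Defines the data-generating process used to exercise the fitting and
#' reconstruction stages without any external download: per arm and
#' endpoint a true parametric survival model, arm sizes matching the
#' underlying trial (358 intervention, 182 control), an administrative
#' cutoff and an independent uniform dropout fraction.
#'
#' @param truth Named list: `truth[[arm]][[endpoint]]` is a [parsurv];
#'   endpoints are `"PFS"` and `"OS"`. Default: the whole-population
#'   log-logistic parameters of the base case.
#' @param n Named integer vector of arm sizes.
#' @param cutoff Administrative censoring time in cycles. The default, 26
#'   cycles (~18 months), mirrors the follow-up span of the trial curves.
#' @param dropout Fraction of patients with a uniform dropout time on
#'   `(0, cutoff)`, in `[0, 1)`.
#' @param seed Integer seed making the draw reproducible.
#' @return A `trial_sim_spec` list.
#' @export
trial_sim_spec <- function(truth = NULL,
                           n = c(sugemalimab_chemo = 358L, chemo = 182L),
                           cutoff = 26, dropout = 0.1, seed = 1L) {
  if (is.null(truth)) {
    truth <- list(
      sugemalimab_chemo = list(
        PFS = parsurv("loglogistic", c(scale = 9.06, shape = 2.15)),
        OS  = parsurv("loglogistic", c(scale = 20.92, shape = 1.66))),
      chemo = list(
        PFS = parsurv("loglogistic", c(scale = 6.61, shape = 2.53)),
        OS  = parsurv("loglogistic", c(scale = 16.12, shape = 2.00))))
  }
  if (is.null(names(n)) || !setequal(names(n), names(truth)))
    stop("n must be named after the arms in truth")
  if (any(n < 1)) stop("arm sizes must be >= 1")
  if (cutoff <= 0) stop("cutoff must be > 0")
  if (dropout < 0 || dropout >= 1) stop("dropout must be in [0, 1)")
  structure(list(truth = truth, n = n, cutoff = cutoff,
                 dropout = dropout, seed = as.integer(seed)),
            class = "trial_sim_spec")
}

#' Simulate endpoint-level individual patient data
#'
#' Event times are drawn by inverse-CDF sampling from each true model;
#' observation is censored at the earlier of the administrative cutoff and
#' an independent uniform dropout time. PFS and OS cohorts are drawn
#' independently (only the marginal curves matter to a partitioned
#' survival model).
#'
#' @param spec A [trial_sim_spec].
#' @return IPD data frame: `time`, `event`, `arm`, `endpoint`, `subgroup`.
#' @export
simulate_ipd <- function(spec) {
  stopifnot(inherits(spec, "trial_sim_spec"))
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(spec$seed)
  out <- list()
  for (arm in names(spec$truth)) {
    for (ep in names(spec$truth[[arm]])) {
      n <- spec$n[[arm]]
      u <- stats::runif(n)
      tev <- surv_inverse(spec$truth[[arm]][[ep]], u)
      cens <- rep(spec$cutoff, n)
      drop_flag <- stats::runif(n) < spec$dropout
      tdrop <- stats::runif(n, 0, spec$cutoff)
      cens[drop_flag] <- pmin(cens[drop_flag], tdrop[drop_flag])
      time <- pmin(tev, cens)
      out[[paste(arm, ep)]] <- data.frame(
        time = pmax(time, 1e-9), event = as.integer(tev <= cens),
        arm = arm, endpoint = ep, subgroup = "whole",
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Write the simulated-trial CSV dialects
#'
#' Emits the IPD, the digitized KM coordinates, and the risk tables for
#' each arm/endpoint into a directory, in the plain-CSV formats consumed
#' by the fitting and reconstruction stages.
#'
#' @param spec A [trial_sim_spec].
#' @param dir Output directory (created if needed).
#' @param grid_n Number of digitization grid points per curve.
#' @param risk_times Times for the numbers-at-risk table (default every 3
#'   cycles to the cutoff).
#' @return Invisibly, the list of files written.
#' @export
write_sim_bundle <- function(spec, dir, grid_n = 200,
                             risk_times = seq(0, spec$cutoff, by = 3)) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ipd <- simulate_ipd(spec)
  files <- character(0)
  f <- file.path(dir, "ipd.csv")
  utils::write.csv(ipd, f, row.names = FALSE)
  files <- c(files, f)
  for (arm in unique(ipd$arm)) for (ep in unique(ipd$endpoint)) {
    sub <- ipd[ipd$arm == arm & ipd$endpoint == ep, ]
    km <- km_estimate(sub)
    dig <- digitize_km(km, seq(0, max(sub$time), length.out = grid_n))
    rt <- risk_table_at(sub, risk_times)
    f1 <- file.path(dir, sprintf("km_%s_%s.csv", arm, ep))
    f2 <- file.path(dir, sprintf("risk_%s_%s.csv", arm, ep))
    utils::write.csv(dig[, c("time", "surv")], f1, row.names = FALSE)
    utils::write.csv(rt, f2, row.names = FALSE)
    files <- c(files, f1, f2)
  }
  invisible(files)
}
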