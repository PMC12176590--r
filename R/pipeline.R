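#' Run the analysis pipeline and write its artifact bundle
#'
#' Executes the requested stages against one config and writes plot-ready
#' plain-text outputs to a results directory: the comparison table
#' (`table_base_case.csv`), tornado (`tornado_<scenario>.csv`), PSA
#' scatter (`psa_scatter_<scenario>.csv`), CEAC (`ceac_<scenario>.csv`),
#' price caps (`price_caps.json`) and, for the simulate/fit stages, the
#' simulated-trial bundle and a fit summary. Every CSV opens with a
#' comment line recording the config hash and seed, so reruns are
#' byte-comparable.
#'
#' @param config A `psmcea_config`.
#' @param out_dir Output directory (created if needed).
#' @param stages Subset of
#'   `c("cea", "owsa", "psa", "price_cap", "simulate", "fit")`.
#' @param scenario Scenario used by the owsa/psa stages.
#' @param seed Seed for the stochastic stages (default: the config's).
#' @param n_psa PSA draws.
#' @return Invisibly, a named list of written file paths.
#' @export
run_pipeline <- function(config, out_dir,
                         stages = c("cea", "owsa", "psa", "price_cap"),
                         scenario = "whole", seed = NULL, n_psa = 1000) {
  stopifnot(inherits(config, "psmcea_config"))
  stages <- match.arg(stages, c("cea", "owsa", "psa", "price_cap",
                                "simulate", "fit"), several.ok = TRUE)
  if (is.null(seed)) seed <- if (is.null(config$seed)) 1L else config$seed
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- .config_hash(config)
  stamp <- sprintf("# psmcea v%s config=%s seed=%d",
                   as.character(utils::packageVersion("psmcea")), hash,
                   as.integer(seed))
  files <- list()
  wcsv <- function(df, name) {
    path <- file.path(out_dir, name)
    con <- file(path, "w")
    writeLines(stamp, con)
    utils::write.csv(df, con, row.names = FALSE)
    close(con)
    path
  }
  if ("cea" %in% stages)
    files$base_case <- wcsv(run_all(config), "table_base_case.csv")
  if ("owsa" %in% stages)
    files$tornado <- wcsv(owsa(config, scenario),
                          sprintf("tornado_%s.csv", scenario))
  if ("psa" %in% stages) {
    psa <- run_psa(config, scenario, n = n_psa, seed = seed)
    files$psa_scatter <- wcsv(psa$draws, sprintf("psa_scatter_%s.csv", scenario))
    grid <- seq(0, 4 * config$econ$wtp, length.out = 81)
    files$ceac <- wcsv(ceac(psa, grid), sprintf("ceac_%s.csv", scenario))
  }
  if ("price_cap" %in% stages) {
    caps <- lapply(c(base = "whole", pap = "pap"), function(sc)
      price_threshold(config, sc))
    path <- file.path(out_dir, "price_caps.json")
    jsonlite::write_json(caps, path, auto_unbox = TRUE, digits = NA)
    files$price_caps <- path
  }
  if ("simulate" %in% stages || "fit" %in% stages) {
    spec <- trial_sim_spec(seed = seed)
    sim_dir <- file.path(out_dir, "sim")
    files$sim <- write_sim_bundle(spec, sim_dir)
    if ("fit" %in% stages) {
      ipd <- simulate_ipd(spec)
      rows <- list()
      for (arm in names(spec$truth)) for (ep in c("PFS", "OS")) {
        sub <- ipd[ipd$arm == arm & ipd$endpoint == ep, ]
        fits <- select_best(sub)
        rows[[paste(arm, ep)]] <- do.call(rbind, lapply(fits, function(f)
          data.frame(arm = arm, endpoint = ep, family = f$family,
                     param1 = f$model$params[[1]],
                     param2 = if (length(f$model$params) > 1)
                       f$model$params[[2]] else NA_real_,
                     aic = f$aic, bic = f$bic, stringsAsFactors = FALSE)))
      }
      files$fit_summary <- wcsv(do.call(rbind, rows), "fit_summary.csv")
    }
  }
  invisible(files)
}

.config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  dump_config(config, tmp)
  unname(tools::md5sum(tmp))
}

#' Read an IPD CSV in the package dialect
#'
#' Columns: `time` (cycles), `event` (0/1), and optionally `arm`,
#' `endpoint`, `subgroup`.
#'
#' @param path CSV file.
#' @return Validated IPD data frame.
#' @export
read_ipd <- function(path) {
  ipd <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  check_ipd(ipd)
}
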