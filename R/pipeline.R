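#' Read a flat run-configuration file
#'
#' Flat YAML key-value file mirroring the pipeline options (input paths,
#' MCMC settings, health-model settings, seed, output directory). Values
#' given in `overrides` (e.g. parsed command-line flags) take precedence.
#'
#' @param path YAML file path (optional).
#' @param overrides named list overriding file values.
#' @return named list of configuration values.
#' @export
read_run_config <- function(path = NULL, overrides = list()) {
  cfg <- if (!is.null(path)) yaml::read_yaml(path) else list()
  utils::modifyList(cfg, overrides[!vapply(overrides, is.null, TRUE)])
}

run_log <- function(outdir, stage, seed, config, elapsed) {
  tf <- tempfile()
  saveRDS(config, tf)
  hash <- unname(tools::md5sum(tf))
  unlink(tf)
  line <- sprintf(
    "[%s] stage=%s seed=%s config_md5=%s R=%s pkg=%s elapsed=%.2fs",
    format(Sys.time(), "%Y-%m-%d %H:%M:%S"), stage, seed, hash,
    getRversion(), as.character(utils::packageVersion("airhealth")), elapsed)
  message(line)
  if (!is.null(outdir))
    cat(line, "\n", file = file.path(outdir, "run.log"), append = TRUE)
  invisible(line)
}

#' Simulate a synthetic scenario to disk
#'
#' Thin wrapper over [make_scenario] writing the CSV inputs consumed by the
#' pipeline plus the generative `truth.json`.
#'
#' @param preset preset name.
#' @param seed integer seed.
#' @param outdir output directory.
#' @param overrides scenario overrides.
#' @return (invisibly) the scenario object.
#' @export
cmd_simulate <- function(preset, seed, outdir, overrides = list()) {
  t0 <- proc.time()[[3L]]
  sc <- make_scenario(preset, overrides, seed = seed, dir = outdir)
  run_log(outdir, "simulate", seed, sc$config, proc.time()[[3L]] - t0)
  invisible(sc)
}

#' Fit the stage-1 exposure model from CSV inputs
#'
#' Reads a long-format pollutant panel and monitor coordinates, runs the
#' Gibbs sampler, and writes `exposure.csv` (daily posterior concentration
#' summary) and `posterior.json` (parameter summaries) to `outdir`.
#'
#' @param pollution_csv long-format panel CSV (`date,site_id,value`).
#' @param monitors_csv monitor coordinates CSV.
#' @param outdir output directory.
#' @param config an [mcmc_config].
#' @param mode back-transformation mode for [summarize_exposure].
#' @return (invisibly) the `exposure_posterior`.
#' @export
cmd_fit_exposure <- function(pollution_csv, monitors_csv, outdir,
                             config = mcmc_config(),
                             mode = "mean-of-exp") {
  t0 <- proc.time()[[3L]]
  net <- read_monitors_csv(monitors_csv)
  panel <- read_pollution_csv(pollution_csv, site_ids = net$site_ids)
  post <- run_mcmc(panel, net, config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_exposure_csv(summarize_exposure(post, mode),
                     file.path(outdir, "exposure.csv"))
  write_posterior_json(post, file.path(outdir, "posterior.json"))
  run_log(outdir, "fit-exposure", config$seed, config,
          proc.time()[[3L]] - t0)
  invisible(post)
}

#' Fit the stage-2 health models from CSV inputs
#'
#' For each exposure series, fits single-pollutant quasi-Poisson models at
#' lags 0-6 (and per stratum when stratified admissions are present and
#' `strata = TRUE`), writing `results.csv` to `outdir`.
#'
#' @param admissions_csv admissions CSV (`date,count[,stratum]`).
#' @param exposure_csvs named character vector of exposure CSV paths (names
#'   are the pollutant labels).
#' @param meteorology_csv meteorology CSV.
#' @param outdir output directory.
#' @param lags integer lags to fit (default 0:6).
#' @param strata also fit sex/age strata if present.
#' @param spec a [health_model_spec].
#' @param city_label label for the results CSV.
#' @return (invisibly) the results data.frame.
#' @export
cmd_fit_health <- function(admissions_csv, exposure_csvs, meteorology_csv,
                           outdir, lags = 0:6, strata = FALSE,
                           spec = health_model_spec(),
                           city_label = "synthetic") {
  t0 <- proc.time()[[3L]]
  adm <- read_admissions_csv(admissions_csv)
  met <- read_meteorology_csv(meteorology_csv)
  if (is.null(names(exposure_csvs)))
    names(exposure_csvs) <- paste0("pollutant", seq_along(exposure_csvs))
  series <- if (strata) adm else adm["total"]
  res <- do.call(rbind, lapply(names(exposure_csvs), function(pol) {
    ex <- read_exposure_csv(exposure_csvs[[pol]])
    do.call(rbind, lapply(series, function(a)
      do.call(rbind, lapply(lags, function(l)
        fit_single_pollutant(a, ex, met, lag = l, spec = spec,
                             pollutant = pol)))))
  }))
  rownames(res) <- NULL
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_results_csv(res, file.path(outdir, "results.csv"), city_label)
  run_log(outdir, "fit-health", NA, spec, proc.time()[[3L]] - t0)
  invisible(res)
}

#' Assemble a markdown + JSON report from health results
#'
#' Groups results into single- and multipollutant sections in the layout of
#' the standard reporting tables (one block per pollutant, rows "single",
#' "+X", "+All"), with percent change and 95% CI formatted per cell.
#'
#' @param results a `health_effect_result` data.frame (or results CSV path).
#' @param outdir output directory for `report.md` and `report.json`.
#' @return (invisibly) the report list.
#' @export
cmd_report <- function(results, outdir) {
  if (is.character(results)) results <- utils::read.csv(results)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  md <- c("# Health-effect results", "")
  if (nrow(results) == 0L) {
    warning("empty results; writing empty report")
    md <- c(md, "(no results)")
  } else {
    fmt <- function(r) sprintf("%.3f (%.3f, %.3f)%s", r$pct, r$lo, r$hi,
                               ifelse(r$p < 0.05, " *", ""))
    for (pol in unique(results$pollutant)) {
      md <- c(md, paste0("## ", pol), "",
              "| adjustment | stratum | lag | % change (95% CI) |",
              "|---|---|---|---|")
      sub <- results[results$pollutant == pol, , drop = FALSE]
      sub <- sub[order(sub$adjustment != "single", sub$adjustment,
                       sub$stratum, sub$lag), , drop = FALSE]
      for (i in seq_len(nrow(sub)))
        md <- c(md, sprintf("| %s | %s | %d | %s |", sub$adjustment[i],
                            sub$stratum[i], sub$lag[i], fmt(sub[i, ])))
      md <- c(md, "")
    }
  }
  writeLines(md, file.path(outdir, "report.md"))
  jsonlite::write_json(results, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(list(markdown = md, results = results))
}

#' Run the full two-stage pipeline on one pollutant
#'
#' Convenience wrapper: simulate (optionally), fit the exposure model, then
#' the health models, then write the report.
#'
#' @param indir directory with `pollution.csv`, `monitors.csv`,
#'   `meteorology.csv`, `admissions.csv` (e.g. from [cmd_simulate]).
#' @param outdir output directory.
#' @param config an [mcmc_config].
#' @param lags lags for stage 2.
#' @param strata fit strata too.
#' @return (invisibly) the results data.frame.
#' @export
cmd_run_all <- function(indir, outdir, config = mcmc_config(),
                        lags = 0:6, strata = FALSE) {
  cmd_fit_exposure(file.path(indir, "pollution.csv"),
                   file.path(indir, "monitors.csv"), outdir, config)
  res <- cmd_fit_health(file.path(indir, "admissions.csv"),
                        c(pollutant = file.path(outdir, "exposure.csv")),
                        file.path(indir, "meteorology.csv"),
                        outdir, lags = lags, strata = strata)
  cmd_report(res, outdir)
  invisible(res)
}
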