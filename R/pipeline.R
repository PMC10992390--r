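#' Read and validate a pipeline configuration
#'
#' The pipeline stages share one YAML configuration with per-stage
#' sections (`simulate`, `fit`, `assess`, `power`). Unknown section or
#' key names raise a named validation error rather than being ignored.
#'
#' @param config a file path to a YAML file, or an equivalent named list.
#' @return The validated configuration list.
#' @export
read_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a list or YAML path",
                             call. = FALSE)
  known <- list(
    simulate = c("design", "parameters", "rho", "alpha",
                 "baseline_deviation"),
    fit = c("n_chains", "draws", "warmup", "adapt", "covariates", "model"),
    assess = c("baseline_year", "categories", "by_site"),
    power = c("rho", "alpha", "n_replicates", "parameters",
              "baseline_deviation", "include_beta1", "design"))
  bad <- setdiff(names(config), names(known))
  if (length(bad) > 0) {
    stop("unknown config section(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  for (sec in names(config)) {
    bad <- setdiff(names(config[[sec]]), known[[sec]])
    if (length(bad) > 0) {
      stop("unknown key(s) in config section '", sec, "': ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  config
}

config_design <- function(x) {
  if (is.null(x) || identical(x, "study")) return(study_design())
  excl <- if (!is.null(x$exclusions)) {
    do.call(rbind, lapply(x$exclusions, as.data.frame))
  }
  incl <- if (!is.null(x$inclusion)) {
    do.call(rbind, lapply(x$inclusion, as.data.frame))
  }
  sampling_design(x$sites, x$years,
                  stations_per_site = x$stations_per_site %||% 5L,
                  inclusion = incl, exclusions = excl)
}

config_params <- function(x) {
  if (is.null(x) || identical(x, "default")) {
    return(default_generative_parameters())
  }
  do.call(generative_parameters, x)
}

config_categories <- function(x) {
  if (is.null(x)) return(health_categories())
  health_categories(categories = x$names, lower = as.numeric(x$lower),
                    colours = x$colours %||%
                      grDevices::hcl.colors(length(x$names), "RdYlGn"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_manifest <- function(out_dir, command, config, seed, outputs,
                           extra = list()) {
  manifest <- c(list(
    command = command,
    package = "bruvshealth",
    version = as.character(utils::packageVersion("bruvshealth")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config = config,
    outputs = outputs), extra)
  path <- file.path(out_dir, "manifest.yaml")
  yaml::write_yaml(manifest, path)
  path
}

#' Pipeline stage: simulate a synthetic monitoring dataset
#'
#' Generates counts from the generative model over the configured design
#' and writes the dataset CSV, a parameter sidecar YAML, and a run
#' manifest. Identical seeds reproduce byte-identical data files.
#'
#' @param config configuration list or YAML path; uses the `simulate`
#'   section (design, parameters, optional `rho`/`alpha` to append a
#'   disturbed year).
#' @param out_dir output directory (created if needed).
#' @param seed integer seed.
#' @return Invisibly, the named vector of written file paths.
#' @export
cli_simulate <- function(config = list(), out_dir, seed = 1L) {
  config <- read_config(config)
  sc <- config$simulate
  design <- config_design(sc$design)
  params <- config_params(sc$parameters)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  sim <- if (!is.null(sc$rho)) {
    simulate_study(params, design, rho = sc$rho,
                   alpha = sc$alpha %||% design$stations_per_site,
                   baseline_deviation = sc$baseline_deviation %||% "neutral",
                   seed = seed)
  } else {
    simulate_counts(design, params, seed = seed)
  }
  data_path <- file.path(out_dir, "counts.csv")
  write_count_table(sim$table, data_path)
  par_path <- file.path(out_dir, "parameters.yaml")
  yaml::write_yaml(c(unclass(params), list(seed = seed)), par_path)
  outputs <- c(counts = data_path, parameters = par_path)
  manifest <- write_manifest(out_dir, "simulate", config, seed,
                             as.list(outputs))
  invisible(c(outputs, manifest = manifest))
}

#' Pipeline stage: fit the abundance model and assess health status
#'
#' Reads a count table, fits the hierarchical abundance model, and writes
#' the posterior draws (CSV: `chain`, `iteration`, one column per
#' parameter), a diagnostics table and text report, and per-year plus
#' per-site health-assessment tables with credibilities expressed as
#' percentages to one decimal place (pie-chart-ready). Sites lacking a
#' baseline-year level are reported with a `no baseline` note, not
#' dropped. Raises an error naming the baseline year if it is absent
#' from the data.
#'
#' @param data_path CSV path of the input [count_table()].
#' @param config configuration list or YAML path (`fit` and `assess`
#'   sections).
#' @param out_dir output directory.
#' @param seed integer seed for the sampler.
#' @return Invisibly, the named vector of written file paths (plus the
#'   fit, as attribute `fit`).
#' @export
cli_fit_assess <- function(data_path, config = list(), out_dir, seed = 1L) {
  config <- read_config(config)
  fc <- config$fit
  ac <- config$assess
  data <- read_count_table(data_path,
                           baseline_year = ac$baseline_year)
  if (!attr(data, "baseline_year") %in% data$year) {
    stop("baseline year ", attr(data, "baseline_year"),
         " is absent from the data", call. = FALSE)
  }
  cfg <- model_config(n_chains = fc$n_chains %||% 4L,
                      draws = fc$draws %||% 10000L,
                      warmup = fc$warmup %||% 500L,
                      adapt = fc$adapt %||% 500L,
                      covariates = fc$covariates, seed = seed)
  fit <- if (identical(fc$model, "change")) {
    fit_change_model(data, cfg)
  } else {
    fit_abundance_model(data, cfg)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  draws_path <- file.path(out_dir, "draws.csv")
  utils::write.csv(data.frame(chain = fit$chain, iteration = fit$iteration,
                              fit$draws, check.names = FALSE),
                   draws_path, row.names = FALSE)
  report <- diagnostics_report(fit)
  diag_path <- file.path(out_dir, "diagnostics.csv")
  utils::write.csv(report$parameters, diag_path, row.names = FALSE)
  diag_txt <- file.path(out_dir, "diagnostics.txt")
  writeLines(utils::capture.output(print(report)), diag_txt)

  spec <- config_categories(ac$categories)
  as_pct <- function(df) {
    for (cc in spec$category) df[[cc]] <- round(100 * df[[cc]], 1)
    df$probability_of_decline <- round(100 * df$probability_of_decline, 1)
    df
  }
  overall <- as_pct(assess_health(fit, spec = spec, by_site = FALSE))
  by_site <- as_pct(assess_health(fit, spec = spec, by_site = TRUE))
  overall_path <- file.path(out_dir, "assessment_overall.csv")
  site_path <- file.path(out_dir, "assessment_sites.csv")
  utils::write.csv(overall, overall_path, row.names = FALSE)
  utils::write.csv(by_site, site_path, row.names = FALSE)

  outputs <- c(draws = draws_path, diagnostics = diag_path,
               diagnostics_text = diag_txt,
               assessment_overall = overall_path,
               assessment_sites = site_path)
  manifest <- write_manifest(out_dir, "fit_assess", config, seed,
                             as.list(outputs),
                             extra = list(input = data_path))
  out <- c(outputs, manifest = manifest)
  attr(out, "fit") <- fit
  invisible(out)
}

#' Pipeline stage: run the monitoring-design power evaluation
#'
#' Runs [run_power_grid()] for the configured grid, checkpointing each
#' completed replicate to `replicates.csv` as it finishes. With
#' `resume = TRUE` (the default) an interrupted run picks up from the
#' completed replicates in that file; because replicate seeds derive
#' deterministically from `seed`, a resumed run equals a fresh full run.
#' Writes the per-cell summary to `cells.csv` and records the planned run
#' count in the manifest.
#'
#' @param config configuration list or YAML path (`power` section:
#'   `rho`, `alpha`, `n_replicates`, `parameters`, `baseline_deviation`,
#'   `include_beta1`, `design`).
#' @param out_dir output directory.
#' @param seed root seed for replicate derivation.
#' @param resume skip replicates already present in `replicates.csv`.
#' @param fit_config optional [model_config()] override for replicate
#'   fits (defaults to [power_fit_config()]).
#' @return Invisibly, the named vector of written file paths.
#' @export
cli_power <- function(config = list(), out_dir, seed = 1L, resume = TRUE,
                      fit_config = power_fit_config()) {
  config <- read_config(config)
  pc <- config$power
  if (is.null(pc)) stop("config has no 'power' section", call. = FALSE)
  grid_args <- list()
  if (!is.null(pc$rho)) grid_args$rho <- as.numeric(pc$rho)
  if (!is.null(pc$alpha)) grid_args$alpha <- as.integer(pc$alpha)
  if (!is.null(pc$n_replicates)) {
    grid_args$n_replicates <- as.integer(pc$n_replicates)
  }
  grid <- do.call(power_grid, grid_args)
  params <- config_params(pc$parameters)
  design <- config_design(pc$design)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  rep_path <- file.path(out_dir, "replicates.csv")
  done <- NULL
  if (resume && file.exists(rep_path)) {
    done <- utils::read.csv(rep_path)
    done <- done[!is.na(done$p_negative), ]
  }
  checkpoint <- function(row) {
    have <- file.exists(rep_path)
    utils::write.table(row, rep_path, sep = ",", row.names = FALSE,
                       col.names = !have, append = have)
  }
  results <- run_power_grid(
    grid, params, design = design, config = fit_config,
    baseline_deviation = pc$baseline_deviation %||% "neutral",
    include_beta1 = isTRUE(pc$include_beta1),
    root_seed = seed, callback = checkpoint, done = done)

  cells <- summarize_power(results)
  pct_cols <- c("power", grep("^cred_", names(cells), value = TRUE))
  report <- cells
  for (cc in pct_cols) report[[cc]] <- round(100 * report[[cc]], 1)
  cells_path <- file.path(out_dir, "cells.csv")
  utils::write.csv(report, cells_path, row.names = FALSE)

  outputs <- c(replicates = rep_path, cells = cells_path)
  manifest <- write_manifest(
    out_dir, "power", config, seed, as.list(outputs),
    extra = list(planned_runs = planned_runs(grid),
                 completed_runs = sum(!is.na(results$p_negative))))
  invisible(c(outputs, manifest = manifest))
}
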