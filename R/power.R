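#' Scenario grid for the monitoring-design power evaluation
#'
#' The design evaluation crosses multiplicative declines `rho` with
#' per-site sampling efforts `alpha` and repeats the four-step simulation
#' `n_replicates` times per cell. The default grid is the reference
#' evaluation: rho in {0.05, 0.25, 0.5, 0.7, 0.9, 1} by alpha in
#' {5, 10, 20} with 500 replicates, i.e. 500 x 18 = 9,000 simulated
#' datasets and model runs in total.
#'
#' @param rho decline multipliers in (0, 1].
#' @param alpha per-site sampling efforts (deployments per site).
#' @param n_replicates replicates per (rho, alpha) cell.
#' @return An object of class `power_grid`: one row per cell with a
#'   `n_replicates` attribute.
#' @export
power_grid <- function(rho = c(0.05, 0.25, 0.5, 0.7, 0.9, 1),
                       alpha = c(5L, 10L, 20L), n_replicates = 500L) {
  stopifnot(all(rho > 0), all(rho <= 1), all(alpha >= 1), n_replicates >= 1)
  g <- expand.grid(rho = rho, alpha = as.integer(alpha))
  structure(g, n_replicates = as.integer(n_replicates),
            class = c("power_grid", "data.frame"))
}

#' @rdname power_grid
#' @param grid a `power_grid`.
#' @return `planned_runs()` returns the total number of simulate-and-fit
#'   runs the grid enumerates (cells times replicates).
#' @export
planned_runs <- function(grid) {
  nrow(grid) * attr(grid, "n_replicates")
}

#' MCMC settings for power-simulation replicate fits
#'
#' Replicate-level change-model fits use shortened chains (2 chains,
#' 1,600 post-warmup draws in total after 500 burn-in per chain) so that
#' grids remain tractable on a single CPU. Shorter chains measurably
#' dilute detection probabilities towards 0.5 through incomplete mixing
#' of the disturbance coefficient; these lengths keep that bias inside
#' the replicate Monte-Carlo noise. The full-length [model_config()] can
#' be supplied instead for reference-scale runs.
#'
#' @param ... overrides passed to [model_config()].
#' @return A [model_config()].
#' @export
power_fit_config <- function(...) {
  args <- utils::modifyList(list(n_chains = 2L, draws = 1600L,
                                 warmup = 500L, adapt = 300L), list(...))
  do.call(model_config, args)
}

#' Run one power-simulation replicate (the four simulation steps)
#'
#' Executes one full cycle of the design evaluation: (1) simulate
#' background (non-disturbed) data over `design`; (2) simulate a
#' disturbed new year at decline `rho` and effort `alpha`, reusing the
#' site deviations and original stations; (3) concatenate into one
#' before/after table; (4) fit the change model and read off the
#' probability of the disturbance coefficient being negative,
#' `P(beta1 < 0 | D)` (the fraction of `beta1` draws below zero), and the
#' posterior of the realized decline
#' `rho_hat = exp(beta0 + D_Y=new) / exp(beta0 + D_Y=baseline)` classified
#' against the health categories.
#'
#' @param params a [generative_parameters()].
#' @param rho,alpha decline multiplier and per-site effort.
#' @param design background [sampling_design()].
#' @param config a [model_config()] for the replicate fit.
#' @param spec a [health_categories()] specification.
#' @param baseline_deviation passed to [simulate_study()]: `"neutral"`,
#'   `"random"`, or a numeric value for the baseline year's deviation.
#' @param include_beta1 include `beta1` in the `rho_hat` numerator
#'   (default `FALSE`: the ratio is read from the year deviations alone).
#' @param seed integer seed for this replicate.
#' @return A one-row data frame: `p_negative` (P(beta1 < 0)), one
#'   credibility column per category, `rhat_beta1` and the seed.
#' @export
run_replicate <- function(params, rho, alpha, design = study_design(),
                          config = power_fit_config(),
                          spec = health_categories(),
                          baseline_deviation = "neutral",
                          include_beta1 = FALSE, seed = NULL) {
  sim <- simulate_study(params, design, rho = rho, alpha = alpha,
                        baseline_deviation = baseline_deviation,
                        seed = seed)
  cfg <- config
  cfg$seed <- if (is.null(seed)) NULL else derive_seed(seed, 1L)
  fit <- fit_change_model(sim$table, cfg)
  b1 <- posterior(fit, "beta1")
  fc <- fold_change_draws(fit, year = sim$new_year,
                          baseline_year = sim$baseline_year,
                          include_beta1 = include_beta1)
  cred <- classify_health(fc, spec)$credibility
  out <- data.frame(rho = rho, alpha = alpha,
                    p_negative = mean(b1 < 0),
                    rhat_beta1 = split_rhat(chain_matrix(fit, "beta1")),
                    seed = if (is.null(seed)) NA_integer_ else seed)
  out[paste0("cred_", names(cred))] <- as.list(unname(cred))
  out
}

# internal: generative parameters + baseline deviation from one posterior draw
params_from_draw <- function(fit, i) {
  d <- fit$draws[i, ]
  p <- generative_parameters(
    beta0 = d[["beta0"]],
    sigma_station = d[["sigma_station"]],
    sigma_site = d[["sigma_site"]],
    sigma_year = d[["sigma_year"]],
    sigma_site_year = d[["sigma_site_year"]],
    phi = d[["phi"]])
  base_col <- paste0("d_year[", attr(fit$data, "baseline_year"), "]")
  attr(p, "baseline_deviation") <- if (base_col %in% names(d)) d[[base_col]]
  p
}

#' Run the power-simulation grid
#'
#' Repeats [run_replicate()] `n_replicates` times for every (rho, alpha)
#' cell. The generative parameters are either fixed values (one
#' [generative_parameters()] used throughout) or a posterior parameter
#' source (a `posterior_draws` fit, from which each replicate takes a
#' different draw, including that draw's baseline-year deviation).
#' Replicate seeds are derived deterministically from `root_seed`, so a
#' grid can be re-run or resumed reproducibly; fits whose `beta1` split
#' R-hat exceeds 1.05 are flagged, not discarded. Failed replicate fits
#' are recorded with `NA` results rather than aborting the grid.
#'
#' @param grid a [power_grid()].
#' @param params a [generative_parameters()] or a `posterior_draws`
#'   object to draw generative values from.
#' @param design,config,spec,baseline_deviation,include_beta1 see
#'   [run_replicate()]. When `params` is a posterior source,
#'   `baseline_deviation` is taken from each draw instead.
#' @param root_seed integer seed from which all replicate seeds derive.
#' @param progress print one line per completed cell.
#' @param callback optional function called as `callback(row)` after each
#'   replicate (used by the pipeline layer to checkpoint long runs).
#' @param done optional data frame of already-completed replicates (with
#'   columns `rho`, `alpha`, `seed`) to skip, enabling resumption.
#' @return An object of class `power_result`: one row per replicate.
#' @export
run_power_grid <- function(grid, params, design = study_design(),
                           config = power_fit_config(),
                           spec = health_categories(),
                           baseline_deviation = "neutral",
                           include_beta1 = FALSE,
                           root_seed = 1L, progress = FALSE,
                           callback = NULL, done = NULL) {
  stopifnot(inherits(grid, "power_grid"), nrow(grid) >= 1)
  n_rep <- attr(grid, "n_replicates")
  posterior_source <- inherits(params, "posterior_draws")
  if (posterior_source && nrow(params$draws) < nrow(grid) * n_rep) {
    stop("posterior parameter source has ", nrow(params$draws),
         " draws but the grid needs ", nrow(grid) * n_rep, call. = FALSE)
  }
  done_key <- if (!is.null(done) && nrow(done) > 0) {
    paste(done$rho, done$alpha, done$seed)
  } else character(0)

  rows <- vector("list", nrow(grid) * n_rep)
  k <- 0L
  for (cell in seq_len(nrow(grid))) {
    for (r in seq_len(n_rep)) {
      k <- k + 1L
      seed <- derive_seed(root_seed, (cell - 1L) * n_rep + r)
      if (paste(grid$rho[cell], grid$alpha[cell], seed) %in% done_key) next
      if (posterior_source) {
        idx <- (cell - 1L) * n_rep + r
        p <- params_from_draw(params, idx)
        bdev <- attr(p, "baseline_deviation")
        if (is.null(bdev)) bdev <- baseline_deviation
      } else {
        p <- params
        bdev <- baseline_deviation
      }
      row <- tryCatch(
        run_replicate(p, grid$rho[cell], grid$alpha[cell], design, config,
                      spec, baseline_deviation = bdev,
                      include_beta1 = include_beta1, seed = seed),
        error = function(e) {
          warning("replicate (rho=", grid$rho[cell], ", alpha=",
                  grid$alpha[cell], ", seed=", seed, ") failed: ",
                  conditionMessage(e), call. = FALSE)
          data.frame(rho = grid$rho[cell], alpha = grid$alpha[cell],
                     p_negative = NA_real_, rhat_beta1 = NA_real_,
                     seed = seed)
        })
      row$replicate <- r
      rows[[k]] <- row
      if (!is.null(callback)) callback(row)
    }
    if (progress) {
      message(sprintf("cell %d/%d (rho=%g, alpha=%d) done",
                      cell, nrow(grid), grid$rho[cell], grid$alpha[cell]))
    }
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  out <- if (length(rows) > 0) {
    template <- rows[[which.max(vapply(rows, ncol, integer(1)))]]
    do.call(rbind, lapply(rows, function(r) {
      # align columns across successful and failed replicates
      r[setdiff(names(template), names(r))] <- NA_real_
      r[names(template)]
    }))
  }
  if (!is.null(done) && nrow(done) > 0) {
    if (is.null(out)) {
      out <- done
    } else {
      done[setdiff(names(out), names(done))] <- NA_real_
      out <- rbind(done[names(out)], out)
    }
  }
  if (is.null(out)) stop("no replicates were run", call. = FALSE)
  structure(out[order(out$alpha, out$rho, out$replicate), ],
            parameter_source = if (posterior_source) "posterior" else "fixed",
            root_seed = root_seed,
            class = c("power_result", "data.frame"))
}

#' Summarize a power grid: detection power and expected credibilities
#'
#' Per (rho, alpha) cell: the mean probability of a negative disturbance
#' coefficient across replicates (the statistical power to detect a
#' decline), its Monte-Carlo standard error, and the mean per-category
#' credibilities of the realized-decline posterior. Plain arithmetic
#' means only; no smoothing.
#'
#' @param results a `power_result` from [run_power_grid()].
#' @return A data frame with one row per cell: `power`, `mc_se`, mean
#'   `cred_*` columns, replicate counts and the number of fits flagged
#'   for `beta1` split R-hat > 1.05.
#' @export
summarize_power <- function(results) {
  stopifnot(inherits(results, "power_result") || is.data.frame(results))
  if (nrow(results) == 0) stop("no replicates to summarize", call. = FALSE)
  cred_cols <- grep("^cred_", names(results), value = TRUE)
  cells <- split(results, list(results$rho, results$alpha), drop = TRUE)
  out <- do.call(rbind, lapply(cells, function(d) {
    ok <- !is.na(d$p_negative)
    row <- data.frame(rho = d$rho[1], alpha = d$alpha[1],
                      n_replicates = sum(ok),
                      n_failed = sum(!ok),
                      n_flagged = sum(d$rhat_beta1[ok] > 1.05, na.rm = TRUE),
                      power = mean(d$p_negative[ok]),
                      mc_se = stats::sd(d$p_negative[ok]) /
                        sqrt(max(sum(ok), 1)))
    for (cc in cred_cols) row[[cc]] <- mean(d[[cc]][ok])
    row
  }))
  out <- out[order(out$alpha, out$rho), ]
  rownames(out) <- NULL
  out
}
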