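#' Parameters of the generative abundance model
#'
#' The abundance model assumes deployment-level counts A arise from a
#' negative binomial, A ~ NB(mu, phi) with Var = mu + mu^2/phi, where
#' ln(mu) = beta0 + D_B + D_S + D_Y + D_S:Y (+ beta1 X for a disturbance
#' term): a global log-mean abundance beta0 plus independent centred
#' Gaussian deviations for station (D_B), site (D_S), year (D_Y) and
#' site-by-year (D_S:Y), each with its own standard deviation.
#'
#' @param beta0 global mean log abundance.
#' @param sigma_station,sigma_site,sigma_year,sigma_site_year standard
#'   deviations of the station, site, year and site-by-year deviations;
#'   all must be >= 0 (zero collapses that term to exactly 0, handy for
#'   controlled simulations).
#' @param phi negative-binomial shape (over-dispersion) parameter, > 0;
#'   large phi approaches the Poisson.
#' @param beta1 optional disturbance effect on the log scale (default 0).
#' @return An object of class `generative_parameters`.
#' @seealso [default_generative_parameters()]
#' @export
generative_parameters <- function(beta0, sigma_station, sigma_site,
                                  sigma_year, sigma_site_year, phi,
                                  beta1 = 0) {
  stopifnot(is.finite(beta0),
            sigma_station >= 0, sigma_site >= 0,
            sigma_year >= 0, sigma_site_year >= 0,
            phi > 0, is.finite(beta1))
  structure(list(beta0 = beta0, sigma_station = sigma_station,
                 sigma_site = sigma_site, sigma_year = sigma_year,
                 sigma_site_year = sigma_site_year, phi = phi,
                 beta1 = beta1),
            class = "generative_parameters")
}

#' @export
print.generative_parameters <- function(x, ...) {
  cat("generative_parameters:\n")
  cat(sprintf("  beta0 = %.4f (mean abundance e^beta0 = %.2f)\n",
              x$beta0, exp(x$beta0)))
  cat(sprintf("  sigma: station %.3f, site %.3f, year %.3f, site:year %.3f\n",
              x$sigma_station, x$sigma_site, x$sigma_year,
              x$sigma_site_year))
  cat(sprintf("  phi = %.3f, beta1 = %.3f\n", x$phi, x$beta1))
  invisible(x)
}

#' Default generative parameters for a coral-reef BRUVS indicator
#'
#' Point values representing a realistic tropical coral-reef indicator
#' assemblage as estimated for the motivating monitoring program: a mean
#' combined MaxN of 13.5 fish per deployment, moderate over-dispersion
#' (phi = 1.82), station-level variability sigma = 0.22, and larger site
#' (0.62), year (0.38) and site-by-year (0.48) variability. These are the
#' study conditions for every simulation-based check in the package.
#'
#' @return A [generative_parameters()] object.
#' @export
default_generative_parameters <- function() {
  generative_parameters(beta0 = log(13.5),
                        sigma_station = 0.22,
                        sigma_site = 0.62,
                        sigma_year = 0.38,
                        sigma_site_year = 0.48,
                        phi = 1.82)
}

#' Draw the hierarchical deviations for a sampling design
#'
#' Each grouping level receives an independent centred Gaussian deviation
#' with its stated standard deviation (realised as a standardised draw
#' times sigma): one per station within site, per site, per year, and per
#' included (site, year) cell.
#'
#' @param design a [sampling_design()].
#' @param params a [generative_parameters()].
#' @param seed optional integer seed; `NULL` continues the current RNG
#'   stream.
#' @return An object of class `deviation_set`: a list with elements
#'   `site` and `year` (named numeric vectors) and `site_year` and
#'   `station` (data frames with a `deviation` column).
#' @export
draw_deviations <- function(design, params, seed = NULL) {
  stopifnot(inherits(design, "sampling_design"),
            inherits(params, "generative_parameters"))
  if (!is.null(seed)) set.seed(seed)
  sites <- design$sites
  years <- design$years
  stations <- paste0("st", seq_len(design$stations_per_site))

  site <- stats::setNames(stats::rnorm(length(sites), 0, params$sigma_site),
                          sites)
  year <- stats::setNames(stats::rnorm(length(years), 0, params$sigma_year),
                          as.character(years))
  sy <- unique(design$inclusion[, c("site_id", "year")])
  sy$deviation <- stats::rnorm(nrow(sy), 0, params$sigma_site_year)
  st <- expand.grid(site_id = sites, station_id = stations,
                    stringsAsFactors = FALSE)
  st$deviation <- stats::rnorm(nrow(st), 0, params$sigma_station)
  structure(list(site = site, year = year, site_year = sy, station = st),
            class = "deviation_set")
}

# internal: per-record log-means for a design given parameters + deviations
record_log_means <- function(records, params, deviations) {
  sy_key <- pair_key(deviations$site_year$site_id, deviations$site_year$year)
  st_key <- pair_key(deviations$station$site_id, deviations$station$station_id)
  i_sy <- match(pair_key(records$site_id, records$year), sy_key)
  i_st <- match(pair_key(records$site_id, records$station_id), st_key)
  i_s <- match(records$site_id, names(deviations$site))
  i_y <- match(as.character(records$year), names(deviations$year))
  if (anyNA(c(i_sy, i_st, i_s, i_y))) {
    stop("deviation set does not cover every (site, year, station) in the design",
         call. = FALSE)
  }
  params$beta0 + params$beta1 * records$disturbance_flag +
    deviations$site[i_s] + deviations$year[i_y] +
    deviations$site_year$deviation[i_sy] +
    deviations$station$deviation[i_st]
}

nb_draw <- function(n, mu, phi) {
  stats::rnbinom(n, size = phi, mu = mu)
}

#' Simulate counts from the generative abundance model
#'
#' Expands the design, computes each record's mean abundance
#' mu = exp(beta0 + deviations), and draws independent negative-binomial
#' counts with shape `phi` (variance mu + mu^2/phi).
#'
#' @inheritParams draw_deviations
#' @param deviations a `deviation_set` covering the design; drawn
#'   internally (from the same stream) when `NULL`.
#' @param seed optional integer seed.
#' @return An object of class `simulated_dataset`: a list with the
#'   [count_table()] (`table`), the per-record expected count (`mean`),
#'   the `deviations` used, the generating `params` and the `seed`.
#' @export
simulate_counts <- function(design, params, deviations = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(deviations)) deviations <- draw_deviations(design, params)
  tab <- expand_design(design)
  lmu <- record_log_means(tab, params, deviations)
  if (any(lmu > 30)) {
    stop("simulated log-mean exceeds 30; counts would overflow", call. = FALSE)
  }
  mu <- exp(unname(lmu))
  tab$count <- nb_draw(nrow(tab), mu, params$phi)
  structure(list(table = tab, mean = mu, deviations = deviations,
                 params = params, seed = seed),
            class = "simulated_dataset")
}

#' @export
print.simulated_dataset <- function(x, ...) {
  cat(sprintf("simulated_dataset: %d record(s), mean count %.2f (seed %s)\n",
              nrow(x$table), mean(x$table$count),
              if (is.null(x$seed)) "unset" else x$seed))
  invisible(x)
}

#' Simulate a disturbed new monitoring year
#'
#' Generates deployment counts for a hypothetical new year in which the
#' population mean is anchored to the baseline-year level scaled by a
#' multiplicative decline `rho`:
#' `ln(mu*) = ln(exp(beta0 + D_Y=baseline) * rho) + D_S + D*_Y + D*_S:Y + D*_B`.
#' The site deviations `D_S` are reused, the original stations keep their
#' supplied station deviations (stations are spatially fixed), and only
#' the additional stations needed to reach `alpha` deployments per site
#' receive fresh station draws; the year and site-by-year deviations of
#' the new year are always drawn fresh.
#'
#' @param params a [generative_parameters()].
#' @param baseline_year_deviation scalar year deviation of the baseline
#'   year (D_Y=baseline) used in the anchoring term.
#' @param site_deviations named numeric vector of reused site deviations.
#' @param station_deviations data frame with columns `site_id`,
#'   `station_id`, `deviation`: the original stations' reused deviations.
#' @param rho multiplicative decline in (0, 1]; `rho = 0.7` is a 30%
#'   decline, `rho = 1` no change.
#' @param alpha number of deployments per site in the new year; must be at
#'   least the number of supplied original stations per site.
#' @param new_year integer year label for the simulated records.
#' @param seed optional integer seed.
#' @return A `simulated_dataset` whose records all carry
#'   `disturbance_flag = 1`.
#' @export
simulate_disturbed_year <- function(params, baseline_year_deviation,
                                    site_deviations, station_deviations,
                                    rho, alpha, new_year = 2023L,
                                    seed = NULL) {
  stopifnot(inherits(params, "generative_parameters"),
            rho > 0, rho <= 1, alpha >= 1)
  if (!is.null(seed)) set.seed(seed)
  sites <- names(site_deviations)
  per_site <- split(station_deviations, station_deviations$site_id)
  n_orig <- vapply(per_site, nrow, integer(1))
  if (any(alpha < n_orig[sites])) {
    stop("alpha (", alpha, ") is smaller than the number of supplied ",
         "station deviations per site", call. = FALSE)
  }

  d_year_new <- stats::rnorm(1, 0, params$sigma_year)
  d_sy_new <- stats::setNames(
    stats::rnorm(length(sites), 0, params$sigma_site_year), sites)

  rec <- list()
  for (s in sites) {
    orig <- per_site[[s]]
    n_fresh <- alpha - nrow(orig)
    fresh <- if (n_fresh > 0) {
      data.frame(site_id = s,
                 station_id = paste0("new", seq_len(n_fresh)),
                 deviation = stats::rnorm(n_fresh, 0, params$sigma_station))
    }
    rec[[s]] <- rbind(orig[, c("site_id", "station_id", "deviation")], fresh)
  }
  rec <- do.call(rbind, rec)

  anchor <- log(exp(params$beta0 + baseline_year_deviation) * rho)
  lmu <- anchor + site_deviations[rec$site_id] + d_year_new +
    d_sy_new[rec$site_id] + rec$deviation
  if (any(lmu > 30)) {
    stop("simulated log-mean exceeds 30; counts would overflow", call. = FALSE)
  }
  mu <- exp(unname(lmu))
  tab <- count_table(data.frame(site_id = rec$site_id,
                                year = as.integer(new_year),
                                station_id = rec$station_id,
                                count = nb_draw(length(mu), mu, params$phi),
                                disturbance_flag = 1L),
                     baseline_year = as.integer(new_year))
  deviations <- list(
    site = site_deviations,
    year = stats::setNames(d_year_new, as.character(new_year)),
    site_year = data.frame(site_id = sites, year = as.integer(new_year),
                           deviation = unname(d_sy_new)),
    station = rec)
  class(deviations) <- "deviation_set"
  structure(list(table = tab, mean = mu, deviations = deviations,
                 params = params, seed = seed, rho = rho, alpha = alpha),
            class = "simulated_dataset")
}

#' Simulate a full monitoring study: background years plus a disturbed year
#'
#' Runs the background generative process over `design` (all records with
#' `disturbance_flag = 0`), then appends a disturbed new year at decline
#' `rho` and sampling effort `alpha` per [simulate_disturbed_year()],
#' reusing the background site deviations and the original stations'
#' deviations. The concatenated table partitions into the "before"
#' (background) and "after" (new year) blocks by `disturbance_flag`.
#'
#' @inheritParams simulate_disturbed_year
#' @param design a [sampling_design()] with at least two years; its
#'   earliest year acts as the baseline.
#' @param baseline_deviation how the baseline year's deviation enters the
#'   new-year anchor: `"neutral"` forces D_Y=baseline to exactly 0 (the
#'   new year is anchored to an average year), `"random"` keeps the value
#'   drawn for the background simulation, or a numeric scalar fixes it
#'   explicitly.
#' @param seed optional integer seed for the whole study simulation.
#' @return A `simulated_dataset`; its `table` holds background plus
#'   new-year records and its `deviations` the union of both draws.
#' @export
simulate_study <- function(params, design = study_design(), rho, alpha,
                           baseline_deviation = c("neutral", "random"),
                           new_year = NULL, seed = NULL) {
  stopifnot(length(design$years) >= 2)
  if (!is.null(seed)) set.seed(seed)
  baseline <- min(design$years)
  if (is.null(new_year)) new_year <- max(design$years) + 1L

  dev <- draw_deviations(design, params)
  if (is.numeric(baseline_deviation)) {
    dev$year[as.character(baseline)] <- baseline_deviation
  } else {
    baseline_deviation <- match.arg(baseline_deviation)
    if (baseline_deviation == "neutral") {
      dev$year[as.character(baseline)] <- 0
    }
  }
  background <- simulate_counts(design, params, deviations = dev)

  orig_stations <- dev$station
  disturbed <- simulate_disturbed_year(
    params,
    baseline_year_deviation = dev$year[[as.character(baseline)]],
    site_deviations = dev$site,
    station_deviations = orig_stations,
    rho = rho, alpha = alpha, new_year = new_year)

  tab <- count_table(rbind(as.data.frame(background$table),
                           as.data.frame(disturbed$table)),
                     baseline_year = baseline)
  merged <- list(
    site = dev$site,
    year = c(dev$year, disturbed$deviations$year),
    site_year = rbind(dev$site_year, disturbed$deviations$site_year),
    station = unique(rbind(dev$station, disturbed$deviations$station)))
  class(merged) <- "deviation_set"
  structure(list(table = tab, mean = c(background$mean, disturbed$mean),
                 deviations = merged, params = params, seed = seed,
                 rho = rho, alpha = alpha, baseline_year = baseline,
                 new_year = as.integer(new_year)),
            class = "simulated_dataset")
}
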