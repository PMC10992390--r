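#' Baseline-relative fold-change posterior
#'
#' The fold change of a year's modelled mean abundance relative to the
#' baseline year, per posterior draw:
#' `exp(beta0 + D_Y=year) / exp(beta0 + D_Y=baseline)`, in which `beta0`
#' cancels, leaving `exp(D_Y=year - D_Y=baseline)`. The site-specific
#' variant additionally includes both years' site-by-year deviations
#' (`D_S` cancels the same way). A fold change of 1 means no change; the
#' distribution of these ratios is what the traffic-light categories are
#' read from.
#'
#' @param fit a `posterior_draws` object.
#' @param year the year to assess.
#' @param baseline_year the reference year; defaults to the fitted data's
#'   baseline.
#' @param site optional site label for a site-specific fold change. A
#'   site never sampled in the baseline year has no site-level baseline to
#'   compare against and raises a "no baseline" error.
#' @param include_beta1 for change-model fits, also add the disturbance
#'   effect `beta1` to the numerator when `year` is the disturbed year
#'   (default `FALSE`: the ratio is read from the year deviations alone).
#' @return An object of class `fold_change`: positive per-draw ratios plus
#'   the target labels.
#' @export
fold_change_draws <- function(fit, year, baseline_year = NULL, site = NULL,
                              include_beta1 = FALSE) {
  stopifnot(inherits(fit, "posterior_draws"))
  if (is.null(baseline_year)) baseline_year <- attr(fit$data, "baseline_year")
  if (is.null(baseline_year)) {
    stop("no baseline year available", call. = FALSE)
  }
  year_col <- function(y) {
    cn <- paste0("d_year[", y, "]")
    if (!cn %in% colnames(fit$draws)) {
      stop("year ", y, " is not a level of the fitted model", call. = FALSE)
    }
    fit$draws[, cn]
  }
  log_ratio <- year_col(year) - year_col(baseline_year)
  if (!is.null(site)) {
    sy_col <- function(y) {
      cn <- paste0("d_site_year[", site, ",", y, "]")
      if (!cn %in% colnames(fit$draws)) {
        stop("site ", site, " has no ", y,
             " level: cannot back-calculate changes relative to the ",
             "baseline year (no baseline)", call. = FALSE)
      }
      fit$draws[, cn]
    }
    log_ratio <- log_ratio + sy_col(year) - sy_col(baseline_year)
  }
  if (include_beta1 && "beta1" %in% colnames(fit$draws)) {
    log_ratio <- log_ratio + fit$draws[, "beta1"]
  }
  structure(list(draws = unname(exp(log_ratio)),
                 year = year, baseline_year = baseline_year, site = site),
            class = "fold_change")
}

#' @export
print.fold_change <- function(x, ...) {
  h <- hdi(x$draws)
  cat(sprintf("fold_change %s vs %s%s: median %.3f (95%% HDI %.3f-%.3f), P(decline) = %.3f\n",
              x$year, x$baseline_year,
              if (is.null(x$site)) "" else paste0(" at ", x$site),
              stats::median(x$draws), h[["lower"]], h[["upper"]],
              prob_decline(x)))
  invisible(x)
}

#' Classify a fold-change posterior into health-status credibilities
#'
#' Each category's credibility is the share of posterior draws falling in
#' its fold-change band (the relative area under the posterior curve over
#' that band). Credibilities sum to one; the modal category is the one
#' with maximal credibility.
#'
#' @param fold a [fold_change_draws()] object (or bare positive numeric
#'   vector of draws).
#' @param spec a [health_categories()] specification.
#' @return An object of class `health_assessment`: per-category
#'   credibilities, the probability of decline (share of draws below 1),
#'   and the modal category.
#' @export
classify_health <- function(fold, spec = health_categories()) {
  draws <- if (inherits(fold, "fold_change")) fold$draws else fold
  if (length(draws) == 0) stop("empty draw vector", call. = FALSE)
  stopifnot(all(draws > 0))
  idx <- findInterval(draws, spec$lower)
  cred <- tabulate(idx, nbins = nrow(spec)) / length(draws)
  names(cred) <- spec$category
  structure(list(
    target = if (inherits(fold, "fold_change")) {
      list(year = fold$year, baseline_year = fold$baseline_year,
           site = fold$site)
    },
    credibility = cred,
    probability_of_decline = mean(draws < 1),
    modal_category = spec$category[which.max(cred)],
    n_draws = length(draws), spec = spec),
    class = "health_assessment")
}

#' @export
print.health_assessment <- function(x, ...) {
  tgt <- if (!is.null(x$target)) {
    paste0(x$target$year, " vs ", x$target$baseline_year,
           if (!is.null(x$target$site)) paste0(" at ", x$target$site))
  } else "draws"
  cat(sprintf("health_assessment (%s): modal category %s\n",
              tgt, x$modal_category))
  cat(paste(sprintf("  %-10s %5.1f%%", names(x$credibility),
                    100 * x$credibility), collapse = "\n"), "\n")
  cat(sprintf("  P(decline) = %.1f%%  [%d draws]\n",
              100 * x$probability_of_decline, x$n_draws))
  invisible(x)
}

#' Probability of decline
#'
#' The share of fold-change draws strictly below 1.
#'
#' @param fold a [fold_change_draws()] object or numeric draw vector.
#' @return A fraction in [0, 1].
#' @export
prob_decline <- function(fold) {
  draws <- if (inherits(fold, "fold_change")) fold$draws else fold
  if (length(draws) == 0) stop("empty draw vector", call. = FALSE)
  mean(draws < 1)
}

#' Fold variation implied by a deviation standard deviation
#'
#' A deviation standard deviation sigma on the log scale implies a typical
#' `exp(2 * sigma)`-fold spread in mean abundance across that grouping's
#' levels (roughly +/- one standard deviation end to end).
#' `fold_variation()` applies the transform per draw and then summarizes
#' (mean and HDI of the transformed draws); because `exp` is convex the
#' per-draw mean exceeds the point transform of the posterior mean for
#' skewed sigma posteriors (Jensen's inequality), so the two can differ
#' noticeably. `fold_variation_point()` is the plain point transform used
#' when quoting a single sigma value.
#'
#' @param sigma_draws positive numeric vector of posterior sigma draws.
#' @param mass HDI probability mass.
#' @return `fold_variation()` returns a list with the transformed draws
#'   and their `mean` and `hdi`; `fold_variation_point()` returns
#'   `exp(2 * sigma)` elementwise.
#' @export
fold_variation <- function(sigma_draws, mass = 0.95) {
  stopifnot(all(sigma_draws >= 0))
  tr <- exp(2 * sigma_draws)
  structure(list(draws = tr, mean = mean(tr), hdi = hdi(tr, mass)),
            class = "fold_variation")
}

#' @rdname fold_variation
#' @param sigma non-negative value(s) of a deviation standard deviation.
#' @export
fold_variation_point <- function(sigma) {
  stopifnot(all(sigma >= 0))
  exp(2 * sigma)
}

#' @export
print.fold_variation <- function(x, ...) {
  cat(sprintf("fold_variation: mean %.2f-fold (HDI %.2f-%.2f)\n",
              x$mean, x$hdi[["lower"]], x$hdi[["upper"]]))
  invisible(x)
}

#' Tabulate health assessments across years (and sites)
#'
#' Convenience wrapper looping [fold_change_draws()] and
#' [classify_health()] over assessment targets. Site-years without a
#' baseline level are kept in the table with a `no baseline` note rather
#' than silently dropped.
#'
#' @param fit a `posterior_draws` object.
#' @param years years to assess; defaults to all non-baseline years in the
#'   fit.
#' @param baseline_year reference year; defaults to the data's baseline.
#' @param spec a [health_categories()] specification.
#' @param by_site assess each site separately (adding the site-by-year
#'   deviations) instead of the overall reporting level.
#' @return A data frame with one row per target: credibilities (as
#'   fractions), probability of decline, modal category and a `note`
#'   column.
#' @export
assess_health <- function(fit, years = NULL, baseline_year = NULL,
                          spec = health_categories(), by_site = FALSE) {
  stopifnot(inherits(fit, "posterior_draws"))
  if (is.null(baseline_year)) baseline_year <- attr(fit$data, "baseline_year")
  if (is.null(years)) years <- setdiff(fit$levels$year, baseline_year)
  sites <- if (by_site) fit$levels$site else NA_character_
  grid <- expand.grid(year = years, site = sites, stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    site <- if (is.na(grid$site[i])) NULL else grid$site[i]
    base <- data.frame(year = grid$year[i],
                       site = if (is.null(site)) NA_character_ else site,
                       stringsAsFactors = FALSE)
    res <- tryCatch({
      fc <- fold_change_draws(fit, grid$year[i], baseline_year, site)
      a <- classify_health(fc, spec)
      cbind(base, as.data.frame(as.list(a$credibility)),
            data.frame(probability_of_decline = a$probability_of_decline,
                       modal_category = a$modal_category,
                       note = ""))
    }, error = function(e) {
      cred <- stats::setNames(as.list(rep(NA_real_, nrow(spec))),
                              spec$category)
      cbind(base, as.data.frame(cred),
            data.frame(probability_of_decline = NA_real_,
                       modal_category = NA_character_,
                       note = if (grepl("no baseline", conditionMessage(e)))
                         "no baseline" else conditionMessage(e)))
    })
    res
  })
  out <- do.call(rbind, rows)
  attr(out, "baseline_year") <- baseline_year
  out
}
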