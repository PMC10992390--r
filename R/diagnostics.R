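#' Split R-hat convergence diagnostic
#'
#' The Gelman--Rubin potential scale reduction computed over half-chains:
#' each chain is split in two, and with `n` the half-chain length, `W` the
#' mean within-half-chain variance and `B/n` the variance of half-chain
#' means, `Rhat = sqrt(((n - 1)/n * W + B/n) / W)`. Values near 1 indicate
#' the chains have mixed; the conventional threshold used throughout this
#' package is 1.01 for final fits (1.05 to flag power-simulation
#' replicates).
#'
#' @param x an iterations-by-chains numeric matrix (at least 2 chains of
#'   at least 4 iterations), or a `posterior_draws` object.
#' @param ... unused.
#' @return For a matrix, the scalar R-hat; zero within-chain variance
#'   yields `Inf` with a warning. For a `posterior_draws`, a named vector
#'   over all parameters.
#' @export
split_rhat <- function(x, ...) UseMethod("split_rhat")

#' @export
split_rhat.matrix <- function(x, ...) {
  if (ncol(x) < 2) stop("need at least 2 chains", call. = FALSE)
  if (nrow(x) < 4) stop("need at least 4 iterations per chain", call. = FALSE)
  h <- nrow(x) %/% 2
  halves <- cbind(x[seq_len(h), , drop = FALSE],
                  x[seq.int(nrow(x) - h + 1, nrow(x)), , drop = FALSE])
  W <- mean(apply(halves, 2, stats::var))
  if (W == 0) {
    warning("zero within-chain variance; split R-hat is infinite",
            call. = FALSE)
    return(Inf)
  }
  B <- h * stats::var(colMeans(halves))
  sqrt(((h - 1) / h * W + B / h) / W)
}

#' @export
split_rhat.posterior_draws <- function(x, ...) {
  vapply(colnames(x$draws),
         function(p) {
           m <- chain_matrix(x, p)
           if (all(m == m[1])) return(1)  # pinned derived quantity
           split_rhat(m)
         },
         numeric(1))
}

#' Highest density interval of a draw vector
#'
#' The shortest contiguous interval over the sorted draws containing
#' `ceiling(mass * n)` points. When several windows share the minimal
#' width, the lowest such window is returned (a deterministic tie-break).
#'
#' @param samples numeric vector of at least 10 draws.
#' @param mass probability mass in (0, 1); default 0.95.
#' @return Named numeric vector `c(lower, upper)`.
#' @export
hdi <- function(samples, mass = 0.95) {
  stopifnot(length(samples) >= 10, mass > 0, mass < 1)
  x <- sort(samples)
  n <- length(x)
  k <- ceiling(mass * n)
  if (k >= n) return(c(lower = x[1], upper = x[n]))
  widths <- x[seq.int(k, n)] - x[seq.int(1, n - k + 1)]
  i <- which.min(widths)  # ties: lowest window
  c(lower = x[i], upper = x[i + k - 1])
}

# internal: per-record linear predictor for each draw (rows = draws)
linear_predictor <- function(fit, records = NULL, draw_idx = NULL,
                             fresh_unseen = FALSE) {
  if (is.null(records)) records <- as.data.frame(fit$data)
  if (is.null(draw_idx)) draw_idx <- seq_len(nrow(fit$draws))
  d <- fit$draws[draw_idx, , drop = FALSE]
  n <- nrow(records)

  col_or_na <- function(nms) ifelse(nms %in% colnames(d),
                                    nms, NA_character_)
  pick <- function(prefix, keys) {
    cols <- col_or_na(paste0(prefix, "[", keys, "]"))
    out <- matrix(NA_real_, nrow(d), n)
    seen <- !is.na(cols)
    if (any(seen)) out[, seen] <- d[, cols[seen], drop = FALSE]
    out
  }
  lp <- matrix(d[, "beta0"], nrow(d), n) +
    pick("d_site", records$site_id) +
    pick("d_year", records$year) +
    pick("d_site_year", paste0(records$site_id, ",", records$year)) +
    pick("d_station", paste0(records$site_id, ",", records$station_id))
  marginalized <- colSums(is.na(lp)) > 0
  if (any(marginalized)) {
    if (!fresh_unseen) {
      stop("records reference grouping levels absent from the fit",
           call. = FALSE)
    }
    # marginalize over unseen levels: fresh deviations from each draw's sigmas
    fill <- function(prefix, sigma_col, keys) {
      cols <- paste0(prefix, "[", keys, "]")
      unseen_keys <- unique(keys[!cols %in% colnames(d)])
      out <- matrix(0, nrow(d), n)
      for (key in unseen_keys) {
        z <- stats::rnorm(nrow(d), 0, d[, sigma_col])
        out[, keys == key] <- z
      }
      out
    }
    lp[is.na(lp)] <- 0
    lp <- lp +
      fill("d_site", "sigma_site", records$site_id) +
      fill("d_year", "sigma_year", as.character(records$year)) +
      fill("d_site_year", "sigma_site_year",
           paste0(records$site_id, ",", records$year)) +
      fill("d_station", "sigma_station",
           paste0(records$site_id, ",", records$station_id))
  }
  if ("beta1" %in% colnames(d) && !is.null(records$disturbance_flag)) {
    lp <- lp + d[, "beta1"] %o% as.numeric(records$disturbance_flag)
  }
  if (!is.null(fit$covariate_scaling)) {
    sc <- fit$covariate_scaling
    for (v in names(sc$center)) {
      z <- (records[[v]] - sc$center[[v]]) / sc$scale[[v]]
      lp <- lp + d[, paste0("b_", v)] %o% z
    }
  }
  attr(lp, "marginalized") <- marginalized
  lp
}

#' Posterior predictive checks
#'
#' For each retained draw, simulates one replicated dataset from the
#' fitted negative-binomial likelihood over the design of the data (or a
#' supplied record skeleton) and compares summary statistics of the
#' replicates with the observed data. Records referencing grouping levels
#' the model never saw are marginalized over by drawing fresh deviations
#' from that draw's standard deviations (flagged in the output).
#'
#' @param fit a `posterior_draws` object.
#' @param records optional data frame of records to replicate over;
#'   defaults to the fitted data.
#' @param n_rep number of replicated datasets (draws are thinned evenly).
#' @param statistics named list of functions applied to each count vector;
#'   defaults to mean, variance, proportion of zeros, and maximum.
#' @param seed optional seed for the replicate simulations.
#' @return An object of class `posterior_predictive`: a list with the
#'   comparison table (`summary`: observed value, replicate mean and 95%
#'   interval, tail probability of replicate >= observed), the replicate
#'   statistic draws, the replicated count matrix, and which records were
#'   marginalized.
#' @export
posterior_predictive <- function(fit, records = NULL, n_rep = 100,
                                 statistics = list(
                                   mean = mean,
                                   variance = stats::var,
                                   prop_zero = function(a) mean(a == 0),
                                   max = max),
                                 seed = NULL) {
  stopifnot(inherits(fit, "posterior_draws"))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(records)) records <- as.data.frame(fit$data)
  n_rep <- min(n_rep, nrow(fit$draws))
  draw_idx <- round(seq(1, nrow(fit$draws), length.out = n_rep))
  lp <- linear_predictor(fit, records, draw_idx, fresh_unseen = TRUE)
  phi <- fit$draws[draw_idx, "phi"]
  reps <- matrix(0L, n_rep, nrow(records))
  for (g in seq_len(n_rep)) {
    reps[g, ] <- nb_draw(nrow(records), exp(lp[g, ]), phi[g])
  }
  observed <- as.data.frame(fit$data)$count
  stat_draws <- vapply(statistics,
                       function(f) apply(reps, 1, f),
                       numeric(n_rep))
  obs_stats <- vapply(statistics, function(f) f(observed), numeric(1))
  comparison <- data.frame(
    statistic = names(statistics),
    observed = unname(obs_stats),
    rep_mean = colMeans(stat_draws),
    rep_lower = apply(stat_draws, 2, stats::quantile, 0.025),
    rep_upper = apply(stat_draws, 2, stats::quantile, 0.975),
    p_tail = vapply(seq_along(statistics),
                    function(j) mean(stat_draws[, j] >= obs_stats[j]),
                    numeric(1)),
    row.names = NULL)
  structure(list(summary = comparison, statistic_draws = stat_draws,
                 replicates = reps,
                 marginalized = attr(lp, "marginalized")),
            class = "posterior_predictive")
}

#' @export
print.posterior_predictive <- function(x, ...) {
  cat(sprintf("posterior_predictive: %d replicated dataset(s) of %d record(s)%s\n",
              nrow(x$replicates), ncol(x$replicates),
              if (any(x$marginalized))
                sprintf(" (%d record(s) marginalized over unseen levels)",
                        sum(x$marginalized)) else ""))
  print(transform(x$summary,
                  observed = signif(observed, 4),
                  rep_mean = signif(rep_mean, 4),
                  rep_lower = signif(rep_lower, 4),
                  rep_upper = signif(rep_upper, 4)))
  invisible(x)
}

#' Bayesian R-squared for the fitted abundance model
#'
#' Per posterior draw, the share of response-scale variance the model's
#' expected counts explain:
#' `R2 = V(mu) / (V(mu) + mean(mu + mu^2 / phi))`, where `V` is the
#' variance of the per-record posterior mean `mu` over records for that
#' draw and the second term is the mean negative-binomial residual
#' variance. A draw whose expected counts are constant across records has
#' `R2 = 0`.
#'
#' @param fit a `posterior_draws` object.
#' @param max_draws cap on the number of draws evaluated (evenly thinned);
#'   keeps the record-by-draw expansion light on large designs.
#' @return A numeric vector of per-draw R-squared values in [0, 1).
#' @export
bayes_r2 <- function(fit, max_draws = 2000) {
  stopifnot(inherits(fit, "posterior_draws"))
  draw_idx <- if (nrow(fit$draws) > max_draws) {
    round(seq(1, nrow(fit$draws), length.out = max_draws))
  } else {
    seq_len(nrow(fit$draws))
  }
  lp <- linear_predictor(fit, draw_idx = draw_idx)
  mu <- exp(lp)
  phi <- fit$draws[draw_idx, "phi"]
  v_fit <- apply(mu, 1, stats::var)
  v_res <- rowMeans(mu + mu^2 / phi)
  r2 <- v_fit / (v_fit + v_res)
  r2[v_fit == 0] <- 0
  unname(r2)
}

#' Convergence and fit diagnostics for a posterior sample
#'
#' Per-parameter split R-hat and 95% highest density intervals, plus the
#' Bayesian R-squared distribution.
#'
#' @param fit a `posterior_draws` object.
#' @param mass HDI probability mass.
#' @return An object of class `diagnostics_report`: a list with a
#'   per-parameter table (`parameters`) and the Bayesian R-squared draws
#'   (`r2`).
#' @export
diagnostics_report <- function(fit, mass = 0.95) {
  rhat <- split_rhat(fit)
  tab <- data.frame(
    parameter = colnames(fit$draws),
    mean = colMeans(fit$draws),
    sd = apply(fit$draws, 2, stats::sd),
    hdi_lower = apply(fit$draws, 2, function(v) hdi(v, mass)[["lower"]]),
    hdi_upper = apply(fit$draws, 2, function(v) hdi(v, mass)[["upper"]]),
    rhat = unname(rhat),
    row.names = NULL)
  structure(list(parameters = tab, r2 = bayes_r2(fit), mass = mass),
            class = "diagnostics_report")
}

#' @export
print.diagnostics_report <- function(x, ...) {
  core <- x$parameters[!grepl("^d_", x$parameters$parameter), ]
  cat("diagnostics_report\n")
  print(transform(core, mean = round(mean, 3), sd = round(sd, 3),
                  hdi_lower = round(hdi_lower, 3),
                  hdi_upper = round(hdi_upper, 3),
                  rhat = round(rhat, 4)), row.names = FALSE)
  cat(sprintf("max split R-hat over all %d parameters: %.4f\n",
              nrow(x$parameters), max(x$parameters$rhat)))
  r2h <- hdi(x$r2, x$mass)
  cat(sprintf("Bayesian R2: mean %.3f (%.0f%% HDI %.3f-%.3f)\n",
              mean(x$r2), 100 * x$mass, r2h[["lower"]], r2h[["upper"]]))
  invisible(x)
}
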