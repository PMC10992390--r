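#' MCMC configuration for the hierarchical abundance model
#'
#' Settings for posterior sampling. The default mirrors the reference
#' analysis: 4 chains and 10,000 post-warmup draws in total (2,500 per
#' chain). Priors are weakly informative on the natural-log abundance
#' scale: beta0 and beta1 ~ Normal(0, 1); every deviation standard
#' deviation ~ Gamma(shape 2, rate 2) (mean 1); phi ~ Gamma(shape 2,
#' rate 1) (mean 2); standardized covariate coefficients ~ Normal(0, 1).
#'
#' @param n_chains number of MCMC chains.
#' @param draws total post-warmup draws across all chains; must be
#'   divisible by `n_chains`.
#' @param warmup burn-in iterations per chain after adaptation.
#' @param adapt sampler adaptation iterations per chain.
#' @param priors list with elements `beta0`, `beta1`, `covariate`
#'   (c(mean, sd)) and `sigma`, `phi` (c(shape, rate)); all
#'   scale/shape/rate hyperparameters must be strictly positive.
#' @param covariates optional character vector of covariate columns to
#'   include as standardized fixed effects.
#' @param seed optional integer seed controlling chain initialisation and
#'   sampling.
#' @return An object of class `model_config`.
#' @export
model_config <- function(n_chains = 4L, draws = 10000L, warmup = 500L,
                         adapt = 500L,
                         priors = list(beta0 = c(0, 1), beta1 = c(0, 1),
                                       covariate = c(0, 1),
                                       sigma = c(2, 2), phi = c(2, 1)),
                         covariates = NULL, seed = NULL) {
  stopifnot(n_chains >= 1, draws >= n_chains, warmup >= 0, adapt >= 1)
  if (draws %% n_chains != 0) {
    stop("draws (", draws, ") must be divisible by n_chains (", n_chains,
         ")", call. = FALSE)
  }
  defaults <- list(beta0 = c(0, 1), beta1 = c(0, 1), covariate = c(0, 1),
                   sigma = c(2, 2), phi = c(2, 1))
  priors <- utils::modifyList(defaults, priors)
  if (priors$beta0[2] <= 0 || priors$beta1[2] <= 0 ||
      priors$covariate[2] <= 0 || any(priors$sigma <= 0) ||
      any(priors$phi <= 0)) {
    stop("prior scale, shape and rate hyperparameters must be strictly positive",
         call. = FALSE)
  }
  structure(list(n_chains = as.integer(n_chains),
                 draws = as.integer(draws),
                 warmup = as.integer(warmup), adapt = as.integer(adapt),
                 priors = priors, covariates = covariates, seed = seed),
            class = "model_config")
}

# JAGS model source. The posterior is that of the non-centered model
# (every deviation is a standardised draw times its sigma); for sampling
# efficiency under one-at-a-time Gibbs updates the site, year and
# site-by-year terms are hierarchically centred (a posterior-identical
# reparameterization) and the deviations recovered as derived nodes,
# while the weakly-informed station term keeps the zeta * sigma form.
# When the disturbance dummy X is constant within year levels, beta1 is
# likewise centred into the disturbed years' level means (X enters as a
# per-year covariate yX); the explicit beta1 * X[i] likelihood term is
# the general fallback.
jags_model_source <- function(config, change_model, n_covariates,
                              year_aligned_x = FALSE) {
  pr <- config$priors
  cov_term <- if (n_covariates > 0) " + inprod(b_cov[], C[i, ])" else ""
  x_term <- if (change_model && !year_aligned_x) " + beta1 * X[i]" else ""
  year_decl <- if (change_model && year_aligned_x) {
    "for (j in 1:n_year) {
    a_year[j] ~ dnorm(beta1 * yX[j], prec_year)
    d_year[j] <- a_year[j] - beta1 * yX[j]
  }"
  } else {
    "for (j in 1:n_year) { a_year[j] ~ dnorm(0, prec_year)
    d_year[j] <- a_year[j] }"
  }
  src <- sprintf("
model {
  for (i in 1:N) {
    A[i] ~ dnegbin(pnb[i], phi)
    pnb[i] <- phi / (phi + mu[i])
    log(mu[i]) <- a_site[site[i]] + a_year[year[i]] + d_siteyear[siteyear[i]] + d_station[station[i]]%s%s
  }
  for (j in 1:n_site) {
    a_site[j] ~ dnorm(beta0, prec_site)
    d_site[j] <- a_site[j] - beta0
  }
  %s
  for (j in 1:n_siteyear) { d_siteyear[j] ~ dnorm(0, prec_siteyear) }
  for (j in 1:n_station) {
    z_station[j] ~ dnorm(0, 1)
    d_station[j] <- z_station[j] * sigma_station
  }
  prec_site <- pow(sigma_site, -2)
  prec_year <- pow(sigma_year, -2)
  prec_siteyear <- pow(sigma_site_year, -2)
  beta0 ~ dnorm(%g, %g)
  sigma_station ~ dgamma(%g, %g)
  sigma_site ~ dgamma(%g, %g)
  sigma_year ~ dgamma(%g, %g)
  sigma_site_year ~ dgamma(%g, %g)
  phi ~ dgamma(%g, %g)",
    x_term, cov_term, year_decl,
    pr$beta0[1], 1 / pr$beta0[2]^2,
    pr$sigma[1], pr$sigma[2], pr$sigma[1], pr$sigma[2],
    pr$sigma[1], pr$sigma[2], pr$sigma[1], pr$sigma[2],
    pr$phi[1], pr$phi[2])
  if (change_model) {
    src <- paste0(src, sprintf("\n  beta1 ~ dnorm(%g, %g)",
                               pr$beta1[1], 1 / pr$beta1[2]^2))
  }
  if (n_covariates > 0) {
    src <- paste0(src, sprintf(
      "\n  for (k in 1:n_cov) { b_cov[k] ~ dnorm(%g, %g) }",
      pr$covariate[1], 1 / pr$covariate[2]^2))
  }
  paste0(src, "\n}\n")
}

# internal: factorize a count table into JAGS index vectors
model_frame <- function(data, config, change_model) {
  df <- as.data.frame(data)
  if (nrow(df) == 0) stop("data is empty", call. = FALSE)
  if (anyNA(df$count)) stop("data contains missing counts", call. = FALSE)
  for (v in c("site_id", "year", "station_id")) {
    if (anyNA(df[[v]])) stop("missing ", v, " in data", call. = FALSE)
  }
  site_levels <- sort(unique(df$site_id))
  year_levels <- sort(unique(df$year))
  sy <- unique(df[, c("site_id", "year")])
  sy <- sy[order(sy$site_id, sy$year), ]
  st <- unique(df[, c("site_id", "station_id")])
  st <- st[order(st$site_id, st$station_id), ]

  for (nm in c(site = "site_id", year = "year")) {
    if (length(unique(df[[nm]])) == 1) {
      warning("grouping factor ", nm, " has a single level; it is retained",
              call. = FALSE)
    }
  }
  jd <- list(
    A = df$count, N = nrow(df),
    site = match(df$site_id, site_levels),
    year = match(df$year, year_levels),
    siteyear = match(pair_key(df$site_id, df$year),
                     pair_key(sy$site_id, sy$year)),
    station = match(pair_key(df$site_id, df$station_id),
                    pair_key(st$site_id, st$station_id)),
    n_site = length(site_levels), n_year = length(year_levels),
    n_siteyear = nrow(sy), n_station = nrow(st))
  scaling <- NULL
  if (!is.null(config$covariates)) {
    miss <- setdiff(config$covariates, names(df))
    if (length(miss) > 0) {
      stop("covariate column(s) not in data: ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
    C <- as.matrix(df[, config$covariates, drop = FALSE])
    ctr <- colMeans(C)
    scl <- apply(C, 2, stats::sd)
    scl[scl == 0] <- 1
    jd$C <- sweep(sweep(C, 2, ctr), 2, scl, "/")
    jd$n_cov <- ncol(C)
    scaling <- list(center = ctr, scale = scl)
  }
  year_aligned_x <- FALSE
  if (change_model) {
    x_by_year <- tapply(df$disturbance_flag, df$year,
                        function(v) length(unique(v)))
    year_aligned_x <- all(x_by_year == 1)
    if (year_aligned_x) {
      jd$yX <- as.numeric(tapply(df$disturbance_flag, df$year,
                                 unique)[as.character(year_levels)])
    } else {
      jd$X <- df$disturbance_flag
    }
  }
  list(jags_data = jd, site_levels = site_levels, year_levels = year_levels,
       site_year_levels = sy, station_levels = st,
       covariate_scaling = scaling, year_aligned_x = year_aligned_x)
}

fit_model_impl <- function(data, config, change_model) {
  mf <- model_frame(data, config, change_model)
  n_cov <- if (is.null(mf$jags_data$n_cov)) 0L else mf$jags_data$n_cov
  src <- jags_model_source(config, change_model, n_cov, mf$year_aligned_x)
  seed <- if (is.null(config$seed)) sample.int(2^30, 1) else config$seed

  # start the intercept at the empirical log mean count (the prior mean
  # would impose a long warmup transient); retries jitter around it
  b0_start <- log(mean(mf$jags_data$A) + 0.5)
  make_inits <- function(jitter) {
    lapply(seq_len(config$n_chains), function(k) {
      ini <- list(.RNG.name = "base::Mersenne-Twister",
                  .RNG.seed = derive_seed(seed, k + 100L * jitter),
                  beta0 = b0_start)
      if (jitter > 0) {
        set.seed(derive_seed(seed, 7L * k + 1000L * jitter))
        ini$beta0 <- stats::rnorm(1, b0_start, 0.3)
      }
      ini
    })
  }
  monitors <- c("beta0", "sigma_station", "sigma_site", "sigma_year",
                "sigma_site_year", "phi", "d_site", "d_year", "d_siteyear",
                "d_station")
  if (change_model) monitors <- c(monitors, "beta1")
  if (n_cov > 0) monitors <- c(monitors, "b_cov")

  iter <- config$draws %/% config$n_chains
  samples <- NULL
  for (attempt in 0:1) {
    samples <- tryCatch({
      jm <- rjags::jags.model(textConnection(src), data = mf$jags_data,
                              inits = make_inits(attempt),
                              n.chains = config$n_chains,
                              n.adapt = config$adapt, quiet = TRUE)
      if (config$warmup > 0) {
        stats::update(jm, config$warmup, progress.bar = "none")
      }
      rjags::coda.samples(jm, monitors, n.iter = iter,
                          progress.bar = "none")
    }, error = function(e) e)
    if (!inherits(samples, "error")) break
  }
  if (inherits(samples, "error")) {
    stop("MCMC sampling failed after a retry with jittered initial values: ",
         conditionMessage(samples), call. = FALSE)
  }

  mat <- do.call(rbind, lapply(samples, as.matrix))
  colnames(mat) <- rename_jags_columns(colnames(mat), mf, config$covariates)
  structure(list(
    draws = mat,
    chain = rep(seq_len(config$n_chains), each = iter),
    iteration = rep(seq_len(iter), config$n_chains),
    levels = list(site = mf$site_levels, year = mf$year_levels,
                  site_year = mf$site_year_levels,
                  station = mf$station_levels),
    model = if (change_model) "change" else "abundance",
    data = data, config = config, seed = seed,
    covariate_scaling = mf$covariate_scaling),
    class = "posterior_draws")
}

rename_jags_columns <- function(nms, mf, covariates) {
  # JAGS drops the bracket index on single-element arrays
  for (bare in c("d_site", "d_year", "d_siteyear", "d_station", "b_cov")) {
    nms[nms == bare] <- paste0(bare, "[1]")
  }
  out <- nms
  idx <- function(n) as.integer(sub(".*\\[(\\d+)\\]", "\\1", n))
  for (i in seq_along(nms)) {
    n <- nms[i]
    out[i] <- if (startsWith(n, "d_site[")) {
      paste0("d_site[", mf$site_levels[idx(n)], "]")
    } else if (startsWith(n, "d_year[")) {
      paste0("d_year[", mf$year_levels[idx(n)], "]")
    } else if (startsWith(n, "d_siteyear[")) {
      j <- idx(n)
      paste0("d_site_year[", mf$site_year_levels$site_id[j], ",",
             mf$site_year_levels$year[j], "]")
    } else if (startsWith(n, "d_station[")) {
      j <- idx(n)
      paste0("d_station[", mf$station_levels$site_id[j], ",",
             mf$station_levels$station_id[j], "]")
    } else if (startsWith(n, "b_cov[")) {
      paste0("b_", covariates[idx(n)])
    } else n
  }
  out
}

#' Fit the hierarchical negative-binomial abundance model
#'
#' Samples the posterior of the abundance model (see
#' [generative_parameters()] for the generative form) by MCMC: counts are
#' negative binomial with shape `phi`, the log mean is a global intercept
#' plus crossed station, site, year and site-by-year Gaussian deviations,
#' and priors are the weakly informative set in [model_config()].
#' `fit_change_model()` fits the identical hierarchy plus a disturbance
#' term `beta1 * X` on the log scale, where `X` is the 0/1
#' `disturbance_flag`; the disturbed records additionally contribute a
#' year level and site-year levels of their own, and the partial
#' confounding between `beta1` and the new-year deviation is resolved by
#' shrinkage.
#'
#' @param data a [count_table()] (or data frame with the same columns)
#'   with complete counts.
#' @param config a [model_config()].
#' @return An object of class `posterior_draws`: a draw matrix (one row
#'   per retained draw, exactly `config$draws` rows; columns `beta0`,
#'   `sigma_station`, `sigma_site`, `sigma_year`, `sigma_site_year`,
#'   `phi`, all deviations `d_site[...]`, `d_year[...]`,
#'   `d_site_year[...]`, `d_station[...]`, plus `beta1` and covariate
#'   coefficients where applicable) together with chain/iteration labels,
#'   the grouping-level dictionaries, the data and the configuration.
#' @seealso [diagnostics_report()], [fold_change_draws()]
#' @export
fit_abundance_model <- function(data, config = model_config()) {
  fit_model_impl(data, config, change_model = FALSE)
}

#' @rdname fit_abundance_model
#' @export
fit_change_model <- function(data, config = model_config()) {
  df <- as.data.frame(data)
  flags <- unique(df$disturbance_flag)
  if (length(flags) < 2) {
    stop("disturbance_flag is constant (all ", flags,
         "); the disturbance effect is not identifiable", call. = FALSE)
  }
  fit_model_impl(data, config, change_model = TRUE)
}

#' @export
print.posterior_draws <- function(x, ...) {
  cat(sprintf("posterior_draws (%s model): %d draws x %d parameters, %d chain(s)\n",
              x$model, nrow(x$draws), ncol(x$draws),
              max(x$chain)))
  hyper <- intersect(c("beta0", "beta1", "sigma_station", "sigma_site",
                       "sigma_year", "sigma_site_year", "phi"),
                     colnames(x$draws))
  sm <- t(vapply(hyper, function(p) {
    d <- x$draws[, p]
    c(mean = mean(d), sd = stats::sd(d), hdi(d))
  }, numeric(4)))
  colnames(sm) <- c("mean", "sd", "hdi_lower", "hdi_upper")
  print(round(sm, 3))
  invisible(x)
}

#' Extract draws of one or more parameters
#'
#' @param fit a `posterior_draws` object.
#' @param pars parameter name(s); see [fit_abundance_model()] for the
#'   naming scheme.
#' @return A numeric vector (one parameter) or draw matrix.
#' @export
posterior <- function(fit, pars) {
  stopifnot(inherits(fit, "posterior_draws"))
  miss <- setdiff(pars, colnames(fit$draws))
  if (length(miss) > 0) {
    stop("unknown parameter(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  fit$draws[, pars]
}

#' @rdname posterior
#' @param par a single parameter name.
#' @return `chain_matrix()` returns an iterations-by-chains matrix for one
#'   parameter, the layout the convergence diagnostics consume.
#' @export
chain_matrix <- function(fit, par) {
  v <- posterior(fit, par)
  matrix(v, ncol = max(fit$chain))
}
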