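test_that("model configuration enforces its invariants and defaults", {
  cfg <- model_config()
  expect_equal(cfg$n_chains, 4L)
  expect_equal(cfg$draws, 10000L)
  expect_equal(cfg$priors$sigma, c(2, 2))
  expect_equal(cfg$priors$phi, c(2, 1))
  expect_error(model_config(n_chains = 3, draws = 1000), "divisible")
  expect_error(model_config(priors = list(sigma = c(2, -1))), "positive")
})

test_that("abundance fits return the configured draws with sane structure", {
  fit <- small_fit()
  cfg <- fit$config
  expect_s3_class(fit, "posterior_draws")
  expect_equal(nrow(fit$draws), cfg$draws)
  expect_equal(max(fit$chain), cfg$n_chains)
  expect_true(all(c("beta0", "sigma_station", "sigma_site", "sigma_year",
                    "sigma_site_year", "phi") %in% colnames(fit$draws)))
  # deviations for every level
  expect_length(grep("^d_site\\[", colnames(fit$draws)), 4)
  expect_length(grep("^d_year\\[", colnames(fit$draws)), 3)
  expect_length(grep("^d_station\\[", colnames(fit$draws)), 16)
  # positivity constraints and the log link
  expect_true(all(fit$draws[, "phi"] > 0))
  expect_true(all(fit$draws[, "sigma_site"] > 0))
  expect_true(all(exp(fit$draws[, "beta0"]) > 0))
  expect_true(all(is.finite(fit$draws)))

  # same seed, same draws
  refit <- fit_abundance_model(small_sim()$table, quick_cfg(seed = 104L))
  expect_identical(refit$draws, fit$draws)

  expect_error(fit_abundance_model(small_sim()$table[0, ], quick_cfg()),
               "empty")
})

test_that("the change model requires both disturbance states and finds a strong decline", {
  p <- default_generative_parameters()
  sim <- simulate_study(p, study_design(), rho = 0.05, alpha = 20,
                        seed = 41)
  # X == 0 everywhere is rejected before fitting
  bg <- sim$table[sim$table$disturbance_flag == 0, ]
  expect_error(fit_change_model(bg, quick_cfg()), "identifiable")

  fit <- fit_change_model(sim$table,
                          model_config(n_chains = 2L, draws = 4000L,
                                       warmup = 1000L, adapt = 500L,
                                       seed = 41))
  expect_true("beta1" %in% colnames(fit$draws))
  # removing 95% of the population is detected decisively; part of the
  # shock is absorbed by the new year's own deviation (the model
  # resolves that confounding by shrinkage), so P(beta1 < 0) sits
  # around 0.9 rather than at 1 even for this extreme decline
  expect_gt(mean(posterior(fit, "beta1") < 0), 0.85)
  # the disturbed year contributes year and site-year levels of its own
  expect_true("d_year[2023]" %in% colnames(fit$draws))
  expect_length(grep(",2023\\]$", colnames(fit$draws)), 5)
})

test_that("optional covariates enter as standardized fixed effects", {
  sim <- simulate_counts(tiny_design(), default_generative_parameters(),
                         seed = 51)
  tab <- as.data.frame(sim$table)
  set.seed(51)
  tab$depth <- runif(nrow(tab), 3, 9)
  fit <- fit_abundance_model(count_table(tab),
                             quick_cfg(covariates = "depth", seed = 51))
  expect_true("b_depth" %in% colnames(fit$draws))
  expect_equal(names(fit$covariate_scaling$center), "depth")
  # a covariate drawn independently of the counts stays near zero
  expect_lt(abs(mean(posterior(fit, "b_depth"))), 0.5)
})

test_that("split R-hat matches direct formula evaluation and flags bad mixing", {
  # hand computation on two constant-shifted chains
  set.seed(61)
  n <- 2000
  base <- rnorm(n)
  m <- cbind(base, base + 10)
  h <- n %/% 2
  halves <- cbind(m[1:h, ], m[(n - h + 1):n, ])
  W <- mean(apply(halves, 2, var))
  B <- h * var(colMeans(halves))
  by_hand <- sqrt(((h - 1) / h * W + B / h) / W)
  expect_equal(split_rhat(m), by_hand)
  expect_gt(by_hand, 3)  # disjoint chains are loudly non-converged

  # well-mixed chains from the same distribution sit in [1, 1.01]
  set.seed(62)
  ok <- matrix(rnorm(4 * 10000), ncol = 4)
  r <- split_rhat(ok)
  expect_gte(r, 1 - 1e-8)
  expect_lt(r, 1.01)

  # degenerate: duplicated constant chain
  expect_warning(r0 <- split_rhat(matrix(1, 100, 2)), "zero within-chain")
  expect_identical(r0, Inf)

  expect_error(split_rhat(matrix(1:8, ncol = 1)), "2 chains")
  expect_error(split_rhat(matrix(1:6, ncol = 2)), "4 iterations")
})

test_that("hdi returns the brute-force shortest window", {
  # forced windows
  expect_equal(hdi(1:100, 0.95), c(lower = 1, upper = 95))
  expect_equal(unname(diff(hdi(1:100, 0.95))), 94)
  expect_equal(hdi(c(0, 0, 0, 0, 10, 1, 2, 3, 4, 5), 0.95),
               c(lower = 0, upper = 10))

  brute <- function(x, mass) {
    x <- sort(x); n <- length(x); k <- ceiling(mass * n)
    best <- c(-Inf, Inf)
    for (i in 1:(n - k + 1)) {
      if (x[i + k - 1] - x[i] < best[2] - best[1]) {
        best <- c(x[i], x[i + k - 1])
      }
    }
    setNames(best, c("lower", "upper"))
  }
  set.seed(71)
  for (i in 1:20) {
    x <- switch(1 + i %% 3,
                rgamma(1e4, shape = 2, rate = 2),
                rnorm(200),
                rlnorm(500))
    mass <- sample(c(0.5, 0.8, 0.9, 0.95), 1)
    expect_equal(hdi(x, mass), brute(x, mass))
    # permutation invariance
    expect_equal(hdi(sample(x), mass), hdi(x, mass))
  }
  expect_error(hdi(1:5), "length")
})

test_that("Bayesian R2 respects its limits and definition", {
  d <- tiny_design(n_sites = 2, n_years = 1, n_stations = 2)
  tab <- expand_design(d)
  tab$count <- 5L

  cols <- c("beta0", "sigma_station", "sigma_site", "sigma_year",
            "sigma_site_year", "phi",
            paste0("d_site[", c("S1", "S2"), "]"), "d_year[2018]",
            paste0("d_site_year[", c("S1", "S2"), ",2018]"),
            paste0("d_station[",
                   c("S1,st1", "S1,st2", "S2,st1", "S2,st2"), "]"))
  base <- matrix(0, nrow = 20, ncol = length(cols),
                 dimnames = list(NULL, cols))
  base[, "beta0"] <- 2
  base[, "phi"] <- 2
  base[, c("sigma_station", "sigma_site", "sigma_year",
           "sigma_site_year")] <- 0.5

  # constant expected counts across records -> R2 exactly 0
  fit0 <- fake_fit(base, tab)
  expect_equal(bayes_r2(fit0), rep(0, 20))

  # strongly separated site means with phi -> Inf push R2 towards 1
  sep <- base
  sep[, "beta0"] <- 6
  sep[, "d_site[S1]"] <- 3
  sep[, "d_site[S2]"] <- -3
  sep[, "phi"] <- 1e8
  fit1 <- fake_fit(sep, tab)
  expect_true(all(bayes_r2(fit1) > 0.95))

  # hand check of the formula on a non-trivial draw
  mix <- base
  mix[, "d_site[S1]"] <- 1
  r2 <- bayes_r2(fit_mix <- fake_fit(mix, tab))
  mu <- exp(2 + c(1, 1, 0, 0))
  expected <- var(mu) / (var(mu) + mean(mu + mu^2 / 2))
  expect_equal(r2, rep(expected, 20))

  # draws from a real fit stay inside [0, 1)
  r2f <- bayes_r2(small_fit())
  expect_length(r2f, nrow(small_fit()$draws))
  expect_true(all(r2f >= 0 & r2f < 1))
})

test_that("posterior predictive replicates match the design and calibrate", {
  fit <- small_fit()
  pp <- posterior_predictive(fit, n_rep = 40, seed = 81)
  expect_equal(dim(pp$replicates), c(40, nrow(fit$data)))
  expect_setequal(pp$summary$statistic,
                  c("mean", "variance", "prop_zero", "max"))
  expect_false(any(pp$marginalized))
  # data simulated from the model itself: observed mean inside the
  # central replicated interval
  expect_gte(pp$summary$observed[1], pp$summary$rep_lower[1])
  expect_lte(pp$summary$observed[1], pp$summary$rep_upper[1])

  # custom statistic list is honoured
  pp2 <- posterior_predictive(fit, n_rep = 10,
                              statistics = list(median = median), seed = 82)
  expect_equal(pp2$summary$statistic, "median")

  # unseen design levels are marginalized with fresh deviations, flagged
  extra <- as.data.frame(expand_design(
    sampling_design(c("S1", "ZZ"), 2018, 2)))
  pp3 <- posterior_predictive(fit, records = extra, n_rep = 10, seed = 83)
  expect_true(any(pp3$marginalized))
})
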