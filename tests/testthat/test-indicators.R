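test_that("fold-change draws equal the cancelled algebraic form", {
  fit <- small_fit()
  fc <- fold_change_draws(fit, 2020)
  # full numerator/denominator form agrees with the cancelled form
  full <- exp(fit$draws[, "beta0"] + fit$draws[, "d_year[2020]"]) /
    exp(fit$draws[, "beta0"] + fit$draws[, "d_year[2018]"])
  expect_equal(fc$draws, unname(full), tolerance = 1e-12)
  expect_true(all(fc$draws > 0))

  # baseline vs itself is exactly 1
  fc0 <- fold_change_draws(fit, 2018)
  expect_true(all(fc0$draws == 1))

  # site-specific variant includes both interaction terms
  fcs <- fold_change_draws(fit, 2020, site = "S2")
  manual <- exp(
    fit$draws[, "d_year[2020]"] - fit$draws[, "d_year[2018]"] +
      fit$draws[, "d_site_year[S2,2020]"] -
      fit$draws[, "d_site_year[S2,2018]"])
  expect_equal(fcs$draws, unname(manual))

  expect_error(fold_change_draws(fit, 1999), "not a level")

  # a single hand-built draw: year deviation ln 2 against baseline 0
  tab <- small_sim()$table
  cols <- colnames(fit$draws)
  one <- matrix(0, 12, length(cols), dimnames = list(NULL, cols))
  one[, "d_year[2020]"] <- log(2)
  ff <- fake_fit(one, tab)
  expect_equal(fold_change_draws(ff, 2020)$draws, rep(2, 12))
})

test_that("a site unsampled in the baseline year raises a no-baseline error", {
  p <- default_generative_parameters()
  sim <- simulate_counts(study_design(), p, seed = 91)
  fit <- fit_abundance_model(sim$table, quick_cfg(seed = 91))
  # S5 is only sampled in 2020 and 2022; its 2018 interaction level
  # does not exist, so site-level change cannot be back-calculated
  expect_error(fold_change_draws(fit, 2020, site = "S5"), "no baseline")
  # but the table view keeps the row with a note instead of dropping it
  tab <- assess_health(fit, years = 2020, by_site = TRUE)
  expect_equal(tab$note[tab$site == "S5"], "no baseline")
  expect_true(is.na(tab$probability_of_decline[tab$site == "S5"]))
  ok <- tab[tab$site == "S1", ]
  expect_equal(sum(ok[, c("poor", "fair", "good", "very_good")]), 1)
})

test_that("credibilities are AUC shares: analytic uniform case and invariants", {
  # uniform draws on (0.4, 1.4): band masses are 10/20/20/50 percent
  mid <- seq(0.4005, 1.3995, by = 0.001)
  a <- classify_health(mid)
  expect_equal(unname(a$credibility),
               c(0.10, 0.20, 0.20, 0.50), tolerance = 1e-12)
  expect_equal(sum(a$credibility), 1)
  expect_equal(a$modal_category, "very_good")
  expect_equal(a$probability_of_decline, 0.6, tolerance = 1e-12)

  # boundary value 0.9 counts as very_good (half-open bands)
  b <- classify_health(rep(0.9, 50))
  expect_equal(unname(b$credibility["very_good"]), 1)

  set.seed(92)
  for (i in 1:10) {
    x <- rlnorm(500, meanlog = rnorm(1, 0, 0.3), sdlog = runif(1, 0.1, 1))
    cl <- classify_health(x)
    # sums to one, order-invariant
    expect_equal(sum(cl$credibility), 1, tolerance = 1e-12)
    expect_equal(classify_health(sample(x))$credibility, cl$credibility)
    # monotone: scaling all draws down never moves mass to better health
    worse <- classify_health(x * 0.8)
    expect_true(all(cumsum(worse$credibility) >=
                      cumsum(cl$credibility) - 1e-12))
  }

  expect_error(classify_health(numeric(0)), "empty")
})

test_that("probability of decline is the share of draws below one", {
  expect_equal(prob_decline(c(0.5, 1.5)), 0.5)
  expect_equal(prob_decline(rep(0.2, 10)), 1)
  set.seed(93)
  x <- c(runif(75, 0.2, 0.99), runif(25, 1.01, 3))
  expect_equal(prob_decline(x), 0.75)
  fit <- small_fit()
  expect_equal(prob_decline(fold_change_draws(fit, 2019)),
               mean(fold_change_draws(fit, 2019)$draws < 1))
})

test_that("fold variation transforms per draw and reproduces point figures", {
  # point transforms of the station-level sigma summaries round to the
  # reported 1.6-fold (mean) and 2.4-fold (upper HDI) figures
  expect_equal(round(fold_variation_point(0.22), 1), 1.6)
  expect_equal(round(fold_variation_point(0.43), 1), 2.4)
  expect_equal(fold_variation_point(0), 1)

  # per-draw transform then summarize; Jensen: mean exp >= exp mean
  set.seed(94)
  sig <- rgamma(5000, shape = 2, rate = 2 / 0.62)  # right-skewed posterior
  fv <- fold_variation(sig)
  expect_equal(fv$mean, mean(exp(2 * sig)))
  expect_gte(fv$mean, fold_variation_point(2 * mean(sig) / 2))
  expect_lt(fv$hdi[["lower"]], fv$hdi[["upper"]])
  expect_error(fold_variation(c(-0.1, 0.2)), "sigma_draws")
})
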