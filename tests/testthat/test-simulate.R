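test_that("hierarchical deviations have the stated structure and scale", {
  d <- tiny_design(n_sites = 5)
  p <- default_generative_parameters()
  dev <- draw_deviations(d, p, seed = 1)
  # one entry per level of every grouping
  expect_length(dev$site, 5)
  expect_length(dev$year, 3)
  expect_equal(nrow(dev$site_year), 15)
  expect_equal(nrow(dev$station), 20)

  # all-zero sigmas collapse every deviation to exactly 0
  p0 <- generative_parameters(beta0 = 2, sigma_station = 0, sigma_site = 0,
                              sigma_year = 0, sigma_site_year = 0, phi = 1)
  dev0 <- draw_deviations(d, p0, seed = 2)
  expect_true(all(dev0$site == 0) && all(dev0$year == 0) &&
                all(dev0$site_year$deviation == 0) &&
                all(dev0$station$deviation == 0))

  # Monte-Carlo: 1e5 year-level draws reproduce sigma_year = 0.38 within 1%
  dbig <- sampling_design("A", seq_len(1e5), stations_per_site = 1)
  devb <- draw_deviations(dbig, p, seed = 3)
  expect_lt(abs(sd(devb$year) - 0.38) / 0.38, 0.01)
  expect_lt(abs(mean(devb$year)), 0.01)
})

test_that("simulated counts match the negative-binomial mean/variance laws", {
  flat <- function(beta0, phi) {
    generative_parameters(beta0 = beta0, sigma_station = 0, sigma_site = 0,
                          sigma_year = 0, sigma_site_year = 0, phi = phi)
  }
  d <- sampling_design("A", 2018, stations_per_site = 1e5)

  # Poisson limit: phi -> Inf gives variance ~= mean
  sim_pois <- simulate_counts(d, flat(log(10), 1e6), seed = 11)
  x <- sim_pois$table$count
  expect_lt(abs(mean(x) - 10), 3 * sd(x) / sqrt(length(x)))
  v <- var(x)
  se_v <- sd((x - mean(x))^2) / sqrt(length(x))
  expect_lt(abs(v - 10), 3 * se_v)

  # closed-form NB moments: mu = 5, phi = 2 -> variance 5 + 25/2 = 17.5
  sim_nb <- simulate_counts(d, flat(log(5), 2), seed = 12)
  y <- sim_nb$table$count
  expect_lt(abs(mean(y) - 5), 3 * sd(y) / sqrt(length(y)))
  se_vy <- sd((y - mean(y))^2) / sqrt(length(y))
  expect_lt(abs(var(y) - 17.5), 3 * se_vy)

  # realistic parameters produce over-dispersed counts (variance/mean > 1)
  simr <- simulate_counts(sampling_design(paste0("S", 1:5), 2018:2022, 20),
                          default_generative_parameters(), seed = 13)
  expect_gt(var(simr$table$count) / mean(simr$table$count), 1)

  # log means reproduce beta0 + deviations exactly
  dd <- tiny_design()
  pp <- default_generative_parameters()
  dev <- draw_deviations(dd, pp, seed = 14)
  sim <- simulate_counts(dd, pp, deviations = dev, seed = 15)
  manual <- with(as.data.frame(sim$table), {
    sy <- paste(site_id, year); st <- paste(site_id, station_id)
    pp$beta0 + dev$site[site_id] + dev$year[as.character(year)] +
      dev$site_year$deviation[match(sy, paste(dev$site_year$site_id,
                                              dev$site_year$year))] +
      dev$station$deviation[match(st, paste(dev$station$site_id,
                                            dev$station$station_id))]
  })
  expect_equal(log(sim$mean), unname(manual))

  # overflow-scale means are refused
  expect_error(simulate_counts(dd, flat(35, 1), seed = 16), "log-mean")
})

test_that("disturbed-year simulation reuses original stations and scales by rho", {
  p <- default_generative_parameters()
  sites <- setNames(c(0.1, -0.2, 0, 0.3, -0.1), paste0("S", 1:5))
  stn <- expand.grid(site_id = paste0("S", 1:5),
                     station_id = paste0("st", 1:5),
                     stringsAsFactors = FALSE)
  set.seed(20); stn$deviation <- rnorm(25, 0, p$sigma_station)

  sim <- simulate_disturbed_year(p, baseline_year_deviation = 0.05,
                                 site_deviations = sites,
                                 station_deviations = stn,
                                 rho = 0.7, alpha = 20, seed = 21)
  expect_equal(nrow(sim$table), 100)
  expect_true(all(sim$table$disturbance_flag == 1))
  # 5 reused + 15 fresh station deviations per site
  for (s in names(sites)) {
    devs <- sim$deviations$station
    here <- devs[devs$site_id == s, ]
    expect_equal(nrow(here), 20)
    reused <- merge(here, stn, by = c("site_id", "station_id"))
    expect_equal(nrow(reused), 5)
    expect_equal(reused$deviation.x, reused$deviation.y)
  }
  # fewer requested samples than supplied stations is a design error
  expect_error(simulate_disturbed_year(p, 0, sites, stn, rho = 1,
                                       alpha = 3, seed = 1), "alpha")

  # with all randomness switched off, every mean is exactly exp(beta0) * rho
  p0 <- generative_parameters(beta0 = log(8), sigma_station = 0,
                              sigma_site = 0, sigma_year = 0,
                              sigma_site_year = 0, phi = 5)
  z_sites <- setNames(numeric(5), paste0("S", 1:5))
  z_stn <- stn; z_stn$deviation <- 0
  s1 <- simulate_disturbed_year(p0, 0, z_sites, z_stn, rho = 1,
                                alpha = 5, seed = 22)
  expect_equal(s1$mean, rep(8, 25))

  # Monte-Carlo halving: rho = 0.5 halves the empirical mean
  dhuge <- setNames(0, "A")
  shuge <- data.frame(site_id = "A", station_id = paste0("st", 1:5),
                      deviation = 0)
  m1 <- simulate_disturbed_year(p0, 0, dhuge, shuge, rho = 1,
                                alpha = 1e4, seed = 23)
  m5 <- simulate_disturbed_year(p0, 0, dhuge, shuge, rho = 0.5,
                                alpha = 1e4, seed = 24)
  ratio <- mean(m5$table$count) / mean(m1$table$count)
  expect_lt(abs(ratio - 0.5), 0.02)
})

test_that("full study simulation concatenates before/after blocks reproducibly", {
  p <- default_generative_parameters()
  d <- study_design()
  sim <- simulate_study(p, d, rho = 0.05, alpha = 5, seed = 30)
  expect_equal(nrow(sim$table), 108 + 5 * 5)
  # the disturbance flag partitions the table into the two blocks
  expect_equal(unname(table(sim$table$disturbance_flag)),
               c(108L, 25L), ignore_attr = TRUE)
  expect_true(all(sim$table$year[sim$table$disturbance_flag == 1] == 2023))

  # identical seeds reproduce identical datasets bit-for-bit
  sim2 <- simulate_study(p, d, rho = 0.05, alpha = 5, seed = 30)
  expect_identical(sim$table, sim2$table)
  expect_identical(sim$mean, sim2$mean)

  # a severe decline pushes new-year counts far below background
  set.seed(300)
  meds <- replicate(30, {
    s <- simulate_study(p, d, rho = 0.05, alpha = 5,
                        seed = sample.int(1e6, 1))
    tapply(s$table$count, s$table$disturbance_flag, median)
  })
  expect_gt(mean(meds[1, ] > meds[2, ]), 0.9)

  # neutral anchoring forces the baseline year deviation to zero
  expect_equal(unname(sim$deviations$year["2018"]), 0)
  simr <- simulate_study(p, d, rho = 1, alpha = 5,
                         baseline_deviation = "random", seed = 31)
  expect_false(simr$deviations$year[["2018"]] == 0)
  simf <- simulate_study(p, d, rho = 1, alpha = 5,
                         baseline_deviation = 0.4, seed = 31)
  expect_equal(unname(simf$deviations$year["2018"]), 0.4)
})
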