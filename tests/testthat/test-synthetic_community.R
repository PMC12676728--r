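noise_free <- function(...) {
  scenario_config(sd_size = 0, sd_abund = 0, sd_temp = 0, sd_po4 = 0,
                  sd_din = 0, sd_salinity = 0, bloom_prob = 0,
                  detect_prob = 1, ...)
}

test_that("noise-free environment is exactly linear plus seasonality", {
  cfg <- noise_free(n_stations = 3, months = 48, seasonal_amp = 0)
  env <- generate_environment(cfg, seed = 1)
  temp <- env[env$param == "temperature" & env$station_id == "S02", ]
  temp <- add_lagged_month(temp, cfg$start_date)
  tr <- linear_trend(temp, value = value)
  expect_true(tr$exact_fit)
  expect_equal(tr$slope_month, cfg$warming[2] / 12, tolerance = 1e-12)
  expect_equal(tr$intercept, cfg$t0[2], tolerance = 1e-10)
})

test_that("generation is deterministic under a fixed seed", {
  cfg <- scenario_config(n_stations = 2, months = 30, n_diatom = 6,
                         n_dinoflagellate = 4, n_other = 2)
  a <- simulate_community(cfg, seed = 42)
  b <- simulate_community(cfg, seed = 42)
  expect_equal(a$observations, b$observations)
  expect_equal(a$environment, b$environment)
  expect_equal(a$pool, b$pool)
  c <- simulate_community(cfg, seed = 43)
  expect_false(isTRUE(all.equal(a$observations, c$observations)))
})

test_that("the species pool has the requested structure", {
  cfg <- scenario_config(n_diatom = 10, n_dinoflagellate = 10, n_other = 5)
  pool <- generate_species_pool(cfg, seed = 3)
  expect_equal(nrow(pool), 25)
  counts <- table(pool$group)[c("diatom", "dinoflagellate", "other")]
  expect_equal(unname(counts), c(10L, 10L, 5L), ignore_attr = TRUE)
  expect_true(all(pool$v0 > 0))
  # bottom-quartile flag: floor(25 * 0.25) = 6 species
  expect_equal(sum(pool$small), 6)
  expect_true(max(pool$v0[pool$small]) <= min(pool$v0[!pool$small]))
  # lognormal pool spans several orders of magnitude
  big <- generate_species_pool(scenario_config(n_diatom = 120,
                                               n_dinoflagellate = 60,
                                               n_other = 20), seed = 1)
  expect_lt(quantile(big$v0, 0.02), 1e2)
  expect_gt(quantile(big$v0, 0.98), 1e5)
})

test_that("noise-free observations follow the closed-form size model", {
  # gamma = beta = 0: biovolume constant over time for every species
  cfg0 <- noise_free(n_stations = 1, months = 36, n_diatom = 4,
                     n_dinoflagellate = 3, n_other = 2,
                     beta_mean = 0, beta_sd = 0, gamma_mean = 0,
                     gamma_sd = 0)
  sim0 <- simulate_community(cfg0, seed = 5)
  spread <- dplyr::summarise(
    dplyr::group_by(sim0$observations, species_id),
    d = diff(range(cell_biovolume)))
  expect_lt(max(spread$d), 1e-9)

  # beta = 0, gamma = -0.002: log-size slope is exactly -0.002/month
  cfg1 <- noise_free(n_stations = 1, months = 120, n_diatom = 4,
                     n_dinoflagellate = 3, n_other = 2,
                     beta_mean = 0, beta_sd = 0, gamma_mean = -0.002,
                     gamma_sd = 0)
  sim1 <- simulate_community(cfg1, seed = 5)
  series <- species_size_series(sim1$observations, scope = "station")
  slopes <- fit_trends(series, value = biovolume, by = "species_id",
                       log_scale = TRUE)
  expect_equal(slopes$slope_month, rep(-0.002, nrow(slopes)),
               tolerance = 1e-10)
})

test_that("composition drift produces a matching Small% trend", {
  cfg <- scenario_config(n_stations = 1, months = 240, n_diatom = 12,
                         n_dinoflagellate = 8, n_other = 4,
                         delta = -0.003)
  sim <- simulate_community(cfg, seed = 7)
  small <- small_fraction(sim$observations,
                          classify_small_species(sim$observations))
  tr <- linear_trend(small, value = small_fraction)
  expect_lt(tr$slope_month, 0)
  expect_lt(tr$p, 0.05)
})

test_that("truth summary gives closed-form injected slopes", {
  cfg0 <- noise_free(n_stations = 2, months = 60, n_diatom = 4,
                     n_dinoflagellate = 3, n_other = 2,
                     beta_mean = 0, beta_sd = 0, gamma_mean = 0,
                     gamma_sd = 0, delta = 0)
  tr0 <- truth_summary(cfg0, seed = 1)
  expect_true(all(tr0$species_slopes$slope_month == 0))
  expect_equal(tr0$small_trend_sign, 0)

  # pure warming: slope = beta * w / 12 per month
  cfgw <- noise_free(n_stations = 2, months = 60, n_diatom = 4,
                     n_dinoflagellate = 3, n_other = 2,
                     beta_mean = -0.03, beta_sd = 0, gamma_mean = 0,
                     gamma_sd = 0, warming = c(0.024, 0.048))
  trw <- truth_summary(cfgw, seed = 1)
  s1 <- trw$species_slopes[trw$species_slopes$station_id == "S01", ]
  expect_equal(unique(s1$slope_month), -0.03 * 0.024 / 12)
  # deterministic regeneration
  trw2 <- truth_summary(cfgw, seed = 1)
  expect_equal(trw$partition, trw2$partition)
})

test_that("noise-free estimators recover injected slopes exactly", {
  cfg <- noise_free(n_stations = 1, months = 120, n_diatom = 4,
                    n_dinoflagellate = 3, n_other = 2,
                    seasonal_amp = 0, beta_mean = -0.02, beta_sd = 0,
                    gamma_mean = -0.001, gamma_sd = 0)
  sim <- simulate_community(cfg, seed = 9)
  injected <- sim$truth$species_slopes
  series <- species_size_series(sim$observations, scope = "station")
  est <- fit_trends(series, value = biovolume, by = "species_id",
                    log_scale = TRUE)
  merged <- dplyr::inner_join(est, injected,
                              by = "species_id")
  expect_lt(max(abs(merged$slope_month.x - merged$slope_month.y)), 1e-8)
})

test_that("scenario validation rejects impossible configurations", {
  expect_error(scenario_config(months = 12), "24")
  expect_error(scenario_config(sd_size = -1), "SD")
  expect_error(scenario_config(bloom_meanlog = -0.5), "1")
  expect_error(scenario_config(detect_prob = 0), "detect_prob")
})
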