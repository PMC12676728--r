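#' Scenario configuration for the synthetic coastal community
#'
#' Defines a multi-station monthly monitoring scenario with known ground
#' truth: station-specific warming and phosphate decline, annual seasonality
#' (period 12), a lognormal species pool in three taxonomic groups, per-species
#' temperature-size coefficients (`beta`, log-size change per degree C) and
#' intrinsic size drifts (`gamma`, log-size change per month), a composition
#' drift (`delta`, per-month log shift of abundance away from bottom-quartile
#' species when negative), and sporadic multiplicative bloom spikes.
#'
#' The default scenario is the desk-scale validation condition used throughout
#' the package's tests: 5 stations, 240 months, 50 species (25 diatoms, 17
#' dinoflagellates, 8 others). [scenario_hk()] gives a preset at the scale of
#' a two-decade 25-station coastal monitoring programme.
#'
#' @param n_stations Number of monitoring stations.
#' @param months Number of consecutive monthly samples (>= 24).
#' @param n_diatom,n_dinoflagellate,n_other Species counts per group.
#' @param t0 Baseline temperatures per station (degC); recycled.
#' @param warming Warming slopes per station (degC per year).
#' @param seasonal_amp Seasonal temperature amplitude (degC).
#' @param seasonal_phase Month index (0-11) of the temperature maximum.
#' @param po4_0 Baseline phosphate per station (ug/L).
#' @param po4_slope Phosphate trend (ug/L per year, typically negative).
#' @param po4_floor Lower bound for phosphate (ug/L).
#' @param din_0,din_slope DIN baseline (mg/L) and trend (mg/L per year).
#' @param salinity_0 Baseline salinity (PSU).
#' @param tref Reference temperature for the size response (degC).
#' @param v0_meanlog,v0_sdlog Lognormal parameters of baseline cell biovolume
#'   (um^3); defaults span roughly 10^1 to 10^6 um^3.
#' @param beta_mean,beta_sd Temperature-size coefficient distribution
#'   (per degC on log size; the mean of -0.025 reflects the ~2.5% volume loss
#'   per degC reported for protists).
#' @param gamma_mean,gamma_sd Intrinsic log-size drift distribution
#'   (per month).
#' @param abund_meanlog,abund_sdlog Lognormal abundance-weight parameters
#'   (cells/L).
#' @param season_abund_amp Max per-species seasonal amplitude on log abundance.
#' @param delta Composition drift: per-month additive shift on the log
#'   abundance of bottom-quartile (small) species; negative values shift the
#'   community toward larger species.
#' @param bloom_prob Probability that a station-month carries a bloom spike.
#' @param bloom_meanlog,bloom_sdlog Lognormal parameters of the bloom
#'   multiplier (>= 1 enforced). No field bloom-frequency statistics inform
#'   these defaults; they are placeholders chosen for qualitative realism.
#' @param sd_size,sd_abund Lognormal noise SDs for size and abundance.
#' @param sd_temp,sd_po4,sd_din,sd_salinity Environmental noise SDs.
#' @param detect_prob Probability that a present species is recorded in a
#'   sample (microscopy detection/occupancy thinning).
#' @param small_q Quantile defining the small-species set in the pool.
#' @param stations_per_zone Stations grouped into each water control zone.
#' @param start_date First sampling month.
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(n_stations = 5, months = 240,
                            n_diatom = 25, n_dinoflagellate = 17, n_other = 8,
                            t0 = NULL, warming = NULL,
                            seasonal_amp = 4, seasonal_phase = 7,
                            po4_0 = NULL, po4_slope = -0.5, po4_floor = 0.5,
                            din_0 = 0.3, din_slope = 0, salinity_0 = 31,
                            tref = 22,
                            v0_meanlog = log(10) * 3.5, v0_sdlog = 2.3,
                            beta_mean = -0.025, beta_sd = 0.01,
                            gamma_mean = -3e-4, gamma_sd = 4e-4,
                            abund_meanlog = log(1000), abund_sdlog = 1.5,
                            season_abund_amp = 0.5,
                            delta = -0.003,
                            bloom_prob = 0.02, bloom_meanlog = log(10),
                            bloom_sdlog = 0.5,
                            sd_size = 0.2, sd_abund = 0.8,
                            sd_temp = 0.5, sd_po4 = 2, sd_din = 0.05,
                            sd_salinity = 0.5,
                            detect_prob = 0.9, small_q = 0.25,
                            stations_per_zone = 3,
                            start_date = as.Date("2000-01-01")) {
  cfg <- list(
    n_stations = n_stations, months = months,
    n_diatom = n_diatom, n_dinoflagellate = n_dinoflagellate,
    n_other = n_other,
    t0 = rep_len(t0 %||% seq(21.5, 23.5, length.out = n_stations), n_stations),
    warming = rep_len(warming %||% seq(0.02, 0.06, length.out = n_stations),
                      n_stations),
    seasonal_amp = rep_len(seasonal_amp, n_stations),
    seasonal_phase = rep_len(seasonal_phase, n_stations),
    po4_0 = rep_len(po4_0 %||% seq(15, 45, length.out = n_stations),
                    n_stations),
    po4_slope = rep_len(po4_slope, n_stations),
    po4_floor = po4_floor,
    din_0 = rep_len(din_0, n_stations),
    din_slope = rep_len(din_slope, n_stations),
    salinity_0 = rep_len(salinity_0, n_stations),
    tref = tref,
    v0_meanlog = v0_meanlog, v0_sdlog = v0_sdlog,
    beta_mean = beta_mean, beta_sd = beta_sd,
    gamma_mean = gamma_mean, gamma_sd = gamma_sd,
    abund_meanlog = abund_meanlog, abund_sdlog = abund_sdlog,
    season_abund_amp = season_abund_amp,
    delta = delta,
    bloom_prob = bloom_prob, bloom_meanlog = bloom_meanlog,
    bloom_sdlog = bloom_sdlog,
    sd_size = sd_size, sd_abund = sd_abund, sd_temp = sd_temp,
    sd_po4 = sd_po4, sd_din = sd_din, sd_salinity = sd_salinity,
    detect_prob = detect_prob, small_q = small_q,
    stations_per_zone = stations_per_zone,
    start_date = as.Date(start_date)
  )
  if (cfg$months < 24) abort("`months` must be >= 24 (two full annual cycles).")
  if (cfg$n_diatom + cfg$n_dinoflagellate + cfg$n_other < 4) {
    abort("At least 4 species are required.")
  }
  if (cfg$bloom_meanlog < 0) abort("Bloom magnitude must be >= 1 (meanlog >= 0).")
  sds <- c(cfg$sd_size, cfg$sd_abund, cfg$sd_temp, cfg$sd_po4, cfg$sd_din,
           cfg$sd_salinity, cfg$bloom_sdlog)
  if (any(sds < 0)) abort("All noise SDs must be >= 0.")
  if (cfg$detect_prob <= 0 || cfg$detect_prob > 1) {
    abort("`detect_prob` must be in (0, 1].")
  }
  structure(cfg, class = "scenario_config")
}

#' @rdname scenario_config
#' @param ... Overrides passed on to [scenario_config()].
#' @export
scenario_hk <- function(...) {
  scenario_config(n_stations = 25, months = 252,
                  n_diatom = 91, n_dinoflagellate = 60, n_other = 18, ...)
}

#' Offset scenario: species miniaturization masked by composition drift
#'
#' All species shrink (universal within-species miniaturization) while the
#' composition drifts toward larger species, so the two partition components
#' nearly cancel and the community mean size shows little net trend. With a
#' bottom-quartile abundance share near 0.25, the composition component can
#' contribute at most `-log(1 - 0.25) ~ 0.29` on the log scale over the
#' record, so the within-species loss is set to a comparable 0.24
#' (`gamma = -0.001/month` over 240 months) against a strong drift
#' `delta = -0.008/month`.
#'
#' @param ... Overrides passed on to [scenario_config()].
#' @return A `scenario_config`.
#' @export
scenario_offset <- function(...) {
  scenario_config(gamma_mean = -0.001, gamma_sd = 1e-4,
                  beta_mean = -0.002, beta_sd = 0.001,
                  delta = -0.008, ...)
}

station_ids <- function(cfg) sprintf("S%02d", seq_len(cfg$n_stations))

station_zones <- function(cfg) {
  sprintf("Z%02d", ceiling(seq_len(cfg$n_stations) / cfg$stations_per_zone))
}

scenario_dates <- function(cfg) {
  seq(cfg$start_date, by = "month", length.out = cfg$months)
}

#' Generate the environmental table of a scenario
#'
#' Temperature follows `T0 + w t/12 + A cos(2 pi (t - phase)/12) + noise`
#' per station; phosphate declines linearly (floored at a small positive
#' value) with mild winter-peaking seasonality; DIN and salinity carry
#' seasonality and noise only by default. Deterministic given `seed`.
#'
#' @param cfg A [scenario_config()].
#' @param seed Integer seed.
#' @return Long environment tibble (`station_id`, `date`, `param`, `value`,
#'   `below_detection`).
#' @export
generate_environment <- function(cfg, seed = 1) {
  stopifnot(inherits(cfg, "scenario_config"))
  set.seed(seed)
  t <- rep(seq_len(cfg$months) - 1L, times = cfg$n_stations)
  s <- rep(seq_len(cfg$n_stations), each = cfg$months)
  n <- length(t)
  temperature <- cfg$t0[s] + cfg$warming[s] * t / 12 +
    cfg$seasonal_amp[s] * cos(2 * pi * (t - cfg$seasonal_phase[s]) / 12) +
    rnorm(n, 0, cfg$sd_temp)
  po4 <- pmax(cfg$po4_floor,
              cfg$po4_0[s] + cfg$po4_slope[s] * t / 12 +
                0.1 * cfg$po4_0[s] * cos(2 * pi * (t - 1) / 12) +
                rnorm(n, 0, cfg$sd_po4))
  din <- pmax(0.001,
              cfg$din_0[s] + cfg$din_slope[s] * t / 12 +
                0.1 * cfg$din_0[s] * cos(2 * pi * t / 12) +
                rnorm(n, 0, cfg$sd_din))
  salinity <- cfg$salinity_0[s] - 1.5 * cos(2 * pi * (t - 7) / 12) +
    rnorm(n, 0, cfg$sd_salinity)
  base <- tibble::tibble(
    station_id = station_ids(cfg)[s],
    date = scenario_dates(cfg)[t + 1L],
    temperature = temperature, PO4 = po4, DIN = din, salinity = salinity
  )
  out <- tidyr::pivot_longer(base, cols = c("temperature", "PO4", "DIN",
                                            "salinity"),
                             names_to = "param", values_to = "value")
  out$below_detection <- FALSE
  dplyr::arrange(out, .data$station_id, .data$date, .data$param)
}

#' Generate the species pool of a scenario
#'
#' Draws per-species baseline biovolumes (lognormal), temperature-size
#' coefficients, intrinsic drifts, abundance weights and seasonal phenology,
#' and flags the bottom `small_q` quantile of the pool by baseline biovolume
#' as "small" (the set targeted by the composition drift).
#'
#' @inheritParams generate_environment
#' @return Tibble with one row per species: `species_id`, `group`, `v0`,
#'   `beta`, `gamma`, `weight`, `season_amp`, `season_phase`, `small`.
#' @export
generate_species_pool <- function(cfg, seed = 1) {
  stopifnot(inherits(cfg, "scenario_config"))
  set.seed(seed)
  n <- cfg$n_diatom + cfg$n_dinoflagellate + cfg$n_other
  pool <- tibble::tibble(
    species_id = sprintf("sp%03d", seq_len(n)),
    group = rep(phyto_groups,
                times = c(cfg$n_diatom, cfg$n_dinoflagellate, cfg$n_other)),
    v0 = rlnorm(n, cfg$v0_meanlog, cfg$v0_sdlog),
    beta = rnorm(n, cfg$beta_mean, cfg$beta_sd),
    gamma = rnorm(n, cfg$gamma_mean, cfg$gamma_sd),
    weight = rlnorm(n, cfg$abund_meanlog, cfg$abund_sdlog),
    season_amp = runif(n, 0, cfg$season_abund_amp),
    season_phase = runif(n, 0, 12)
  )
  n_small <- max(1L, floor(n * cfg$small_q))
  ord <- order(pool$v0, pool$species_id)
  pool$small <- FALSE
  pool$small[ord[seq_len(n_small)]] <- TRUE
  pool
}

#' Generate the observation table of a scenario
#'
#' Cell biovolume follows
#' `v0 exp(gamma t) exp(beta (T - Tref)) exp(size noise)`; log abundance is
#' the species weight plus seasonal phenology, the composition drift
#' (`delta t` on small-flagged species), lognormal noise, and an occasional
#' multiplicative bloom spike applied to one high-weight species in a
#' station-month. Species rows are thinned with `detect_prob`; zero-abundance
#' rows never occur (abundance is lognormal).
#'
#' @param pool Species pool from [generate_species_pool()].
#' @param environment Environment table from [generate_environment()] (must
#'   share the scenario's station/month grid).
#' @inheritParams generate_environment
#' @return Observation tibble in the format of [read_observations()].
#' @export
generate_observations <- function(pool, environment, cfg, seed = 1) {
  stopifnot(inherits(cfg, "scenario_config"))
  set.seed(seed)
  temp <- environment[environment$param == "temperature",
                      c("station_id", "date", "value")]
  names(temp)[3] <- "temperature"
  temp <- add_lagged_month(temp, origin = cfg$start_date)
  zones <- setNames(station_zones(cfg), station_ids(cfg))

  grid <- tidyr::crossing(temp, pool)
  n <- nrow(grid)
  log_v <- log(grid$v0) + grid$gamma * grid$lagged_month +
    grid$beta * (grid$temperature - cfg$tref) +
    rnorm(n, 0, cfg$sd_size)
  log_n <- log(grid$weight) +
    grid$season_amp * cos(2 * pi * (grid$lagged_month - grid$season_phase) / 12) +
    ifelse(grid$small, cfg$delta * grid$lagged_month, 0) +
    rnorm(n, 0, cfg$sd_abund)

  # Bloom spikes: one randomly chosen high-weight species per affected
  # station-month gets a multiplicative abundance boost.
  sm <- dplyr::distinct(grid, .data$station_id, .data$date)
  bloom_here <- runif(nrow(sm)) < cfg$bloom_prob
  abundant <- pool$species_id[pool$weight >= quantile(pool$weight, 0.75)]
  sm$bloom_species <- sample(abundant, nrow(sm), replace = TRUE)
  sm$bloom_mult <- pmax(1, rlnorm(nrow(sm), cfg$bloom_meanlog, cfg$bloom_sdlog))
  sm$bloom_mult[!bloom_here] <- 1
  grid <- dplyr::left_join(grid, sm, by = c("station_id", "date"))
  is_bloom <- grid$species_id == grid$bloom_species & grid$bloom_mult > 1
  log_n <- log_n + ifelse(is_bloom, log(grid$bloom_mult), 0)

  keep <- if (cfg$detect_prob < 1) runif(n) < cfg$detect_prob else rep(TRUE, n)
  out <- tibble::tibble(
    station_id = grid$station_id,
    wcz = unname(zones[grid$station_id]),
    date = grid$date,
    species_id = grid$species_id,
    group = grid$group,
    abundance = exp(log_n),
    cell_biovolume = exp(log_v)
  )[keep, ]
  dplyr::arrange(out, .data$station_id, .data$date, .data$species_id)
}

#' Simulate a full scenario
#'
#' Convenience wrapper generating environment, species pool, observations and
#' the ground-truth summary with sub-seeds derived from one seed.
#'
#' @inheritParams generate_environment
#' @return A `community_simulation` list with elements `observations`,
#'   `environment`, `pool`, `truth`, `cfg`, `seed`.
#' @export
simulate_community <- function(cfg = scenario_config(), seed = 1) {
  env <- generate_environment(cfg, seed)
  pool <- generate_species_pool(cfg, seed + 1L)
  obs <- generate_observations(pool, env, cfg, seed + 2L)
  structure(list(observations = obs, environment = env, pool = pool,
                 truth = truth_summary(cfg, seed), cfg = cfg, seed = seed),
            class = "community_simulation")
}

#' Ground truth injected by a scenario
#'
#' Recomputes, deterministically from the configuration and seed, the
#' quantities the estimators are meant to recover: per-species injected
#' log-size slopes (intrinsic drift plus the warming-mediated
#' temperature-size effect, `gamma + beta * w/12` per month), the sign of the
#' Small% trend (the sign of `delta`), and the exact two-window partition
#' components of a noise-free, bloom-free regeneration of the scenario.
#'
#' @inheritParams generate_environment
#' @param windows Two-window specification passed to
#'   [partition_community_change()]; `NULL` for the default first/last
#'   36 months.
#' @return A `truth_record` list with `species_slopes` (per species, per
#'   station and regional, log um^3 per month), `small_trend_sign`,
#'   `partition` (per station), and `seed`.
#' @export
truth_summary <- function(cfg = scenario_config(), seed = 1, windows = NULL) {
  stopifnot(inherits(cfg, "scenario_config"))
  pool <- generate_species_pool(cfg, seed + 1L)
  per_station <- tidyr::crossing(
    pool[c("species_id", "beta", "gamma")],
    tibble::tibble(station_id = station_ids(cfg), warming = cfg$warming)
  )
  per_station$slope_month <- per_station$gamma +
    per_station$beta * per_station$warming / 12
  regional <- dplyr::summarise(
    dplyr::group_by(per_station, .data$species_id),
    slope_month = mean(.data$slope_month), .groups = "drop")

  cfg0 <- cfg
  cfg0$sd_size <- cfg0$sd_abund <- cfg0$sd_temp <- cfg0$sd_po4 <-
    cfg0$sd_din <- cfg0$sd_salinity <- 0
  cfg0$bloom_prob <- 0
  cfg0$detect_prob <- 1
  env0 <- generate_environment(cfg0, seed)
  obs0 <- generate_observations(pool, env0, cfg0, seed + 2L)
  w0 <- if (is.null(windows)) NULL else windows[[1]]
  w1 <- if (is.null(windows)) NULL else windows[[2]]
  part <- partition_community_change(obs0, scope = "station",
                                     window0 = w0, window1 = w1)
  structure(list(
    species_slopes = dplyr::select(per_station, "species_id", "station_id",
                                   "slope_month"),
    regional_slopes = regional,
    small_trend_sign = sign(cfg$delta),
    partition = part,
    seed = seed
  ), class = "truth_record")
}
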