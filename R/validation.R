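#' Parameter-recovery study on the synthetic community
#'
#' Repeatedly simulates the scenario, re-estimates the injected quantities
#' with the package's own estimators, and summarizes recovery:
#' per-species regional log-size slopes (OLS on the regional size series,
#' compared to the injected `gamma + beta w/12`), the sign of the regional
#' Small% trend (compared to `sign(delta)`), and -- optionally -- the
#' Shapley driver rankings: temperature for species size (gradient-boosted
#' model on within-species centred log biovolume against the monthly
#' environmental factors) and phosphate for Small% (random-forest model on
#' station-year means, where annual averaging removes the seasonal cycle so
#' the attribution addresses the long-term signal).
#'
#' @param cfg A [scenario_config()].
#' @param n_seeds Number of independent simulations.
#' @param seed Base seed; replicate `k` uses `seed + 1000 k`.
#' @param drivers Also run the (slower) Shapley driver-ranking recovery.
#' @param features Environmental factors used by the driver models.
#' @return A `recovery_study` list: `species` (per seed and species,
#'   estimated vs injected slope), `per_seed` (Small% slope and sign match,
#'   driver ranks), and `summary` (one-row tibble with
#'   `median_slope_rel_err` computed on per-species medians across seeds,
#'   `small_sign_match_rate`, `temp_top1_rate`, `po4_top2_rate`).
#' @export
recovery_study <- function(cfg = scenario_config(), n_seeds = 20, seed = 1,
                           drivers = TRUE,
                           features = c("temperature", "PO4", "DIN",
                                        "salinity")) {
  # one fixed species pool: the injected slopes are the estimand, and each
  # replicate draws a fresh stochastic realization around them
  pool <- generate_species_pool(cfg, seed + 1L)
  injected_regional <- tibble::tibble(
    species_id = pool$species_id,
    injected = pool$gamma + pool$beta * mean(cfg$warming) / 12)
  runs <- purrr::map(seq_len(n_seeds), function(k) {
    s <- seed + 1000L * k
    env <- generate_environment(cfg, seed = s)
    obs <- generate_observations(pool, env, cfg, seed = s + 2L)
    sim <- list(observations = obs, environment = env)
    series <- species_size_series(sim$observations, scope = "region")
    est <- fit_trends(series, value = biovolume, by = "species_id",
                      log_scale = TRUE)
    est <- est[est$method == "lm", c("species_id", "slope_month")]
    species <- dplyr::inner_join(
      dplyr::rename(est, estimated = "slope_month"),
      injected_regional, by = "species_id")
    species$seed <- s

    small <- small_fraction(sim$observations,
                            classify_small_species(sim$observations),
                            scope = "region")
    small_slope <- linear_trend(small, value = small_fraction)$slope_month

    temp_rank <- po4_rank <- NA_integer_
    if (drivers) {
      joined <- join_env(sim$observations, sim$environment)
      joined$clogv <- log(joined$cell_biovolume)
      joined <- dplyr::mutate(
        dplyr::group_by(joined, .data$species_id),
        clogv = .data$clogv - mean(.data$clogv))
      joined <- dplyr::ungroup(joined)
      temp_rank <- .driver_rank(
        x = as.matrix(joined[features]), y = joined$clogv,
        learner = "xgboost", feature = "temperature", seed = s)

      sm_st <- small_fraction(sim$observations,
                              classify_small_species(sim$observations),
                              scope = "station")
      js <- dplyr::inner_join(sm_st, env_wide(sim$environment),
                              by = c("scope_id" = "station_id",
                                     "date" = "date"))
      js$year <- format(js$date, "%Y")
      ann <- dplyr::summarise(
        dplyr::group_by(js, .data$scope_id, .data$year),
        small_fraction = mean(.data$small_fraction),
        dplyr::across(dplyr::all_of(features), mean), .groups = "drop")
      po4_rank <- .driver_rank(
        x = as.matrix(ann[features]), y = ann$small_fraction,
        learner = "ranger", feature = "PO4", seed = s)
    }
    list(species = species,
         per_seed = tibble::tibble(seed = s, small_slope = small_slope,
                                   sign_match = sign(small_slope) ==
                                     sign(cfg$delta),
                                   temp_rank_size = temp_rank,
                                   po4_rank_small = po4_rank))
  })
  species <- purrr::map_dfr(runs, "species")
  per_seed <- purrr::map_dfr(runs, "per_seed")
  per_species <- dplyr::summarise(
    dplyr::group_by(species, .data$species_id),
    estimated = median(.data$estimated),
    injected = .data$injected[1], .groups = "drop")
  per_species$rel_err <- abs(per_species$estimated - per_species$injected) /
    abs(per_species$injected)
  summary <- tibble::tibble(
    median_slope_rel_err = median(per_species$rel_err),
    small_sign_match_rate = mean(per_seed$sign_match),
    temp_top1_rate = if (drivers) mean(per_seed$temp_rank_size == 1)
                     else NA_real_,
    po4_top2_rate = if (drivers) mean(per_seed$po4_rank_small <= 2)
                    else NA_real_)
  structure(list(species = species, per_species = per_species,
                 per_seed = per_seed, summary = summary),
            class = "recovery_study")
}

# Fit one learner and return the Shapley importance rank of `feature`.
.driver_rank <- function(x, y, learner, feature, seed,
                         n_rows = 150, n_background = 50) {
  if (learner == "xgboost") {
    fit <- xgboost::xgb.train(
      params = list(max_depth = 4, eta = 0.1, nthread = 1,
                    objective = "reg:squarederror"),
      data = xgboost::xgb.DMatrix(x, label = y, nthread = 1),
      nrounds = 100, verbose = 0)
    pf <- function(m) {
      as.numeric(predict(fit, xgboost::xgb.DMatrix(m, nthread = 1)))
    }
  } else {
    fit <- ranger::ranger(x = as.data.frame(x), y = y, num.trees = 300,
                          seed = seed, num.threads = 1)
    pf <- function(m) {
      predict(fit, data = as.data.frame(m), num.threads = 1)$predictions
    }
  }
  set.seed(seed)
  xr <- x[sample.int(nrow(x), min(n_rows, nrow(x))), , drop = FALSE]
  bg <- x[sample.int(nrow(x), min(n_background, nrow(x))), , drop = FALSE]
  sh <- shapley_values(pf, xr, background = bg, mode = "exact")
  gi <- global_importance(sh)
  gi$rank[gi$feature == feature]
}

#' @export
print.recovery_study <- function(x, ...) {
  cat("<recovery_study>\n")
  print(x$summary)
  invisible(x)
}

#' Type-I error of the temperature-size rule test under a null scenario
#'
#' Simulates a reduced scenario with no temperature-size coupling and no
#' intrinsic drift (`beta = gamma = 0`), applies [tsr_test()] to every
#' species, and reports the pooled fraction of tests rejecting at `alpha`.
#' Intrinsic drift is also zeroed because, under station warming, elapsed
#' time confounds temperature for a test that (like the field analysis)
#' holds only the measured environmental factors constant.
#'
#' @param n_seeds Number of simulated null datasets.
#' @param seed Base seed.
#' @param alpha Nominal level.
#' @param cfg Null scenario; the default is 2 stations x 120 months x 12
#'   species.
#' @return A tibble with `type1_rate`, `n_tests`, `alpha`.
#' @export
tsr_type1_study <- function(n_seeds = 200, seed = 1, alpha = 0.05,
                            cfg = NULL) {
  cfg <- cfg %||% scenario_config(
    n_stations = 2, months = 120, n_diatom = 6, n_dinoflagellate = 4,
    n_other = 2, beta_mean = 0, beta_sd = 0, gamma_mean = 0, gamma_sd = 0)
  ps <- purrr::map(seq_len(n_seeds), function(k) {
    sim <- simulate_community(cfg, seed = seed + 1000L * k)
    res <- tsr_test(sim$observations, sim$environment,
                    covariates = c("PO4", "DIN", "salinity"), alpha = alpha)
    res$p
  })
  p <- unlist(ps)
  p <- p[!is.na(p)]
  tibble::tibble(type1_rate = mean(p < alpha), n_tests = length(p),
                 alpha = alpha)
}

#' Offset-scenario study: miniaturization masked by composition drift
#'
#' Runs the full pipeline on [scenario_offset()] replicates and summarizes
#' how the station-level community trend and scenario labels come out. In
#' this configuration every species shrinks while abundance drifts toward
#' larger species, so the community mean size should show no significant
#' trend at most stations and the pipeline should label stations as
#' scenario `ii`.
#'
#' @param n_seeds Number of replicates.
#' @param seed Base seed.
#' @param n_perm ANOSIM permutations per pipeline run.
#' @return A tibble with pooled `frac_community_none`, `frac_scenario_ii`,
#'   `n_stations` across replicates.
#' @export
offset_scenario_study <- function(n_seeds = 5, seed = 1, n_perm = 99) {
  out <- purrr::map_dfr(seq_len(n_seeds), function(k) {
    sim <- simulate_community(scenario_offset(), seed = seed + 1000L * k)
    res <- suppressWarnings(run_pipeline(sim, n_perm = n_perm,
                                         seed = seed + 1000L * k))
    res$scenario
  })
  tibble::tibble(
    frac_community_none = mean(out$community_class == "none"),
    frac_scenario_ii = mean(out$scenario == "ii"),
    n_stations = nrow(out))
}
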