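#' Run the full miniaturization analysis pipeline
#'
#' Orchestrates the complete analysis on one observation/environment pair:
#' size metrics (species series for the top abundant species, community mean
#' size, Small%), raw and seasonally adjusted linear trends with BH
#' correction, the exact two-window partition of community mean-size change
#' with per-station scenario classification, ANOSIM community-turnover tests
#' for temporal and spatial groupings, and environmental driver attribution
#' (species-factor correlations, response-group clustering, per-species TSR
#' partial effects, Small% partial effects, and Shapley attribution of a
#' random-forest Small% model). Deterministic given `seed`.
#'
#' @param observations Observation tibble (or a `community_simulation`).
#' @param environment Long environment tibble (ignored when `observations`
#'   is a simulation).
#' @param top_counts Per-group representative species counts.
#' @param alpha Significance level for trend classes.
#' @param period Season length for the decomposition.
#' @param windows Optional list of two lagged-month windows for the
#'   partition.
#' @param n_perm ANOSIM permutations.
#' @param anosim_groupings Grouping factors tested by ANOSIM.
#' @param shapley_rows,shapley_background Row counts for the Shapley
#'   explanation and background sets.
#' @param seed Integer seed for every stochastic step.
#' @param out_dir Optional directory: when given, every table is written as
#'   a tidy CSV plus a `run_log.txt` with the seed and a configuration hash.
#' @return A `pipeline_result` list of tibbles: `species_trends`,
#'   `community_trends`, `small_fraction_trends`, `partition`, `anosim`,
#'   `correlations`, `clusters`, `partial_effects`, `shapley`, plus
#'   `scenario` (per station) and `meta`.
#' @export
run_pipeline <- function(observations, environment = NULL,
                         top_counts = c(diatom = 10, dinoflagellate = 10,
                                        other = 5),
                         alpha = 0.05, period = 12, windows = NULL,
                         n_perm = 199,
                         anosim_groupings = c("year", "month", "station_id",
                                              "wcz"),
                         shapley_rows = 150, shapley_background = 50,
                         seed = 1, out_dir = NULL) {
  if (inherits(observations, "community_simulation")) {
    environment <- observations$environment
    observations <- observations$observations
  }
  if (is.null(environment)) abort("An environment table is required.")
  origin <- min(parse_year_month(observations$date))
  meta <- tibble::tibble(
    key = c("seed", "alpha", "period", "n_perm", "origin", "config_hash"),
    value = c(seed, alpha, period, n_perm, format(origin),
              rlang::hash(list(top_counts, alpha, period, windows, n_perm,
                               anosim_groupings, shapley_rows,
                               shapley_background, seed)))
  )

  # --- size metrics and trends -------------------------------------------
  top <- select_top_species(observations, top_counts)
  sp_series <- species_size_series(observations, species = top$species_id,
                                   scope = "region", origin = origin)
  species_trends <- fit_trends(sp_series, value = biovolume,
                               by = "species_id", alpha = alpha,
                               deseason = TRUE, period = period)

  comm <- community_size(observations, scope = "station", origin = origin)
  community_trends <- fit_trends(comm, value = mean_size, by = "scope_id",
                                 alpha = alpha, deseason = TRUE,
                                 period = period)

  small_set <- classify_small_species(observations)
  small <- small_fraction(observations, small_set, scope = "station",
                          origin = origin)
  small_trends <- fit_trends(small, value = small_fraction, by = "scope_id",
                             alpha = alpha, deseason = TRUE, period = period)

  # --- partition and scenario classification ----------------------------
  part <- partition_community_change(
    observations, scope = "station",
    window0 = if (is.null(windows)) NULL else windows[[1]],
    window1 = if (is.null(windows)) NULL else windows[[2]],
    origin = origin)

  station_species <- fit_trends(
    species_size_series(observations, species = top$species_id,
                        scope = "station", origin = origin),
    value = biovolume, by = c("scope_id", "species_id"), alpha = alpha)
  pick <- function(df, id) {
    cl <- df$class[df$method == "lm" & df$scope_id == id]
    if (length(cl) == 0 || is.na(cl[1])) "none" else cl[1]
  }
  scenario <- purrr::map_dfr(sort(unique(comm$scope_id)), function(st) {
    spc <- station_species[station_species$method == "lm" &
                             station_species$scope_id == st, ]
    sc <- scenario_classify(
      species_classes = spc$class,
      small_class = pick(small_trends, st),
      community_class = pick(community_trends, st))
    dplyr::bind_cols(tibble::tibble(scope_id = st), sc)
  })
  part <- dplyr::left_join(part, scenario[c("scope_id", "scenario")],
                           by = "scope_id")

  # --- community turnover -------------------------------------------------
  mat <- abundance_matrix(observations)
  d <- bray_curtis(mat)
  anosim_tbl <- purrr::imap_dfr(anosim_groupings, function(gr, i) {
    res <- tryCatch(anosim(d, gr, n_perm = n_perm, seed = seed + i),
                    error = function(e) NULL)
    if (is.null(res)) {
      # grouping degenerate in this dataset (e.g. a single zone)
      return(tibble::tibble(grouping = gr, statistic = NA_real_,
                            p = NA_real_, n_perm = n_perm,
                            n_samples = nrow(mat)))
    }
    tibble::tibble(grouping = gr, statistic = res$statistic, p = res$p,
                   n_perm = res$n_perm, n_samples = res$n_samples)
  })

  # --- driver attribution -------------------------------------------------
  corr <- species_env_correlations(observations, environment,
                                   species = top$species_id)
  clusters <- cluster_response_groups(corr)
  tsr <- tsr_test(observations, environment, species = top$species_id)
  partial_effects <- dplyr::mutate(tsr, response = "log_biovolume",
                                   focal = "temperature")

  joined_small <- dplyr::inner_join(small, env_wide(environment),
                                    by = c("scope_id" = "station_id",
                                           "date" = "date"))
  factors <- setdiff(unique(environment$param), character(0))
  small_pe <- purrr::map_dfr(c("PO4", "temperature"), function(f) {
    if (!f %in% names(joined_small)) return(tibble::tibble())
    pe <- tryCatch(
      partial_effect(joined_small, response = "small_fraction", focal = f,
                     covariates = setdiff(intersect(factors,
                                                    names(joined_small)), f),
                     group = "scope_id"),
      error = function(e) NULL)
    if (is.null(pe)) return(tibble::tibble())
    tibble::tibble(species_id = NA_character_, estimate = pe$estimate,
                   se = pe$se, p = pe$p, n = pe$n, tsr_class = NA_character_,
                   response = "small_fraction", focal = f)
  })
  partial_effects <- dplyr::bind_rows(partial_effects, small_pe)

  shap_data <- joined_small[complete.cases(joined_small[c("small_fraction",
                                                          factors)]), ]
  set.seed(seed)
  rf <- ranger::ranger(x = as.data.frame(shap_data[factors]),
                       y = shap_data$small_fraction, num.trees = 300,
                       seed = seed, num.threads = 1)
  predict_rf <- function(m) {
    predict(rf, data = as.data.frame(m), num.threads = 1)$predictions
  }
  set.seed(seed + 1)
  xrows <- shap_data[sample.int(nrow(shap_data),
                                min(shapley_rows, nrow(shap_data))), factors]
  shap <- shapley_values(predict_rf, xrows,
                         background = as.matrix(
                           shap_data[sample.int(nrow(shap_data),
                                                min(shapley_background,
                                                    nrow(shap_data))),
                                     factors]),
                         mode = "exact", seed = seed)
  shapley_tbl <- tidy(shap)

  result <- structure(list(
    species_trends = species_trends,
    community_trends = community_trends,
    small_fraction_trends = small_trends,
    partition = tibble::as_tibble(part),
    anosim = anosim_tbl,
    correlations = tibble::as_tibble(corr),
    clusters = clusters,
    partial_effects = partial_effects,
    shapley = shapley_tbl,
    scenario = scenario,
    meta = meta
  ), class = "pipeline_result")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    tables <- c("species_trends", "community_trends",
                "small_fraction_trends", "partition", "anosim",
                "correlations", "clusters", "partial_effects", "shapley")
    for (tb in tables) {
      write_tidy_csv(result[[tb]], file.path(out_dir, paste0(tb, ".csv")))
    }
    writeLines(c(sprintf("seed: %d", seed),
                 sprintf("config_hash: %s", meta$value[meta$key == "config_hash"]),
                 sprintf("generated: %s tables", length(tables))),
               file.path(out_dir, "run_log.txt"))
  }
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  for (nm in setdiff(names(x), "meta")) {
    cat(sprintf("  $%s: %d rows\n", nm, nrow(x[[nm]])))
  }
  invisible(x)
}
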