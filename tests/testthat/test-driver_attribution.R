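env_from_wide <- function(df) {
  tidyr::pivot_longer(df, cols = -c("station_id", "date"),
                      names_to = "param", values_to = "value") |>
    dplyr::mutate(below_detection = FALSE)
}

test_that("species-factor correlations hit the exact limits", {
  dates <- seq(as.Date("2000-01-01"), by = "month", length.out = 24)
  base <- sin(seq_along(dates))
  obs <- make_obs("A", format(dates, "%Y-%m"), "sp1", 1, exp(base))
  env <- env_from_wide(tibble::tibble(
    station_id = "A", date = dates,
    temperature = base, mirror = -base, flat = 2))
  corr <- species_env_correlations(obs, env)
  r_of <- function(f) corr$r[corr$factor == f]
  expect_equal(r_of("temperature"), 1)
  expect_equal(r_of("mirror"), -1)
  expect_true(is.na(r_of("flat")))
  expect_equal(corr$reason[corr$factor == "flat"], "zero variance")
  expect_error(species_env_correlations(obs, env, factors = character(0)),
               "at least one")
  # support below the minimum is reported, not computed
  short <- species_env_correlations(obs[1:2, ], env)
  expect_true(all(short$reason == "insufficient support"))
})

test_that("response-group clustering separates archetypes and labels them", {
  set.seed(8)
  archetype <- function(id, t_r, n_r) {
    tibble::tibble(species_id = id,
                   factor = c("temperature", "DIN", "PO4", "salinity"),
                   r = c(t_r, n_r, n_r, 0) + rnorm(4, 0, 0.03),
                   n = 50, reason = NA_character_)
  }
  corr <- dplyr::bind_rows(
    purrr::map(sprintf("warm%d", 1:4), archetype, t_r = 0.8, n_r = 0),
    purrr::map(sprintf("cold%d", 1:4), archetype, t_r = -0.8, n_r = 0.4))
  cl <- cluster_response_groups(corr, k = 2)
  expect_equal(dplyr::n_distinct(cl$cluster[grepl("warm", cl$species_id)]), 1)
  expect_equal(dplyr::n_distinct(cl$cluster[grepl("cold", cl$species_id)]), 1)
  expect_setequal(unique(cl$label[grepl("warm", cl$species_id)]), "T+")
  expect_setequal(unique(cl$label[grepl("cold", cl$species_id)]), "T-&N+")

  # k = species count gives singletons; duplicates co-cluster
  cl_all <- cluster_response_groups(corr, k = 8)
  expect_equal(dplyr::n_distinct(cl_all$cluster), 8)
  dup <- dplyr::bind_rows(
    archetype("twin1", 0.5, -0.5), archetype("twin1b", 0.5, -0.5))
  dup$r <- rep(dup$r[1:4], 2) # exactly duplicated rows
  cl_dup <- cluster_response_groups(dup, k = 2)
  expect_error(cluster_response_groups(dup, k = 5), "exceeds")
})

test_that("partial effects recover exact coefficients and flag collinearity", {
  set.seed(10)
  n <- 150
  df <- tibble::tibble(
    temperature = rnorm(n, 22, 3), PO4 = rnorm(n, 30, 8),
    station_id = sample(c("A", "B", "C"), n, TRUE))
  offs <- c(A = 0, B = 2, C = -1)
  df$y <- 2 - 0.5 * df$temperature + 1.0 * df$PO4 + offs[df$station_id]
  pe <- suppressWarnings(
    partial_effect(df, "y", "temperature", "PO4", group = "station_id"))
  expect_equal(pe$estimate, -0.5, tolerance = 1e-10)

  df$dup <- df$PO4
  expect_error(
    partial_effect(df, "y", "temperature", c("PO4", "dup"),
                   group = "station_id"),
    "collinear")

  # orthogonal focal equals the simple-regression slope
  x1 <- rep(c(-1, 1), 50)
  x2 <- rep(c(-1, -1, 1, 1), 25)
  y <- 3 * x1 + 5 * x2 + rnorm(100, 0, 0.3)
  d2 <- tibble::tibble(y = y, x1 = x1, x2 = x2)
  pe2 <- partial_effect(d2, "y", "x1", "x2")
  simple <- ols_oracle(x1, y)$slope
  expect_equal(pe2$estimate, simple, tolerance = 1e-10)
})

test_that("partial effects match the normal-equations oracle on random designs", {
  set.seed(12)
  for (i in 1:20) {
    n <- 80
    X <- matrix(rnorm(n * 3), n, 3)
    colnames(X) <- c("f", "c1", "c2")
    y <- 1 + 0.7 * X[, 1] - 0.3 * X[, 2] + 0.1 * X[, 3] + rnorm(n, 0, 0.5)
    df <- tibble::as_tibble(as.data.frame(X))
    df$y <- y
    pe <- partial_effect(df, "y", "f", c("c1", "c2"))
    beta <- solve(t(cbind(1, X)) %*% cbind(1, X), t(cbind(1, X)) %*% y)
    expect_lt(abs(pe$estimate - beta[2]), 1e-8)
  }
})

test_that("the TSR test classifies injected temperature responses", {
  base <- function(beta) {
    scenario_config(n_stations = 2, months = 120, n_diatom = 4,
                    n_dinoflagellate = 3, n_other = 3,
                    beta_mean = beta, beta_sd = 0,
                    gamma_mean = 0, gamma_sd = 0,
                    sd_size = 0.05, bloom_prob = 0)
  }
  sim_neg <- simulate_community(base(-0.05), seed = 21)
  res_neg <- tsr_test(sim_neg$observations, sim_neg$environment)
  expect_true(all(res_neg$tsr_class == "follows_tsr"))
  expect_true(all(res_neg$estimate < 0))

  sim_pos <- simulate_community(base(0.05), seed = 22)
  res_pos <- tsr_test(sim_pos$observations, sim_pos$environment)
  expect_true(all(res_pos$tsr_class == "anti_tsr"))
})

test_that("the tournament is deterministic and picks the right learner", {
  set.seed(30)
  n <- 120
  df <- tibble::tibble(x1 = rnorm(n), x2 = rnorm(n))
  df$y <- 2 + 3 * df$x1 - df$x2 + rnorm(n, 0, 0.1)
  truth <- learner("truth",
                   fit = function(x, y) lm(y ~ x1 + x2,
                                           data = cbind(as.data.frame(x),
                                                        y = y)),
                   predict = function(m, x) predict(m, as.data.frame(x)))
  mean_only <- learner("mean_only",
                       fit = function(x, y) mean(y),
                       predict = function(m, x) rep(m, nrow(x)))
  tour <- model_tournament(df, "y", c("x1", "x2"),
                           learners = list(truth, mean_only), seed = 4)
  expect_equal(tournament_winner(tour), "truth")
  expect_lt(tidy(tour)$r_squared[2], 0.1)

  tour2 <- model_tournament(df, "y", c("x1", "x2"),
                            learners = list(truth, mean_only), seed = 4)
  expect_equal(tidy(tour), tidy(tour2))

  solo <- model_tournament(df, "y", c("x1", "x2"),
                           learners = list(mean_only), seed = 4)
  expect_equal(tournament_winner(solo), "mean_only")
  expect_error(model_tournament(df, "y", c("x1", "x2"), test_frac = 1.2),
               "test_frac")
  expect_error(model_tournament(df[1:10, ], "y", c("x1", "x2"),
                                learners = list(mean_only)),
               "too small")
})

test_that("all five default learners fit and beat the mean on smooth data", {
  set.seed(33)
  n <- 150
  df <- tibble::tibble(x1 = runif(n, -2, 2), x2 = runif(n, -2, 2))
  df$y <- sin(df$x1) + df$x2^2 + rnorm(n, 0, 0.1)
  tour <- model_tournament(df, "y", c("x1", "x2"), seed = 5)
  scores <- tidy(tour)
  expect_equal(nrow(scores), 5)
  expect_setequal(scores$learner, c("ridge", "random_forest", "xgboost",
                                    "neural_net", "svm_rbf"))
  nonlinear <- scores$r_squared[scores$learner != "ridge"]
  expect_true(all(nonlinear > 0.5))
})
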