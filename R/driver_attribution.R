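#' Species-by-factor Pearson correlation screening
#'
#' Correlates each species' station-month biovolume with each environmental
#' factor over matched (station, month) samples. Cells with fewer than
#' `min_support` paired observations, or with a zero-variance factor or
#' series, are reported as missing with a reason.
#'
#' @param observations Observation tibble.
#' @param environment Long environment tibble.
#' @param species Optional species subset (e.g. from
#'   [select_top_species()]).
#' @param factors Optional factor subset (default: every parameter).
#' @param min_support Minimum paired observations per cell (default 3).
#' @param log_size Correlate log biovolume (default) rather than raw.
#' @return A `correlation_matrix` tibble: `species_id`, `factor`, `r`, `n`,
#'   `reason` (`NA` for computed cells).
#' @export
species_env_correlations <- function(observations, environment,
                                     species = NULL, factors = NULL,
                                     min_support = 3, log_size = TRUE) {
  if (!is.null(factors) && length(factors) == 0) {
    abort("`factors` must name at least one environmental parameter.")
  }
  if (!is.null(species)) {
    observations <- observations[observations$species_id %in% species, ]
  }
  env <- environment
  if (!is.null(factors)) env <- env[env$param %in% factors, ]
  obs <- observations[observations$abundance > 0,
                      c("station_id", "date", "species_id", "cell_biovolume")]
  if (log_size) obs$cell_biovolume <- log(obs$cell_biovolume)
  joined <- dplyr::inner_join(obs, env[c("station_id", "date", "param",
                                         "value")],
                              by = c("station_id", "date"),
                              relationship = "many-to-many")
  joined <- joined[is.finite(joined$cell_biovolume) &
                     is.finite(joined$value), ]
  out <- dplyr::summarise(
    dplyr::group_by(joined, .data$species_id, .data$param),
    n = dplyr::n(),
    sd_f = sd(.data$value),
    sd_y = sd(.data$cell_biovolume),
    r = suppressWarnings(cor(.data$cell_biovolume, .data$value)),
    .groups = "drop")
  out$reason <- dplyr::case_when(
    out$n < min_support ~ "insufficient support",
    out$sd_f == 0 | out$sd_y == 0 ~ "zero variance",
    TRUE ~ NA_character_
  )
  out$r[!is.na(out$reason)] <- NA_real_
  out <- dplyr::rename(out, factor = "param")
  out <- out[c("species_id", "factor", "r", "n", "reason")]
  structure(dplyr::arrange(out, .data$species_id, .data$factor),
            class = c("correlation_matrix", class(out)))
}

#' Wide species x factor matrix of correlations
#'
#' @param corr A [species_env_correlations()] result.
#' @return Numeric matrix, rows = species, columns = factors.
#' @export
correlation_wide <- function(corr) {
  wide <- tidyr::pivot_wider(corr[c("species_id", "factor", "r")],
                             names_from = "factor", values_from = "r")
  m <- as.matrix(wide[-1])
  rownames(m) <- wide$species_id
  m
}

#' Cluster species by their environmental response patterns
#'
#' Agglomerative (average-linkage) clustering on the Euclidean distance
#' between species' correlation profiles, cut at `k` clusters. Each cluster
#' is labelled by the sign of its mean temperature correlation (`T-`/`T+`)
#' with a nutrient qualifier (`&N+`/`&N-`) appended when the magnitude of the
#' mean correlation over the nutrient factors exceeds `threshold`.
#'
#' @param corr A [species_env_correlations()] result.
#' @param k Number of clusters (default 4).
#' @param temperature_factor Name of the temperature factor.
#' @param nutrient_factors Names of the nutrient factor block.
#' @param threshold Minimum |mean r| for a nutrient qualifier (default 0.1).
#' @return Tibble `species_id`, `cluster`, `label`, `imputed` (missing
#'   correlations imputed to 0 before clustering).
#' @export
cluster_response_groups <- function(corr, k = 4,
                                    temperature_factor = "temperature",
                                    nutrient_factors = c("DIN", "PO4"),
                                    threshold = 0.1) {
  m <- correlation_wide(corr)
  if (k > nrow(m)) abort("`k` exceeds the number of species.")
  imputed <- rowSums(is.na(m)) > 0
  m[is.na(m)] <- 0
  cl <- if (k == nrow(m)) {
    setNames(seq_len(nrow(m)), rownames(m))
  } else {
    cutree(hclust(dist(m), method = "average"), k = k)
  }
  labels <- vapply(seq_len(k), function(ci) {
    rows <- m[cl == ci, , drop = FALSE]
    t_mean <- mean(rows[, temperature_factor], na.rm = TRUE)
    lab <- if (t_mean < 0) "T-" else "T+"
    nut <- intersect(nutrient_factors, colnames(rows))
    if (length(nut) > 0) {
      n_mean <- mean(rows[, nut], na.rm = TRUE)
      if (is.finite(n_mean) && abs(n_mean) > threshold) {
        lab <- paste0(lab, if (n_mean > 0) "&N+" else "&N-")
      }
    }
    lab
  }, character(1))
  tibble::tibble(species_id = rownames(m), cluster = unname(cl),
                 label = labels[cl], imputed = unname(imputed))
}

#' Partial effect of a focal factor with grouped intercepts
#'
#' Least-squares fit of `response ~ focal + covariates + group intercepts`,
#' reporting the focal coefficient with its standard error and two-sided
#' p-value: the "pure" effect of the focal factor with the other measured
#' factors held constant. A rank-deficient design is an error naming the
#' collinear columns.
#'
#' @param data Analysis tibble (e.g. from [join_env()]).
#' @param response,focal Column names (strings).
#' @param covariates Character vector of covariate column names.
#' @param group Optional grouping column (e.g. `"station_id"`) given fixed
#'   intercepts; ignored when it has a single level.
#' @return A `partial_effect` object; see [tidy()]/[glance()].
#' @export
partial_effect <- function(data, response, focal, covariates = character(),
                           group = NULL) {
  cols <- c(response, focal, covariates, group)
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0) {
    abort(paste0("Missing column(s): ", paste(missing, collapse = ", ")))
  }
  df <- data[cols]
  df <- df[complete.cases(df), ]
  use_group <- !is.null(group) && dplyr::n_distinct(df[[group]]) > 1
  rhs <- c(paste0("`", c(focal, covariates), "`"),
           if (use_group) paste0("factor(`", group, "`)"))
  form <- as.formula(paste0("`", response, "` ~ ", paste(rhs, collapse = " + ")))
  n_par <- 1 + length(covariates) + 1 +
    if (use_group) dplyr::n_distinct(df[[group]]) - 1 else 0
  if (nrow(df) <= n_par + 2) {
    abort("Too few rows for the requested design (need n > #parameters + 2).")
  }
  fit <- lm(form, data = df)
  aliased <- names(coef(fit))[is.na(coef(fit))]
  if (length(aliased) > 0) {
    abort(paste0("Rank-deficient design; collinear column(s): ",
                 paste(aliased, collapse = ", ")))
  }
  sm <- summary(fit)$coefficients
  focal_row <- paste0("`", focal, "`")
  if (!focal_row %in% rownames(sm)) focal_row <- focal
  structure(list(response = response, focal = focal,
                 estimate = sm[focal_row, 1], se = sm[focal_row, 2],
                 statistic = sm[focal_row, 3], p = sm[focal_row, 4],
                 n = nrow(df), covariates = covariates,
                 group = if (use_group) group else NULL,
                 r_squared = summary(fit)$r.squared,
                 fit = fit),
            class = "partial_effect")
}

#' @export
print.partial_effect <- function(x, ...) {
  cat(sprintf(
    "<partial_effect> %s ~ %s: %.4g (se %.3g, p = %.3g, n = %d)\n",
    x$response, x$focal, x$estimate, x$se, x$p, x$n))
  invisible(x)
}

#' Temperature-size rule test per species
#'
#' For each species, estimates the partial effect of temperature on (log)
#' cell biovolume holding the other environmental covariates constant, with
#' station intercepts, and classifies the species as `follows_tsr`
#' (significantly negative temperature effect), `anti_tsr` (significantly
#' positive), or `none`.
#'
#' @param observations Observation tibble.
#' @param environment Long environment tibble.
#' @param species Species to test (default: all with enough data).
#' @param covariates Environmental covariates held constant (default every
#'   parameter except temperature).
#' @param alpha Significance level.
#' @param log_size Model log biovolume (default TRUE; size responses are
#'   proportional).
#' @param group Grouping column for intercepts (default station).
#' @return Tibble `species_id`, `estimate` (per degC), `se`, `p`, `n`,
#'   `tsr_class`.
#' @export
tsr_test <- function(observations, environment, species = NULL,
                     covariates = NULL, alpha = 0.05, log_size = TRUE,
                     group = "station_id") {
  params <- unique(environment$param)
  if (!"temperature" %in% params) {
    abort("Environment table must contain a 'temperature' parameter.")
  }
  covariates <- covariates %||% setdiff(params, "temperature")
  joined <- join_env(observations, environment)
  joined$size <- if (log_size) log(joined$cell_biovolume) else
    joined$cell_biovolume
  species <- species %||% sort(unique(joined$species_id))
  purrr::map_dfr(species, function(sp) {
    sub <- joined[joined$species_id == sp & joined$abundance > 0, ]
    pe <- tryCatch(
      partial_effect(sub, response = "size", focal = "temperature",
                     covariates = covariates, group = group),
      error = function(e) NULL)
    if (is.null(pe)) {
      return(tibble::tibble(species_id = sp, estimate = NA_real_,
                            se = NA_real_, p = NA_real_, n = nrow(sub),
                            tsr_class = "none"))
    }
    cls <- if (pe$p < alpha && pe$estimate < 0) "follows_tsr"
           else if (pe$p < alpha && pe$estimate > 0) "anti_tsr"
           else "none"
    tibble::tibble(species_id = sp, estimate = pe$estimate, se = pe$se,
                   p = pe$p, n = pe$n, tsr_class = cls)
  })
}

new_learner <- function(id, fit, predict) {
  structure(list(id = id, fit = fit, predict = predict), class = "learner")
}

#' Register a custom learner for the tournament
#'
#' A learner is a contract: `fit(x, y)` returns any model object and
#' `predict(model, x)` returns numeric predictions; `x` is a numeric matrix.
#'
#' @param id Learner name (used for registration-order tie-breaks).
#' @param fit,predict Functions as described above.
#' @return A `learner` object.
#' @export
learner <- function(id, fit, predict) new_learner(id, fit, predict)

#' The five default learner adapters
#'
#' Ridge regression (glmnet), random forest (ranger), gradient-boosted trees
#' (xgboost), a small feed-forward neural network (nnet, standardized
#' inputs), and an RBF support-vector regressor (e1071). Internals are
#' deliberately off-the-shelf: the tournament contract, not the learners,
#' is the analysis surface.
#'
#' @param seed Integer seed forwarded to the stochastic learners.
#' @return List of [learner()] objects.
#' @export
default_learners <- function(seed = 1) {
  list(
    new_learner("ridge",
      fit = function(x, y) {
        set.seed(seed)
        glmnet::cv.glmnet(x, y, alpha = 0, nfolds = 5)
      },
      predict = function(m, x) as.numeric(predict(m, x, s = "lambda.min"))),
    new_learner("random_forest",
      fit = function(x, y) {
        ranger::ranger(x = as.data.frame(x), y = y, num.trees = 300,
                       seed = seed, num.threads = 1)
      },
      predict = function(m, x) {
        predict(m, data = as.data.frame(x), num.threads = 1)$predictions
      }),
    new_learner("xgboost",
      fit = function(x, y) {
        xgboost::xgb.train(
          params = list(max_depth = 4, eta = 0.1, nthread = 1,
                        objective = "reg:squarederror"),
          data = xgboost::xgb.DMatrix(x, label = y, nthread = 1),
          nrounds = 150, verbose = 0)
      },
      predict = function(m, x) {
        as.numeric(predict(m, xgboost::xgb.DMatrix(x, nthread = 1)))
      }),
    new_learner("neural_net",
      fit = function(x, y) {
        set.seed(seed)
        ctr <- list(mu = colMeans(x), sd = pmax(apply(x, 2, sd), 1e-8),
                    y_mu = mean(y), y_sd = max(sd(y), 1e-8))
        xs <- scale(x, ctr$mu, ctr$sd)
        net <- nnet::nnet(xs, (y - ctr$y_mu) / ctr$y_sd, size = 8,
                          decay = 0.01, maxit = 500, linout = TRUE,
                          trace = FALSE)
        list(net = net, ctr = ctr)
      },
      predict = function(m, x) {
        xs <- scale(x, m$ctr$mu, m$ctr$sd)
        as.numeric(predict(m$net, xs)) * m$ctr$y_sd + m$ctr$y_mu
      }),
    new_learner("svm_rbf",
      fit = function(x, y) e1071::svm(x, y, kernel = "radial"),
      predict = function(m, x) as.numeric(predict(m, x)))
  )
}

#' Held-out model tournament
#'
#' Splits the data once into train and test subsets (random `test_frac`
#' share), fits each learner on the training rows and scores it on the held
#' -out rows; the winner has maximal held-out R-squared, with ties broken by
#' registration order.
#'
#' @param data Analysis tibble.
#' @param response Response column name.
#' @param features Character vector of feature column names.
#' @param learners List of [learner()] objects (default
#'   [default_learners()]).
#' @param test_frac Held-out fraction in (0, 1); `n * test_frac >= 5`
#'   required.
#' @param seed Integer seed controlling the split (and stochastic learners).
#' @return A `tournament_result`: tibble of per-learner `r_squared` and
#'   `rmse` with attributes `winner`, `seed`, `test_frac`, `n_train`,
#'   `n_test`.
#' @export
model_tournament <- function(data, response, features,
                             learners = default_learners(seed),
                             test_frac = 0.2, seed = 1) {
  if (test_frac <= 0 || test_frac >= 1) abort("`test_frac` must be in (0, 1).")
  df <- data[c(response, features)]
  df <- df[complete.cases(df), ]
  x <- as.matrix(df[features])
  y <- as.numeric(df[[response]])
  n <- nrow(x)
  n_test <- round(n * test_frac)
  if (n_test < 5) abort("Test split too small (need n * test_frac >= 5).")
  set.seed(seed)
  test_idx <- sort(sample.int(n, n_test))
  xtr <- x[-test_idx, , drop = FALSE]; ytr <- y[-test_idx]
  xte <- x[test_idx, , drop = FALSE]; yte <- y[test_idx]
  scores <- purrr::imap_dfr(learners, function(l, i) {
    model <- l$fit(xtr, ytr)
    pred <- l$predict(model, xte)
    ss_res <- sum((yte - pred)^2)
    ss_tot <- sum((yte - mean(yte))^2)
    tibble::tibble(learner = l$id, order = as.integer(i),
                   r_squared = 1 - ss_res / ss_tot,
                   rmse = sqrt(mean((yte - pred)^2)))
  })
  winner <- scores$learner[order(-scores$r_squared, scores$order)][1]
  structure(scores[c("learner", "r_squared", "rmse")],
            class = c("tournament_result", class(scores)),
            winner = winner, seed = seed, test_frac = test_frac,
            n_train = n - n_test, n_test = n_test)
}

#' Winning learner of a tournament
#'
#' @param x A `tournament_result`.
#' @return The winner's id string.
#' @export
tournament_winner <- function(x) attr(x, "winner")
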