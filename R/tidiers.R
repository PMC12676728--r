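#' @exportS3Method generics::tidy
tidy.trend_result <- function(x, ...) {
  tibble::tibble(
    term = c("intercept", "slope_month"),
    estimate = c(x$intercept, x$slope_month),
    std.error = c(NA_real_, x$se),
    p.value = c(NA_real_, x$p))
}

#' @exportS3Method generics::glance
glance.trend_result <- function(x, ...) {
  tibble::tibble(slope_month = x$slope_month, slope_year = x$slope_year,
                 p.value = x$p, r.squared = x$r_squared, nobs = x$n,
                 exact_fit = x$exact_fit)
}

#' @exportS3Method generics::tidy
tidy.anosim_result <- function(x, ...) {
  tibble::tibble(grouping = x$grouping, statistic = x$statistic,
                 p.value = x$p, n_perm = x$n_perm, n_samples = x$n_samples,
                 n_pairs = x$n_pairs)
}

#' @exportS3Method generics::glance
glance.anosim_result <- function(x, ...) tidy(x)

#' @exportS3Method generics::tidy
tidy.partial_effect <- function(x, ...) {
  tibble::tibble(response = x$response, term = x$focal,
                 estimate = x$estimate, std.error = x$se,
                 statistic = x$statistic, p.value = x$p)
}

#' @exportS3Method generics::glance
glance.partial_effect <- function(x, ...) {
  tibble::tibble(r.squared = x$r_squared, nobs = x$n,
                 n_covariates = length(x$covariates),
                 grouped = !is.null(x$group))
}

#' @exportS3Method generics::tidy
tidy.tournament_result <- function(x, ...) {
  out <- tibble::as_tibble(x)
  out$winner <- out$learner == attr(x, "winner")
  out
}

#' @exportS3Method generics::glance
glance.tournament_result <- function(x, ...) {
  tibble::tibble(winner = attr(x, "winner"), seed = attr(x, "seed"),
                 test_frac = attr(x, "test_frac"),
                 n_train = attr(x, "n_train"), n_test = attr(x, "n_test"))
}

#' @exportS3Method generics::tidy
tidy.shapley_matrix <- function(x, ...) {
  phi <- tibble::as_tibble(x$phi)
  phi$sample <- seq_len(nrow(phi))
  long <- tidyr::pivot_longer(phi, cols = -"sample", names_to = "feature",
                              values_to = "phi")
  vals <- tibble::as_tibble(x$x)
  vals$sample <- seq_len(nrow(vals))
  vals <- tidyr::pivot_longer(vals, cols = -"sample", names_to = "feature",
                              values_to = "feature_value")
  dplyr::inner_join(long, vals, by = c("sample", "feature"))
}

#' @exportS3Method generics::glance
glance.shapley_matrix <- function(x, ...) {
  tibble::tibble(baseline = x$baseline, mode = x$mode,
                 n_samples = nrow(x$phi), n_features = ncol(x$phi),
                 max_abs_residual = max(abs(x$residual)))
}
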