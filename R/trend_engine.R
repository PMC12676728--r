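#' Ordinary least-squares trend of a monthly series
#'
#' Fits `value ~ lagged_month` by OLS and reports the slope per month and per
#' year, the intercept (fitted value at month 0), the two-sided t-test
#' p-value on the slope (n - 2 df), and r^2. Degenerate cases follow fixed
#' conventions: a constant series has slope 0 and p = 1; a non-constant
#' series fit exactly (zero residual variance) is flagged `exact_fit` with
#' p = 0.
#'
#' @param data A data frame, or a numeric vector of values (then `time` may
#'   be the vector of time points).
#' @param time,value Column names (tidy-eval) when `data` is a data frame.
#' @return A `trend_result` object; see [tidy()] and [glance()] methods.
#' @export
linear_trend <- function(data, time = lagged_month, value = value) {
  if (is.numeric(data) && is.atomic(data)) {
    y <- as.numeric(data)
    t_arg <- tryCatch(time, error = function(e) NULL)
    t <- if (is.numeric(t_arg)) as.numeric(t_arg) else seq_along(y) - 1
  } else {
    t <- as.numeric(dplyr::pull(data, {{ time }}))
    y <- as.numeric(dplyr::pull(data, {{ value }}))
  }
  ok <- is.finite(t) & is.finite(y)
  t <- t[ok]; y <- y[ok]
  n <- length(y)
  if (n < 3) abort("Need at least 3 non-missing points for a trend.")
  if (length(unique(t)) < 2) abort("Need at least 2 distinct time points.")
  fit <- lm(y ~ t)
  slope <- unname(coef(fit)[2])
  intercept <- unname(coef(fit)[1])
  rss <- sum(resid(fit)^2)
  tss <- sum((y - mean(y))^2)
  scale2 <- max(mean(y^2), 1)
  constant <- tss <= 1e-24 * scale2
  exact <- !constant && rss <= 1e-20 * scale2
  if (constant) {
    slope <- 0; p <- 1; se <- NA_real_; r2 <- NA_real_; exact <- FALSE
  } else if (exact) {
    p <- 0
    se <- 0
    r2 <- 1
  } else {
    se <- unname(sqrt(diag(vcov(fit)))[2])
    p <- 2 * pt(abs(slope / se), df = n - 2, lower.tail = FALSE)
    r2 <- 1 - rss / tss
  }
  structure(list(slope_month = slope, slope_year = 12 * slope,
                 intercept = intercept, se = se, p = p, r_squared = r2,
                 n = n, exact_fit = exact, q = NA_real_),
            class = "trend_result")
}

#' @export
print.trend_result <- function(x, ...) {
  cat(sprintf(
    "<trend_result> slope %.4g/month (%.4g/year), p = %.3g, r2 = %.3g, n = %d%s\n",
    x$slope_month, x$slope_year, x$p, x$r_squared, x$n,
    if (x$exact_fit) " [exact fit]" else ""))
  invisible(x)
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up false-discovery-rate adjustment, returned in input order and
#' capped at 1. Applied within one analysis family (e.g. the regional
#' species-trend tests), not globally.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Vector of q-values, `q >= p` elementwise.
#' @export
bh_adjust <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1))) abort("p-values must lie in [0, 1].")
  p.adjust(p, method = "BH")
}

#' Seasonal-trend decomposition of a monthly series (period 12)
#'
#' LOESS-based STL decomposition into trend, seasonal and residual
#' components that reconstruct the input exactly at every observed point.
#' The series is re-indexed to a complete monthly grid; internal gaps are
#' linearly interpolated before decomposition and re-masked afterwards
#' (`interpolated` column; `value` and `residual` are `NA` there).
#'
#' @inheritParams linear_trend
#' @param period Samples per cycle (12 for monthly data with an annual
#'   cycle).
#' @param robust Use the robust STL outer loop.
#' @param s_window Seasonal LOESS window; `"periodic"` (default) constrains
#'   the seasonal pattern to be identical across years. The trend window is
#'   STL's default `nextodd(ceiling(1.5 p / (1 - 1.5/s_window)))`.
#' @return A `decomposition_result`: tibble `time`, `value`, `trend`,
#'   `seasonal`, `residual`, `interpolated`, with the period as attribute.
#' @export
stl_decompose <- function(data, time = lagged_month, value = value,
                          period = 12, robust = FALSE,
                          s_window = "periodic") {
  t <- as.numeric(dplyr::pull(data, {{ time }}))
  y <- as.numeric(dplyr::pull(data, {{ value }}))
  ok <- is.finite(t) & is.finite(y)
  t <- t[ok]; y <- y[ok]
  o <- order(t); t <- t[o]; y <- y[o]
  grid <- seq(min(t), max(t))
  yg <- rep(NA_real_, length(grid))
  yg[match(t, grid)] <- y
  interpolated <- is.na(yg)
  if (sum(!interpolated) < 2 * period || length(grid) < 2 * period) {
    abort("Need at least two full periods of data to decompose.")
  }
  yfill <- approx(grid[!interpolated], yg[!interpolated], xout = grid,
                  rule = 2)$y
  dec <- stl(ts(yfill, frequency = period), s.window = s_window,
             robust = robust)
  comp <- as.data.frame(dec$time.series)
  out <- tibble::tibble(
    time = grid,
    value = yg,
    trend = comp$trend,
    seasonal = comp$seasonal,
    residual = ifelse(interpolated, NA_real_, comp$remainder),
    interpolated = interpolated
  )
  structure(out, class = c("decomposition_result", class(out)),
            period = period)
}

#' Trend of the seasonally adjusted series
#'
#' Decomposes the series with [stl_decompose()] and fits [linear_trend()] to
#' the seasonally adjusted values (trend + residual) at the observed (non
#' interpolated) points. Equals `linear_trend()` when the series has no
#' seasonal component.
#'
#' @inheritParams stl_decompose
#' @return A `trend_result`.
#' @export
deseasoned_trend <- function(data, time = lagged_month, value = value,
                             period = 12, robust = FALSE,
                             s_window = "periodic") {
  dec <- stl_decompose(data, {{ time }}, {{ value }}, period = period,
                       robust = robust, s_window = s_window)
  adj <- dec[!dec$interpolated, ]
  linear_trend(tibble::tibble(t = adj$time,
                              y = adj$trend + adj$residual),
               time = t, value = y)
}

#' Three-way trend classification
#'
#' `decline` if slope < 0 and significant, `increase` if slope > 0 and
#' significant, otherwise `none`.
#'
#' @param slope,p Numeric vectors (or a single `trend_result` as `slope`).
#' @param alpha Significance level (default 0.05).
#' @return Character vector in `c("decline", "increase", "none")`.
#' @export
classify_trend <- function(slope, p = NULL, alpha = 0.05) {
  if (inherits(slope, "trend_result")) {
    p <- slope$p
    slope <- slope$slope_month
  }
  dplyr::case_when(
    is.na(slope) | is.na(p) ~ "none",
    slope < 0 & p < alpha ~ "decline",
    slope > 0 & p < alpha ~ "increase",
    TRUE ~ "none"
  )
}

#' Annual relative change of a fitted trend
#'
#' The yearly slope expressed as a percentage of the fitted baseline (the
#' fitted value at month 0). Invariant to rescaling the whole series.
#'
#' @param tr A `trend_result`.
#' @return Percent per year; `NA` (with a warning) for a non-positive
#'   baseline.
#' @export
annual_relative_change <- function(tr) {
  stopifnot(inherits(tr, "trend_result"))
  if (!is.finite(tr$intercept) || tr$intercept <= 0) {
    warn("Non-positive baseline; annual relative change undefined.")
    return(NA_real_)
  }
  100 * tr$slope_year / tr$intercept
}

#' Fit trends for every group of a series table
#'
#' Grouped convenience wrapper around [linear_trend()] and
#' [deseasoned_trend()]: one row per group with both the raw linear and the
#' seasonally adjusted slope, BH-adjusted q-values per method across the
#' table (one analysis family), and trend classes.
#'
#' @param data Series tibble (e.g. from [species_size_series()],
#'   [community_size()] or [small_fraction()]).
#' @param value Value column (tidy-eval).
#' @param by Character vector of grouping columns.
#' @param time Time column (tidy-eval), default `lagged_month`.
#' @param alpha Significance level for classification.
#' @param deseason Also fit the seasonally adjusted trend (needs >= 2 full
#'   periods per group).
#' @param period Season length for the decomposition.
#' @param log_scale Fit on `log(value)` instead of the raw scale.
#' @param min_n Minimum points per group; smaller groups are dropped.
#' @return Tibble with columns `by`, `method` (`lm`, `deseason`),
#'   `slope_month`, `slope_year`, `intercept`, `p`, `q`, `r_squared`, `n`,
#'   `class`, `annual_pct`.
#' @export
fit_trends <- function(data, value = value, by = "scope_id",
                       time = lagged_month, alpha = 0.05,
                       deseason = FALSE, period = 12, log_scale = FALSE,
                       min_n = 3) {
  data <- dplyr::mutate(data, .value = as.numeric({{ value }}),
                        .time = as.numeric({{ time }}))
  if (log_scale) data$.value <- log(data$.value)
  data <- data[is.finite(data$.value) & is.finite(data$.time), ]
  one <- function(sub) {
    fits <- list(lm = tryCatch(
      linear_trend(sub, time = .time, value = .value),
      error = function(e) NULL))
    if (deseason) {
      fits$deseason <- tryCatch(
        deseasoned_trend(sub, time = .time, value = .value, period = period),
        error = function(e) NULL)
    }
    purrr::imap_dfr(fits, function(tr, method) {
      if (is.null(tr)) return(tibble::tibble())
      tibble::tibble(
        method = method, slope_month = tr$slope_month,
        slope_year = tr$slope_year, intercept = tr$intercept,
        p = tr$p, r_squared = tr$r_squared, n = tr$n,
        annual_pct = suppressWarnings(annual_relative_change(tr)))
    })
  }
  out <- dplyr::group_modify(
    dplyr::group_by(data, dplyr::across(dplyr::all_of(by))),
    function(sub, keys) {
      if (nrow(sub) < min_n) return(tibble::tibble())
      one(sub)
    })
  out <- dplyr::ungroup(out)
  if (nrow(out) == 0) return(out)
  out <- dplyr::mutate(dplyr::group_by(out, .data$method),
                       q = bh_adjust(.data$p))
  out <- dplyr::ungroup(out)
  out$class <- classify_trend(out$slope_month, out$p, alpha)
  dplyr::arrange(out, .data$method,
                 dplyr::across(dplyr::all_of(by)))
}
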