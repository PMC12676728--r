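test_that("linear trends handle exact fits and degenerate series", {
  t <- 0:49
  tr <- linear_trend(tibble::tibble(lagged_month = t, value = 2 - 0.01 * t))
  expect_equal(tr$slope_month, -0.01)
  expect_equal(tr$slope_year, -0.12)
  expect_true(tr$exact_fit)
  expect_equal(tr$p, 0)

  flat <- linear_trend(rep(3.3, 10))
  expect_equal(flat$slope_month, 0)
  expect_equal(flat$p, 1)

  expect_error(linear_trend(c(1, 2)), "at least 3")
  expect_error(
    linear_trend(tibble::tibble(lagged_month = c(1, 1, 1),
                                value = c(1, 2, 3))),
    "distinct time")
})

test_that("linear trends agree with the normal-equations oracle", {
  set.seed(7)
  for (i in 1:100) {
    n <- sample(10:60, 1)
    t <- sort(sample(0:240, n))
    y <- rnorm(n, 5 - 0.02 * t, 2)
    tr <- linear_trend(tibble::tibble(lagged_month = t, value = y))
    o <- ols_oracle(t, y)
    expect_lt(abs(tr$slope_month - o$slope), 1e-10)
    expect_lt(abs(tr$intercept - o$intercept), 1e-10)
    expect_lt(abs(tr$p - o$p), 1e-10)
  }
})

test_that("BH adjustment equals the textbook step-up rule", {
  expect_equal(bh_adjust(0.03), 0.03)
  # hand application of q_(i) = min_{j>=i} m p_(j)/j
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")

  set.seed(11)
  for (i in 1:50) {
    m <- sample(1:10, 1)
    p <- round(runif(m), 3)
    q <- bh_adjust(p)
    expect_equal(q, bh_oracle(p))
    expect_true(all(q >= p))
    # rejection set at alpha equals the textbook step-up rejection set
    alpha <- 0.2
    k <- max(c(0, which(sort(p) <= alpha * seq_len(m) / m)))
    rejected <- if (k == 0) integer(0) else order(p)[seq_len(k)]
    expect_setequal(which(q <= alpha), rejected)
    # monotone in sorted p
    expect_true(all(diff(q[order(p)]) >= -1e-15))
  }
})

test_that("seasonal decomposition recovers trend and amplitude and reconstructs exactly", {
  t <- 0:119
  y <- 0.5 * t + 3 * cos(2 * pi * t / 12)
  dec <- stl_decompose(tibble::tibble(lagged_month = t, value = y))
  # reconstruction identity at observed points
  expect_lt(max(abs(dec$value - (dec$trend + dec$seasonal + dec$residual)),
                na.rm = TRUE), 1e-10)
  # trend slope within 5%, seasonal amplitude within 10%
  trend_slope <- linear_trend(tibble::tibble(lagged_month = dec$time,
                                             value = dec$trend))$slope_month
  expect_lt(abs(trend_slope - 0.5) / 0.5, 0.05)
  amp <- (max(dec$seasonal) - min(dec$seasonal)) / 2
  expect_lt(abs(amp - 3) / 3, 0.10)
  # seasonal mean per full cycle near zero
  cyc <- tapply(dec$seasonal[1:120], rep(1:10, each = 12), mean)
  expect_lt(max(abs(cyc)), 0.05)

  const <- stl_decompose(tibble::tibble(lagged_month = t, value = rep(4, 120)))
  expect_lt(max(abs(const$seasonal)), 1e-8)
  expect_lt(max(abs(const$trend - 4)), 1e-8)

  expect_error(stl_decompose(tibble::tibble(lagged_month = 0:20,
                                            value = rnorm(21))),
               "two full periods")
})

test_that("gaps are interpolated for decomposition then re-masked", {
  t <- 0:119
  y <- 0.2 * t + 2 * sin(2 * pi * t / 12) + rnorm(120, 0, 0.1)
  keep <- setdiff(t, c(30, 31, 77))
  dec <- stl_decompose(tibble::tibble(lagged_month = keep,
                                      value = y[keep + 1]))
  expect_equal(dec$time[dec$interpolated], c(30, 31, 77))
  expect_true(all(is.na(dec$value[dec$interpolated])))
  expect_true(all(is.na(dec$residual[dec$interpolated])))
  expect_lt(max(abs(dec$value - (dec$trend + dec$seasonal + dec$residual)),
                na.rm = TRUE), 1e-10)
})

test_that("de-seasoned trends recover injected slopes and reduce to plain OLS", {
  t <- 0:119
  pure_season <- tibble::tibble(lagged_month = t,
                                value = 5 + 2 * cos(2 * pi * t / 12))
  tr0 <- deseasoned_trend(pure_season)
  expect_lt(abs(tr0$slope_month), 0.01)
  expect_gt(tr0$p, 0.05)

  mixed <- tibble::tibble(lagged_month = t,
                          value = 1 + 0.03 * t + 2 * cos(2 * pi * t / 12))
  expect_lt(abs(deseasoned_trend(mixed)$slope_month - 0.03) / 0.03, 0.05)

  set.seed(3)
  no_season <- tibble::tibble(lagged_month = t, value = rnorm(120, 10, 1))
  expect_equal(deseasoned_trend(no_season)$slope_month,
               linear_trend(no_season)$slope_month, tolerance = 0.15)
})

test_that("trend classification and annual relative change follow conventions", {
  expect_equal(classify_trend(c(-2, -2, 2, 0.5), c(0.01, 0.2, 0.001, NA)),
               c("decline", "none", "increase", "none"))
  tr <- linear_trend(tibble::tibble(lagged_month = 0:40,
                                    value = 1000 - 25 / 12 * (0:40)))
  expect_equal(annual_relative_change(tr), -2.5)
  # scale invariance
  tr2 <- linear_trend(tibble::tibble(lagged_month = 0:40,
                                     value = 7 * (1000 - 25 / 12 * (0:40))))
  expect_equal(annual_relative_change(tr2), -2.5)
  flat <- linear_trend(rep(10, 10))
  expect_equal(annual_relative_change(flat), 0)
  neg <- linear_trend(tibble::tibble(lagged_month = 0:10,
                                     value = -5 + 0 * (0:10) + rnorm(11)))
  if (neg$intercept <= 0) expect_warning(annual_relative_change(neg))
})

test_that("fit_trends returns one family-adjusted row per group and method", {
  set.seed(5)
  d <- tidyr::crossing(id = sprintf("g%d", 1:6),
                       lagged_month = 0:59)
  d$value <- 10 - 0.02 * d$lagged_month * (d$id %in% c("g1", "g2")) +
    rnorm(nrow(d), 0, 0.5)
  out <- fit_trends(d, value = value, by = "id", deseason = TRUE)
  expect_setequal(unique(out$method), c("lm", "deseason"))
  expect_equal(sum(out$method == "lm"), 6)
  expect_true(all(out$q >= out$p))
  expect_true(all(out$class[out$method == "lm" & out$id %in% c("g1", "g2")] ==
                    "decline"))
})
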