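test_that("exact Shapley values are closed-form for linear predictors", {
  set.seed(1)
  beta <- c(1.5, -2, 0.5, 0.8)
  f <- function(m) as.numeric(m %*% beta) + 3
  x <- matrix(rnorm(24), 6, 4,
              dimnames = list(NULL, c("a", "b", "c", "d")))
  b <- matrix(rnorm(4), 1, 4, dimnames = list(NULL, colnames(x)))
  s <- shapley_values(f, x, background = b, mode = "exact")
  expected <- sweep(x, 2, as.numeric(b)) %*% diag(beta)
  expect_lt(max(abs(s$phi - expected)), 1e-10)
  expect_lt(max(abs(s$residual)), 1e-8)
  expect_equal(s$baseline, f(b))
})

test_that("Shapley axioms hold in exact mode", {
  set.seed(2)
  # dummy: a feature the predictor ignores gets phi = 0
  f <- function(m) m[, 1]^2 - 2 * m[, 2]
  x <- matrix(rnorm(30), 10, 3, dimnames = list(NULL, c("u", "v", "w")))
  bg <- matrix(rnorm(15), 5, 3, dimnames = list(NULL, colnames(x)))
  s <- shapley_values(f, x, background = bg, mode = "exact")
  expect_lt(max(abs(s$phi[, "w"])), 1e-10)
  # efficiency
  expect_lt(max(abs(s$residual)), 1e-8)
  # symmetry: exchangeable features at symmetric inputs get equal phi
  g <- function(m) m[, 1] * m[, 2]
  xs <- matrix(c(2, 2), 1, 2, dimnames = list(NULL, c("p", "q")))
  bgs <- matrix(c(0.5, 0.5), 1, 2, dimnames = list(NULL, c("p", "q")))
  ss <- shapley_values(g, xs, background = bgs, mode = "exact")
  expect_equal(unname(ss$phi[1, "p"]), unname(ss$phi[1, "q"]))
  expect_error(shapley_values(g, matrix(0, 1, 13), mode = "exact"),
               "montecarlo")
})

test_that("exact Shapley values match brute-force coalition enumeration", {
  set.seed(3)
  f <- function(m) sin(m[, 1]) * m[, 2] + 0.5 * m[, 3]^2
  x <- matrix(rnorm(12), 4, 3, dimnames = list(NULL, c("a", "b", "c")))
  bg <- matrix(rnorm(9), 3, 3, dimnames = list(NULL, colnames(x)))
  s <- shapley_values(f, x, background = bg, mode = "exact")
  expect_lt(max(abs(s$phi - shapley_oracle(f, x, bg))), 1e-10)
})

test_that("Monte-Carlo Shapley approximates the exact values and converges", {
  set.seed(4)
  # includes a genuine three-way interaction so permutation sampling is
  # the binding error source
  f <- function(m) {
    sin(m[, 1]) * m[, 2] + m[, 3]^2 - 0.5 * m[, 4] * m[, 5] +
      0.5 * m[, 1] * m[, 4] * m[, 5]
  }
  x <- matrix(rnorm(25), 5, 5)
  bg <- matrix(rnorm(50), 10, 5)
  ex <- shapley_values(f, x, background = bg, mode = "exact")
  mc <- shapley_values(f, x, background = bg, mode = "montecarlo",
                       n_samples = 4096, seed = 11)
  rel_rms <- sqrt(mean((ex$phi - mc$phi)^2)) / sqrt(mean(ex$phi^2))
  expect_lt(rel_rms, 0.02)
  # quadrupling the permutations roughly halves the error
  err_at <- function(n, seed) {
    m <- shapley_values(f, x, background = bg, mode = "montecarlo",
                        n_samples = n, seed = seed)
    sqrt(mean((ex$phi - m$phi)^2))
  }
  rms <- function(v) sqrt(mean(v^2))
  e_small <- rms(vapply(1:12, function(s) err_at(256, s + 256), numeric(1)))
  e_big <- rms(vapply(1:12, function(s) err_at(1024, s + 1024), numeric(1)))
  expect_gt(e_small / e_big, 1.4)
  expect_lt(e_small / e_big, 2.6)
})

test_that("interaction index isolates multiplicative structure", {
  # additive predictor: zero interaction
  add <- function(m) 2 * m[, 1] - 3 * m[, 2]
  x <- matrix(rnorm(10), 5, 2, dimnames = list(NULL, c("a", "b")))
  bg <- matrix(rnorm(6), 3, 2, dimnames = list(NULL, c("a", "b")))
  iv <- shapley_interaction(add, x, c("a", "b"), background = bg)
  expect_lt(max(abs(iv$value)), 1e-8)

  # f = x1 x2 with zero background: interaction equals the product,
  # also with a third additive feature present
  prod2 <- function(m) m[, 1] * m[, 2]
  for (p in 2:4) {
    f <- if (p == 2) prod2 else function(m) {
      m[, 1] * m[, 2] + rowSums(m[, 3:p, drop = FALSE])
    }
    xx <- matrix(rnorm(3 * p), 3, p,
                 dimnames = list(NULL, paste0("f", 1:p)))
    bb <- matrix(0, 1, p, dimnames = list(NULL, paste0("f", 1:p)))
    ivp <- shapley_interaction(f, xx, c("f1", "f2"), background = bb)
    expect_equal(ivp$value, xx[, 1] * xx[, 2], tolerance = 1e-10)
    # symmetry in the pair
    ivr <- shapley_interaction(f, xx, c("f2", "f1"), background = bb)
    expect_equal(ivp$value, ivr$value)
  }
  expect_error(shapley_interaction(prod2, x, c("a", "a"), background = bg),
               "distinct")
})

test_that("global importance ranks by mean absolute attribution", {
  set.seed(6)
  # dominant feature: largest |beta| x spread
  f <- function(m) 5 * m[, 1] + 0.2 * m[, 2]
  x <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("big", "small")))
  bg <- x
  s <- shapley_values(f, x, background = bg, mode = "exact")
  imp <- global_importance(s)
  expect_equal(imp$feature[1], "big")

  # all-zero column ranks last with importance 0
  s$phi <- cbind(s$phi, nil = 0)
  imp2 <- global_importance(s)
  expect_equal(imp2$feature[3], "nil")
  expect_equal(imp2$importance[3], 0)

  # ranking invariant to sample order
  s3 <- shapley_values(f, x[20:1, ], background = bg, mode = "exact")
  expect_equal(global_importance(s3)$feature, imp$feature)
})

test_that("tidied Shapley output is long with feature values attached", {
  f <- function(m) m[, 1] + m[, 2]
  x <- matrix(1:6, 3, 2, dimnames = list(NULL, c("a", "b")))
  s <- shapley_values(f, x, background = x, mode = "exact")
  td <- tidy(s)
  expect_equal(nrow(td), 6)
  expect_setequal(names(td), c("sample", "feature", "phi", "feature_value"))
  expect_equal(td$feature_value[td$sample == 2 & td$feature == "b"], 5)
  gl <- glance(s)
  expect_equal(gl$n_features, 2)
  expect_lt(gl$max_abs_residual, 1e-8)
})
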