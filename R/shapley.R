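# Coalition value v(S) under interventional (marginal) semantics:
# features in S keep the explained row's values, features outside S are
# replaced by background rows and the prediction is averaged over the
# background set. Returns an n_x by n_masks matrix of values.
coalition_values <- function(predict_fn, x, background, masks) {
  p <- ncol(x)
  n <- nrow(x)
  m <- nrow(background)
  bg_rep <- background[rep(seq_len(m), times = n), , drop = FALSE]
  x_rep <- x[rep(seq_len(n), each = m), , drop = FALSE]
  vals <- matrix(NA_real_, n, length(masks))
  for (k in seq_along(masks)) {
    cols_in <- which(bitwAnd(masks[k], bitwShiftL(1L, seq_len(p) - 1L)) != 0L)
    z <- bg_rep
    if (length(cols_in) > 0) z[, cols_in] <- x_rep[, cols_in, drop = FALSE]
    pred <- as.numeric(predict_fn(z))
    vals[, k] <- colMeans(matrix(pred, nrow = m, ncol = n))
  }
  vals
}

all_permutations <- function(p) {
  if (p == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(p - 1L)
  do.call(rbind, lapply(seq_len(p), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

as_feature_matrix <- function(x) {
  m <- as.matrix(x)
  storage.mode(m) <- "double"
  if (is.null(colnames(m))) colnames(m) <- paste0("x", seq_len(ncol(m)))
  m
}

default_background <- function(x, background, seed) {
  if (!is.null(background)) return(as_feature_matrix(background))
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(x)
  as_feature_matrix(x[sample.int(n, min(100, n)), , drop = FALSE])
}

#' Model-agnostic Shapley values
#'
#' Attributes each prediction to the features as Shapley values of the
#' coalition game `v(S) = E_background f(x_S, B_notS)` (absent features
#' replaced by background rows, interventional semantics). `mode = "exact"`
#' enumerates all coalitions with the exact Shapley weights
#' `|S|! (p - |S| - 1)! / p!`; `mode = "montecarlo"` averages marginal
#' contributions over random feature permutations (one background row drawn
#' per permutation). The per-sample efficiency residual
#' `sum(phi) + baseline - f(x)` is reported; it is below 1e-8 in exact mode.
#'
#' @param predict_fn Function taking a numeric feature matrix and returning
#'   numeric predictions.
#' @param x Matrix or data frame of rows to explain.
#' @param background Background matrix defining the baseline (default: up to
#'   100 rows subsampled from `x` with `seed`).
#' @param mode `"exact"` or `"montecarlo"`.
#' @param exact_limit Maximum feature count for exact enumeration.
#' @param n_samples Number of permutations in Monte-Carlo mode.
#' @param seed Optional seed (background subsampling and permutations).
#' @return A `shapley_matrix`: list with `phi` (n x p matrix), `baseline`
#'   (mean background prediction), `prediction`, `residual`, `features`,
#'   `x`, `mode`.
#' @export
shapley_values <- function(predict_fn, x, background = NULL,
                           mode = c("exact", "montecarlo"),
                           exact_limit = 12, n_samples = 2048, seed = NULL) {
  mode <- match.arg(mode)
  x <- as_feature_matrix(x)
  background <- default_background(x, background, seed)
  p <- ncol(x)
  n <- nrow(x)
  pred <- as.numeric(predict_fn(x))
  baseline <- mean(as.numeric(predict_fn(background)))
  phi <- matrix(0, n, p, dimnames = list(rownames(x), colnames(x)))
  if (mode == "exact") {
    if (p > exact_limit) {
      abort(sprintf(
        "%d features exceed exact_limit = %d; use mode = \"montecarlo\".",
        p, exact_limit))
    }
    masks <- 0:(2^p - 1)
    vals <- coalition_values(predict_fn, x, background, masks)
    sizes <- vapply(masks, function(mk) sum(bitwAnd(mk, bitwShiftL(1L, 0:(p - 1))) != 0L),
                    numeric(1))
    for (j in seq_len(p)) {
      bit <- bitwShiftL(1L, j - 1L)
      without_j <- masks[bitwAnd(masks, bit) == 0L]
      for (mk in without_j) {
        s <- sizes[mk + 1L]
        w <- exp(lfactorial(s) + lfactorial(p - s - 1) - lfactorial(p))
        phi[, j] <- phi[, j] +
          w * (vals[, mk + bit + 1L] - vals[, mk + 1L])
      }
    }
  } else {
    if (!is.null(seed)) set.seed(seed)
    m <- nrow(background)
    # marginal contributions along random feature orderings, averaged over
    # the full background set; antithetic pairs (every second ordering is
    # the reverse of the previous one) cancel first-order position bias
    bg_rep <- background[rep(seq_len(m), times = n), , drop = FALSE]
    prev <- NULL
    for (r in seq_len(n_samples)) {
      perm <- if (r %% 2 == 1 || is.null(prev)) sample.int(p) else rev(prev)
      prev <- perm
      blocks <- vector("list", p + 1)
      z <- bg_rep
      blocks[[1]] <- z
      for (k in seq_len(p)) {
        col <- perm[k]
        z[, col] <- rep(x[, col], each = m)
        blocks[[k + 1]] <- z
      }
      preds <- as.numeric(predict_fn(do.call(rbind, blocks)))
      vbar <- matrix(colMeans(matrix(preds, nrow = m)), n, p + 1)
      contrib <- vbar[, -1, drop = FALSE] - vbar[, -(p + 1), drop = FALSE]
      phi[, perm] <- phi[, perm] + contrib
    }
    phi <- phi / n_samples
  }
  structure(list(phi = phi, baseline = baseline, prediction = pred,
                 residual = rowSums(phi) + baseline - pred,
                 features = colnames(x), x = x, mode = mode),
            class = "shapley_matrix")
}

#' @export
print.shapley_matrix <- function(x, ...) {
  cat(sprintf("<shapley_matrix> %d samples x %d features (%s mode), baseline %.4g, max |residual| %.3g\n",
              nrow(x$phi), ncol(x$phi), x$mode, x$baseline,
              max(abs(x$residual))))
  invisible(x)
}

#' Shapley interaction index for a feature pair
#'
#' The pairwise interaction index
#' `sum_S |S|! (p - |S| - 2)! / (p - 1)! * [f(S+ij) - f(S+i) - f(S+j) + f(S)]`
#' over coalitions `S` excluding both features, under the same background
#' semantics as [shapley_values()] (exact enumeration only). Symmetric in
#' the pair and zero (to tolerance) for additively separable predictors.
#'
#' @inheritParams shapley_values
#' @param pair Length-2 vector of feature names or indices.
#' @return An `interaction_values` tibble: `sample`, `value`, with the pair
#'   as attribute.
#' @export
shapley_interaction <- function(predict_fn, x, pair, background = NULL,
                                exact_limit = 10, seed = NULL) {
  x <- as_feature_matrix(x)
  p <- ncol(x)
  if (p > exact_limit) {
    abort(sprintf("%d features exceed exact_limit = %d.", p, exact_limit))
  }
  if (is.character(pair)) pair <- match(pair, colnames(x))
  pair <- as.integer(pair)
  if (anyNA(pair) || length(pair) != 2) abort("`pair` must name two features.")
  if (pair[1] == pair[2]) abort("Interaction requires two distinct features.")
  background <- default_background(x, background, seed)
  i <- pair[1]; j <- pair[2]
  others <- setdiff(seq_len(p), pair)
  bit_i <- bitwShiftL(1L, i - 1L)
  bit_j <- bitwShiftL(1L, j - 1L)
  base_masks <- 0L
  for (o in others) {
    base_masks <- c(base_masks, base_masks + bitwShiftL(1L, o - 1L))
  }
  all_masks <- sort(unique(c(base_masks, base_masks + bit_i,
                             base_masks + bit_j,
                             base_masks + bit_i + bit_j)))
  vals <- coalition_values(predict_fn, x, background, all_masks)
  col_of <- function(mk) match(mk, all_masks)
  value <- rep(0, nrow(x))
  for (mk in base_masks) {
    s <- sum(bitwAnd(mk, bitwShiftL(1L, 0:(p - 1))) != 0L)
    w <- exp(lfactorial(s) + lfactorial(p - s - 2) - lfactorial(p - 1))
    value <- value + w * (vals[, col_of(mk + bit_i + bit_j)] -
                            vals[, col_of(mk + bit_i)] -
                            vals[, col_of(mk + bit_j)] +
                            vals[, col_of(mk)])
  }
  out <- tibble::tibble(sample = seq_len(nrow(x)), value = value)
  structure(out, class = c("interaction_values", class(out)),
            pair = colnames(x)[pair])
}

#' Global feature importance from Shapley values
#'
#' Mean absolute attribution per feature, ranked descending (ties broken by
#' feature name).
#'
#' @param shap A [shapley_values()] result.
#' @return Tibble `feature`, `importance`, `rank`.
#' @export
global_importance <- function(shap) {
  stopifnot(inherits(shap, "shapley_matrix"))
  imp <- colMeans(abs(shap$phi))
  out <- tibble::tibble(feature = names(imp), importance = unname(imp))
  out <- dplyr::arrange(out, dplyr::desc(.data$importance), .data$feature)
  out$rank <- seq_len(nrow(out))
  out
}
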