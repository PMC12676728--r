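#' Sample-by-species abundance matrix from long observations
#'
#' @param observations Observation tibble.
#' @return A numeric matrix (rows = station-month samples, columns =
#'   species, entries = cell abundance) with a `sample_info` attribute
#'   tibble carrying `sample_id`, `station_id`, `wcz`, `date`, `year`,
#'   `month` for grouping in [anosim()].
#' @export
abundance_matrix <- function(observations) {
  observations$sample_id <- paste(observations$station_id,
                                  format(observations$date, "%Y-%m"),
                                  sep = "_")
  wide <- tidyr::pivot_wider(
    dplyr::summarise(
      dplyr::group_by(observations, .data$sample_id, .data$species_id),
      abundance = sum(.data$abundance), .groups = "drop"),
    names_from = "species_id", values_from = "abundance", values_fill = 0)
  mat <- as.matrix(wide[-1])
  rownames(mat) <- wide$sample_id
  mat <- mat[, order(colnames(mat)), drop = FALSE]
  info <- dplyr::distinct(observations, .data$sample_id, .data$station_id,
                          .data$wcz, .data$date)
  info <- info[match(rownames(mat), info$sample_id), ]
  info$year <- format(info$date, "%Y")
  info$month <- format(info$date, "%m")
  attr(mat, "sample_info") <- tibble::as_tibble(info)
  mat
}

#' Bray-Curtis dissimilarity matrix
#'
#' `BC(j, k) = sum_i |x_ij - x_ik| / sum_i (x_ij + x_ik)` between every pair
#' of samples (rows). Entries lie in \[0, 1\]; identical samples give 0 and
#' samples with disjoint species sets give 1. A pair of all-zero samples is
#' 0 by convention (with a warning). Abundances are used untransformed.
#'
#' @param x Numeric matrix or data frame, rows = samples, columns = species,
#'   non-negative entries.
#' @return A symmetric `dissimilarity_matrix` (base matrix subclass) with
#'   zero diagonal; any `sample_info` attribute on `x` is carried through.
#' @export
bray_curtis <- function(x) {
  m <- as.matrix(x)
  if (any(m < 0)) abort("Abundances must be non-negative.")
  if (nrow(m) < 2) abort("Need at least 2 samples.")
  num <- as.matrix(dist(m, method = "manhattan"))
  rs <- rowSums(m)
  den <- outer(rs, rs, "+")
  bc <- num / den
  zero_pair <- den == 0
  if (any(zero_pair[upper.tri(zero_pair)])) {
    warn("All-zero sample pair(s): Bray-Curtis set to 0 by convention.")
  }
  bc[zero_pair] <- 0
  diag(bc) <- 0
  if (is.null(rownames(bc))) {
    rownames(bc) <- colnames(bc) <- paste0("sample", seq_len(nrow(m)))
  }
  structure(bc, class = c("dissimilarity_matrix", class(bc)),
            sample_info = attr(x, "sample_info"))
}

anosim_r <- function(rank_d, within, denom) {
  (mean(rank_d[!within]) - mean(rank_d[within])) / denom
}

#' Analysis of similarities (ANOSIM)
#'
#' Clarke's rank-based test of whether between-group dissimilarities exceed
#' within-group dissimilarities. All `M = n(n-1)/2` pairwise dissimilarities
#' are ranked with mid-ranks for ties;
#' `R = (mean between-group rank - mean within-group rank) / (n(n-1)/4)`,
#' so `R` lies in \[-1, 1\] with 0 expected under no group structure. The
#' p-value is the permutation tail probability
#' `(#{R_perm >= R_obs} + 1) / (n_perm + 1)` under random relabelling.
#'
#' @param d A [bray_curtis()] matrix, `dist`, or symmetric matrix.
#' @param groups Grouping vector (length = samples), or the name of a column
#'   in the matrix's `sample_info` attribute (e.g. `"station_id"`, `"wcz"`,
#'   `"year"`, `"month"`).
#' @param n_perm Number of label permutations (default 999).
#' @param seed Optional integer seed for reproducible permutations.
#' @return An `anosim_result` with fields `statistic` (R), `p`, `n_perm`,
#'   `grouping`, `n_samples`, `n_pairs`, `seed`.
#' @export
anosim <- function(d, groups, n_perm = 999, seed = NULL) {
  grouping_name <- if (is.character(groups) && length(groups) == 1) groups
                   else deparse(substitute(groups))
  if (is.character(groups) && length(groups) == 1) {
    info <- attr(d, "sample_info")
    if (is.null(info) || !groups %in% names(info)) {
      abort(sprintf("No '%s' column in the sample_info attribute.", groups))
    }
    groups <- info[[groups]]
  }
  m <- as.matrix(d)
  n <- nrow(m)
  if (length(groups) != n) abort("`groups` length must match sample count.")
  groups <- as.factor(groups)
  sizes <- table(groups)
  if (length(sizes) < 2) abort("Need at least 2 groups.")
  if (any(sizes < 2)) abort("Every group needs at least 2 samples.")
  lt <- lower.tri(m)
  dvec <- m[lt]
  if (sd(dvec) == 0) {
    warn("Constant dissimilarities: ANOSIM R undefined.")
    return(structure(list(statistic = NA_real_, p = NA_real_,
                          n_perm = n_perm, grouping = grouping_name,
                          n_samples = n, n_pairs = length(dvec),
                          seed = seed),
                     class = "anosim_result"))
  }
  rank_d <- rank(dvec) # mid-ranks for ties
  pair_i <- row(m)[lt]
  pair_j <- col(m)[lt]
  denom <- n * (n - 1) / 4
  g <- as.integer(groups)
  r_obs <- anosim_r(rank_d, g[pair_i] == g[pair_j], denom)
  if (!is.null(seed)) set.seed(seed)
  r_perm <- vapply(seq_len(n_perm), function(k) {
    gp <- g[sample.int(n)]
    anosim_r(rank_d, gp[pair_i] == gp[pair_j], denom)
  }, numeric(1))
  p <- (sum(r_perm >= r_obs) + 1) / (n_perm + 1)
  structure(list(statistic = r_obs, p = p, n_perm = n_perm,
                 grouping = grouping_name, n_samples = n,
                 n_pairs = length(dvec), seed = seed,
                 permuted = r_perm),
            class = "anosim_result")
}

#' @export
print.anosim_result <- function(x, ...) {
  cat(sprintf("<anosim_result> grouping '%s': R = %.3f, p = %.4g (%d permutations, n = %d)\n",
              x$grouping, x$statistic, x$p, x$n_perm, x$n_samples))
  invisible(x)
}
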