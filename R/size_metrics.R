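scope_column <- function(observations, scope = c("station", "wcz", "region")) {
  scope <- match.arg(scope)
  switch(scope,
         station = observations$station_id,
         wcz = observations$wcz,
         region = rep("region", nrow(observations)))
}

#' Species-level biovolume series
#'
#' One value per month where a species occurs: at station scope the sample's
#' mean cell biovolume; at zone or region scope the unweighted mean over the
#' stations reporting the species that month (so bloom stations are not
#' double-counted). Months without the species are absent from the series,
#' not zero: a zero biovolume is biologically meaningless.
#'
#' @param observations Observation tibble.
#' @param species Optional character vector of species to keep (default all);
#'   an unknown species is an error.
#' @param scope `"region"` (default), `"wcz"` or `"station"`.
#' @param origin Origin date for the lagged-month axis; defaults to the
#'   earliest date in `observations`.
#' @return Tibble `species_id`, `scope`, `scope_id`, `date`, `lagged_month`,
#'   `biovolume` (um^3), ordered by species and month.
#' @export
species_size_series <- function(observations,
                                species = NULL,
                                scope = c("region", "wcz", "station"),
                                origin = NULL) {
  scope <- match.arg(scope)
  if (!is.null(species)) {
    missing <- setdiff(species, unique(observations$species_id))
    if (length(missing) > 0) {
      abort(paste0("No observations for species: ",
                   paste(missing, collapse = ", ")))
    }
    observations <- observations[observations$species_id %in% species, ]
  }
  observations <- observations[observations$abundance > 0, ]
  observations$scope_id <- scope_column(observations, scope)
  out <- dplyr::summarise(
    dplyr::group_by(observations, .data$species_id, .data$scope_id,
                    .data$date),
    biovolume = mean(.data$cell_biovolume), .groups = "drop")
  out$scope <- scope
  out <- add_lagged_month(out, origin = origin)
  dplyr::arrange(
    out[c("species_id", "scope", "scope_id", "date", "lagged_month",
          "biovolume")],
    .data$species_id, .data$scope_id, .data$lagged_month)
}

#' Community mean cell size per sample
#'
#' The community mean size C of a sample is its total biovolume divided by
#' its total cell abundance -- an abundance-weighted mean cell size, and a
#' convex combination of the species' biovolumes. At zone or region scope,
#' cells are pooled across the member stations before the ratio is taken.
#'
#' @inheritParams species_size_series
#' @param scope `"station"` (default), `"wcz"` or `"region"`.
#' @return Tibble `scope`, `scope_id`, `date`, `lagged_month`,
#'   `total_abundance` (cells/L), `total_biovolume` (um^3/L), `mean_size`
#'   (um^3). Samples with zero total abundance get `NA` mean size.
#' @export
community_size <- function(observations,
                           scope = c("station", "wcz", "region"),
                           origin = NULL) {
  scope <- match.arg(scope)
  observations$scope_id <- scope_column(observations, scope)
  out <- dplyr::summarise(
    dplyr::group_by(observations, .data$scope_id, .data$date),
    total_abundance = sum(.data$abundance),
    total_biovolume = sum(.data$abundance * .data$cell_biovolume),
    .groups = "drop")
  out$mean_size <- ifelse(out$total_abundance > 0,
                          out$total_biovolume / out$total_abundance, NA_real_)
  if (anyNA(out$mean_size)) {
    warn("Samples with zero total abundance: mean size reported as NA.")
  }
  out$scope <- scope
  out <- add_lagged_month(out, origin = origin)
  dplyr::arrange(
    out[c("scope", "scope_id", "date", "lagged_month", "total_abundance",
          "total_biovolume", "mean_size")],
    .data$scope_id, .data$lagged_month)
}

#' Identify the small-species set by the bottom-quartile rule
#'
#' Species are ranked by their average biovolume (unweighted mean of the
#' cell biovolume over all samples where the species is present, pooled
#' across all communities); the smallest `floor(S * q)` species (at least
#' one) form the small set. Ties at the cut are broken by species id
#' (lexicographically smaller id included).
#'
#' @inheritParams species_size_series
#' @param q Quantile defining "small" (default 0.25, the last quartile).
#' @return A `small_species_set`: list with `members` (character), `threshold`
#'   (largest member's average biovolume, um^3), `q`, and `ranking` (tibble of
#'   all species' average biovolumes).
#' @export
classify_small_species <- function(observations, q = 0.25) {
  if (q <= 0 || q > 1) abort("`q` must be in (0, 1].")
  observations <- observations[observations$abundance > 0, ]
  avg <- dplyr::summarise(
    dplyr::group_by(observations, .data$species_id),
    avg_biovolume = mean(.data$cell_biovolume),
    n_samples = dplyr::n(), .groups = "drop")
  s <- nrow(avg)
  if (s < ceiling(1 / q)) {
    abort(sprintf("Need at least %d species for q = %g (found %d).",
                  ceiling(1 / q), q, s))
  }
  avg <- dplyr::arrange(avg, .data$avg_biovolume, .data$species_id)
  n_small <- max(1L, floor(s * q))
  members <- avg$species_id[seq_len(n_small)]
  structure(list(members = members,
                 threshold = avg$avg_biovolume[n_small],
                 q = q, ranking = avg),
            class = "small_species_set")
}

#' @export
print.small_species_set <- function(x, ...) {
  cat(sprintf(
    "<small_species_set> %d of %d species (q = %g), threshold %.4g um^3\n",
    length(x$members), nrow(x$ranking), x$q, x$threshold))
  invisible(x)
}

#' Proportion of small species (Small%) per sample
#'
#' The abundance-weighted share of cells belonging to the small-species set
#' (default), or the share of species richness (`weighting = "richness"`).
#' The abundance-weighted form is the default because declining Small% in
#' field data traces to the reduced relative abundance of small taxa.
#'
#' @inheritParams community_size
#' @param small_set A [classify_small_species()] result (or a character
#'   vector of species ids).
#' @param weighting `"abundance"` (default) or `"richness"`.
#' @return Tibble `scope`, `scope_id`, `date`, `lagged_month`,
#'   `small_fraction` in \[0, 1\], `weighting`. Empty samples give `NA`.
#' @export
small_fraction <- function(observations, small_set,
                           scope = c("station", "wcz", "region"),
                           weighting = c("abundance", "richness"),
                           origin = NULL) {
  scope <- match.arg(scope)
  weighting <- match.arg(weighting)
  members <- if (inherits(small_set, "small_species_set")) {
    small_set$members
  } else {
    as.character(small_set)
  }
  observations$scope_id <- scope_column(observations, scope)
  observations$is_small <- observations$species_id %in% members
  grouped <- dplyr::group_by(observations, .data$scope_id, .data$date)
  out <- if (weighting == "abundance") {
    dplyr::summarise(grouped,
                     small_fraction = ifelse(sum(.data$abundance) > 0,
                                             sum(.data$abundance[.data$is_small]) /
                                               sum(.data$abundance),
                                             NA_real_),
                     .groups = "drop")
  } else {
    dplyr::summarise(grouped,
                     small_fraction =
                       dplyr::n_distinct(.data$species_id[.data$is_small]) /
                       dplyr::n_distinct(.data$species_id),
                     .groups = "drop")
  }
  out$scope <- scope
  out$weighting <- weighting
  out <- add_lagged_month(out, origin = origin)
  dplyr::arrange(
    out[c("scope", "scope_id", "date", "lagged_month", "small_fraction",
          "weighting")],
    .data$scope_id, .data$lagged_month)
}

#' Equivalent spherical diameter from biovolume
#'
#' @param v Cell biovolume (um^3), strictly positive.
#' @return ESD in um: `(6 v / pi)^(1/3)`.
#' @export
#' @examples
#' esd_from_biovolume(pi / 6) # 1 um
esd_from_biovolume <- function(v) {
  if (any(!is.finite(v) | v <= 0)) abort("Biovolume must be positive and finite.")
  (6 * v / pi)^(1 / 3)
}

#' Select the most abundant species per taxonomic group
#'
#' Ranks species within each group by total cell abundance summed over all
#' samples and keeps the requested number per group (default: top 10 diatoms,
#' top 10 dinoflagellates, top 5 others). Ties break by species id; ranking
#' is invariant to row order.
#'
#' @inheritParams species_size_series
#' @param counts Named integer vector of per-group counts.
#' @return Tibble `species_id`, `group`, `total_abundance`, `rank` (within
#'   group).
#' @export
select_top_species <- function(observations,
                               counts = c(diatom = 10, dinoflagellate = 10,
                                          other = 5)) {
  totals <- dplyr::summarise(
    dplyr::group_by(observations, .data$group, .data$species_id),
    total_abundance = sum(.data$abundance), .groups = "drop")
  out <- purrr::map_dfr(names(counts), function(g) {
    sub <- totals[totals$group == g, ]
    k <- counts[[g]]
    if (nrow(sub) < k) {
      abort(sprintf("Group '%s' has %d species; %d requested.",
                    g, nrow(sub), k))
    }
    sub <- dplyr::arrange(sub, dplyr::desc(.data$total_abundance),
                          .data$species_id)
    sub <- sub[seq_len(k), ]
    sub$rank <- seq_len(k)
    sub
  })
  out[c("species_id", "group", "total_abundance", "rank")]
}
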