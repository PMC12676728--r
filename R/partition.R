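window_mask <- function(lagged, window) {
  lagged >= window[1] & lagged <= window[2]
}

partition_one <- function(sub, w0, w1) {
  in0 <- window_mask(sub$lagged_month, w0)
  in1 <- window_mask(sub$lagged_month, w1)
  if (!any(in0) || !any(in1)) {
    abort("Empty analysis window; no samples in scope.")
  }
  win_stats <- function(rows) {
    tot <- sum(rows$abundance)
    dplyr::summarise(
      dplyr::group_by(rows, .data$species_id),
      p_bar = sum(.data$abundance) / tot,
      v_bar = sum(.data$abundance * .data$cell_biovolume) /
        sum(.data$abundance),
      .groups = "drop")
  }
  s0 <- win_stats(sub[in0, ])
  s1 <- win_stats(sub[in1, ])
  all <- dplyr::full_join(s0, s1, by = "species_id",
                          suffix = c("_0", "_1"))
  # a species absent from one window contributes through p = 0 there;
  # its biovolume in the missing window is carried over so the
  # within-species term is exactly zero for it
  all$p_bar_0[is.na(all$p_bar_0)] <- 0
  all$p_bar_1[is.na(all$p_bar_1)] <- 0
  all$v_bar_0 <- ifelse(is.na(all$v_bar_0), all$v_bar_1, all$v_bar_0)
  all$v_bar_1 <- ifelse(is.na(all$v_bar_1), all$v_bar_0, all$v_bar_1)
  c0 <- sum(all$p_bar_0 * all$v_bar_0)
  c1 <- sum(all$p_bar_1 * all$v_bar_1)
  within <- sum((all$p_bar_0 + all$p_bar_1) / 2 * (all$v_bar_1 - all$v_bar_0))
  comp <- sum((all$v_bar_0 + all$v_bar_1) / 2 * (all$p_bar_1 - all$p_bar_0))
  tibble::tibble(c0 = c0, c1 = c1, delta_c = c1 - c0,
                 within_species = within, composition = comp,
                 residual = within + comp - (c1 - c0))
}

#' Exact partition of community mean-size change
#'
#' Splits the change in community mean cell size between two time windows
#' into a within-species component (size shift: species' biovolumes change
#' at midpoint-averaged abundance shares) and a composition component
#' (species shift: abundance shares move between species of different
#' midpoint-averaged sizes). With the midpoint (Bennet) weights
#' `within = sum (p0+p1)/2 (v1-v0)` and
#' `composition = sum (v0+v1)/2 (p1-p0)`
#' the two components sum to `delta C` exactly, with no cross term.
#' Window statistics are cell-weighted: `p_i(w)` is the species' share of
#' all cells in the window and `v_i(w)` its abundance-weighted mean
#' biovolume, so `C(w) = sum p_i v_i` is the window's community mean size.
#'
#' @param observations Observation tibble.
#' @param scope `"station"` (default), `"wcz"` or `"region"`.
#' @param window0,window1 Integer length-2 lagged-month ranges
#'   `c(first, last)`, inclusive; default the first and last 36 months of
#'   the record.
#' @param origin Origin for the lagged-month axis.
#' @return A `partition_result` tibble: one row per scope unit with `c0`,
#'   `c1`, `delta_c`, `within_species`, `composition`, `residual` (um^3)
#'   and the window bounds.
#' @export
partition_community_change <- function(observations,
                                       scope = c("station", "wcz", "region"),
                                       window0 = NULL, window1 = NULL,
                                       origin = NULL) {
  scope <- match.arg(scope)
  observations <- observations[observations$abundance > 0, ]
  observations <- add_lagged_month(observations, origin = origin)
  t_max <- max(observations$lagged_month)
  window0 <- window0 %||% c(0L, min(35L, t_max %/% 2))
  window1 <- window1 %||% c(max(t_max - 35L, t_max %/% 2 + 1L), t_max)
  observations$scope_id <- scope_column(observations, scope)
  out <- dplyr::group_modify(
    dplyr::group_by(observations, .data$scope_id),
    function(sub, keys) partition_one(sub, window0, window1))
  out <- dplyr::ungroup(out)
  out$scope <- scope
  out$window0_start <- window0[1]; out$window0_end <- window0[2]
  out$window1_start <- window1[1]; out$window1_end <- window1[2]
  out <- out[c("scope", "scope_id", "window0_start", "window0_end",
               "window1_start", "window1_end", "c0", "c1", "delta_c",
               "within_species", "composition", "residual")]
  structure(out, class = c("partition_result", class(out)))
}

majority_class <- function(classes) {
  tab <- sort(table(classes), decreasing = TRUE)
  if (length(tab) > 1 && tab[1] == tab[2]) return("none")
  names(tab)[1]
}

#' Classify the community size-change scenario
#'
#' Combines the species-level trend summary (majority class across species),
#' the Small% trend class and the community mean-size trend class into the
#' two-scenario framework: scenario `i` (community miniaturization expected)
#' when species sizes decline while Small% increases or is stable; scenario
#' `ii` (uncertain/offsetting pattern) when species sizes and Small% both
#' decline; `none` otherwise.
#'
#' @param species_classes Character vector of per-species trend classes
#'   (`decline`/`increase`/`none`).
#' @param small_class Small% trend class.
#' @param community_class Community mean-size trend class (reported, not
#'   used for the scenario call).
#' @return One-row tibble `species_summary`, `small_class`,
#'   `community_class`, `scenario` (`"i"`, `"ii"` or `"none"`).
#' @export
scenario_classify <- function(species_classes, small_class,
                              community_class = "none") {
  if (length(species_classes) == 0) abort("Need at least one species class.")
  sp <- majority_class(species_classes)
  scenario <- if (sp == "decline" && small_class %in% c("increase", "none")) {
    "i"
  } else if (sp == "decline" && small_class == "decline") {
    "ii"
  } else {
    "none"
  }
  tibble::tibble(species_summary = sp, small_class = small_class,
                 community_class = community_class, scenario = scenario)
}
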