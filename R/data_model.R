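#' Column-name dialects for delimited monitoring tables
#'
#' Monitoring exports rarely share column names; a dialect maps the canonical
#' field names used throughout the package to the column names found in a
#' particular file. Every value is the name of a column in the file.
#'
#' @param station_id,wcz,date,species_id,group,abundance,cell_biovolume
#'   Column names in the observation file. `wcz` (water control zone, the
#'   regional grouping of stations) may be `NA` if the file has no zone column.
#' @return A named character vector usable as the `dialect` argument of
#'   [read_observations()].
#' @export
#' @examples
#' obs_dialect(species_id = "species", cell_biovolume = "biovolume")
obs_dialect <- function(station_id = "station_id", wcz = "wcz", date = "date",
                        species_id = "species_id", group = "group",
                        abundance = "abundance",
                        cell_biovolume = "cell_biovolume") {
  c(station_id = station_id, wcz = wcz, date = date, species_id = species_id,
    group = group, abundance = abundance, cell_biovolume = cell_biovolume)
}

#' @rdname obs_dialect
#' @export
env_dialect <- function(station_id = "station_id", date = "date") {
  c(station_id = station_id, date = date)
}

phyto_groups <- c("diatom", "dinoflagellate", "other")

# Parse year-month input: "2000-01", "2000-01-15", Date, or POSIXt.
# Day-of-month is discarded; sampling granularity is monthly.
parse_year_month <- function(x) {
  if (inherits(x, "Date")) {
    out <- x
  } else if (inherits(x, "POSIXt")) {
    out <- as.Date(x)
  } else {
    x <- as.character(x)
    x <- ifelse(grepl("^\\d{4}-\\d{2}$", x), paste0(x, "-01"), x)
    out <- as.Date(x)
  }
  as.Date(format(out, "%Y-%m-01"))
}

#' Months elapsed since the first sampling occasion
#'
#' The regression time axis used throughout: the whole number of calendar
#' months between a sampling date and the origin (first) sampling date, with
#' the origin mapping to 0.
#'
#' @param date,origin_date Year-month values (`Date`, `"YYYY-MM"` strings, or
#'   anything [as.Date()] accepts); day-of-month is ignored.
#' @return Integer vector of elapsed months.
#' @export
#' @examples
#' lagged_month("2000-12", "2000-01") # 11
lagged_month <- function(date, origin_date) {
  d <- parse_year_month(date)
  o <- parse_year_month(origin_date)
  dy <- as.integer(format(d, "%Y")) - as.integer(format(o, "%Y"))
  dm <- as.integer(format(d, "%m")) - as.integer(format(o, "%m"))
  out <- 12L * dy + dm
  if (any(out < 0, na.rm = TRUE)) {
    abort("`date` precedes `origin_date`; lagged months must be non-negative.")
  }
  out
}

#' Add a lagged-month column to a monitoring table
#'
#' @param data A data frame with a `date` column of year-month values.
#' @param origin Origin date; defaults to the earliest date in `data`.
#' @return `data` with a `lagged_month` integer column.
#' @export
add_lagged_month <- function(data, origin = NULL) {
  stopifnot("date" %in% names(data))
  origin <- origin %||% min(parse_year_month(data$date))
  dplyr::mutate(data, lagged_month = lagged_month(.data$date, .env$origin))
}

reject_report <- function(accepted, rejects, what, quiet) {
  if (!quiet) {
    inform(sprintf("%s: %d records accepted, %d rejected.",
                   what, accepted, nrow(rejects)))
  }
  rejects
}

#' Read and validate a species-observation table
#'
#' Reads a delimited text file of station-month-species records (cell
#' abundance in cells/L and mean cell biovolume in um^3 per cell), validates
#' each row, and returns the accepted records as a tibble. Rows violating the
#' record invariants are dropped and reported, with the source row number and
#' a reason, in the `"rejects"` attribute (also retrievable with
#' [rejected_rows()]).
#'
#' Validation rules: abundance must be present and non-negative; a positive
#' abundance requires a finite positive biovolume; the taxonomic group must be
#' one of `diatom`, `dinoflagellate`, `other`; duplicated
#' (station, date, species) keys keep the first row with a warning.
#'
#' @param path Path to a delimited text file with a header row.
#' @param dialect Column-name mapping from [obs_dialect()].
#' @param delim Field delimiter (default comma).
#' @param quiet Suppress the accepted/rejected count message.
#' @return A tibble with columns `station_id`, `wcz`, `date`, `species_id`,
#'   `group`, `abundance`, `cell_biovolume`.
#' @export
read_observations <- function(path, dialect = obs_dialect(), delim = ",",
                              quiet = FALSE) {
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  have_wcz <- !is.na(dialect[["wcz"]]) && dialect[["wcz"]] %in% names(raw)
  required <- dialect[setdiff(names(dialect), "wcz")]
  missing <- setdiff(unname(required), names(raw))
  if (length(missing) > 0) {
    abort(paste0("Missing required column(s): ", paste(missing, collapse = ", ")))
  }
  out <- tibble::tibble(
    .row = seq_len(nrow(raw)),
    station_id = as.character(raw[[dialect[["station_id"]]]]),
    wcz = if (have_wcz) as.character(raw[[dialect[["wcz"]]]]) else NA_character_,
    date = parse_year_month(raw[[dialect[["date"]]]]),
    species_id = as.character(raw[[dialect[["species_id"]]]]),
    group = tolower(as.character(raw[[dialect[["group"]]]])),
    abundance = suppressWarnings(as.numeric(raw[[dialect[["abundance"]]]])),
    cell_biovolume = suppressWarnings(as.numeric(raw[[dialect[["cell_biovolume"]]]]))
  )
  reason <- dplyr::case_when(
    is.na(out$date) ~ "unparseable date",
    is.na(out$abundance) ~ "abundance missing",
    out$abundance < 0 ~ "negative abundance",
    !(out$group %in% phyto_groups) ~ "unknown group",
    out$abundance > 0 & is.na(out$cell_biovolume) ~ "biovolume missing",
    out$abundance > 0 & (!is.finite(out$cell_biovolume) | out$cell_biovolume <= 0) ~
      "nonpositive biovolume",
    TRUE ~ NA_character_
  )
  rejects <- tibble::tibble(row = out$.row[!is.na(reason)],
                            reason = reason[!is.na(reason)])
  out <- out[is.na(reason), ]
  dup <- duplicated(out[c("station_id", "date", "species_id")])
  if (any(dup)) {
    warn(sprintf("%d duplicate (station, date, species) rows; keeping first.",
                 sum(dup)))
    out <- out[!dup, ]
  }
  out$.row <- NULL
  attr(out, "rejects") <- reject_report(nrow(out), rejects, "observations", quiet)
  out
}

#' Rejected rows from a reader
#'
#' @param x A tibble returned by [read_observations()] or [read_environment()].
#' @return A tibble of source row numbers and rejection reasons.
#' @export
rejected_rows <- function(x) {
  attr(x, "rejects") %||% tibble::tibble(row = integer(), reason = character())
}

#' Read an environmental-parameter table
#'
#' Reads a wide delimited file (one row per station-month, one column per
#' environmental parameter) into a long tibble. Values reported below the
#' analytical detection limit, written as `"<limit"` (e.g. `"<0.1"`), are
#' substituted according to `dl_rule` and flagged in `below_detection`.
#'
#' @param path Path to the delimited file.
#' @param dialect Column mapping from [env_dialect()]; every column not named
#'   there is treated as a parameter column.
#' @param dl_rule Below-detection substitution: `"half"` (half the limit, the
#'   common monitoring convention and default), `"zero"`, or `"asis"` (the
#'   limit itself).
#' @param delim Field delimiter.
#' @param quiet Suppress the count message.
#' @return A long tibble with columns `station_id`, `date`, `param`, `value`,
#'   `below_detection`. Negative concentrations and out-of-range temperatures
#'   are rejected (see [rejected_rows()]).
#' @export
read_environment <- function(path, dialect = env_dialect(),
                             dl_rule = c("half", "zero", "asis"),
                             delim = ",", quiet = FALSE) {
  dl_rule <- match.arg(dl_rule)
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE,
                           col_types = readr::cols(.default = readr::col_character()))
  missing <- setdiff(unname(dialect), names(raw))
  if (length(missing) > 0) {
    abort(paste0("Missing required column(s): ", paste(missing, collapse = ", ")))
  }
  params <- setdiff(names(raw), unname(dialect))
  if (length(params) == 0) abort("No parameter columns found.")
  long <- tibble::tibble(
    .row = seq_len(nrow(raw)),
    station_id = as.character(raw[[dialect[["station_id"]]]]),
    date = parse_year_month(raw[[dialect[["date"]]]])
  )
  long <- tidyr::pivot_longer(
    dplyr::bind_cols(long, raw[params]),
    cols = dplyr::all_of(params), names_to = "param", values_to = ".raw"
  )
  bd <- grepl("^\\s*<", long$.raw)
  limit <- suppressWarnings(as.numeric(sub("^\\s*<\\s*", "", long$.raw)))
  plain <- suppressWarnings(as.numeric(long$.raw))
  long$value <- ifelse(bd,
                       switch(dl_rule, half = limit / 2, zero = 0, asis = limit),
                       plain)
  long$below_detection <- bd
  long <- long[!is.na(long$.raw), ]
  is_temp <- long$param == "temperature"
  reason <- dplyr::case_when(
    is.na(long$value) ~ "unparseable value",
    !is_temp & long$value < 0 ~ "negative concentration",
    is_temp & (long$value <= -5 | long$value >= 45) ~ "temperature out of range",
    TRUE ~ NA_character_
  )
  rejects <- tibble::tibble(row = long$.row[!is.na(reason)],
                            param = long$param[!is.na(reason)],
                            reason = reason[!is.na(reason)])
  long <- long[is.na(reason), ]
  dup <- duplicated(long[c("station_id", "date", "param")])
  if (any(dup)) {
    warn(sprintf("%d duplicate (station, date, param) values; keeping first.",
                 sum(dup)))
    long <- long[!dup, ]
  }
  long$.raw <- NULL
  long$.row <- NULL
  attr(long, "rejects") <- reject_report(nrow(long), rejects, "environment", quiet)
  long
}

#' Molar N/P ratio from mass concentrations
#'
#' Converts dissolved inorganic nitrogen (mg N/L) and phosphate to molar
#' concentrations and returns their ratio, comparable to the Redfield value
#' of 16. Monitoring exports report phosphate either as ug P/L (default
#' interpretation) or as ug PO4/L; set `po4_as_p = FALSE` for the latter.
#'
#' @param din_mg_per_l DIN in mg N per litre.
#' @param po4_ug_per_l Phosphate in ug per litre (P by default).
#' @param po4_as_p Interpret phosphate mass as elemental P (default) rather
#'   than as the PO4 ion.
#' @return Dimensionless molar N:P ratio; `NA` (with a warning) where
#'   phosphate is zero or negative.
#' @export
#' @examples
#' molar_np_ratio(16 * 14.007 / 1000, 30.974) # 16
molar_np_ratio <- function(din_mg_per_l, po4_ug_per_l, po4_as_p = TRUE) {
  n_umol <- din_mg_per_l * 1000 / 14.007
  p_mass <- if (po4_as_p) 30.974 else 94.971
  p_umol <- po4_ug_per_l / p_mass
  bad <- !is.na(p_umol) & p_umol <= 0
  if (any(bad)) {
    warn("N/P undefined where phosphate <= 0; returning NA.")
  }
  out <- n_umol / p_umol
  out[bad] <- NA_real_
  out
}

#' Pivot a long environment table to one column per parameter
#'
#' @param environment Long tibble from [read_environment()] or
#'   [generate_environment()].
#' @return A tibble with one row per (station, date) and one column per
#'   parameter.
#' @export
env_wide <- function(environment) {
  tidyr::pivot_wider(environment[c("station_id", "date", "param", "value")],
                     names_from = "param", values_from = "value")
}

#' Join observations with environmental parameters
#'
#' Inner join on (station, date). Sample keys present on only one side are
#' reported in the `"unmatched"` attribute; an empty intersection is an error.
#'
#' @param observations Observation tibble ([read_observations()]).
#' @param environment Long environment tibble ([read_environment()]).
#' @param params Optional character vector restricting the joined parameters.
#' @return The joined analysis tibble with a `lagged_month` column (origin =
#'   earliest observation date) and one column per environmental parameter.
#' @export
join_env <- function(observations, environment, params = NULL) {
  if (!is.null(params)) {
    environment <- environment[environment$param %in% params, ]
  }
  wide <- env_wide(environment)
  obs_keys <- dplyr::distinct(observations, .data$station_id, .data$date)
  env_keys <- dplyr::distinct(wide, .data$station_id, .data$date)
  unmatched <- dplyr::bind_rows(
    dplyr::mutate(dplyr::anti_join(obs_keys, env_keys,
                                   by = c("station_id", "date")),
                  side = "observations"),
    dplyr::mutate(dplyr::anti_join(env_keys, obs_keys,
                                   by = c("station_id", "date")),
                  side = "environment")
  )
  joined <- dplyr::inner_join(observations, wide, by = c("station_id", "date"))
  if (nrow(joined) == 0) {
    abort(paste0(
      "No overlapping (station, date) keys between observations and ",
      "environment (", nrow(obs_keys), " vs ", nrow(env_keys), " keys)."))
  }
  joined <- add_lagged_month(joined, origin = min(observations$date))
  joined <- dplyr::arrange(joined, .data$station_id, .data$date,
                           .data$species_id)
  attr(joined, "unmatched") <- dplyr::arrange(unmatched, .data$side,
                                              .data$station_id, .data$date)
  joined
}

#' Unmatched sample keys from a join
#'
#' @param x Result of [join_env()].
#' @return Tibble of (station, date, side) keys lacking a partner.
#' @export
unmatched_keys <- function(x) {
  attr(x, "unmatched") %||%
    tibble::tibble(station_id = character(), date = as.Date(character()),
                   side = character())
}

#' Write a tidy table with a stable column order
#'
#' Thin wrapper over [readr::write_csv()] used for all pipeline outputs.
#'
#' @param data Tibble to write.
#' @param path Output path.
#' @return `data`, invisibly.
#' @export
write_tidy_csv <- function(data, path) {
  readr::write_csv(data, path)
  invisible(data)
}
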