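# Tabular input/output. All tables are plain CSV (UTF-8, "." decimal,
# ISO-8601 dates) so that artifacts are exchangeable across languages.

consumer_cols <- c("individual_id", "capture_date", "segment_index",
                   "d13C", "d15N", "season")
source_cols <- c("group", "mu_d13C", "sd_d13C", "mu_d15N", "sd_d15N",
                 "conc_C", "conc_N", "tdf_d13C_mean", "tdf_d15N_mean",
                 "tdf_sd_d13C", "tdf_sd_d15N")
scat_cols <- c("scat_id", "season", "items")

check_schema <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(what, " table is missing column(s): ", paste(missing, collapse = ", "))
  }
  invisible(df)
}

#' Read a consumer (whisker segment) table
#'
#' One row per whisker segment: `individual_id`, `capture_date`
#' (ISO-8601), `segment_index` (0 = segment closest to the follicle,
#' i.e. most recent growth), `d13C`, `d15N` (permil), `season`
#' (`"summer"` or `"winter"`). Duplicated (individual, segment) pairs and
#' non-finite isotope values are rejected; unparseable dates are reported
#' with their row index.
#'
#' @param path path to a CSV file.
#' @return A validated data frame with parsed `capture_date`.
#' @export
read_consumer_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  check_schema(df, consumer_cols, "consumer")
  validate_consumer_table(df)
}

#' Validate an in-memory consumer table
#'
#' @param df data frame with the consumer-table columns.
#' @return The validated data frame (dates parsed to `Date`).
#' @export
validate_consumer_table <- function(df) {
  check_schema(df, consumer_cols, "consumer")
  dates <- as.Date(as.character(df$capture_date), format = "%Y-%m-%d")
  bad <- which(is.na(dates))
  if (length(bad)) stop("unparseable capture_date at row(s): ", paste(bad, collapse = ", "))
  df$capture_date <- dates
  for (col in c("d13C", "d15N", "segment_index")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(!is.finite(v))
    if (length(bad)) stop("non-finite ", col, " at row(s): ", paste(bad, collapse = ", "))
    df[[col]] <- v
  }
  df$segment_index <- as.integer(df$segment_index)
  if (any(!nzchar(df$season)) || any(is.na(df$season))) stop("season labels must be nonempty")
  key <- paste(df$individual_id, df$segment_index)
  if (anyDuplicated(key)) {
    stop("duplicated (individual_id, segment_index): ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  }
  df
}

#' Read a diet source (end-member) table
#'
#' One row per diet group with isotope means/sds (permil), elemental
#' concentrations `conc_C`/`conc_N` (mass fraction in (0, 1]), and TDF
#' means/sds per isotope.
#'
#' @param path path to a CSV file.
#' @return A validated data frame; `nrow` is the number of groups K.
#' @export
read_source_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  validate_source_table(df)
}

#' Validate an in-memory source table
#' @param df data frame with the source-table columns.
#' @return The validated data frame.
#' @export
validate_source_table <- function(df) {
  check_schema(df, source_cols, "source")
  if (anyDuplicated(df$group)) stop("duplicated group names in source table")
  num_cols <- setdiff(source_cols, "group")
  for (col in num_cols) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(!is.finite(v))
    if (length(bad)) stop("non-finite ", col, " at row(s): ", paste(bad, collapse = ", "))
    df[[col]] <- v
  }
  if (any(df$sd_d13C < 0) || any(df$sd_d15N < 0) ||
      any(df$tdf_sd_d13C < 0) || any(df$tdf_sd_d15N < 0)) {
    stop("standard deviations must be nonnegative")
  }
  for (col in c("conc_C", "conc_N")) {
    if (any(df[[col]] <= 0 | df[[col]] > 1)) {
      stop(col, " must lie in (0, 1]")
    }
  }
  df
}

#' Read a scat occurrence table
#'
#' One row per scat: `scat_id`, `season`, and `items`, a
#' semicolon-separated list of detected diet groups (possibly empty).
#'
#' @param path path to a CSV file.
#' @return A validated data frame.
#' @export
read_scat_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  check_schema(df, scat_cols, "scat")
  df$items[is.na(df$items)] <- ""
  if (anyDuplicated(df$scat_id)) stop("duplicated scat_id")
  df
}

#' Write a pipeline table to CSV
#'
#' Values round-trip at full double precision (15 significant digits).
#'
#' @param df data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(df, path) {
  out <- df
  for (col in names(out)) {
    if (is.numeric(out[[col]]) && !is.integer(out[[col]])) {
      out[[col]] <- formatC(out[[col]], digits = 15, format = "g")
    }
  }
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Flag season labels that contradict capture dates
#'
#' Season labels are data (assigned by fieldwork period), never inferred;
#' this helper only warns when a capture date falls in the park-open
#' window but is labelled winter, or vice versa.
#'
#' @param consumers validated consumer table.
#' @param cfg a `whiskr_config` (park calendar).
#' @return Integer vector of suspicious row indices (invisibly); warns if
#'   any are found.
#' @export
check_season_labels <- function(consumers, cfg = default_config()) {
  doy <- day_of_year(consumers$capture_date)
  open <- doy >= cfg$park_open_doy & doy < cfg$park_close_doy
  suspicious <- which((open & consumers$season == "winter") |
                      (!open & consumers$season == "summer"))
  if (length(suspicious)) {
    warning("season label contradicts capture date at row(s): ",
            paste(suspicious, collapse = ", "))
  }
  invisible(suspicious)
}

# day-of-year with Feb-29 folded so every year has 365 days
day_of_year <- function(dates) {
  doy <- as.integer(format(dates, "%j"))
  leap <- as.integer(format(dates, "%Y")) %% 4 == 0 &
    (as.integer(format(dates, "%Y")) %% 100 != 0 |
       as.integer(format(dates, "%Y")) %% 400 == 0)
  after_feb <- leap & doy >= 60
  doy[after_feb] <- doy[after_feb] - 1L
  pmin(doy, 365L)
}
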