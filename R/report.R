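# Assembly of stage outputs: subsidy series aligned to the park
# calendar, subsidy correlation, event-relative changes, and the final
# report document.

#' Two-week subsidy series from per-segment diet posteriors
#'
#' Posterior mean wolf-carrion and human-food proportions of every
#' whisker segment are spread over their calendar windows, smoothed
#' with a circular two-week running average, and sampled at 26 two-week
#' steps (block midpoints). Each series also gets a z-scored version
#' ("standardized proportion") and a park-open indicator.
#'
#' @param segment_posteriors list of `whiskr_posterior` from
#'   [fit_individual_segments()], aligned with `windows` rows.
#' @param windows data frame with `window_start`, `window_end` per
#'   segment (e.g. `attr(consumers, "windows")` or built via
#'   [segment_windows()]).
#' @param cfg a `whiskr_config`.
#' @return Data frame with `step`, `day`, `wolf`, `human`, `wolf_z`,
#'   `human_z`, `park_open`.
#' @export
subsidy_series <- function(segment_posteriors, windows, cfg = default_config()) {
  stopifnot(length(segment_posteriors) == nrow(windows))
  obs <- windows
  obs$wolf <- vapply(segment_posteriors,
                     function(p) mean(p$draws[, "wolf_carrion"]), numeric(1))
  obs$human <- vapply(segment_posteriors,
                      function(p) mean(p$draws[, "human_foods"]), numeric(1))
  days <- seq(7, 365, by = 14)[1:26]
  take <- function(varname) {
    s <- running_average(stack_to_julian(obs, varname), 14)
    s$value[days]
  }
  wolf <- take("wolf")
  human <- take("human")
  zs <- function(v) {
    ok <- !is.na(v)
    if (sd(v[ok]) == 0) return(ifelse(ok, 0, NA_real_))
    (v - mean(v[ok])) / sd(v[ok])
  }
  data.frame(
    step = 1:26, day = days, wolf = wolf, human = human,
    wolf_z = zs(wolf), human_z = zs(human),
    park_open = days >= cfg$park_open_doy & days < cfg$park_close_doy
  )
}

#' Correlation between wolf and human subsidy series
#'
#' @param series a [subsidy_series()] data frame.
#' @return List with Pearson `r` and `R2 = r^2` over complete steps.
#' @export
subsidy_correlation <- function(series) {
  ok <- complete.cases(series$wolf, series$human)
  if (sum(ok) < 5) stop("need >= 5 paired steps")
  if (sd(series$wolf[ok]) == 0 || sd(series$human[ok]) == 0) {
    stop("zero-variance series")
  }
  r <- cor(series$wolf[ok], series$human[ok])
  list(r = r, R2 = r^2, n = sum(ok))
}

#' Subsidy changes aligned to park opening and closing
#'
#' For each event (park opening, park closing) and each subsidy series,
#' reports the percent change at +2 and +4 weeks after the event
#' relative to the pre-event baseline (mean of the two steps preceding
#' the event; steps wrap around the year).
#'
#' @param series a [subsidy_series()] data frame.
#' @param cfg a `whiskr_config`.
#' @return Data frame `event`, `series`, `lag_weeks`, `baseline`,
#'   `value`, `percent_change`.
#' @export
park_alignment <- function(series, cfg = default_config()) {
  step_of <- function(doy) which(abs(series$day - doy) == min(abs(series$day - doy)))[1]
  events <- c(opening = step_of(cfg$park_open_doy),
              closing = step_of(cfg$park_close_doy))
  n_steps <- nrow(series)
  wrap <- function(i) (i - 1) %% n_steps + 1
  out <- list()
  for (ev in names(events)) {
    e <- events[[ev]]
    for (var in c("wolf", "human")) {
      v <- series[[var]]
      base_idx <- wrap(c(e - 2, e - 1))
      base <- mean(v[base_idx])
      if (any(is.na(v[base_idx]))) stop("event baseline outside series span")
      for (lag in c(1L, 2L)) {
        val <- v[wrap(e + lag)]
        if (is.na(val)) stop("event lag outside series span")
        out[[length(out) + 1L]] <- data.frame(
          event = ev, series = var, lag_weeks = 2L * lag,
          baseline = base, value = val,
          percent_change = if (base != 0) 100 * (val - base) / base else NA_real_
        )
      }
    }
  }
  do.call(rbind, out)
}

#' Assemble the final report
#'
#' Collects every stage's headline quantities into one JSON-ready
#' document with provenance (seed, package version). Missing stages are
#' an error naming what is absent.
#'
#' @param stages named list with elements `seasonal_delta`, `niche`,
#'   `population_diet`, `strategies`, `pianka`, `simper`, `colwell`,
#'   `wavelet`, `subsidy`.
#' @param seed the run seed recorded as provenance.
#' @param path optional path to write JSON.
#' @return The report list (invisibly if written).
#' @export
build_report <- function(stages, seed = NA_integer_, path = NULL) {
  required <- c("seasonal_delta", "niche", "population_diet", "strategies",
                "pianka", "simper", "colwell", "wavelet", "subsidy")
  missing <- setdiff(required, names(stages))
  if (length(missing)) {
    stop("missing stage(s): ", paste(missing, collapse = ", "))
  }
  report <- c(
    list(provenance = list(
      package = "whiskr",
      version = as.character(utils::packageVersion("whiskr")),
      seed = seed
    )),
    stages[required]
  )
  if (!is.null(path)) {
    json <- jsonlite::toJSON(report, auto_unbox = TRUE, digits = 10,
                             dataframe = "rows", force = TRUE)
    writeLines(json, path)
    return(invisible(report))
  }
  report
}
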