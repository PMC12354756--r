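# Whisker segments -> calendar windows -> day-of-year series.

#' Calendar windows of whisker segments
#'
#' A whisker grows at a constant rate, so a segment of fixed length maps
#' to a fixed number of days. Segment 0 (closest to the follicle) ends at
#' the capture date; segment i spans the half-open interval
#' `[capture - (i+1)*d, capture - i*d)` with
#' `d = round(segment_length_mm / growth_rate_mm_per_day)` days
#' (16 by default; set `window_days_override = 18` for the coarser
#' ~18-day convention).
#'
#' @param capture_date a `Date`.
#' @param n_segments number of segments (>= 1).
#' @param cfg a `whiskr_config`.
#' @return Data frame with `segment_index`, `window_start`, `window_end`
#'   (`window_end` exclusive).
#' @export
segment_windows <- function(capture_date, n_segments, cfg = default_config()) {
  if (cfg$growth_rate_mm_per_day <= 0) stop("growth rate must be positive")
  if (n_segments < 1) stop("n_segments must be >= 1")
  capture_date <- as.Date(capture_date)
  d <- window_days(cfg)
  i <- seq_len(n_segments) - 1L
  data.frame(
    segment_index = i,
    window_start = capture_date - (i + 1L) * d,
    window_end = capture_date - i * d
  )
}

#' Segment window duration in days
#' @param cfg a `whiskr_config`.
#' @return Integer number of days one segment represents.
#' @export
window_days <- function(cfg = default_config()) {
  if (!is.null(cfg$window_days_override)) {
    return(as.integer(cfg$window_days_override))
  }
  as.integer(round(cfg$segment_length_mm / cfg$growth_rate_mm_per_day))
}

#' Label whisker segments by the season of their calendar window
#'
#' Computes each segment's window from the growth model and assigns
#' `"summer"` when the window midpoint falls inside the park-open
#' period, else `"winter"`. Unlike the capture-season label carried in
#' the data, this tracks what each segment actually recorded.
#'
#' @param consumers consumer table.
#' @param cfg a `whiskr_config`.
#' @return `consumers` with `season` replaced by the window-midpoint
#'   season and the windows attached as `attr(, "windows")`.
#' @export
assign_window_season <- function(consumers, cfg = default_config()) {
  wins <- list()
  for (id in unique(consumers$individual_id)) {
    rows <- which(consumers$individual_id == id)
    w <- segment_windows(consumers$capture_date[rows[1]],
                         max(consumers$segment_index[rows]) + 1L, cfg)
    w <- w[match(consumers$segment_index[rows], w$segment_index), ]
    w$row <- rows
    wins[[id]] <- w
  }
  w <- do.call(rbind, wins)
  w <- w[order(w$row), ]
  mid <- w$window_start + floor(as.numeric(w$window_end - w$window_start) / 2)
  doy <- day_of_year(mid)
  consumers$season <- ifelse(doy >= cfg$park_open_doy & doy < cfg$park_close_doy,
                             "summer", "winter")
  attr(consumers, "windows") <- data.frame(
    individual_id = consumers$individual_id,
    segment_index = consumers$segment_index,
    window_start = w$window_start, window_end = w$window_end
  )
  consumers
}

#' Stack segment observations onto a single day-of-year axis
#'
#' Each observation's value is spread uniformly across the days of its
#' calendar window (wrapped around the year, Feb 29 folded into day 365
#' of a 365-day year); the per-day value is the mean over contributing
#' observations and `n` records how many observations contribute. Days
#' with no contribution are `NA`, never zero-filled.
#'
#' @param observations data frame with `window_start`, `window_end`
#'   (exclusive) and the value column named by `variable`.
#' @param variable name of the value column.
#' @return Data frame `day` (1..365), `value`, `n`, with the variable
#'   name stored in `attr(, "variable")`.
#' @export
stack_to_julian <- function(observations, variable) {
  if (!variable %in% names(observations)) {
    stop("unknown variable: ", variable)
  }
  sums <- numeric(365)
  n <- integer(365)
  for (i in seq_len(nrow(observations))) {
    s <- as.Date(observations$window_start[i])
    e <- as.Date(observations$window_end[i])
    if (e <= s) stop("window_end must follow window_start (row ", i, ")")
    days <- seq(s, e - 1, by = "day")
    doy <- day_of_year(days)
    v <- observations[[variable]][i]
    for (dd in doy) {
      sums[dd] <- sums[dd] + v
      n[dd] <- n[dd] + 1L
    }
  }
  value <- ifelse(n > 0, sums / pmax(n, 1L), NA_real_)
  out <- data.frame(day = 1:365, value = value, n = n)
  attr(out, "variable") <- variable
  out
}

#' Circular running average of a day-of-year series
#'
#' Centered moving mean over the available (non-missing) days within a
#' window, circular over the 365-day year. Output is missing wherever no
#' data fall in the window.
#'
#' @param series output of [stack_to_julian()].
#' @param window_days window width in days (default 14, a two-week
#'   running average).
#' @return Data frame of the same shape (`n` counts days with data in
#'   each window).
#' @export
running_average <- function(series, window_days = 14) {
  if (window_days < 1) stop("window_days must be >= 1")
  v <- series$value
  offsets <- seq.int(-(window_days %/% 2), window_days - window_days %/% 2 - 1)
  out_v <- rep(NA_real_, 365)
  out_n <- integer(365)
  for (d in 1:365) {
    idx <- (d + offsets - 1L) %% 365L + 1L
    w <- v[idx]
    ok <- !is.na(w)
    out_n[d] <- sum(ok)
    if (out_n[d] > 0) out_v[d] <- mean(w[ok])
  }
  out <- data.frame(day = 1:365, value = out_v, n = out_n)
  attr(out, "variable") <- attr(series, "variable")
  out
}
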