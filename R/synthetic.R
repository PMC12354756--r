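# Synthetic study generator: sources, seasonal diet trajectories,
# whisker-segment observations, and scat records. Emulates a
# mesocarnivore switching between wolf-killed carrion (winter peak) and
# human food subsidies keyed to a park open/close calendar (summer).

#' Generate a diet source (end-member) table
#'
#' For `K = 4` returns the default four groups (small prey, wolf
#' carrion, human foods, berries) with fixed isotope means chosen to be
#' isotopically distinct, elemental concentrations of (0.47, 0.14),
#' (0.47, 0.14), (0.53, 0.07) and (0.48, 0.01) for C/N respectively, and
#' TDFs from the configuration (2.5/3.4 permil with a -1.0 permil d13C
#' hair adjustment for prey groups; 2.0/3.5 permil for human foods). For
#' other `K`, group means are drawn uniformly in a realistic isotope box
#' and re-drawn until all pairwise distances reach `separation`.
#'
#' @param K number of groups (>= 2).
#' @param separation minimum pairwise Euclidean distance in
#'   (d13C, d15N) space, permil.
#' @param seed optional RNG seed.
#' @param cfg a `whiskr_config`.
#' @return A validated source table (see [read_source_table()]).
#' @export
make_sources <- function(K = 4, separation = 3, seed = NULL,
                         cfg = default_config()) {
  if (K < 2) stop("K must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  if (K == 4) {
    df <- data.frame(
      group = c("small_prey", "wolf_carrion", "human_foods", "berries"),
      mu_d13C = c(-25.0, -27.5, -20.0, -26.5),
      sd_d13C = c(0.6, 0.5, 0.8, 0.5),
      mu_d15N = c(3.5, 1.0, 6.0, -2.0),
      sd_d15N = c(0.7, 0.5, 0.8, 0.5),
      conc_C = c(0.47, 0.47, 0.53, 0.48),
      conc_N = c(0.14, 0.14, 0.07, 0.01),
      stringsAsFactors = FALSE
    )
  } else {
    for (try in 1:1000) {
      mu <- cbind(runif(K, -28, -19), runif(K, -2, 8))
      if (K == 1 || min(dist(mu)) >= separation) break
      if (try == 1000) stop("could not place ", K, " groups ", separation,
                            " permil apart")
    }
    df <- data.frame(
      group = sprintf("group_%02d", seq_len(K)),
      mu_d13C = mu[, 1], sd_d13C = rep(0.5, K),
      mu_d15N = mu[, 2], sd_d15N = rep(0.5, K),
      conc_C = rep(0.5, K), conc_N = rep(0.1, K),
      stringsAsFactors = FALSE
    )
  }
  human <- df$group == "human_foods"
  df$tdf_d13C_mean <- ifelse(human, cfg$tdf_human[["d13C"]],
                             cfg$tdf_default[["d13C"]] + cfg$hair_c13_adjust)
  df$tdf_d15N_mean <- ifelse(human, cfg$tdf_human[["d15N"]],
                             cfg$tdf_default[["d15N"]])
  df$tdf_sd_d13C <- rep(cfg$tdf_sd_default[["d13C"]], K)
  df$tdf_sd_d15N <- rep(cfg$tdf_sd_default[["d15N"]], K)
  dmin <- min(dist(cbind(df$mu_d13C, df$mu_d15N)))
  if (dmin < separation) stop("default groups closer than requested separation")
  validate_source_table(df)
}

#' Default diet trajectory parameters
#'
#' Baseline logits per group plus an annual cosine on the wolf-carrion
#' logit (peaking in early winter, about two months after the park
#' closes) and a step on the human-foods logit while the park is open.
#' Defaults are calibrated so that seasonal mean diets approximate a
#' carrion-dominated winter (~0.6) and a mixed summer with substantial
#' human foods (~0.3).
#'
#' @param cfg a `whiskr_config`.
#' @return A named list of trajectory parameters.
#' @export
trajectory_params <- function(cfg = default_config()) {
  list(
    groups = cfg$source_groups,
    baseline_logit = c(small_prey = -0.09, wolf_carrion = 0.86,
                       human_foods = -0.38, berries = -1.99),
    carrion_amplitude = 0.42,
    carrion_peak_doy = 330,
    park_step = 0.85,
    berries_summer_step = 2.30,
    park_open_doy = cfg$park_open_doy,
    park_close_doy = cfg$park_close_doy
  )
}

#' Build a daily diet-proportion trajectory
#'
#' @param params list as returned by [trajectory_params()]; amplitudes
#'   may be set to zero for a constant trajectory.
#' @return A `whiskr_trajectory`: 365 x K matrix of diet proportions
#'   (rows sum to 1) with the parameters attached.
#' @export
make_trajectory <- function(params = trajectory_params()) {
  groups <- params$groups
  K <- length(groups)
  doy <- 1:365
  logits <- matrix(rep(params$baseline_logit[groups], each = 365), 365, K,
                   dimnames = list(NULL, groups))
  open <- doy >= params$park_open_doy & doy < params$park_close_doy
  if ("wolf_carrion" %in% groups) {
    logits[, "wolf_carrion"] <- logits[, "wolf_carrion"] +
      params$carrion_amplitude * cos(2 * pi * (doy - params$carrion_peak_doy) / 365)
  }
  if ("human_foods" %in% groups) {
    logits[, "human_foods"] <- logits[, "human_foods"] + params$park_step * open
  }
  if ("berries" %in% groups && !is.null(params$berries_summer_step)) {
    logits[, "berries"] <- logits[, "berries"] + params$berries_summer_step * open
  }
  logits <- pmin(pmax(logits, -30), 30)
  p <- t(apply(logits, 1, softmax))
  structure(list(p = p, groups = groups, params = params),
            class = "whiskr_trajectory")
}

#' Average a trajectory over a calendar window
#'
#' @param trajectory a `whiskr_trajectory`.
#' @param start,end `Date`s (`end` exclusive); the window wraps the year.
#' @return Mean diet proportion vector over the window's days.
#' @export
window_diet <- function(trajectory, start, end) {
  days <- seq(as.Date(start), as.Date(end) - 1, by = "day")
  doy <- day_of_year(days)
  colMeans(trajectory$p[doy, , drop = FALSE])
}

#' Simulate the full synthetic study truth
#'
#' Draws the individual roster (default 16 individuals, half captured in
#' each season across three study years, 5-6 whisker segments each, for
#' about 88 segments in total) and fixes the daily diet trajectory and
#' noise levels.
#'
#' @param cfg a `whiskr_config`.
#' @param seed RNG seed.
#' @param n_individuals total individuals (half per season).
#' @param noise_sd residual isotope noise sd, permil (length 2:
#'   d13C, d15N).
#' @param params trajectory parameters.
#' @return A `whiskr_truth` list: `trajectory`, `individuals`,
#'   `noise_sd`, `seed`.
#' @export
make_truth <- function(cfg = default_config(), seed = 1,
                       n_individuals = 16, noise_sd = c(0.3, 0.3),
                       params = trajectory_params(cfg)) {
  set.seed(seed)
  trajectory <- make_trajectory(params)
  n_half <- n_individuals %/% 2
  years <- sample(2021:2023, n_individuals, replace = TRUE)
  # summer captures while the park is open, winter captures while closed
  open_doys <- seq(cfg$park_open_doy + 40, cfg$park_close_doy - 1)
  closed_doys <- c(seq(cfg$park_close_doy + 40, 365), seq(1, cfg$park_open_doy - 1))
  doys <- c(sample(open_doys, n_half, replace = TRUE),
            sample(closed_doys, n_individuals - n_half, replace = TRUE))
  season <- rep(c("summer", "winter"), c(n_half, n_individuals - n_half))
  capture <- as.Date(sprintf("%d-01-01", years)) + (doys - 1)
  individuals <- data.frame(
    individual_id = sprintf("fox_%02d", seq_len(n_individuals)),
    capture_date = capture,
    season = season,
    n_segments = sample(5:6, n_individuals, replace = TRUE),
    stringsAsFactors = FALSE
  )
  structure(list(trajectory = trajectory, individuals = individuals,
                 noise_sd = noise_sd, seed = seed),
            class = "whiskr_truth")
}

#' Simulate whisker-segment isotope observations
#'
#' For each individual and segment the calendar window follows from the
#' growth model; the true diet is the trajectory averaged over that
#' window; one realization of each source mean and TDF is drawn per
#' segment; the segment isotope values are the concentration-weighted
#' mixture mean plus residual Gaussian noise.
#'
#' @param truth a `whiskr_truth`.
#' @param sources a source table.
#' @param cfg a `whiskr_config`.
#' @param seed optional RNG seed (defaults to `truth$seed + 1`).
#' @return A consumer table with the per-segment true diet proportions
#'   attached as `attr(, "true_diet")` (matrix, rows aligned) and the
#'   windows as `attr(, "windows")`.
#' @export
simulate_whiskers <- function(truth, sources, cfg = default_config(),
                              seed = NULL) {
  set.seed(if (is.null(seed)) truth$seed + 1L else seed)
  K <- nrow(sources)
  mats <- source_matrices(sources)
  rows <- list()
  true_p <- list()
  win_rows <- list()
  for (i in seq_len(nrow(truth$individuals))) {
    ind <- truth$individuals[i, ]
    w <- segment_windows(ind$capture_date, ind$n_segments, cfg)
    for (s in seq_len(nrow(w))) {
      p <- window_diet(truth$trajectory, w$window_start[s], w$window_end[s])
      mu_star <- mats$mu + matrix(rnorm(K * 2), K, 2) * mats$sd
      tdf_star <- mats$tdf_mu + matrix(rnorm(K * 2), K, 2) * mats$tdf_sd
      y <- vapply(1:2, function(j) {
        q <- mats$conc[, j]
        sum(p * q * (mu_star[, j] + tdf_star[, j])) / sum(p * q)
      }, numeric(1))
      y <- y + rnorm(2, 0, truth$noise_sd)
      rows[[length(rows) + 1L]] <- data.frame(
        individual_id = ind$individual_id,
        capture_date = ind$capture_date,
        segment_index = w$segment_index[s],
        d13C = y[1], d15N = y[2],
        season = ind$season,
        stringsAsFactors = FALSE
      )
      true_p[[length(true_p) + 1L]] <- p
      win_rows[[length(win_rows) + 1L]] <- data.frame(
        individual_id = ind$individual_id,
        segment_index = w$segment_index[s],
        window_start = w$window_start[s],
        window_end = w$window_end[s]
      )
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "true_diet") <- do.call(rbind, true_p)
  attr(out, "windows") <- do.call(rbind, win_rows)
  out
}

#' Simulate scat occurrence records
#'
#' Scat dates are drawn uniformly within the season (park open days for
#' summer, closed days for winter); each diet group is detected
#' independently with probability `min(1, link_slope * p_k(date))`, so a
#' scat can contain several items (or none).
#'
#' @param trajectory a `whiskr_trajectory`.
#' @param n_summer,n_winter scat counts per season (defaults 378 and 64).
#' @param link_slope detection slope `c` in `Bernoulli(min(1, c * p_k))`.
#' @param seed RNG seed.
#' @param cfg a `whiskr_config` (park calendar).
#' @return A scat table (`scat_id`, `season`, `items`, `day`).
#' @export
simulate_scats <- function(trajectory, n_summer = 378, n_winter = 64,
                           link_slope = 1.5, seed = 1,
                           cfg = default_config()) {
  if (n_summer < 0 || n_winter < 0) stop("scat counts must be >= 0")
  set.seed(seed)
  open_doys <- seq(cfg$park_open_doy, cfg$park_close_doy - 1)
  closed_doys <- setdiff(1:365, open_doys)
  day <- c(sample(open_doys, n_summer, replace = TRUE),
           sample(closed_doys, n_winter, replace = TRUE))
  season <- rep(c("summer", "winter"), c(n_summer, n_winter))
  groups <- trajectory$groups
  items <- character(length(day))
  for (i in seq_along(day)) {
    pr <- pmin(1, link_slope * trajectory$p[day[i], ])
    hit <- runif(length(groups)) < pr
    items[i] <- paste(groups[hit], collapse = ";")
  }
  data.frame(
    scat_id = sprintf("scat_%04d", seq_along(day)),
    season = season, items = items, day = day,
    stringsAsFactors = FALSE
  )
}

#' Simulate a complete synthetic study
#'
#' Convenience wrapper producing every input the downstream pipeline
#' needs: sources, truth, whisker consumer table and scat table.
#'
#' @param cfg a `whiskr_config`.
#' @param seed RNG seed (all stages derive from it).
#' @param ... passed to [make_truth()].
#' @return List with `sources`, `truth`, `consumers`, `scats`.
#' @export
simulate_study <- function(cfg = default_config(), seed = 1, ...) {
  sources <- make_sources(4, cfg = cfg)
  truth <- make_truth(cfg, seed = seed, ...)
  consumers <- simulate_whiskers(truth, sources, cfg)
  scats <- simulate_scats(truth$trajectory, seed = seed + 2L, cfg = cfg)
  list(sources = sources, truth = truth, consumers = consumers, scats = scats)
}
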