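# Isotopic (delta-space) niche metrics: seasonal ANOVA, standard
# ellipse areas, Bayesian ellipses, and ellipse overlap.

#' Seasonal mean test (one-way ANOVA)
#'
#' @param values numeric vector of isotope values.
#' @param groups factor/character of season labels (>= 2 groups, each
#'   with n >= 2).
#' @return List with `F`, `p`, `df1`, `df2`.
#' @export
seasonal_mean_test <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (any(table(groups) < 2)) stop("every group needs n >= 2")
  fit <- aov(values ~ groups)
  s <- summary(fit)[[1]]
  list(F = s[["F value"]][1], p = s[["Pr(>F)"]][1],
       df1 = s[["Df"]][1], df2 = s[["Df"]][2])
}

#' Standard ellipse of a bivariate isotope cloud
#'
#' Fits the sample mean and covariance and returns the standard ellipse
#' area `SEA = pi * sqrt(det(S))` and the small-sample corrected
#' `SEAc = SEA * (n - 1) / (n - 2)`.
#'
#' @param points n x 2 matrix or data frame of (d13C, d15N), n >= 3.
#' @return A `whiskr_ellipse` list: `mean`, `cov`, `n`, `SEA`, `SEAc`.
#' @export
standard_ellipse <- function(points) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (n < 3) stop("need n >= 3 points")
  S <- cov(points)
  d <- det(S)
  if (!is.finite(d) || d <= 0) stop("singular covariance")
  sea <- pi * sqrt(d)
  structure(list(mean = colMeans(points), cov = S, n = n,
                 SEA = sea, SEAc = sea * (n - 1) / (n - 2)),
            class = "whiskr_ellipse")
}

#' Bayesian standard ellipse area
#'
#' Conjugate normal-inverse-Wishart fit of the bivariate normal
#' (weakly informative defaults: nu0 = 3, Psi = 0.01 I, kappa0 = 0.01,
#' mu0 = 0). Each posterior covariance draw yields one SEA draw
#' `pi * sqrt(det(Sigma))`.
#'
#' @param points n x 2 matrix, n >= 3.
#' @param draws number of posterior draws.
#' @param seed optional RNG seed.
#' @return List with `draws` (SEA posterior draws), `mean`, `sd`.
#' @export
bayesian_sea <- function(points, draws = 4000, seed = NULL) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (n < 3) stop("need n >= 3 points")
  if (!is.null(seed)) set.seed(seed)
  nu0 <- 3; kappa0 <- 0.01
  Psi <- diag(0.01, 2); mu0 <- c(0, 0)
  xbar <- colMeans(points)
  Sraw <- crossprod(sweep(points, 2, xbar))
  dm <- xbar - mu0
  Psi_n <- Psi + Sraw + (kappa0 * n / (kappa0 + n)) * tcrossprod(dm)
  nu_n <- nu0 + n
  W <- rWishart(draws, nu_n, solve(Psi_n))
  sea <- vapply(seq_len(draws), function(i) {
    pi * sqrt(1 / det(W[, , i]))  # det(inv(W)) = 1/det(W)
  }, numeric(1))
  list(draws = sea, mean = mean(sea), sd = sd(sea))
}

# ellipse region at probability level prob: mahalanobis^2 <= qchisq(prob, 2)
ellipse_area_at <- function(e, prob) {
  pi * qchisq(prob, 2) * sqrt(det(e$cov))
}

# area of intersection of two probability-level ellipses via x-slice
# integration: each ellipse cuts a y-interval at fixed x; the overlap
# length is integrated by the midpoint rule (robust at the sqrt edges)
ellipse_intersection_area <- function(e1, e2, prob, n_grid = 8192) {
  q <- qchisq(prob, 2)
  slice <- function(e, x) {
    P <- solve(e$cov)
    xr <- x - e$mean[1]
    disc <- -xr^2 * det(P) + P[2, 2] * q
    ok <- disc > 0
    half <- sqrt(pmax(disc, 0)) / P[2, 2]
    ctr <- e$mean[2] - P[1, 2] * xr / P[2, 2]
    list(lo = ifelse(ok, ctr - half, NA), hi = ifelse(ok, ctr + half, NA), ok = ok)
  }
  xr1 <- e1$mean[1] + c(-1, 1) * sqrt(q * e1$cov[1, 1])
  xr2 <- e2$mean[1] + c(-1, 1) * sqrt(q * e2$cov[1, 1])
  lo <- max(xr1[1], xr2[1]); hi <- min(xr1[2], xr2[2])
  if (hi <= lo) return(0)
  h <- (hi - lo) / n_grid
  x <- lo + (seq_len(n_grid) - 0.5) * h
  s1 <- slice(e1, x); s2 <- slice(e2, x)
  len <- pmax(0, pmin(s1$hi, s2$hi) - pmax(s1$lo, s2$lo))
  len[!(s1$ok & s2$ok)] <- 0
  sum(len) * h
}

#' Ellipse overlap statistic
#'
#' Computes the intersection area `O_raw` of the two probability-level
#' ellipses and the normalized overlap
#' `O_delta = O_raw / ((B1 + B2) - O_raw)` (intersection over union),
#' which ranges from 0 (disjoint) to 1 (identical).
#'
#' @param e1,e2 `whiskr_ellipse` objects.
#' @param prob ellipse probability level (default 0.95; set 0.40 for
#'   SEAc-style standard ellipses).
#' @return List with `O_raw` (permil^2), `O_delta`, `B1`, `B2`, `prob`.
#' @export
ellipse_overlap <- function(e1, e2, prob = 0.95) {
  if (prob <= 0 || prob >= 1) stop("prob must lie in (0, 1)")
  B1 <- ellipse_area_at(e1, prob)
  B2 <- ellipse_area_at(e2, prob)
  O <- ellipse_intersection_area(e1, e2, prob)
  O <- min(O, B1, B2)
  list(O_raw = O, O_delta = O / ((B1 + B2) - O), B1 = B1, B2 = B2,
       prob = prob)
}

#' Per-season and per-individual ellipse summaries
#'
#' Fits [standard_ellipse()] (and optionally [bayesian_sea()]) per
#' season at the population level and per individual with >= 3
#' segments (fewer are skipped with a warning).
#'
#' @param consumers consumer table.
#' @param bayesian also compute Bayesian SEA (default `TRUE`).
#' @param draws,seed passed to [bayesian_sea()].
#' @return Data frame with one row per (level, label): mean isotope
#'   values, SEA, SEAc, and Bayesian SEA mean/sd.
#' @export
niche_summary <- function(consumers, bayesian = TRUE, draws = 4000,
                          seed = 1) {
  one <- function(points, level, label) {
    e <- standard_ellipse(points)
    b <- if (bayesian) bayesian_sea(points, draws, seed) else list(mean = NA, sd = NA)
    data.frame(level = level, label = label, n = e$n,
               mu_d13C = e$mean[1], mu_d15N = e$mean[2],
               SEA = e$SEA, SEAc = e$SEAc,
               SEA_B_mean = b$mean, SEA_B_sd = b$sd)
  }
  out <- list()
  for (s in unique(consumers$season)) {
    pts <- consumers[consumers$season == s, c("d13C", "d15N")]
    out[[length(out) + 1L]] <- one(pts, "season", s)
  }
  for (id in unique(consumers$individual_id)) {
    pts <- consumers[consumers$individual_id == id, c("d13C", "d15N")]
    if (nrow(pts) < 3) {
      warning("skipping individual ", id, " with < 3 segments", call. = FALSE)
      next
    }
    out[[length(out) + 1L]] <- one(pts, "individual", id)
  }
  do.call(rbind, out)
}
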