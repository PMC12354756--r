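# Diet-proportion (p-space) metrics: posterior overlap, probabilistic
# niche regions, specialization/similarity strategies, Pianka overlap,
# SIMPER contributions, and a permutation MANOVA season test.

trapz <- function(x, y) sum(diff(x) * (head(y, -1) + y[-1]) / 2)

#' Overlap between two diet posteriors
#'
#' For each diet group, kernel densities of the two posteriors'
#' proportion draws are evaluated on a common 512-point grid over
#' [0, 1] (Silverman bandwidth), renormalized, and the integral of
#' their pointwise minimum taken; the per-group overlaps are averaged.
#'
#' @param d1,d2 `whiskr_posterior` objects with the same groups
#'   (>= 100 draws each).
#' @return Overlap in [0, 1]; symmetric in its arguments.
#' @export
posterior_overlap <- function(d1, d2) {
  if (ncol(d1$draws) != ncol(d2$draws)) stop("posteriors must share K")
  if (nrow(d1$draws) < 100 || nrow(d2$draws) < 100) {
    stop("need at least 100 draws per posterior")
  }
  grid <- seq(0, 1, length.out = 512)
  ov <- vapply(seq_len(ncol(d1$draws)), function(k) {
    f1 <- kde_on_grid(d1$draws[, k], grid)
    f2 <- kde_on_grid(d2$draws[, k], grid)
    trapz(grid, pmin(f1, f2))
  }, numeric(1))
  mean(ov)
}

kde_on_grid <- function(x, grid) {
  bw <- stats::bw.nrd0(x)
  if (bw <= 0 || !is.finite(bw)) bw <- 1e-3
  d <- density(x, bw = bw, n = length(grid), from = min(grid), to = max(grid))
  f <- d$y
  area <- trapz(grid, f)
  if (area <= 0) stop("degenerate kernel density")
  f / area
}

#' Probabilistic dietary niche-region overlap across seasons
#'
#' Individuals' diet proportions are mapped to additive log-ratio (ALR)
#' coordinates, a multivariate normal is fit per season under a
#' conjugate normal-inverse-Wishart posterior, and the directional
#' overlap of A onto B is the posterior-averaged probability that a
#' random individual of season A falls inside season B's
#' `alpha`-probability niche region. The matrix is asymmetric.
#'
#' @param props_by_season named list of matrices (individuals x K diet
#'   proportions), one per season, each with >= 2 rows.
#' @param alpha niche-region probability level (default 0.95).
#' @param n_param posterior parameter draws; `n_x` samples per draw.
#' @param seed RNG seed.
#' @return Square matrix `overlap[A, B]` = P(A in B's region);
#'   diagonal approximates `alpha`.
#' @export
niche_region_overlap <- function(props_by_season, alpha = 0.95,
                                 n_param = 200, n_x = 100, seed = 1) {
  set.seed(seed)
  seasons <- names(props_by_season)
  if (any(vapply(props_by_season, nrow, integer(1)) < 2)) {
    stop("need >= 2 individuals per season")
  }
  Z <- lapply(props_by_season, function(P) {
    P <- pmax(as.matrix(P), 1e-8)
    z <- log(P[, -ncol(P), drop = FALSE] / P[, ncol(P)])
    keep <- apply(z, 2, function(col) var(col) > 1e-12)
    if (!all(keep)) {
      warning("dropping zero-variance log-ratio dimension(s)", call. = FALSE)
      z <- z[, keep, drop = FALSE]
    }
    z
  })
  d <- unique(vapply(Z, ncol, integer(1)))
  if (length(d) != 1) stop("seasons disagree on usable dimensions")
  q <- qchisq(alpha, d)
  # NIW posterior draws of (mu, Sigma) per season
  draw_params <- function(z) {
    n <- nrow(z); kappa0 <- 0.01; nu0 <- d + 1
    Psi <- diag(0.01, d); mu0 <- rep(0, d)
    xbar <- colMeans(z)
    Sraw <- crossprod(sweep(z, 2, xbar))
    dm <- xbar - mu0
    Psi_n <- Psi + Sraw + (kappa0 * n / (kappa0 + n)) * tcrossprod(dm)
    kappa_n <- kappa0 + n; nu_n <- nu0 + n
    mu_n <- (kappa0 * mu0 + n * xbar) / kappa_n
    W <- rWishart(n_param, nu_n, solve(Psi_n))
    lapply(seq_len(n_param), function(i) {
      Sigma <- solve(W[, , i])
      mu <- as.numeric(mu_n + chol(Sigma / kappa_n) %*% rnorm(d))
      list(mu = mu, Sigma = Sigma)
    })
  }
  params <- lapply(Z, draw_params)
  out <- matrix(NA_real_, length(seasons), length(seasons),
                dimnames = list(seasons, seasons))
  for (a in seasons) for (b in seasons) {
    hits <- vapply(seq_len(n_param), function(i) {
      pa <- params[[a]][[i]]; pb <- params[[b]][[i]]
      x <- matrix(rnorm(n_x * d), n_x, d) %*% chol(pa$Sigma)
      x <- sweep(x, 2, pa$mu, "+")
      mean(mahalanobis(x, pb$mu, pb$Sigma) <= q)
    }, numeric(1))
    out[a, b] <- mean(hits)
  }
  out
}

#' Dietary specialization and similarity indices
#'
#' `epsilon` locates a diet between the uniform (generalist) diet `u`
#' and a simplex vertex (ultra-specialist):
#' `epsilon = ||p - u|| / ||vertex - u||`. `s` measures similarity to
#' the population mean diet: `s = 1 - ||p - p_bar|| / max_k ||e_k -
#' p_bar||`. Both use Euclidean norms and lie in [0, 1].
#'
#' @param p_i individual diet proportion vector.
#' @param p_bar population mean diet proportion vector (same K >= 2).
#' @return Named vector `c(epsilon, s)`.
#' @export
specialization_similarity <- function(p_i, p_bar) {
  K <- length(p_i)
  if (K < 2 || length(p_bar) != K) stop("need matching simplex vectors, K >= 2")
  u <- rep(1 / K, K)
  eps <- sqrt(sum((p_i - u)^2)) / sqrt((K - 1) / K)
  vert_d <- vapply(seq_len(K), function(k) {
    e_k <- replace(rep(0, K), k, 1)
    sqrt(sum((e_k - p_bar)^2))
  }, numeric(1))
  s <- 1 - sqrt(sum((p_i - p_bar)^2)) / max(vert_d)
  c(epsilon = min(1, eps), s = max(0, s))
}

#' Quadrant label of a foraging strategy
#' @param epsilon,s specialization and similarity in [0, 1].
#' @return One of `"dissimilar-specialist"`, `"similar-specialist"`,
#'   `"dissimilar-generalist"`, `"similar-generalist"`.
#' @export
strategy_quadrant <- function(epsilon, s) {
  paste0(ifelse(s > 0.5, "similar-", "dissimilar-"),
         ifelse(epsilon > 0.5, "specialist", "generalist"))
}

#' Foraging-strategy table from individual diet estimates
#'
#' @param props matrix (individuals x K) of diet proportions.
#' @param ids individual labels.
#' @param season season label for the table.
#' @return Data frame `individual_id`, `season`, `epsilon`, `s`,
#'   `quadrant`; the population mean diet is the column mean of `props`.
#' @export
strategy_points <- function(props, ids, season) {
  props <- as.matrix(props)
  p_bar <- colMeans(props)
  es <- t(apply(props, 1, specialization_similarity, p_bar = p_bar))
  data.frame(individual_id = ids, season = season,
             epsilon = es[, "epsilon"], s = es[, "s"],
             quadrant = strategy_quadrant(es[, "epsilon"], es[, "s"]),
             stringsAsFactors = FALSE)
}

#' Strategy kernel densities and seasonal overlap
#'
#' 2-D kernel density of (s, epsilon) points per season on a 256 x 256
#' grid over the unit square; `O_Strategy` is the intersection-over-
#' union of the two seasons' 95% highest-density regions.
#'
#' @param points data frame with `s`, `epsilon`, `season` (two seasons,
#'   >= 3 points each; posterior-draw-level points allowed).
#' @param level HDR probability level (default 0.95).
#' @param bandwidth optional bandwidth (scalar or length 2); must be
#'   positive.
#' @param n_grid grid side (default 256).
#' @return List with `O_Strategy`, per-season `summary` (mean/sd of
#'   epsilon and s), and the HDR masks.
#' @export
strategy_kernels <- function(points, level = 0.95, bandwidth = NULL,
                             n_grid = 256) {
  seasons <- unique(points$season)
  if (length(seasons) != 2) stop("need exactly 2 seasons")
  if (!is.null(bandwidth) && any(bandwidth <= 0)) stop("bandwidth must be positive")
  masks <- list()
  summaries <- list()
  for (s in seasons) {
    pts <- points[points$season == s, ]
    if (nrow(pts) < 3) stop("need >= 3 points per season")
    h <- bandwidth
    if (is.null(h)) {
      h <- c(MASS::bandwidth.nrd(pts$s), MASS::bandwidth.nrd(pts$epsilon))
      h[h <= 0] <- 0.1
    }
    kd <- MASS::kde2d(pts$s, pts$epsilon, h = h, n = n_grid,
                      lims = c(0, 1, 0, 1))
    z <- kd$z / sum(kd$z)
    ord <- order(z, decreasing = TRUE)
    cum <- cumsum(z[ord])
    thr <- z[ord][which(cum >= level)[1]]
    masks[[s]] <- z >= thr
    summaries[[s]] <- data.frame(
      season = s,
      epsilon_mean = mean(pts$epsilon), epsilon_sd = sd(pts$epsilon),
      s_mean = mean(pts$s), s_sd = sd(pts$s)
    )
  }
  inter <- sum(masks[[1]] & masks[[2]])
  uni <- sum(masks[[1]] | masks[[2]])
  list(O_Strategy = if (uni > 0) inter / uni else 0,
       summary = do.call(rbind, summaries), masks = masks)
}

#' Pianka's niche overlap index
#'
#' `O = sum(p1 * p2) / sqrt(sum(p1^2) * sum(p2^2))`, in [0, 1] and
#' invariant to rescaling of either vector. When posterior draw
#' matrices are supplied, a bootstrap over `n_boot` posterior draw
#' pairs gives the mean and 95% interval.
#'
#' @param p1,p2 mean diet proportion vectors.
#' @param draws1,draws2 optional posterior draw matrices (draws x K).
#' @param n_boot bootstrap size (default 10000).
#' @param seed RNG seed.
#' @return List with `value`, and with draws: `boot_mean`, `ci`
#'   (2.5/97.5 percentiles).
#' @export
pianka_overlap <- function(p1, p2, draws1 = NULL, draws2 = NULL,
                           n_boot = 10000, seed = 1) {
  idx <- function(a, b) {
    na <- sum(a^2); nb <- sum(b^2)
    if (na == 0 || nb == 0) stop("zero vector")
    sum(a * b) / sqrt(na * nb)
  }
  out <- list(value = idx(p1, p2))
  if (!is.null(draws1) && !is.null(draws2)) {
    set.seed(seed)
    i1 <- sample(nrow(draws1), n_boot, replace = TRUE)
    i2 <- sample(nrow(draws2), n_boot, replace = TRUE)
    boot <- vapply(seq_len(n_boot),
                   function(i) idx(draws1[i1[i], ], draws2[i2[i], ]),
                   numeric(1))
    out$boot_mean <- mean(boot)
    out$ci <- quantile(boot, c(0.025, 0.975))
  }
  out
}

#' SIMPER: per-group contribution to Bray-Curtis dissimilarity
#'
#' Averages, over all between-season pairs (i, j), the per-group
#' Bray-Curtis terms `|x_ik - x_jk| / sum_k (x_ik + x_jk)` and rescales
#' to percent contributions summing to 100.
#'
#' @param X matrix (individuals x K) of diet proportions.
#' @param labels season labels (two groups, >= 1 row each).
#' @return Data frame `group`, `average` (mean dissimilarity term),
#'   `contribution` (percent).
#' @export
simper_contrib <- function(X, labels) {
  X <- as.matrix(X)
  if (any(rowSums(X) == 0)) stop("all-zero rows are not allowed")
  labels <- as.character(labels)
  gs <- unique(labels)
  if (length(gs) != 2) stop("need exactly 2 groups")
  A <- which(labels == gs[1]); B <- which(labels == gs[2])
  K <- ncol(X)
  acc <- numeric(K)
  for (i in A) for (j in B) {
    acc <- acc + abs(X[i, ] - X[j, ]) / sum(X[i, ] + X[j, ])
  }
  avg <- acc / (length(A) * length(B))
  if (sum(avg) == 0) stop("groups are identical: contributions undefined")
  data.frame(group = colnames(X) %||% paste0("g", seq_len(K)),
             average = avg, contribution = 100 * avg / sum(avg),
             row.names = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Permutation MANOVA season test on diet composition
#'
#' Test statistic: ratio of between-group to within-group sums of
#' squares (trace of the SSCP matrices) on the diet proportion matrix;
#' the p-value is the permutation tail probability over label shuffles.
#'
#' @param X matrix (individuals x K).
#' @param labels group labels (>= 2 per group).
#' @param n_perm number of permutations (>= 99).
#' @param seed RNG seed.
#' @return List with `statistic` and `p`.
#' @export
season_test <- function(X, labels, n_perm = 999, seed = 1) {
  if (n_perm < 99) stop("n_perm must be >= 99")
  X <- as.matrix(X)
  labels <- as.character(labels)
  if (any(table(labels) < 2)) stop("need >= 2 rows per group")
  stat <- function(lab) {
    grand <- colMeans(X)
    W <- 0; B <- 0
    for (g in unique(lab)) {
      idx <- lab == g
      m <- colMeans(X[idx, , drop = FALSE])
      W <- W + sum(sweep(X[idx, , drop = FALSE], 2, m)^2)
      B <- B + sum(idx) * sum((m - grand)^2)
    }
    if (W == 0) return(Inf)
    B / W
  }
  obs <- stat(labels)
  set.seed(seed)
  exceed <- sum(vapply(seq_len(n_perm),
                       function(i) stat(sample(labels)) >= obs,
                       logical(1)))
  list(statistic = obs, p = (1 + exceed) / (n_perm + 1))
}
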