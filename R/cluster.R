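# k-means aggregation of raw prey items into isotopically distinct
# diet groups, with the cluster count chosen by an index vote.

#' Aggregate prey items into isotopically distinct groups
#'
#' Runs k-means on the item means in (d13C, d15N) space for each k in
#' `k_range` and picks k by majority vote of three indices: mean
#' silhouette width, the Calinski-Harabasz criterion, and the gap
#' statistic (ties resolved in that order). Group isotope moments pool
#' the item moments (within + between variance, weighted by item sample
#' size); concentrations and TDFs are sample-size-weighted means.
#'
#' @param items data frame with `item`, `mu_d13C`, `sd_d13C`,
#'   `mu_d15N`, `sd_d15N`, `n` (item sample size) and optionally
#'   `conc_C`, `conc_N`, TDF columns.
#' @param k_range candidate cluster counts, within `[2, n_items - 1]`.
#' @param seed RNG seed (k-means starts, gap-statistic bootstraps).
#' @return List with `sources` (aggregated source-table-like data
#'   frame), `assignment` (named item -> group), `k`, `votes`.
#' @export
aggregate_prey_groups <- function(items, k_range = 2:6, seed = 1) {
  if (nrow(items) < 2) stop("need at least 2 items")
  X <- cbind(items$mu_d13C, items$mu_d15N)
  if (all(dist(X) == 0)) stop("all items isotopically identical; nothing to cluster")
  k_range <- sort(unique(as.integer(k_range)))
  if (min(k_range) < 2 || max(k_range) > nrow(items) - 1) {
    stop("k_range must lie within [2, n_items - 1]")
  }
  set.seed(seed)
  fits <- lapply(k_range, function(k) kmeans(X, k, nstart = 25, iter.max = 100))
  sil <- vapply(seq_along(k_range), function(i) {
    s <- cluster::silhouette(fits[[i]]$cluster, dist(X))
    mean(s[, "sil_width"])
  }, numeric(1))
  ch <- vapply(seq_along(k_range), function(i) {
    f <- fits[[i]]
    k <- k_range[i]
    if (f$tot.withinss == 0) return(Inf)
    (f$betweenss / (k - 1)) / (f$tot.withinss / (nrow(X) - k))
  }, numeric(1))
  gap <- cluster::clusGap(X, FUN = function(x, k) kmeans(x, k, nstart = 25),
                          K.max = max(k_range), B = 50, verbose = FALSE)
  gap_k <- with(as.data.frame(gap$Tab[k_range, , drop = FALSE]),
                cluster::maxSE(gap, SE.sim, method = "firstSEmax"))
  votes <- c(
    silhouette = k_range[which.max(sil)],
    calinski_harabasz = k_range[which.max(ch)],
    gap = k_range[gap_k]
  )
  tab <- table(votes)
  k <- as.integer(names(tab)[which.max(tab)])
  if (max(tab) == 1) k <- votes[["silhouette"]]
  fit <- fits[[match(k, k_range)]]
  cl <- fit$cluster
  w <- items$n
  pool <- function(mu, sd) {
    vapply(seq_len(k), function(g) {
      idx <- cl == g
      m <- sum(w[idx] * mu[idx]) / sum(w[idx])
      v <- sum(w[idx] * (sd[idx]^2 + (mu[idx] - m)^2)) / sum(w[idx])
      c(m, sqrt(v))
    }, numeric(2))
  }
  c13 <- pool(items$mu_d13C, items$sd_d13C)
  n15 <- pool(items$mu_d15N, items$sd_d15N)
  wmean <- function(col, default) {
    if (!col %in% names(items)) return(rep(default, k))
    vapply(seq_len(k), function(g) {
      idx <- cl == g
      sum(w[idx] * items[[col]][idx]) / sum(w[idx])
    }, numeric(1))
  }
  sources <- data.frame(
    group = sprintf("group_%02d", seq_len(k)),
    mu_d13C = c13[1, ], sd_d13C = c13[2, ],
    mu_d15N = n15[1, ], sd_d15N = n15[2, ],
    conc_C = wmean("conc_C", 0.5), conc_N = wmean("conc_N", 0.1),
    tdf_d13C_mean = wmean("tdf_d13C_mean", NA_real_),
    tdf_d15N_mean = wmean("tdf_d15N_mean", NA_real_),
    tdf_sd_d13C = wmean("tdf_sd_d13C", 0),
    tdf_sd_d15N = wmean("tdf_sd_d15N", 0),
    stringsAsFactors = FALSE
  )
  list(sources = sources,
       assignment = setNames(sprintf("group_%02d", cl), items$item),
       k = k, votes = votes)
}
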