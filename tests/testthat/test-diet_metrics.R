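sim_post <- function(centers, sds, n = 2000, seed = 1) {
  set.seed(seed)
  draws <- vapply(seq_along(centers), function(k) {
    pmin(pmax(rnorm(n, centers[k], sds[k]), 1e-6), 1 - 1e-6)
  }, numeric(n))
  colnames(draws) <- paste0("g", seq_along(centers))
  mock_posterior(draws)
}

test_that("posterior overlap is 1 for identical and 0 for disjoint fits", {
  d1 <- sim_post(c(0.3, 0.4, 0.2, 0.1), rep(0.04, 4), seed = 2)
  expect_gte(posterior_overlap(d1, d1), 0.98)
  d2 <- sim_post(c(0.9, 0.05, 0.03, 0.02), rep(0.01, 4), seed = 3)
  lo <- sim_post(c(0.1, 0.8, 0.5, 0.6), rep(0.01, 4), seed = 4)
  expect_lt(posterior_overlap(d2, lo), 0.02)
  expect_equal(posterior_overlap(d1, d2), posterior_overlap(d2, d1),
               tolerance = 1e-12)
  short <- mock_posterior(matrix(runif(40), 10, 4))
  expect_error(posterior_overlap(short, short), "100 draws")
})

test_that("posterior overlap matches the normal min-integral oracle", {
  d1 <- sim_post(rep(0.4, 4), rep(0.05, 4), n = 20000, seed = 5)
  d2 <- sim_post(rep(0.6, 4), rep(0.05, 4), n = 20000, seed = 6)
  # quadrature oracle: integral of min of the two normal densities
  oracle <- integrate(function(x) pmin(dnorm(x, 0.4, 0.05),
                                       dnorm(x, 0.6, 0.05)),
                      0, 1)$value # = 2 * pnorm(-2)
  expect_equal(oracle, 2 * pnorm(-2), tolerance = 1e-6)
  expect_lt(abs(posterior_overlap(d1, d2) - oracle), 0.015)
})

test_that("niche-region overlap calibrates to alpha and is directional", {
  set.seed(71)
  mk <- function(n, spread, shift = 0) {
    P <- matrix(abs(rnorm(n * 4, 0.25, 0.05 * spread)), n, 4)
    P[, 1] <- P[, 1] + shift
    P / rowSums(P)
  }
  same <- list(a = mk(15, 1), b = mk(15, 1))
  o <- niche_region_overlap(same, alpha = 0.95, seed = 3)
  expect_equal(unname(diag(o)), c(0.95, 0.95), tolerance = 0.04)
  # independent samples of the same distribution overlap substantially
  expect_gt(o["a", "b"], 0.5)

  far <- list(a = mk(15, 1), b = mk(15, 1, shift = 40))
  o2 <- niche_region_overlap(far, alpha = 0.95, seed = 4)
  expect_lt(o2["a", "b"], 0.05)

  uneq <- list(wide = mk(15, 10), narrow = mk(15, 0.5))
  o3 <- niche_region_overlap(uneq, alpha = 0.95, seed = 5)
  # the narrow niche sits inside the wide one, not conversely
  expect_gt(o3["narrow", "wide"], o3["wide", "narrow"])
})

test_that("specialization and similarity hit their geometric anchors", {
  u <- rep(0.25, 4)
  expect_equal(specialization_similarity(u, u)[["epsilon"]], 0)
  expect_equal(specialization_similarity(c(1, 0, 0, 0), u)[["epsilon"]], 1)
  expect_equal(specialization_similarity(c(0.4, 0.3, 0.2, 0.1),
                                         c(0.4, 0.3, 0.2, 0.1))[["s"]], 1)
  # invariance under a common permutation of diet groups
  p <- c(0.5, 0.3, 0.15, 0.05); q <- c(0.3, 0.3, 0.3, 0.1)
  perm <- c(3, 1, 4, 2)
  expect_equal(specialization_similarity(p, q),
               specialization_similarity(p[perm], q[perm]))
  expect_error(specialization_similarity(1, 1), "K >= 2")
  expect_equal(strategy_quadrant(0.7, 0.3), "dissimilar-specialist")
  expect_equal(strategy_quadrant(0.2, 0.8), "similar-generalist")
})

test_that("strategy kernels overlap fully, vanish, and match a disk oracle", {
  set.seed(72)
  pts <- data.frame(s = runif(300), epsilon = runif(300))
  both <- rbind(transform(pts, season = "a"), transform(pts, season = "b"))
  expect_equal(strategy_kernels(both)$O_Strategy, 1)

  sep <- rbind(
    data.frame(s = runif(100, 0.05, 0.15), epsilon = runif(100, 0.05, 0.15),
               season = "a"),
    data.frame(s = runif(100, 0.85, 0.95), epsilon = runif(100, 0.85, 0.95),
               season = "b")
  )
  expect_equal(strategy_kernels(sep)$O_Strategy, 0)
  expect_error(strategy_kernels(both, bandwidth = -1), "bandwidth")

  # two isotropic Gaussian clouds one sd apart: the 95% HDRs are disks,
  # whose intersection-over-union has a closed form
  sd0 <- 0.06; n <- 6000
  g1 <- data.frame(s = rnorm(n, 0.42, sd0), epsilon = rnorm(n, 0.5, sd0),
                   season = "a")
  g2 <- data.frame(s = rnorm(n, 0.48, sd0), epsilon = rnorm(n, 0.5, sd0),
                   season = "b")
  r <- sqrt(qchisq(0.95, 2)) # HDR radius in sd units
  d <- 1
  inter <- 2 * r^2 * acos(d / (2 * r)) - (d / 2) * sqrt(4 * r^2 - d^2)
  iou <- inter / (2 * pi * r^2 - inter)
  got <- strategy_kernels(rbind(g1, g2))$O_Strategy
  expect_equal(got, iou, tolerance = 0.02)
})

test_that("Pianka's index honours its identities and bounds", {
  expect_equal(pianka_overlap(c(0.3, 0.7), c(0.3, 0.7))$value, 1)
  expect_equal(pianka_overlap(c(1, 0), c(0, 1))$value, 0)
  expect_equal(pianka_overlap(c(0.5, 0.5, 0, 0), c(1, 0, 0, 0))$value,
               0.5 / sqrt(0.5), tolerance = 1e-12)
  # scaling invariance
  p <- runif(4); q <- runif(4)
  expect_equal(pianka_overlap(p, q)$value, pianka_overlap(3 * p, 10 * q)$value)
  expect_error(pianka_overlap(c(0, 0), c(1, 0)), "zero")
  d1 <- sim_post(c(0.6, 0.2, 0.1, 0.1), rep(0.03, 4), seed = 8)
  d2 <- sim_post(c(0.2, 0.6, 0.1, 0.1), rep(0.03, 4), seed = 9)
  pb <- pianka_overlap(colMeans(d1$draws), colMeans(d2$draws),
                       d1$draws, d2$draws, n_boot = 2000, seed = 1)
  expect_true(pb$ci[1] <= pb$boot_mean && pb$boot_mean <= pb$ci[2])
})

test_that("SIMPER contributions match a brute-force pairwise oracle", {
  X <- rbind(c(1, 0), c(0, 1))
  r <- simper_contrib(X, c("s", "w"))
  expect_equal(r$contribution, c(50, 50))

  set.seed(73)
  Y <- matrix(abs(rnorm(40, 0.25, 0.1)), 10, 4)
  Y <- Y / rowSums(Y)
  colnames(Y) <- paste0("g", 1:4)
  labels <- rep(c("s", "w"), each = 5)
  got <- simper_contrib(Y, labels)
  # brute-force oracle with explicit index arithmetic
  oracle <- numeric(4)
  np <- 0
  for (i in 1:5) for (j in 6:10) {
    oracle <- oracle + abs(Y[i, ] - Y[j, ]) / sum(Y[i, ] + Y[j, ])
    np <- np + 1
  }
  oracle <- oracle / np
  expect_equal(got$average, unname(oracle), tolerance = 1e-10)
  expect_equal(sum(got$contribution), 100, tolerance = 1e-9)
  expect_error(simper_contrib(rbind(c(1, 0), c(1, 0)), c("s", "w")),
               "identical")
})

test_that("SIMPER agrees with the community-ecology reference implementation", {
  set.seed(74)
  Y <- matrix(abs(rnorm(48, 0.25, 0.08)), 12, 4)
  Y <- Y / rowSums(Y)
  colnames(Y) <- paste0("g", 1:4)
  labels <- rep(c("s", "w"), each = 6)
  got <- simper_contrib(Y, labels)
  ref <- summary(vegan::simper(Y, labels))[[1]]
  expect_equal(got$average[match(rownames(ref), paste0("g", 1:4))],
               unname(ref$average), tolerance = 1e-10)
})

test_that("the permutation season test detects separation and is invariant", {
  set.seed(75)
  A <- rep(c(0.55, 0.25, 0.15, 0.05), each = 5) + rnorm(20, 0, 0.01)
  B <- rep(c(0.05, 0.15, 0.25, 0.55), each = 7) + rnorm(28, 0, 0.01)
  X <- rbind(matrix(A, 5, 4), matrix(B, 7, 4))
  X <- X / rowSums(X)
  labels <- rep(c("s", "w"), c(5, 7))
  r <- season_test(X, labels, n_perm = 199, seed = 1)
  # only a chance re-draw of the original partition can tie the statistic
  expect_lte(r$p, 2 / 200)
  # column permutation leaves the statistic unchanged
  r2 <- season_test(X[, c(4, 1, 3, 2)], labels, n_perm = 199, seed = 1)
  expect_equal(r$statistic, r2$statistic)
  expect_error(season_test(X, labels, n_perm = 50), "99")
})
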