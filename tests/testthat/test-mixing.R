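test_that("softmax maps logits to the simplex without overflow", {
  expect_equal(softmax(c(0, 0, 0, 0)), rep(0.25, 4))
  # winter prior means in source order (small prey, carrion, human, berries)
  p <- softmax(c(0.69, 1.82, -1.58, -0.94))
  expect_equal(p, c(0.2275, 0.7044, 0.0235, 0.0446), tolerance = 1e-3)
  expect_equal(sum(p), 1)
  expect_equal(softmax(c(100, 0)), c(1, 0), tolerance = 1e-40)
  expect_error(softmax(c(1, Inf)), "finite")
})

test_that("log-likelihood matches an independent brute-force oracle", {
  set.seed(21)
  src <- make_sources(4)
  src$sd_d13C <- runif(4, 0.2, 0.8)
  src$sd_d15N <- runif(4, 0.2, 0.8)
  src$tdf_sd_d13C <- runif(4, 0, 0.4)
  src$tdf_sd_d15N <- runif(4, 0, 0.4)
  y <- cbind(rnorm(5, -24, 1), rnorm(5, 5, 1))
  inputs <- mixing_inputs(y, src)
  for (i in 1:10) {
    theta <- rnorm(4)
    sigma <- runif(2, 0.1, 2)
    expect_equal(log_likelihood(theta, sigma, inputs),
                 brute_force_loglik(theta, sigma, y, src),
                 tolerance = 1e-8)
  }
  expect_error(log_likelihood(rep(0, 4), c(0, 1), inputs), "positive")
})

test_that("equal concentrations collapse to the plain mixture mean", {
  src <- two_source_table(conc_C = c(0.5, 0.5), conc_N = c(0.1, 0.1))
  theta <- c(0.3, -0.2)
  p <- softmax(theta)
  plain_mean_13C <- sum(p * (src$mu_d13C + src$tdf_d13C_mean))
  y <- cbind(plain_mean_13C, sum(p * (src$mu_d15N + src$tdf_d15N_mean)))
  inputs <- mixing_inputs(y, src)
  # at the exact mixture mean the density is the normalizing constant only
  ll <- log_likelihood(theta, c(0.5, 0.5), inputs)
  expect_equal(ll, 2 * dnorm(0, 0, 0.5, log = TRUE))
})

test_that("posterior dimensions, simplex constraint and prior-dominated limit", {
  cfg <- desk_config(2000L, 1000L, 2L, 2L)
  src <- make_sources(4)
  m_w <- default_config()$prior_mean_winter
  inputs <- mixing_inputs(cbind(-24.5, 5.0), src,
                          prior_spec(m_w, rep(1e-3, 4)), cfg)
  post <- suppressWarnings(run_mcmc(inputs, seed = 5))
  D <- cfg$chains * (cfg$iterations - cfg$burn_in) / cfg$thin
  expect_equal(nrow(post$draws), D)
  expect_equal(rowSums(post$draws), rep(1, D), tolerance = 1e-10)
  expect_true(all(post$sigma_draws > 0))
  # near-degenerate prior pins the posterior at softmax(m)
  expect_equal(colMeans(post$draws), setNames(softmax(m_w), src$group),
               tolerance = 0.01)
})

test_that("a consumer at a corrected source mean is assigned to that source", {
  cfg <- desk_config()
  src <- make_sources(4)
  carrion <- src[src$group == "wolf_carrion", ]
  y <- cbind(carrion$mu_d13C + carrion$tdf_d13C_mean,
             carrion$mu_d15N + carrion$tdf_d15N_mean)
  inputs <- mixing_inputs(y, src, prior_spec(rep(0, 4), rep(1, 4)), cfg)
  post <- suppressWarnings(run_mcmc(inputs, seed = 6))
  pm <- colMeans(post$draws)
  expect_equal(names(which.max(pm)), "wolf_carrion")
})

test_that("a symmetric two-source problem has a symmetric posterior", {
  cfg <- desk_config()
  src <- two_source_table()
  src$sd_d13C <- src$sd_d15N <- c(0.5, 0.5)
  y <- cbind(mean(src$mu_d13C + src$tdf_d13C_mean),
             mean(src$mu_d15N + src$tdf_d15N_mean))
  inputs <- mixing_inputs(y, src, prior_spec(c(0, 0), c(1, 1)), cfg)
  post <- suppressWarnings(run_mcmc(inputs, seed = 7))
  pm <- colMeans(post$draws)
  mcse <- apply(post$draws, 2, sd) /
    sqrt(pmax(post$ess[1:2], 1))
  expect_true(all(abs(pm - 0.5) < 3 * pmax(mcse, 0.01)))
})

test_that("scat frequencies elicit centred log-ratio priors", {
  scats <- data.frame(
    scat_id = sprintf("s%02d", 1:20), season = "summer",
    items = c(rep("a", 2), rep("b", 12), rep("c", 4), rep("a;d", 2)),
    stringsAsFactors = FALSE
  )
  pr <- elicit_priors_from_scats(scats, c("a", "b", "c", "d"))
  fo <- attr(pr, "FO")
  expect_equal(unname(fo), c(0.2, 0.6, 0.2, 0.1))
  expect_equal(mean(pr$mean), 0)
  expect_equal(softmax(pr$mean), unname(fo / sum(fo)), tolerance = 1e-12)
  expect_equal(pr$provenance, "scat_elicited")

  even <- data.frame(scat_id = 1:4, season = "s",
                     items = c("a;b;c;d", "a;b;c;d", "a;b;c;d", "a;b;c;d"))
  pr2 <- elicit_priors_from_scats(even, c("a", "b", "c", "d"))
  expect_equal(pr2$mean, rep(0, 4))
  none <- data.frame(scat_id = 1:2, season = "s", items = c("a", "a"))
  expect_error(elicit_priors_from_scats(none, c("a", "b")), "never observed")
})

test_that("hierarchical population fit shrinks when individuals agree", {
  cfg <- desk_config()
  src <- two_source_table(sd = 0.3)
  # all individuals sit exactly at the 50:50 mixture point
  y0 <- c(mean(src$mu_d13C + src$tdf_d13C_mean),
          mean(src$mu_d15N + src$tdf_d15N_mean))
  set.seed(88)
  cons <- data.frame(
    individual_id = rep(c("f1", "f2", "f3"), each = 3),
    capture_date = as.Date("2022-02-01"),
    segment_index = rep(0:2, 3),
    d13C = y0[1] + rnorm(9, 0, 0.01),
    d15N = y0[2] + rnorm(9, 0, 0.01),
    season = "winter", stringsAsFactors = FALSE
  )
  pr <- prior_spec(c(0, 0), c(1, 1))
  post <- suppressWarnings(fit_population(cons, src, pr, "winter", cfg, seed = 8))
  tau <- attr(post, "tau_mean")
  expect_true(all(tau < 1))
  single <- suppressWarnings(
    run_mcmc(mixing_inputs(cbind(y0[1], y0[2]), src, pr, cfg), seed = 8)
  )
  expect_equal(colMeans(post$draws), colMeans(single$draws), tolerance = 0.1)
  expect_equal(unname(colMeans(post$draws)), c(0.5, 0.5), tolerance = 0.05)
  expect_warning(
    fit_population(cons[cons$individual_id == "f1", ], src, pr, "winter",
                   desk_config(1200L, 600L, 2L, 2L), seed = 1,
                   warn_gates = FALSE),
    "single individual"
  )
})

test_that("per-segment fits are exchangeable and carry diagnostics", {
  cfg <- desk_config(3000L, 1500L, 3L)
  src <- make_sources(4)
  cons <- data.frame(
    individual_id = c("f1", "f1"), capture_date = as.Date("2022-02-01"),
    segment_index = 0:1, d13C = c(-24.2, -24.2), d15N = c(5.3, 5.3),
    season = "winter", stringsAsFactors = FALSE
  )
  pr <- seasonal_prior(default_config(), "winter")
  posts <- suppressWarnings(
    fit_individual_segments(cons, src, pr, cfg, seed = 100)
  )
  expect_length(posts, 2)
  expect_true(all(vapply(posts, function(p) all(is.finite(p$ess)), logical(1))))
  # identical segments agree within Monte-Carlo error
  expect_equal(colMeans(posts[[1]]$draws), colMeans(posts[[2]]$draws),
               tolerance = 0.05)
  expect_equal(posts[[1]]$label, "f1:0")
})

test_that("simulation-based calibration ranks are uniform at small scale", {
  cfg <- desk_config(3000L, 1500L, 5L, 2L)
  src <- make_sources(4)
  mats <- list(mu = cbind(src$mu_d13C, src$mu_d15N),
               conc = cbind(src$conc_C, src$conc_N),
               tdf = cbind(src$tdf_d13C_mean, src$tdf_d15N_mean),
               sd = cbind(src$sd_d13C, src$sd_d15N))
  set.seed(31)
  n_sbc <- 60
  ranks <- numeric(n_sbc)
  for (r in seq_len(n_sbc)) {
    theta <- rnorm(4, 0, 1)
    sigma <- abs(rnorm(2, 0, 0.5)) + 0.05
    p <- softmax(theta)
    y <- vapply(1:2, function(j) {
      q <- mats$conc[, j]
      m <- sum(p * q * (mats$mu[, j] + mats$tdf[, j])) / sum(p * q)
      v <- sum(p^2 * q^2 * mats$sd[, j]^2) / sum(p * q)^2 + sigma[j]^2
      rnorm(1, m, sqrt(v))
    }, numeric(1))
    inputs <- mixing_inputs(matrix(y, 1), src,
                            prior_spec(rep(0, 4), rep(1, 4)), cfg)
    post <- suppressWarnings(run_mcmc(inputs, seed = 4000 + r,
                                      warn_gates = FALSE))
    sub <- post$draws[seq(1, nrow(post$draws), by = 4), 1]
    ranks[r] <- sum(sub < p[1]) / length(sub)
  }
  ct <- table(cut(ranks, seq(0, 1, 0.25)))
  expect_gt(chisq.test(ct)$p.value, 0.01)
})

test_that("k-means aggregation recovers well-separated prey groups", {
  set.seed(41)
  centers <- rbind(c(-27, 1), c(-25, 5), c(-20, 7), c(-26, -2))
  items <- do.call(rbind, lapply(1:4, function(g) {
    data.frame(item = sprintf("it%d_%d", g, 1:5),
               mu_d13C = centers[g, 1] + rnorm(5, 0, 0.15),
               mu_d15N = centers[g, 2] + rnorm(5, 0, 0.15),
               sd_d13C = 0.4, sd_d15N = 0.4, n = sample(4:20, 5),
               stringsAsFactors = FALSE)
  }))
  agg <- aggregate_prey_groups(items, k_range = 2:6, seed = 2)
  expect_equal(agg$k, 4)
  expect_equal(length(unique(agg$assignment)), 4)
  # items from one true cluster always land together
  for (g in 1:4) {
    labs <- agg$assignment[items$mu_d13C %in%
                             items$mu_d13C[((g - 1) * 5 + 1):(g * 5)]]
    expect_equal(length(unique(labs)), 1)
  }
  # pooled variance exceeds the within-item variance
  expect_true(all(agg$sources$sd_d13C >= 0.3))

  two <- items[c(1, 6), ]
  expect_error(aggregate_prey_groups(two, k_range = 2:6), "k_range")
  same <- items[1:3, ]
  same$mu_d13C <- -25; same$mu_d15N <- 3
  expect_error(aggregate_prey_groups(same, k_range = 2), "identical")
})
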