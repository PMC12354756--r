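# Shared fixtures: a desk-scale config and small tables built in code.

desk_config <- function(iterations = 6000L, burn_in = 3000L, thin = 3L,
                        chains = 3L) {
  cfg <- default_config()
  cfg$iterations <- iterations
  cfg$burn_in <- burn_in
  cfg$thin <- thin
  cfg$chains <- chains
  cfg
}

# two well-separated sources with equal concentrations and zero sds,
# handy for exact-arithmetic checks
two_source_table <- function(conc_C = c(0.5, 0.5), conc_N = c(0.1, 0.1),
                             sd = 0) {
  data.frame(
    group = c("a", "b"),
    mu_d13C = c(-26, -20), sd_d13C = rep(sd, 2),
    mu_d15N = c(2, 8), sd_d15N = rep(sd, 2),
    conc_C = conc_C, conc_N = conc_N,
    tdf_d13C_mean = c(1.5, 2.0), tdf_d15N_mean = c(3.4, 3.5),
    tdf_sd_d13C = c(0, 0), tdf_sd_d15N = c(0, 0),
    stringsAsFactors = FALSE
  )
}

tiny_consumer_table <- function() {
  data.frame(
    individual_id = c("fox_01", "fox_01", "fox_02"),
    capture_date = c("2022-02-01", "2022-02-01", "2022-07-10"),
    segment_index = c(0L, 1L, 0L),
    d13C = c(-24.1, -24.3, -22.8),
    d15N = c(5.2, 5.0, 6.4),
    season = c("winter", "winter", "summer"),
    stringsAsFactors = FALSE
  )
}

# mock posterior carrying only draws, for metrics that need draws
mock_posterior <- function(draws, label = "mock") {
  structure(list(draws = as.matrix(draws), label = label),
            class = "whiskr_posterior")
}

# shift an ellipse's centre along x (new object, same covariance)
within_shift <- function(e, d) {
  out <- e
  out$mean <- e$mean + c(d, 0)
  out
}

# independent brute-force likelihood: plain R, no shared code path
brute_force_loglik <- function(theta, sigma, y, sources) {
  p <- exp(theta - max(theta))
  p <- p / sum(p)
  mu <- cbind(sources$mu_d13C, sources$mu_d15N)
  sdm <- cbind(sources$sd_d13C, sources$sd_d15N)
  conc <- cbind(sources$conc_C, sources$conc_N)
  tdf <- cbind(sources$tdf_d13C_mean, sources$tdf_d15N_mean)
  tdfsd <- cbind(sources$tdf_sd_d13C, sources$tdf_sd_d15N)
  ll <- 0
  for (j in 1:2) {
    denom <- sum(p * conc[, j])
    m <- sum(p * conc[, j] * (mu[, j] + tdf[, j])) / denom
    v <- sum(p^2 * conc[, j]^2 * (sdm[, j]^2 + tdfsd[, j]^2)) / denom^2 +
      sigma[j]^2
    for (i in seq_len(nrow(y))) {
      ll <- ll + dnorm(y[i, j], m, sqrt(v), log = TRUE)
    }
  }
  ll
}
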