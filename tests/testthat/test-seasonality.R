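test_that("Colwell limits: constant and maximally contingent series", {
  const <- data.frame(day = 1:365, value = 5, n = 1L)
  r <- colwell(const)
  expect_equal(c(r$C, r$M, r$P), c(1, 0, 1))

  # each two-week season always occupies its own state, uniformly
  v <- rep(seq(0, 10, length.out = 26), each = 14)
  per <- data.frame(day = 1:364, value = v, n = 1L)
  r2 <- colwell(per, n_states = 26)
  expect_equal(r2$C, 0, tolerance = 1e-12)
  expect_equal(r2$M, 1, tolerance = 1e-12)
  expect_equal(r2$P, 1, tolerance = 1e-12)
})

test_that("Colwell entropies match a hand-computed 3 x 2 table", {
  # counts by (state, season): [[2,1],[1,2],[0,1]], N = 7
  df <- data.frame(
    day = c(1, 2, 3, 183, 184, 185, 186),
    value = c(0.1, 0.1, 1.1, 0.1, 1.1, 1.1, 2.9),
    n = 1L
  )
  r <- colwell(df, n_states = 3, n_seasons = 2)
  expect_equal(as.numeric(r$counts),
               c(2, 1, 0, 1, 2, 1))
  # hand entropies: HX = ln7 - (3ln3 + 4ln4)/7, HY = ln7 - 6ln3/7,
  # HXY = ln7 - 4ln2/7
  HX <- log(7) - (3 * log(3) + 4 * log(4)) / 7
  HY <- log(7) - 6 * log(3) / 7
  HXY <- log(7) - 4 * log(2) / 7
  expect_equal(r$C, 1 - HY / log(3), tolerance = 1e-12)
  expect_equal(r$M, (HX + HY - HXY) / log(3), tolerance = 1e-12)
  expect_equal(r$P, r$C + r$M, tolerance = 1e-12)
  expect_equal(r$ratio, r$M / (r$C + r$M), tolerance = 1e-12)
})

test_that("Colwell components stay in bounds on random series", {
  set.seed(81)
  for (rep in 1:20) {
    n_obs <- sample(40:365, 1)
    df <- data.frame(day = sort(sample(1:365, n_obs)),
                     value = rnorm(n_obs), n = 1L)
    r <- suppressWarnings(colwell(df, n_states = sample(3:12, 1)))
    expect_true(all(c(r$C, r$M, r$P) >= -1e-12))
    expect_true(all(c(r$C, r$M, r$P) <= 1 + 1e-12))
    expect_lt(abs(r$P - (r$C + r$M)), 1e-12)
  }
})

test_that("autocorrelation matches known processes", {
  set.seed(82)
  a <- autocorrelation(rnorm(200), max_lag = 5)
  expect_equal(a$acf[a$lag == 0], 1)
  ar <- as.numeric(arima.sim(list(ar = 0.8), 2000))
  aa <- autocorrelation(ar, max_lag = 3)
  expect_lt(abs(aa$acf[aa$lag == 1] - 0.8), 0.1)
  # 26-week sinusoid sampled two-weekly (period 13 steps): the
  # half-period lag is antiphase, the full-period lag back in phase
  x <- sin(2 * pi * (1:78) / 13)
  ax <- autocorrelation(x, max_lag = 13)
  expect_lt(ax$acf[ax$lag == 7], 0)
  expect_gt(ax$acf[ax$lag == 13], 0.8)
  expect_error(autocorrelation(rep(1, 50)), "constant")
  expect_error(autocorrelation(rnorm(5)), "10")
})

test_that("wavelet ridges appear at both periods of a two-tone signal", {
  t <- 1:156
  x <- sin(2 * pi * t / 13) + sin(2 * pi * t / (8.7 / 2))
  w <- morlet_wavelet(x, dt_weeks = 2, periods = c(8.7, 26, 48),
                      n_surrogates = 50, seed = 2)
  mid <- 40:116
  p26 <- mean(w$power[mid, w$periods == 26])
  p87 <- mean(w$power[mid, w$periods == 8.7])
  p48 <- mean(w$power[mid, w$periods == 48])
  expect_gt(p26, 5 * p48)
  expect_gt(p87, 5 * p48)
})

test_that("wavelet significance is invariant to amplitude scaling", {
  set.seed(83)
  x <- sin(2 * pi * (1:78) / 13) + rnorm(78, 0, 0.3)
  w1 <- morlet_wavelet(x, n_surrogates = 60, seed = 7)
  w2 <- morlet_wavelet(100 * x, n_surrogates = 60, seed = 7)
  expect_identical(w1$signif, w2$signif)
  expect_equal(w1$predictability_26wk, w2$predictability_26wk)
  expect_error(morlet_wavelet(rnorm(10), dt_weeks = 2), "26-week")
})

test_that("the seasonal state-space model recovers a known harmonic", {
  set.seed(84)
  t <- 1:156
  y <- 1.5 * sin(2 * pi * t / 26) - 0.8 * cos(2 * pi * t / 26) +
    rnorm(156, 0, 0.05)
  fit <- seasonal_state_space(y)
  expect_lt(abs(fit$beta[["b1"]] - 1.5) / 1.5, 0.05)
  expect_lt(abs(fit$beta[["b2"]] + 0.8) / 0.8, 0.05)

  # white noise: harmonic amplitude is consistent with zero
  yn <- rnorm(156)
  fitn <- seasonal_state_space(yn)
  expect_lt(sqrt(sum(fitn$beta^2)), 0.5)

  # constant series: flat level, vanishing innovation variance
  fc <- seasonal_state_space(rep(2.5, 60))
  expect_lt(fc$sigma_w, 1e-3)
  expect_equal(unique(round(fc$smoothed$level, 6)), 2.5)
})

test_that("Kalman likelihood equals the brute-force multivariate normal", {
  set.seed(85)
  for (rep in 1:3) {
    n <- sample(5:10, 1)
    y <- rnorm(n)
    sv2 <- runif(1, 0.2, 2); sw2 <- runif(1, 0.05, 1)
    b1 <- rnorm(1); b2 <- rnorm(1)
    C0 <- 1e4
    ll <- kalman_loglik(y, sv2, sw2, b1, b2, period = 26, init_var = C0)
    t_idx <- 1:n
    m <- b1 * sin(2 * pi * t_idx / 26) + b2 * cos(2 * pi * t_idx / 26)
    S <- outer(1:n, 1:n, function(s, t) C0 + (pmin(s, t) - 1) * sw2) +
      diag(sv2, n)
    ll_mvn <- -0.5 * (n * log(2 * pi) +
                        as.numeric(determinant(S)$modulus) +
                        drop(t(y - m) %*% solve(S) %*% (y - m)))
    expect_equal(ll, ll_mvn, tolerance = 1e-8)
  }
})
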