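# Seasonality statistics: Colwell's constancy/contingency/
# predictability, autocorrelation, Morlet wavelet power with surrogate
# significance, and a univariate seasonal state-space smoother.

#' Colwell's constancy, contingency and predictability
#'
#' Values are binned into `n_states` equal-width states over their
#' observed range and cross-tabulated against `n_seasons` within-year
#' seasons (default 26 two-week blocks). With season totals `X_j`,
#' state totals `Y_i`, grand total `N` and natural-log entropies
#' `H(X)`, `H(Y)`, `H(XY)`:
#' `C = 1 - H(Y)/log(n_states)`,
#' `M = (H(X) + H(Y) - H(XY))/log(n_states)`, `P = C + M`. The ratio
#' `M/(C+M)` quantifies the role of seasonality in predictability.
#'
#' @param series day-of-year series ([stack_to_julian()] output) or a
#'   data frame with `day` and `value`.
#' @param n_states number of discrete states (default 11).
#' @param n_seasons within-year seasons (default 26 two-week blocks).
#' @return A `whiskr_colwell` list: `C`, `M`, `P`, `ratio`
#'   (= M/(C+M)), `counts`, `n_states`, `n_seasons`.
#' @export
colwell <- function(series, n_states = 11, n_seasons = 26) {
  if (n_states < 2) stop("n_states must be >= 2")
  ok <- !is.na(series$value)
  day <- series$day[ok]
  v <- series$value[ok]
  season <- pmin((day - 1) %/% (365 %/% n_seasons) + 1L, n_seasons)
  if (length(unique(season)) < 2) stop("need data in >= 2 seasons")
  if (diff(range(v)) == 0) {
    state <- rep(1L, length(v))
  } else {
    breaks <- seq(min(v), max(v), length.out = n_states + 1)
    state <- cut(v, breaks, include.lowest = TRUE, labels = FALSE)
  }
  counts <- table(factor(state, levels = seq_len(n_states)),
                  factor(season, levels = seq_len(n_seasons)))
  present <- colSums(counts) > 0
  if (!all(present)) {
    warning("dropping ", sum(!present), " empty season(s)", call. = FALSE)
    counts <- counts[, present, drop = FALSE]
  }
  N <- sum(counts)
  ent <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  HX <- ent(colSums(counts) / N)  # seasons
  HY <- ent(rowSums(counts) / N)  # states
  HXY <- ent(as.numeric(counts) / N)
  C <- 1 - HY / log(n_states)
  M <- (HX + HY - HXY) / log(n_states)
  P <- C + M
  structure(list(C = C, M = M, P = P,
                 ratio = if (C + M > 0) M / (C + M) else NA_real_,
                 counts = counts, n_states = n_states,
                 n_seasons = ncol(counts)),
            class = "whiskr_colwell")
}

#' Sample autocorrelation with white-noise bounds
#'
#' @param x numeric vector (>= 10 non-missing values; missing values
#'   are passed through).
#' @param max_lag maximum lag.
#' @return Data frame `lag`, `acf`, plus `ci` bound `1.96/sqrt(n)` as
#'   an attribute.
#' @export
autocorrelation <- function(x, max_lag = 26) {
  n <- sum(!is.na(x))
  if (n < 10) stop("need >= 10 non-missing points")
  if (sd(x, na.rm = TRUE) == 0) stop("constant series: ACF undefined")
  a <- acf(x, lag.max = max_lag, plot = FALSE, na.action = stats::na.pass)
  out <- data.frame(lag = a$lag[, 1, 1], acf = a$acf[, 1, 1])
  attr(out, "ci") <- 1.96 / sqrt(n)
  out
}

#' Morlet continuous wavelet transform with surrogate significance
#'
#' A Morlet mother wavelet (omega0 = 6) is convolved with the evenly
#' spaced series via FFT (Torrence-Compo style); power is normalized by
#' the series variance. Significance of each time-period cell is
#' assessed against `n_surrogates` Gaussian white-noise series of the
#' same length and variance; a cell is significant when its power
#' exceeds the surrogate distribution at level `alpha`. The
#' 26-week-period predictability statistic is the fraction of timesteps
#' significant at the 26-week row.
#'
#' @param x evenly spaced series (one value per `dt_weeks` weeks);
#'   internal gaps are linearly interpolated (fraction reported).
#' @param dt_weeks sampling interval in weeks (default 2).
#' @param periods periods (weeks) to analyse; 26 is always included.
#' @param alpha significance level (default 0.05).
#' @param n_surrogates white-noise surrogates (default 100).
#' @param seed RNG seed for the surrogates.
#' @return A `whiskr_wavelet` list: `power` (time x period), `signif`
#'   mask, `periods`, `predictability_26wk`, `gap_fraction`.
#' @export
morlet_wavelet <- function(x, dt_weeks = 2, periods = NULL, alpha = 0.05,
                           n_surrogates = 100, seed = 1) {
  n <- length(x)
  if (n * dt_weeks < 26) stop("series shorter than one 26-week period")
  gap_fraction <- mean(is.na(x))
  if (any(is.na(x))) {
    ok <- which(!is.na(x))
    if (length(ok) < 2) stop("not enough data to interpolate")
    x <- stats::approx(ok, x[ok], xout = seq_len(n), rule = 2)$y
  }
  if (is.null(periods)) {
    periods <- sort(unique(c(26, 2^seq(log2(8), log2(min(64, n * dt_weeks / 2)),
                                       by = 0.25) * dt_weeks / 2)))
  }
  periods <- sort(unique(c(26, periods)))
  pow <- morlet_power(x, dt_weeks, periods)
  set.seed(seed)
  exceed <- array(0L, dim = dim(pow))
  sdx <- sd(x)
  for (b in seq_len(n_surrogates)) {
    ps <- morlet_power(rnorm(n, 0, sdx), dt_weeks, periods)
    exceed <- exceed + (ps >= pow)
  }
  pval <- (1 + exceed) / (n_surrogates + 1)
  signif <- pval <= alpha
  row26 <- which(periods == 26)
  structure(list(power = pow, signif = signif, periods = periods,
                 predictability_26wk = mean(signif[, row26]),
                 alpha = alpha, gap_fraction = gap_fraction),
            class = "whiskr_wavelet")
}

# variance-normalized Morlet power, time x period
morlet_power <- function(x, dt_weeks, periods) {
  n <- length(x)
  omega0 <- 6
  fourier_factor <- 4 * pi / (omega0 + sqrt(2 + omega0^2))
  scales <- (periods / dt_weeks) / fourier_factor
  x0 <- x - mean(x)
  v <- var(x0)
  if (v == 0) v <- 1
  xh <- stats::fft(x0)
  k <- 0:(n - 1)
  omega <- ifelse(k <= n / 2, 2 * pi * k / n, -2 * pi * (n - k) / n)
  pow <- matrix(0, n, length(scales))
  for (si in seq_along(scales)) {
    s <- scales[si]
    psi <- pi^(-0.25) * sqrt(2 * pi * s) * exp(-((s * omega - omega0)^2) / 2) *
      (omega > 0)
    w <- stats::fft(xh * psi, inverse = TRUE) / n
    pow[, si] <- Mod(w)^2 / v
  }
  pow
}

#' Seasonal state-space model (local level + annual harmonic)
#'
#' Univariate Gaussian state-space fit by maximum likelihood through
#' the Kalman filter:
#' `y_t = x_t + b1 sin(2 pi t / T) + b2 cos(2 pi t / T) + v_t`,
#' `x_t = x_{t-1} + w_t`, with `T` one year in timesteps. Returns the
#' estimates, the log-likelihood and the RTS-smoothed level.
#'
#' @param y evenly spaced series.
#' @param period year length in timesteps (default 26 two-week steps).
#' @param init_var prior variance of the initial level (default 1e7).
#' @return List with `beta` (b1, b2), `sigma_v`, `sigma_w`, `loglik`,
#'   `smoothed`, `convergence`.
#' @export
seasonal_state_space <- function(y, period = 26, init_var = 1e7) {
  y <- as.numeric(y)
  n <- length(y)
  if (n < 4) stop("series too short")
  t_idx <- seq_len(n)
  Zs <- sin(2 * pi * t_idx / period)
  Zc <- cos(2 * pi * t_idx / period)
  nll <- function(par) {
    -kalman_loglik(y, exp(par[1]), exp(par[2]), par[3], par[4],
                   period = period, init_var = init_var)
  }
  v0 <- max(var(y), 1e-6)
  fit <- optim(c(log(v0 / 2), log(v0 / 10), 0, 0), nll, method = "L-BFGS-B",
               lower = c(log(1e-10), log(1e-10), -Inf, -Inf),
               upper = c(log(1e6), log(1e6), Inf, Inf),
               control = list(maxit = 500))
  if (fit$convergence != 0) {
    stop("state-space fit did not converge: ", fit$message)
  }
  sv2 <- exp(fit$par[1]); sw2 <- exp(fit$par[2])
  b1 <- fit$par[3]; b2 <- fit$par[4]
  resid <- y - b1 * Zs - b2 * Zc
  kf <- kalman_filter(resid, sv2, sw2, init_var)
  sm <- rts_smoother(kf, sw2)
  list(beta = c(b1 = b1, b2 = b2),
       sigma_v = sqrt(sv2), sigma_w = sqrt(sw2),
       loglik = -fit$value, smoothed = sm, convergence = fit$convergence)
}

#' Kalman log-likelihood of the seasonal local-level model
#'
#' Exact Gaussian log-likelihood of the model in
#' [seasonal_state_space()] for given parameters; the initial level has
#' prior `N(0, init_var)`.
#'
#' @param y series.
#' @param sigma_v2,sigma_w2 observation and level innovation variances.
#' @param b1,b2 harmonic coefficients.
#' @param period year length in timesteps.
#' @param init_var initial-level prior variance.
#' @return Scalar log-likelihood.
#' @export
kalman_loglik <- function(y, sigma_v2, sigma_w2, b1 = 0, b2 = 0,
                          period = 26, init_var = 1e7) {
  t_idx <- seq_along(y)
  resid <- y - b1 * sin(2 * pi * t_idx / period) -
    b2 * cos(2 * pi * t_idx / period)
  kalman_filter(resid, sigma_v2, sigma_w2, init_var)$loglik
}

# local-level Kalman filter on a (harmonic-removed) series
kalman_filter <- function(y, sv2, sw2, init_var) {
  n <- length(y)
  a <- 0; P <- init_var
  at <- numeric(n); Pt <- numeric(n)
  af <- numeric(n); Pf <- numeric(n)
  ll <- 0
  for (t in seq_len(n)) {
    # predict (level is a random walk)
    if (t > 1) { P <- P + sw2 }
    at[t] <- a; Pt[t] <- P
    Fv <- P + sv2
    e <- y[t] - a
    ll <- ll - 0.5 * (log(2 * pi * Fv) + e^2 / Fv)
    Kg <- P / Fv
    a <- a + Kg * e
    P <- P * (1 - Kg)
    af[t] <- a; Pf[t] <- P
  }
  list(loglik = ll, a_pred = at, P_pred = Pt, a_filt = af, P_filt = Pf)
}

# Rauch-Tung-Striebel smoother for the local level
rts_smoother <- function(kf, sw2) {
  n <- length(kf$a_filt)
  a_sm <- kf$a_filt
  P_sm <- kf$P_filt
  for (t in seq.int(n - 1, 1)) {
    Pp <- kf$P_filt[t] + sw2
    J <- kf$P_filt[t] / Pp
    a_sm[t] <- kf$a_filt[t] + J * (a_sm[t + 1] - kf$a_filt[t])
    P_sm[t] <- kf$P_filt[t] + J^2 * (P_sm[t + 1] - Pp)
  }
  data.frame(t = seq_len(n), level = a_sm, var = P_sm)
}
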