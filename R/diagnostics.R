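# MCMC convergence diagnostics: rank-normalized split-Rhat and
# autocorrelation-based effective sample size (Geyer initial monotone
# sequence truncation).

#' Gelman-Rubin convergence diagnostic (rank-normalized split-Rhat)
#'
#' Chains are rank-normalized, split in half, and the classic
#' between/within variance ratio is computed on the splits. Values near
#' 1 indicate convergence; the pipeline's gate is `Rhat < 1.01`.
#'
#' @param chains list of equal-length numeric vectors (>= 2 chains), or
#'   a matrix with one column per chain.
#' @return Scalar Rhat.
#' @export
gelman_rubin <- function(chains) {
  if (is.matrix(chains)) chains <- lapply(seq_len(ncol(chains)), function(j) chains[, j])
  if (length(chains) < 2) stop("need at least 2 chains")
  n <- unique(lengths(chains))
  if (length(n) != 1) stop("chains must have equal lengths")
  half <- n %/% 2
  splits <- unlist(lapply(chains, function(x) {
    list(x[seq_len(half)], x[seq.int(n - half + 1, n)])
  }), recursive = FALSE)
  # rank-normalize jointly across splits
  all_x <- unlist(splits)
  if (sd(all_x) == 0) return(1.0)
  z <- qnorm((rank(all_x, ties.method = "average") - 3 / 8) /
               (length(all_x) + 1 / 4))
  zs <- split(z, rep(seq_along(splits), each = half))
  m <- length(zs)
  means <- vapply(zs, mean, numeric(1))
  vars <- vapply(zs, var, numeric(1))
  W <- mean(vars)
  B <- half * var(means)
  if (W == 0) return(1.0)
  sqrt(((half - 1) / half * W + B / half) / W)
}

#' Effective sample size
#'
#' Autocorrelation-based ESS with Geyer's initial monotone positive
#' sequence truncation: sums of adjacent autocorrelation pairs are kept
#' while positive and non-increasing.
#'
#' @param draws numeric vector of MCMC draws (one chain).
#' @return Scalar ESS; a constant chain returns 0 with a warning.
#' @export
effective_sample_size <- function(draws) {
  n <- length(draws)
  if (n < 2 || sd(draws) == 0) {
    warning("constant chain: ESS defined as 0", call. = FALSE)
    return(0)
  }
  rho <- acf(draws, lag.max = min(n - 1, 2000), plot = FALSE,
             demean = TRUE)$acf[, 1, 1]
  # pair sums Gamma_m = rho_{2m} + rho_{2m+1}
  n_pairs <- (length(rho)) %/% 2
  if (n_pairs < 1) return(n)
  gam <- rho[2 * seq_len(n_pairs) - 1] + rho[2 * seq_len(n_pairs)]
  # initial positive sequence
  pos <- which(gam <= 0)
  m_max <- if (length(pos)) pos[1] - 1 else n_pairs
  if (m_max < 1) return(n)
  gam <- gam[seq_len(m_max)]
  # monotone non-increasing envelope
  gam <- cummin(gam)
  tau <- -1 + 2 * sum(gam)
  min(n, n / max(tau, 1e-12))
}
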