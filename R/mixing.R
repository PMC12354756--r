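# Concentration-dependent Bayesian mixing model: likelihood, samplers,
# prior elicitation, population and per-segment fits.

#' Softmax transform
#'
#' Maps a real vector to the diet simplex,
#' `p_k = exp(theta_k) / sum(exp(theta))`, stabilized against overflow.
#'
#' @param theta finite numeric vector.
#' @return Proportion vector summing to 1.
#' @export
softmax <- function(theta) {
  if (any(!is.finite(theta))) stop("theta must be finite")
  e <- exp(theta - max(theta))
  e / sum(e)
}

# source table -> K x 2 matrices (columns: d13C, d15N)
source_matrices <- function(sources) {
  list(
    mu = cbind(sources$mu_d13C, sources$mu_d15N),
    sd = cbind(sources$sd_d13C, sources$sd_d15N),
    conc = cbind(sources$conc_C, sources$conc_N),
    tdf_mu = cbind(sources$tdf_d13C_mean, sources$tdf_d15N_mean),
    tdf_sd = cbind(sources$tdf_sd_d13C, sources$tdf_sd_d15N),
    groups = sources$group
  )
}

#' Assemble mixing-model inputs
#'
#' @param y numeric matrix (n observations x 2 isotopes, columns d13C
#'   then d15N) or a consumer table.
#' @param sources a validated source table (K >= 2 groups).
#' @param prior a `whiskr_prior` (length-K mean, sd on the softmax
#'   scale); `NULL` for a vague default (mean 0, sd 1).
#' @param cfg a `whiskr_config`.
#' @return A `whiskr_mixing_inputs` list.
#' @export
mixing_inputs <- function(y, sources, prior = NULL, cfg = default_config()) {
  if (is.data.frame(y)) y <- cbind(y$d13C, y$d15N)
  y <- as.matrix(y)
  if (ncol(y) != 2) stop("y must have 2 isotope columns")
  K <- nrow(sources)
  if (K < 2) stop("mixing model needs K >= 2 sources")
  if (is.null(prior)) prior <- prior_spec(rep(0, K), rep(1, K), "uniform")
  if (length(prior$mean) != K) stop("prior length must match number of sources")
  structure(list(y = y, sources = sources, prior = prior, cfg = cfg),
            class = "whiskr_mixing_inputs")
}

#' Mixing-model log-likelihood
#'
#' For diet logits `theta` (proportions `p = softmax(theta)`), residual
#' sds `sigma` and concentration-dependent sources, each isotope j has
#' mixture mean `sum_k p_k q_kj (mu_kj + tdf_kj) / sum_k p_k q_kj` and
#' variance
#' `sum_k p_k^2 q_kj^2 (sd_kj^2 + tdfsd_kj^2) / (sum_k p_k q_kj)^2 +
#' sigma_j^2`; observations are independent normals.
#'
#' @param theta length-K real vector.
#' @param sigma length-2 positive residual sds (permil).
#' @param inputs a `whiskr_mixing_inputs`.
#' @return Scalar log-likelihood.
#' @export
log_likelihood <- function(theta, sigma, inputs) {
  if (any(sigma <= 0)) stop("sigma must be positive")
  m <- source_matrices(inputs$sources)
  mix_loglik_cpp(theta, sigma, inputs$y, m$mu, m$sd, m$conc, m$tdf_mu, m$tdf_sd)
}

# assemble a whiskr_posterior from per-chain C++ draws
posterior_from_chains <- function(chains, groups, label, cfg,
                                  warn_gates = TRUE) {
  K <- length(groups)
  nchain <- length(chains)
  p_list <- lapply(chains, `[[`, "p")
  sig_list <- lapply(chains, `[[`, "sigma")
  th_list <- lapply(chains, `[[`, "theta")
  draws <- do.call(rbind, p_list)
  colnames(draws) <- groups
  sigma_draws <- do.call(rbind, sig_list)
  colnames(sigma_draws) <- c("d13C", "d15N")
  theta_draws <- do.call(rbind, th_list)
  params <- c(paste0("p_", groups), "sigma_d13C", "sigma_d15N")
  per_param <- function(fun) {
    vapply(seq_along(params), function(ip) {
      per_chain <- lapply(seq_len(nchain), function(cc) {
        if (ip <= K) p_list[[cc]][, ip] else sig_list[[cc]][, ip - K]
      })
      fun(per_chain)
    }, numeric(1))
  }
  rhat <- per_param(function(ch) {
    if (nchain < 2) NA_real_ else gelman_rubin(ch)
  })
  ess <- per_param(function(ch) sum(vapply(ch, effective_sample_size, numeric(1))))
  names(rhat) <- names(ess) <- params
  if (warn_gates) {
    if (any(rhat >= cfg$rhat_max, na.rm = TRUE)) {
      warning(label, ": Rhat >= ", cfg$rhat_max, " for ",
              paste(params[which(rhat >= cfg$rhat_max)], collapse = ", "),
              call. = FALSE)
    }
    if (any(ess <= cfg$ess_min)) {
      warning(label, ": ESS <= ", cfg$ess_min, " for ",
              paste(params[which(ess <= cfg$ess_min)], collapse = ", "),
              call. = FALSE)
    }
  }
  structure(list(draws = draws, theta_draws = theta_draws,
                 sigma_draws = sigma_draws, rhat = rhat, ess = ess,
                 label = label, chains = nchain),
            class = "whiskr_posterior")
}

#' @export
print.whiskr_posterior <- function(x, ...) {
  cat("Diet posterior [", x$label, "]: ", nrow(x$draws), " draws, ",
      ncol(x$draws), " groups\n", sep = "")
  print(round(rbind(mean = colMeans(x$draws),
                    sd = apply(x$draws, 2, sd)), 4))
  invisible(x)
}

#' Posterior summary table
#'
#' @param object a `whiskr_posterior`.
#' @param ... unused.
#' @return Data frame with mean, sd and 2.5/50/97.5 percentiles per
#'   diet group.
#' @export
summary.whiskr_posterior <- function(object, ...) {
  qs <- apply(object$draws, 2, quantile, c(0.025, 0.5, 0.975))
  data.frame(
    group = colnames(object$draws),
    mean = colMeans(object$draws),
    sd = apply(object$draws, 2, sd),
    q2.5 = qs[1, ], q50 = qs[2, ], q97.5 = qs[3, ],
    row.names = NULL
  )
}

#' Sample the mixing-model posterior (single group of observations)
#'
#' Componentwise adaptive random-walk Metropolis on `(theta, log sigma)`
#' with normal priors `theta_k ~ N(m_k, v_k^2)` and half-normal
#' `sigma_j ~ half-N(0, sigma_prior_sd)`. Proposal scales adapt during
#' burn-in only. Convergence gates (`rhat_max`, `ess_min`) warn, never
#' fail.
#'
#' @param inputs a `whiskr_mixing_inputs`.
#' @param seed RNG seed.
#' @param label posterior label.
#' @param warn_gates warn on gate violations (default `TRUE`).
#' @return A `whiskr_posterior`.
#' @export
run_mcmc <- function(inputs, seed = 1, label = "fit", warn_gates = TRUE) {
  cfg <- inputs$cfg
  m <- source_matrices(inputs$sources)
  v <- inputs$prior$sd
  if (is.null(v)) v <- rep(1, length(inputs$prior$mean))
  set.seed(seed)
  chains <- mcmc_flat_cpp(inputs$y, m$mu, m$sd, m$conc, m$tdf_mu, m$tdf_sd,
                          inputs$prior$mean, v,
                          cfg$chains, cfg$iterations, cfg$burn_in, cfg$thin,
                          cfg$sigma_prior_sd)
  posterior_from_chains(chains, m$groups, label, cfg, warn_gates)
}

#' Elicit diet priors from scat frequency of occurrence
#'
#' The frequency of occurrence `FO_k` (fraction of scats containing
#' group k) is mapped to the softmax scale by a centred log transform:
#' `m_k = log(FO_k + eps0) - mean(log(FO + eps0))`, so that
#' `softmax(m)` is proportional to `FO + eps0`.
#'
#' @param scats a scat table (`items` semicolon-separated).
#' @param groups diet group names (order defines the prior order).
#' @param target_sd per-group prior sd, scalar or length-K; default 0.3.
#' @param eps0 additive constant guarding against never-observed groups.
#' @return A `whiskr_prior` with provenance `"scat_elicited"` and the
#'   `FO` vector attached as an attribute.
#' @export
elicit_priors_from_scats <- function(scats, groups, target_sd = 0.3,
                                     eps0 = 0) {
  item_sets <- strsplit(scats$items, ";", fixed = TRUE)
  fo <- vapply(groups, function(g) {
    mean(vapply(item_sets, function(it) g %in% it, logical(1)))
  }, numeric(1))
  if (all(fo + eps0 == 0)) stop("all frequencies of occurrence are zero")
  if (any(fo + eps0 == 0)) {
    stop("group(s) never observed in scats (set eps0 > 0): ",
         paste(groups[fo + eps0 == 0], collapse = ", "))
  }
  m <- log(fo + eps0)
  m <- m - mean(m)
  sd <- rep(target_sd, length.out = length(groups))
  out <- prior_spec(as.numeric(m), sd, "scat_elicited")
  attr(out, "FO") <- fo
  out
}

#' Population-level diet fit (individual as random effect)
#'
#' Hierarchical model: population logits `thbar_k` with prior
#' `N(m_k, v_k^2)`, per-individual logits `theta_ik ~ N(thbar_k,
#' tau_k^2)`, `tau_k ~ half-N(0, 1)`. The returned posterior is over
#' `softmax(thbar)`. With a single individual the fit falls back to the
#' non-hierarchical sampler with a warning.
#'
#' @param consumers consumer table (one season's rows).
#' @param sources source table.
#' @param prior a `whiskr_prior`.
#' @param season season label used to subset `consumers` (optional; if
#'   `NULL` all rows are used).
#' @param cfg a `whiskr_config`.
#' @param seed RNG seed.
#' @param warn_gates warn on convergence-gate violations.
#' @return A `whiskr_posterior` (population proportions), with
#'   per-parameter `tau` summarised in `attr(, "tau_mean")`.
#' @export
fit_population <- function(consumers, sources, prior, season = NULL,
                           cfg = default_config(), seed = 1,
                           warn_gates = TRUE) {
  if (!is.null(season)) consumers <- consumers[consumers$season == season, ]
  if (!nrow(consumers)) stop("no observations for season ", season)
  label <- paste0("population-", if (is.null(season)) "all" else season)
  ids <- unique(consumers$individual_id)
  if (length(ids) < 2) {
    warning("single individual; falling back to non-hierarchical fit",
            call. = FALSE)
    inputs <- mixing_inputs(consumers, sources, prior, cfg)
    return(run_mcmc(inputs, seed, label, warn_gates))
  }
  v <- prior$sd
  if (is.null(v)) v <- rep(1, length(prior$mean))
  consumers <- consumers[order(match(consumers$individual_id, ids)), ]
  grp_sizes <- table(factor(consumers$individual_id, levels = ids))
  grp_start <- c(0L, cumsum(as.integer(grp_sizes)))
  m <- source_matrices(sources)
  y <- cbind(consumers$d13C, consumers$d15N)
  set.seed(seed)
  chains <- mcmc_hier_cpp(y, grp_start, m$mu, m$sd, m$conc, m$tdf_mu,
                          m$tdf_sd, prior$mean, v,
                          cfg$chains, cfg$iterations, cfg$burn_in, cfg$thin,
                          cfg$sigma_prior_sd)
  post <- posterior_from_chains(chains, m$groups, label, cfg, warn_gates)
  tau <- do.call(rbind, lapply(chains, `[[`, "tau"))
  attr(post, "tau_mean") <- setNames(colMeans(tau), m$groups)
  post
}

#' Per-segment individual diet fits
#'
#' Fits the mixing model to each whisker segment separately (one
#' observation per fit). Prior means come from `prior`; the prior sds
#' are left "uninformed" at the module default `v = 1` so the fits can
#' express individual variability around the seasonal means.
#'
#' @param consumers consumer table.
#' @param sources source table.
#' @param prior a `whiskr_prior`; only its means are used.
#' @param cfg a `whiskr_config`.
#' @param seed base RNG seed (incremented per segment).
#' @param warn_gates warn on gate violations (default `FALSE`: per-
#'   segment fits are numerous and gate results are in each posterior).
#' @return List of `whiskr_posterior`, one per row of `consumers`,
#'   labelled `individual:segment`.
#' @export
fit_individual_segments <- function(consumers, sources, prior,
                                    cfg = default_config(), seed = 1,
                                    warn_gates = FALSE) {
  uninformed <- prior_spec(prior$mean, rep(1, length(prior$mean)),
                           provenance = prior$provenance)
  lapply(seq_len(nrow(consumers)), function(i) {
    row <- consumers[i, ]
    inputs <- mixing_inputs(cbind(row$d13C, row$d15N), sources, uninformed, cfg)
    run_mcmc(inputs, seed + i,
             label = paste0(row$individual_id, ":", row$segment_index),
             warn_gates = warn_gates)
  })
}
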