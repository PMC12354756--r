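#include <Rcpp.h>
using namespace Rcpp;

// Concentration-dependent mixing model likelihood and samplers.
//
// Sources are K diet end-members measured on J isotopes. For diet
// proportions p (softmax of theta) the consumer mean and variance on
// isotope j are concentration-weighted:
//   mean_j = sum_k p_k q_kj (mu_kj + tdf_kj) / sum_k p_k q_kj
//   var_j  = sum_k p_k^2 q_kj^2 (sd_kj^2 + tdfsd_kj^2) / (sum_k p_k q_kj)^2
//            + sigma_j^2
// Samplers are componentwise adaptive random-walk Metropolis; proposal
// scales adapt toward 0.44 acceptance during burn-in only.

static void softmax_vec(const std::vector<double>& th, std::vector<double>& p) {
  const int K = th.size();
  double m = th[0];
  for (int k = 1; k < K; ++k) if (th[k] > m) m = th[k];
  double s = 0.0;
  for (int k = 0; k < K; ++k) { p[k] = std::exp(th[k] - m); s += p[k]; }
  for (int k = 0; k < K; ++k) p[k] /= s;
}

// mixture mean / pre-residual variance for one isotope column
static void mix_moments(const std::vector<double>& p,
                        const NumericMatrix& mu, const NumericMatrix& sd,
                        const NumericMatrix& conc,
                        const NumericMatrix& tdf_mu, const NumericMatrix& tdf_sd,
                        int j, double& mean_j, double& var0_j) {
  const int K = p.size();
  double denom = 0.0, num = 0.0, var = 0.0;
  for (int k = 0; k < K; ++k) {
    const double w = p[k] * conc(k, j);
    denom += w;
    num += w * (mu(k, j) + tdf_mu(k, j));
    var += w * w * (sd(k, j) * sd(k, j) + tdf_sd(k, j) * tdf_sd(k, j));
  }
  mean_j = num / denom;
  var0_j = var / (denom * denom);
}

static double norm_lpdf(double x, double mean, double var) {
  const double d = x - mean;
  return -0.5 * std::log(2.0 * M_PI * var) - 0.5 * d * d / var;
}

// [[Rcpp::export]]
double mix_loglik_cpp(NumericVector theta, NumericVector sigma,
                      NumericMatrix y, NumericMatrix mu, NumericMatrix sd,
                      NumericMatrix conc, NumericMatrix tdf_mu,
                      NumericMatrix tdf_sd) {
  const int K = theta.size(), J = y.ncol(), n = y.nrow();
  std::vector<double> th(K), p(K);
  for (int k = 0; k < K; ++k) th[k] = theta[k];
  softmax_vec(th, p);
  double ll = 0.0;
  for (int j = 0; j < J; ++j) {
    double mean_j, var0_j;
    mix_moments(p, mu, sd, conc, tdf_mu, tdf_sd, j, mean_j, var0_j);
    const double var_j = var0_j + sigma[j] * sigma[j];
    for (int i = 0; i < n; ++i) ll += norm_lpdf(y(i, j), mean_j, var_j);
  }
  return ll;
}

struct AdaptScale {
  std::vector<double> ls;     // log proposal sd
  std::vector<int> acc, tot;
  void init(int n, double s0) { ls.assign(n, std::log(s0)); acc.assign(n, 0); tot.assign(n, 0); }
  void adapt(int batch) {
    for (size_t i = 0; i < ls.size(); ++i) {
      if (tot[i] >= batch) {
        const double rate = (double)acc[i] / tot[i];
        ls[i] += (rate > 0.44 ? 0.1 : -0.1);
        acc[i] = 0; tot[i] = 0;
      }
    }
  }
};

// Single-group fit: theta (K) + log sigma (J).
// Returns per-chain thinned draws of p, theta, sigma.
// [[Rcpp::export]]
List mcmc_flat_cpp(NumericMatrix y, NumericMatrix mu, NumericMatrix sd,
                   NumericMatrix conc, NumericMatrix tdf_mu, NumericMatrix tdf_sd,
                   NumericVector prior_m, NumericVector prior_v,
                   int chains, int iterations, int burn_in, int thin,
                   double sigma_prior_sd) {
  const int K = prior_m.size(), J = y.ncol();
  const int D = (iterations - burn_in) / thin;
  List out(chains);

  for (int c = 0; c < chains; ++c) {
    std::vector<double> th(K), lsig(J), p(K);
    for (int k = 0; k < K; ++k) th[k] = prior_m[k] + R::rnorm(0.0, 0.1 + prior_v[k] * 0.5);
    for (int j = 0; j < J; ++j) lsig[j] = std::log(0.5) + R::rnorm(0.0, 0.2);

    AdaptScale ad; ad.init(K + J, 0.5);
    NumericMatrix p_draws(D, K), th_draws(D, K), sig_draws(D, J);

    auto lpost = [&](const std::vector<double>& th_, const std::vector<double>& lsig_) {
      NumericVector tv(K), sv(J);
      for (int k = 0; k < K; ++k) tv[k] = th_[k];
      double lp = 0.0;
      for (int j = 0; j < J; ++j) {
        const double s = std::exp(lsig_[j]);
        sv[j] = s;
        lp += -0.5 * (s / sigma_prior_sd) * (s / sigma_prior_sd) + lsig_[j];
      }
      for (int k = 0; k < K; ++k) lp += norm_lpdf(th_[k], prior_m[k], prior_v[k] * prior_v[k]);
      return lp + mix_loglik_cpp(tv, sv, y, mu, sd, conc, tdf_mu, tdf_sd);
    };

    double cur = lpost(th, lsig);
    int d = 0;
    for (int it = 0; it < iterations; ++it) {
      for (int k = 0; k < K; ++k) {
        const double old = th[k];
        th[k] += R::rnorm(0.0, std::exp(ad.ls[k]));
        const double prop = lpost(th, lsig);
        ad.tot[k]++;
        if (std::log(R::runif(0.0, 1.0)) < prop - cur) { cur = prop; ad.acc[k]++; }
        else th[k] = old;
      }
      for (int j = 0; j < J; ++j) {
        const double old = lsig[j];
        lsig[j] += R::rnorm(0.0, std::exp(ad.ls[K + j]));
        const double prop = lpost(th, lsig);
        ad.tot[K + j]++;
        if (std::log(R::runif(0.0, 1.0)) < prop - cur) { cur = prop; ad.acc[K + j]++; }
        else lsig[j] = old;
      }
      if (it < burn_in && (it + 1) % 50 == 0) ad.adapt(50);
      if (it >= burn_in && (it - burn_in) % thin == 0 && d < D) {
        softmax_vec(th, p);
        for (int k = 0; k < K; ++k) { p_draws(d, k) = p[k]; th_draws(d, k) = th[k]; }
        for (int j = 0; j < J; ++j) sig_draws(d, j) = std::exp(lsig[j]);
        ++d;
      }
    }
    out[c] = List::create(_["p"] = p_draws, _["theta"] = th_draws,
                          _["sigma"] = sig_draws);
  }
  return out;
}

// Hierarchical fit: population mean thbar (K), per-individual theta (G x K)
// with theta_gk ~ N(thbar_k, tau_k^2), tau_k ~ half-N(0,1),
// sigma_j ~ half-N(0, sigma_prior_sd). Observations must arrive sorted by
// individual; grp_start has length G+1 (0-based row offsets into y).
// [[Rcpp::export]]
List mcmc_hier_cpp(NumericMatrix y, IntegerVector grp_start,
                   NumericMatrix mu, NumericMatrix sd, NumericMatrix conc,
                   NumericMatrix tdf_mu, NumericMatrix tdf_sd,
                   NumericVector prior_m, NumericVector prior_v,
                   int chains, int iterations, int burn_in, int thin,
                   double sigma_prior_sd) {
  const int K = prior_m.size(), J = y.ncol();
  const int G = grp_start.size() - 1;
  const int D = (iterations - burn_in) / thin;
  List out(chains);

  for (int c = 0; c < chains; ++c) {
    std::vector<double> thbar(K), ltau(K), lsig(J);
    std::vector<std::vector<double>> th(G, std::vector<double>(K));
    for (int k = 0; k < K; ++k) {
      thbar[k] = prior_m[k] + R::rnorm(0.0, 0.1 + prior_v[k] * 0.5);
      ltau[k] = std::log(0.5) + R::rnorm(0.0, 0.2);
    }
    for (int j = 0; j < J; ++j) lsig[j] = std::log(0.5) + R::rnorm(0.0, 0.2);
    for (int g = 0; g < G; ++g)
      for (int k = 0; k < K; ++k) th[g][k] = thbar[k] + R::rnorm(0.0, 0.2);

    // cached per-individual moments
    std::vector<std::vector<double>> mean_g(G, std::vector<double>(J));
    std::vector<std::vector<double>> var0_g(G, std::vector<double>(J));
    std::vector<double> p(K);
    auto refresh_g = [&](int g) {
      softmax_vec(th[g], p);
      for (int j = 0; j < J; ++j)
        mix_moments(p, mu, sd, conc, tdf_mu, tdf_sd, j, mean_g[g][j], var0_g[g][j]);
    };
    for (int g = 0; g < G; ++g) refresh_g(g);

    auto ll_ind = [&](int g) {
      double ll = 0.0;
      for (int j = 0; j < J; ++j) {
        const double s = std::exp(lsig[j]);
        const double var_j = var0_g[g][j] + s * s;
        for (int i = grp_start[g]; i < grp_start[g + 1]; ++i)
          ll += norm_lpdf(y(i, j), mean_g[g][j], var_j);
      }
      return ll;
    };

    AdaptScale ad; ad.init(G * K + K + J, 0.3);
    NumericMatrix pbar_draws(D, K), thbar_draws(D, K), tau_draws(D, K), sig_draws(D, J);

    int d = 0;
    for (int it = 0; it < iterations; ++it) {
      // Gibbs update of thbar_k (normal-normal conjugate given th, tau)
      for (int k = 0; k < K; ++k) {
        const double tau2 = std::exp(2.0 * ltau[k]);
        const double prec = 1.0 / (prior_v[k] * prior_v[k]) + G / tau2;
        double s = 0.0;
        for (int g = 0; g < G; ++g) s += th[g][k];
        const double mean = (prior_m[k] / (prior_v[k] * prior_v[k]) + s / tau2) / prec;
        thbar[k] = R::rnorm(mean, std::sqrt(1.0 / prec));
      }
      // Metropolis on individual effects
      for (int g = 0; g < G; ++g) {
        for (int k = 0; k < K; ++k) {
          const int idx = g * K + k;
          const double old = th[g][k];
          const std::vector<double> old_mean_j = mean_g[g];
          const std::vector<double> old_var_j = var0_g[g];
          const double tau = std::exp(ltau[k]);
          const double cur = norm_lpdf(old, thbar[k], tau * tau) + ll_ind(g);
          th[g][k] += R::rnorm(0.0, std::exp(ad.ls[idx]));
          refresh_g(g);
          const double prop = norm_lpdf(th[g][k], thbar[k], tau * tau) + ll_ind(g);
          ad.tot[idx]++;
          if (std::log(R::runif(0.0, 1.0)) < prop - cur) { ad.acc[idx]++; }
          else {
            th[g][k] = old;
            for (int j = 0; j < J; ++j) { mean_g[g][j] = old_mean_j[j]; var0_g[g][j] = old_var_j[j]; }
          }
        }
      }
      // Metropolis on log tau
      for (int k = 0; k < K; ++k) {
        const int idx = G * K + k;
        const double old = ltau[k];
        auto tau_lp = [&]() {
          const double tau = std::exp(ltau[k]);
          double lp = -0.5 * tau * tau + ltau[k];  // half-N(0,1) + jacobian
          for (int g = 0; g < G; ++g) lp += norm_lpdf(th[g][k], thbar[k], tau * tau);
          return lp;
        };
        const double cur = tau_lp();
        ltau[k] += R::rnorm(0.0, std::exp(ad.ls[idx]));
        const double prop = tau_lp();
        ad.tot[idx]++;
        if (std::log(R::runif(0.0, 1.0)) < prop - cur) ad.acc[idx]++;
        else ltau[k] = old;
      }
      // Metropolis on log sigma
      for (int j = 0; j < J; ++j) {
        const int idx = G * K + K + j;
        const double old = lsig[j];
        auto sig_lp = [&]() {
          const double s = std::exp(lsig[j]);
          double lp = -0.5 * (s / sigma_prior_sd) * (s / sigma_prior_sd) + lsig[j];
          const double s2 = s * s;
          for (int g = 0; g < G; ++g) {
            const double var_j = var0_g[g][j] + s2;
            for (int i = grp_start[g]; i < grp_start[g + 1]; ++i)
              lp += norm_lpdf(y(i, j), mean_g[g][j], var_j);
          }
          return lp;
        };
        const double cur = sig_lp();
        lsig[j] += R::rnorm(0.0, std::exp(ad.ls[idx]));
        const double prop = sig_lp();
        ad.tot[idx]++;
        if (std::log(R::runif(0.0, 1.0)) < prop - cur) ad.acc[idx]++;
        else lsig[j] = old;
      }
      if (it < burn_in && (it + 1) % 50 == 0) ad.adapt(50);
      if (it >= burn_in && (it - burn_in) % thin == 0 && d < D) {
        softmax_vec(thbar, p);
        for (int k = 0; k < K; ++k) {
          pbar_draws(d, k) = p[k];
          thbar_draws(d, k) = thbar[k];
          tau_draws(d, k) = std::exp(ltau[k]);
        }
        for (int j = 0; j < J; ++j) sig_draws(d, j) = std::exp(lsig[j]);
        ++d;
      }
    }
    out[c] = List::create(_["p"] = pbar_draws, _["theta"] = thbar_draws,
                          _["tau"] = tau_draws, _["sigma"] = sig_draws);
  }
  return out;
}
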