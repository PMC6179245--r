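// Metropolis-within-Gibbs sampler for the hierarchical logit site-use model
// with Bernoulli inclusion-indicator (Kuo-Mallick) variable selection.
//
// Model:
//   Z_i ~ Bernoulli(psi_i),  logit(psi_i) = a[area_i] + sum_c w_c alpha_c x_ic
//   y_ij | Z_i=1 ~ Bernoulli(p_i),  logit(p_i) = beta0 + wb_k b_k [trail dummies]
//   a[area] ~ Normal(mu, tau^2) (or a single Uniform intercept when the
//   random intercept is disabled); alpha_c, beta's ~ Uniform(low, high);
//   w_c, wb_k ~ Bernoulli(incl_prior).
//
// Detection depends on site-level covariates only, so the per-site detection
// likelihood reduces to the sufficient statistics d_i (detections) and n_i
// (observed occasions). Latent Z and the indicators are updated by exact
// Gibbs; continuous parameters by adaptive random-walk Metropolis, scales
// adapted in batches during burn-in only and frozen afterwards.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline double softplus(double x) {
  if (x > 35.0) return x;
  if (x < -35.0) return 0.0;
  return std::log1p(std::exp(x));
}

static inline double inv_logit(double x) {
  return 1.0 / (1.0 + std::exp(-x));
}

// log-likelihood of Z | psi for the whole site vector
static double psi_loglik(const std::vector<double>& eta,
                         const std::vector<int>& Z) {
  double ll = 0.0;
  for (size_t i = 0; i < eta.size(); ++i) {
    ll += Z[i] * eta[i] - softplus(eta[i]);
  }
  return ll;
}

// detection log-likelihood for one trail level given aggregated (D, N)
static inline double det_loglik_level(double eta_p, double D, double N) {
  return D * eta_p - N * softplus(eta_p);
}

// [[Rcpp::export]]
NumericMatrix cpp_run_chain(IntegerVector d, IntegerVector n,
                            NumericMatrix X, IntegerVector area, int n_area,
                            IntegerVector trail, int n_trail,
                            LogicalVector sel_alpha, LogicalVector sel_beta,
                            bool random_intercept,
                            double coef_low, double coef_high,
                            double mu_mean, double mu_sd,
                            double tau_low, double tau_high,
                            double incl_prior,
                            int n_iter, int burn_in, int thin,
                            NumericVector alpha_init, NumericVector a_init,
                            double mu_init, double tau_init,
                            double beta0_init, NumericVector b_init) {
  const int S = d.size();
  const int C = X.ncol();
  const int K = n_trail;          // number of trail levels (>=1)
  const int A = random_intercept ? n_area : 1;
  const double tau_floor = std::max(tau_low, 1e-6);

  // ---- state ----
  std::vector<double> alpha(C), a(A);
  std::vector<int> w(C, 1), wb(K - 1, 1);
  std::vector<double> b(K - 1);
  for (int c = 0; c < C; ++c) alpha[c] = alpha_init[c];
  for (int g = 0; g < A; ++g) a[g] = a_init[g];
  double mu = mu_init, tau = tau_init, beta0 = beta0_init;
  for (int k = 0; k < K - 1; ++k) b[k] = b_init[k];

  std::vector<int> Z(S);
  for (int i = 0; i < S; ++i) Z[i] = (d[i] > 0) ? 1 : (unif_rand() < 0.5);

  // sites per area
  std::vector<std::vector<int> > area_sites(A);
  for (int i = 0; i < S; ++i) {
    int g = random_intercept ? (area[i] - 1) : 0;
    area_sites[g].push_back(i);
  }

  // linear predictor for psi
  std::vector<double> eta(S);
  auto refresh_eta = [&]() {
    for (int i = 0; i < S; ++i) {
      int g = random_intercept ? (area[i] - 1) : 0;
      double e = a[g];
      for (int c = 0; c < C; ++c) e += w[c] * alpha[c] * X(i, c);
      eta[i] = e;
    }
  };
  refresh_eta();

  // ---- adaptation bookkeeping (one RW scale per scalar parameter) ----
  const int n_scale = C + A + 1 + 1 + (K - 1); // alphas, areas, tau, beta0, b
  std::vector<double> scale(n_scale, 0.5), acc(n_scale, 0.0), try_(n_scale, 0.0);
  const int batch = 50;
  int batch_no = 0;
  auto adapt = [&]() {
    ++batch_no;
    double delta = std::min(0.1, 1.0 / std::sqrt((double)batch_no));
    for (int j = 0; j < n_scale; ++j) {
      if (try_[j] > 0) {
        double rate = acc[j] / try_[j];
        scale[j] *= std::exp(delta * (rate > 0.44 ? 1.0 : -1.0));
      }
      acc[j] = try_[j] = 0.0;
    }
  };
  const int s_alpha0 = 0, s_area0 = C, s_tau = C + A, s_beta0 = C + A + 1,
            s_b0 = C + A + 2;

  // ---- output ----
  const int n_keep = (n_iter - burn_in) / thin;
  const int n_cols = C + C + A + (random_intercept ? 2 : 0) + 1 + 2 * (K - 1) + 1;
  NumericMatrix out(n_keep, n_cols);
  int keep_row = 0;

  std::vector<double> p_lev(K), D(K), N(K);

  for (int iter = 0; iter < n_iter; ++iter) {
    // detection probability per trail level
    for (int k = 0; k < K; ++k) {
      double ep = beta0 + ((k > 0) ? wb[k - 1] * b[k - 1] : 0.0);
      p_lev[k] = inv_logit(ep);
    }

    // -- latent Z (exact Gibbs; forced 1 at sites with detections) --
    for (int i = 0; i < S; ++i) {
      if (d[i] > 0) { Z[i] = 1; continue; }
      double psi = inv_logit(eta[i]);
      double q = std::pow(1.0 - p_lev[trail[i] - 1], (double)n[i]);
      double pr = psi * q / (psi * q + 1.0 - psi);
      Z[i] = (unif_rand() < pr) ? 1 : 0;
    }

    // detection sufficient statistics over currently-used sites
    for (int k = 0; k < K; ++k) D[k] = N[k] = 0.0;
    for (int i = 0; i < S; ++i) {
      if (Z[i]) { D[trail[i] - 1] += d[i]; N[trail[i] - 1] += n[i]; }
    }

    // -- site-use slopes: indicator (Gibbs) then coefficient (MH / prior) --
    for (int c = 0; c < C; ++c) {
      if (sel_alpha[c]) {
        double ll0 = 0.0, ll1 = 0.0;
        for (int i = 0; i < S; ++i) {
          double base = eta[i] - w[c] * alpha[c] * X(i, c);
          double e1 = base + alpha[c] * X(i, c);
          ll0 += Z[i] * base - softplus(base);
          ll1 += Z[i] * e1 - softplus(e1);
        }
        double m = std::max(ll0, ll1);
        double p1 = incl_prior * std::exp(ll1 - m);
        double p0 = (1.0 - incl_prior) * std::exp(ll0 - m);
        int w_new = (unif_rand() < p1 / (p1 + p0)) ? 1 : 0;
        if (w_new != w[c]) {
          double sgn = (w_new == 1) ? 1.0 : -1.0;
          for (int i = 0; i < S; ++i) eta[i] += sgn * alpha[c] * X(i, c);
          w[c] = w_new;
        }
      }
      if (w[c] == 1) {
        double prop = alpha[c] + norm_rand() * scale[s_alpha0 + c];
        try_[s_alpha0 + c] += 1.0;
        if (prop > coef_low && prop < coef_high) {
          double dll = 0.0, step = prop - alpha[c];
          for (int i = 0; i < S; ++i) {
            double e_new = eta[i] + step * X(i, c);
            dll += Z[i] * (e_new - eta[i]) - softplus(e_new) + softplus(eta[i]);
          }
          if (std::log(unif_rand()) < dll) {
            for (int i = 0; i < S; ++i) eta[i] += step * X(i, c);
            alpha[c] = prop;
            acc[s_alpha0 + c] += 1.0;
          }
        }
      } else {
        // Kuo-Mallick: excluded coefficient refreshed from its prior
        alpha[c] = coef_low + unif_rand() * (coef_high - coef_low);
      }
    }

    // -- area intercepts (MH; independent across areas) --
    for (int g = 0; g < A; ++g) {
      double prop = a[g] + norm_rand() * scale[s_area0 + g];
      try_[s_area0 + g] += 1.0;
      bool ok;
      double dprior;
      if (random_intercept) {
        ok = true;
        dprior = (-(prop - mu) * (prop - mu) + (a[g] - mu) * (a[g] - mu)) /
                 (2.0 * tau * tau);
      } else {
        ok = (prop > coef_low && prop < coef_high);
        dprior = 0.0;
      }
      if (ok) {
        double dll = dprior, step = prop - a[g];
        for (size_t ii = 0; ii < area_sites[g].size(); ++ii) {
          int i = area_sites[g][ii];
          double e_new = eta[i] + step;
          dll += Z[i] * step - softplus(e_new) + softplus(eta[i]);
        }
        if (std::log(unif_rand()) < dll) {
          for (size_t ii = 0; ii < area_sites[g].size(); ++ii) {
            eta[area_sites[g][ii]] += step;
          }
          a[g] = prop;
          acc[s_area0 + g] += 1.0;
        }
      }
    }

    // -- hyperparameters (random-intercept variant only) --
    if (random_intercept) {
      // mu | a, tau : conjugate normal update
      double suma = 0.0;
      for (int g = 0; g < A; ++g) suma += a[g];
      double prec = A / (tau * tau) + 1.0 / (mu_sd * mu_sd);
      double mean = (suma / (tau * tau) + mu_mean / (mu_sd * mu_sd)) / prec;
      mu = mean + norm_rand() / std::sqrt(prec);

      // tau : MH with Uniform(tau_low, tau_high) prior on the SD scale
      double prop = tau + norm_rand() * scale[s_tau];
      try_[s_tau] += 1.0;
      if (prop > tau_floor && prop < tau_high) {
        double ssq = 0.0;
        for (int g = 0; g < A; ++g) ssq += (a[g] - mu) * (a[g] - mu);
        double dll = -A * (std::log(prop) - std::log(tau)) -
                     ssq / 2.0 * (1.0 / (prop * prop) - 1.0 / (tau * tau));
        if (std::log(unif_rand()) < dll) { tau = prop; acc[s_tau] += 1.0; }
      }
    }

    // -- detection intercept --
    {
      double prop = beta0 + norm_rand() * scale[s_beta0];
      try_[s_beta0] += 1.0;
      if (prop > coef_low && prop < coef_high) {
        double ll_cur = 0.0, ll_new = 0.0;
        for (int k = 0; k < K; ++k) {
          double off = (k > 0) ? wb[k - 1] * b[k - 1] : 0.0;
          ll_cur += det_loglik_level(beta0 + off, D[k], N[k]);
          ll_new += det_loglik_level(prop + off, D[k], N[k]);
        }
        if (std::log(unif_rand()) < ll_new - ll_cur) {
          beta0 = prop;
          acc[s_beta0] += 1.0;
        }
      }
    }

    // -- trail contrasts: indicator then coefficient --
    for (int k = 0; k < K - 1; ++k) {
      if (sel_beta[k]) {
        double ll1 = det_loglik_level(beta0 + b[k], D[k + 1], N[k + 1]);
        double ll0 = det_loglik_level(beta0, D[k + 1], N[k + 1]);
        double m = std::max(ll0, ll1);
        double p1 = incl_prior * std::exp(ll1 - m);
        double p0 = (1.0 - incl_prior) * std::exp(ll0 - m);
        wb[k] = (unif_rand() < p1 / (p1 + p0)) ? 1 : 0;
      }
      if (wb[k] == 1) {
        double prop = b[k] + norm_rand() * scale[s_b0 + k];
        try_[s_b0 + k] += 1.0;
        if (prop > coef_low && prop < coef_high) {
          double dll = det_loglik_level(beta0 + prop, D[k + 1], N[k + 1]) -
                       det_loglik_level(beta0 + b[k], D[k + 1], N[k + 1]);
          if (std::log(unif_rand()) < dll) { b[k] = prop; acc[s_b0 + k] += 1.0; }
        }
      } else {
        b[k] = coef_low + unif_rand() * (coef_high - coef_low);
      }
    }

    // -- adaptation during burn-in only --
    if (iter < burn_in && (iter + 1) % batch == 0) adapt();

    // -- record --
    if (iter >= burn_in && (iter - burn_in) % thin == 0 && keep_row < n_keep) {
      int col = 0;
      for (int c = 0; c < C; ++c) out(keep_row, col++) = alpha[c];
      for (int c = 0; c < C; ++c) out(keep_row, col++) = w[c];
      for (int g = 0; g < A; ++g) out(keep_row, col++) = a[g];
      if (random_intercept) {
        out(keep_row, col++) = mu;
        out(keep_row, col++) = tau;
      }
      out(keep_row, col++) = beta0;
      for (int k = 0; k < K - 1; ++k) out(keep_row, col++) = b[k];
      for (int k = 0; k < K - 1; ++k) out(keep_row, col++) = wb[k];
      int zs = 0;
      for (int i = 0; i < S; ++i) zs += Z[i];
      out(keep_row, col++) = zs;
      ++keep_row;
    }
  }
  return out;
}
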