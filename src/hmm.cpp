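#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Gaussian emission density, floored so that scaled forward recursions
// never divide by zero even for extreme outliers.
static inline double gauss_dens(double x, double mu, double s2) {
  double d = x - mu;
  double v = std::exp(-0.5 * d * d / s2) / std::sqrt(2.0 * M_PI * s2);
  return (v < 1e-300) ? 1e-300 : v;
}

// One E-step over a set of concatenated observation sequences.
// obs: pooled observations; lens: length of each sequence.
// Returns the total log-likelihood plus the sufficient statistics needed
// for the Gaussian Baum-Welch M-step.
// [[Rcpp::export(name = ".hmm_estep")]]
List hmm_estep(NumericVector obs, IntegerVector lens,
               NumericVector mu, NumericVector sigma2,
               NumericMatrix trans, NumericVector init) {
  const int K = mu.size();
  const int S = lens.size();

  double loglik = 0.0;
  NumericVector gamma_sum(K), gamma_x(K), gamma_x2(K), init_sum(K);
  NumericMatrix xi_sum(K, K);

  int offset = 0;
  for (int s = 0; s < S; ++s) {
    const int T = lens[s];
    if (T <= 0) continue;

    NumericMatrix B(T, K);      // emission densities
    NumericMatrix alpha(T, K);  // scaled forward
    NumericMatrix beta(T, K);   // scaled backward
    NumericVector c(T);         // scaling factors

    for (int t = 0; t < T; ++t) {
      double x = obs[offset + t];
      for (int k = 0; k < K; ++k) B(t, k) = gauss_dens(x, mu[k], sigma2[k]);
    }

    // forward
    double norm = 0.0;
    for (int k = 0; k < K; ++k) { alpha(0, k) = init[k] * B(0, k); norm += alpha(0, k); }
    if (norm <= 0) norm = 1e-300;
    c[0] = norm;
    for (int k = 0; k < K; ++k) alpha(0, k) /= norm;
    for (int t = 1; t < T; ++t) {
      norm = 0.0;
      for (int j = 0; j < K; ++j) {
        double a = 0.0;
        for (int i = 0; i < K; ++i) a += alpha(t - 1, i) * trans(i, j);
        a *= B(t, j);
        alpha(t, j) = a;
        norm += a;
      }
      if (norm <= 0) norm = 1e-300;
      c[t] = norm;
      for (int j = 0; j < K; ++j) alpha(t, j) /= norm;
    }
    for (int t = 0; t < T; ++t) loglik += std::log(c[t]);

    // backward (scaled with the forward constants)
    for (int k = 0; k < K; ++k) beta(T - 1, k) = 1.0;
    for (int t = T - 2; t >= 0; --t) {
      for (int i = 0; i < K; ++i) {
        double b = 0.0;
        for (int j = 0; j < K; ++j) b += trans(i, j) * B(t + 1, j) * beta(t + 1, j);
        beta(t, i) = b / c[t + 1];
      }
    }

    // posteriors
    for (int t = 0; t < T; ++t) {
      double g[16]; // K is small in practice; fall back below if larger
      std::vector<double> gv;
      double *gp = g;
      if (K > 16) { gv.resize(K); gp = gv.data(); }
      double gn = 0.0;
      for (int k = 0; k < K; ++k) { gp[k] = alpha(t, k) * beta(t, k); gn += gp[k]; }
      if (gn <= 0) gn = 1e-300;
      double x = obs[offset + t];
      for (int k = 0; k < K; ++k) {
        double gk = gp[k] / gn;
        gamma_sum[k] += gk;
        gamma_x[k] += gk * x;
        gamma_x2[k] += gk * x * x;
        if (t == 0) init_sum[k] += gk;
      }
    }
    for (int t = 0; t + 1 < T; ++t) {
      double xn = 0.0;
      NumericMatrix xt(K, K);
      for (int i = 0; i < K; ++i)
        for (int j = 0; j < K; ++j) {
          double v = alpha(t, i) * trans(i, j) * B(t + 1, j) * beta(t + 1, j);
          xt(i, j) = v;
          xn += v;
        }
      if (xn <= 0) xn = 1e-300;
      for (int i = 0; i < K; ++i)
        for (int j = 0; j < K; ++j) xi_sum(i, j) += xt(i, j) / xn;
    }

    offset += T;
  }

  return List::create(_["loglik"] = loglik,
                      _["gamma_sum"] = gamma_sum,
                      _["gamma_x"] = gamma_x,
                      _["gamma_x2"] = gamma_x2,
                      _["xi_sum"] = xi_sum,
                      _["init_sum"] = init_sum);
}

// Log-likelihood only (scaled forward pass).
// [[Rcpp::export(name = ".hmm_loglik")]]
double hmm_loglik(NumericVector obs, IntegerVector lens,
                  NumericVector mu, NumericVector sigma2,
                  NumericMatrix trans, NumericVector init) {
  const int K = mu.size();
  double loglik = 0.0;
  int offset = 0;
  for (int s = 0; s < lens.size(); ++s) {
    const int T = lens[s];
    if (T <= 0) continue;
    std::vector<double> a(K), anew(K);
    double norm = 0.0;
    for (int k = 0; k < K; ++k) {
      a[k] = init[k] * gauss_dens(obs[offset], mu[k], sigma2[k]);
      norm += a[k];
    }
    if (norm <= 0) norm = 1e-300;
    loglik += std::log(norm);
    for (int k = 0; k < K; ++k) a[k] /= norm;
    for (int t = 1; t < T; ++t) {
      double x = obs[offset + t];
      norm = 0.0;
      for (int j = 0; j < K; ++j) {
        double v = 0.0;
        for (int i = 0; i < K; ++i) v += a[i] * trans(i, j);
        v *= gauss_dens(x, mu[j], sigma2[j]);
        anew[j] = v;
        norm += v;
      }
      if (norm <= 0) norm = 1e-300;
      loglik += std::log(norm);
      for (int j = 0; j < K; ++j) a[j] = anew[j] / norm;
    }
    offset += T;
  }
  return loglik;
}

// Viterbi decoding in log space. Ties are broken toward the lower state
// index (strict > comparisons with ascending scans).
// Returns 1-based state labels.
// [[Rcpp::export(name = ".hmm_viterbi")]]
List hmm_viterbi(NumericVector obs,
                 NumericVector mu, NumericVector sigma2,
                 NumericMatrix trans, NumericVector init) {
  const int T = obs.size();
  const int K = mu.size();
  NumericMatrix delta(T, K);
  IntegerMatrix psi(T, K);
  NumericMatrix ltrans(K, K);
  NumericVector linit(K);
  for (int k = 0; k < K; ++k)
    linit[k] = (init[k] > 0) ? std::log(init[k]) : -1e308;
  for (int i = 0; i < K; ++i)
    for (int j = 0; j < K; ++j)
      ltrans(i, j) = (trans(i, j) > 0) ? std::log(trans(i, j)) : -1e308;

  for (int k = 0; k < K; ++k)
    delta(0, k) = linit[k] + std::log(gauss_dens(obs[0], mu[k], sigma2[k]));
  for (int t = 1; t < T; ++t) {
    for (int j = 0; j < K; ++j) {
      double best = delta(t - 1, 0) + ltrans(0, j);
      int arg = 0;
      for (int i = 1; i < K; ++i) {
        double v = delta(t - 1, i) + ltrans(i, j);
        if (v > best) { best = v; arg = i; }
      }
      delta(t, j) = best + std::log(gauss_dens(obs[t], mu[j], sigma2[j]));
      psi(t, j) = arg;
    }
  }

  IntegerVector path(T);
  double best = delta(T - 1, 0);
  int arg = 0;
  for (int k = 1; k < K; ++k)
    if (delta(T - 1, k) > best) { best = delta(T - 1, k); arg = k; }
  path[T - 1] = arg;
  for (int t = T - 2; t >= 0; --t) path[t] = psi(t + 1, path[t + 1]);
  for (int t = 0; t < T; ++t) path[t] += 1;

  return List::create(_["path"] = path, _["logprob"] = best);
}
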