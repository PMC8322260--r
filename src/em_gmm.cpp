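#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// EM for a 1-D two-component Gaussian mixture with variance and weight
// floors. Hot loop of the bimodality analysis: called hundreds of times
// per bootstrap, so it lives in C++.
//
// Returns loglik = NA on numerical failure.
// [[Rcpp::export(name = ".em_gaussian2_cpp")]]
List em_gaussian2_cpp(NumericVector x,
                      double w2, double mu1, double mu2,
                      double sig1, double sig2,
                      double var_floor, double weight_floor,
                      int max_iter, double tol) {
  const int n = x.size();
  const double sd_floor = std::sqrt(var_floor);
  if (sig1 < sd_floor) sig1 = sd_floor;
  if (sig2 < sd_floor) sig2 = sd_floor;
  double w1 = 1.0 - w2;
  double ll_old = R_NegInf;
  bool converged = false;
  std::vector<double> r2(n);
  const double log2pi_half = 0.5 * std::log(2.0 * M_PI);

  for (int iter = 0; iter < max_iter; ++iter) {
    // E-step and log-likelihood
    double ll = 0.0;
    double inv1 = 1.0 / sig1, inv2 = 1.0 / sig2;
    double lsig1 = std::log(sig1), lsig2 = std::log(sig2);
    double lw1 = std::log(w1), lw2 = std::log(w2);
    for (int i = 0; i < n; ++i) {
      double z1 = (x[i] - mu1) * inv1;
      double z2 = (x[i] - mu2) * inv2;
      double l1 = lw1 - 0.5 * z1 * z1 - lsig1 - log2pi_half;
      double l2 = lw2 - 0.5 * z2 * z2 - lsig2 - log2pi_half;
      double m = l1 > l2 ? l1 : l2;
      double s = std::exp(l1 - m) + std::exp(l2 - m);
      ll += m + std::log(s);
      r2[i] = std::exp(l2 - m) / s;
    }
    if (!std::isfinite(ll)) {
      return List::create(_["loglik"] = NA_REAL);
    }
    if (std::isfinite(ll_old) && std::fabs(ll - ll_old) < tol) {
      converged = true;
      break;
    }
    ll_old = ll;
    // M-step
    double n2 = 0.0;
    for (int i = 0; i < n; ++i) n2 += r2[i];
    double n1 = n - n2;
    if (n1 < 1e-8 || n2 < 1e-8) {
      return List::create(_["loglik"] = NA_REAL);
    }
    w2 = n2 / n;
    if (w2 < weight_floor) w2 = weight_floor;
    if (w2 > 1.0 - weight_floor) w2 = 1.0 - weight_floor;
    w1 = 1.0 - w2;
    double m1 = 0.0, m2 = 0.0;
    for (int i = 0; i < n; ++i) {
      m1 += (1.0 - r2[i]) * x[i];
      m2 += r2[i] * x[i];
    }
    mu1 = m1 / n1;
    mu2 = m2 / n2;
    double v1 = 0.0, v2 = 0.0;
    for (int i = 0; i < n; ++i) {
      double d1 = x[i] - mu1, d2 = x[i] - mu2;
      v1 += (1.0 - r2[i]) * d1 * d1;
      v2 += r2[i] * d2 * d2;
    }
    v1 /= n1; v2 /= n2;
    if (v1 < var_floor) v1 = var_floor;
    if (v2 < var_floor) v2 = var_floor;
    sig1 = std::sqrt(v1);
    sig2 = std::sqrt(v2);
  }
  return List::create(
    _["weight"] = NumericVector::create(w1, w2),
    _["mu"] = NumericVector::create(mu1, mu2),
    _["sigma"] = NumericVector::create(sig1, sig2),
    _["loglik"] = ll_old,
    _["converged"] = converged
  );
}

static double ks_stat_sorted(const std::vector<double>& xs,
                             const std::vector<double>& Fx) {
  const int n = xs.size();
  double D = 0.0;
  for (int i = 0; i < n; ++i) {
    double hi = (i + 1.0) / n - Fx[i];
    double lo = Fx[i] - (double)i / n;
    if (hi > D) D = hi;
    if (lo > D) D = lo;
  }
  return D;
}

struct Mix {
  double w2, mu1, mu2, s1, s2;
  bool ok;
  double loglik;
};

static Mix em_best_quantile_inits(std::vector<double> x, double var_floor,
                                  double weight_floor, int max_iter,
                                  double tol) {
  // deterministic refit: EM restarted from quantile splits at 0.5/0.25/0.75
  const int n = x.size();
  std::vector<double> xs(x);
  std::sort(xs.begin(), xs.end());
  double sdall = 0.0, mall = 0.0;
  for (double v : xs) mall += v;
  mall /= n;
  for (double v : xs) sdall += (v - mall) * (v - mall);
  sdall = std::sqrt(sdall / n);
  const double qs[3] = {0.5, 0.25, 0.75};
  Mix best; best.ok = false; best.loglik = R_NegInf;
  NumericVector xv(x.begin(), x.end());
  // short EM runs from each init, then the best one to full convergence
  for (int k = 0; k < 3; ++k) {
    int cut = (int)std::floor(qs[k] * n);
    if (cut < 2 || n - cut < 2) continue;
    double m1 = 0.0, m2 = 0.0;
    for (int i = 0; i < cut; ++i) m1 += xs[i];
    for (int i = cut; i < n; ++i) m2 += xs[i];
    m1 /= cut; m2 /= (n - cut);
    double v1 = 0.0, v2 = 0.0;
    for (int i = 0; i < cut; ++i) v1 += (xs[i] - m1) * (xs[i] - m1);
    for (int i = cut; i < n; ++i) v2 += (xs[i] - m2) * (xs[i] - m2);
    double s1 = std::max(std::sqrt(v1 / cut), sdall / 10);
    double s2 = std::max(std::sqrt(v2 / (n - cut)), sdall / 10);
    List fit = em_gaussian2_cpp(xv, 1.0 - (double)cut / n, m1, m2, s1, s2,
                                var_floor, weight_floor,
                                std::min(max_iter, 30), tol);
    if (!fit.containsElementNamed("weight")) continue;
    double ll = as<double>(fit["loglik"]);
    if (!std::isfinite(ll)) continue;
    if (!best.ok || ll > best.loglik) {
      NumericVector w = fit["weight"], mu = fit["mu"], sg = fit["sigma"];
      best.ok = true; best.loglik = ll;
      if (mu[0] <= mu[1]) {
        best.w2 = w[1]; best.mu1 = mu[0]; best.mu2 = mu[1];
        best.s1 = sg[0]; best.s2 = sg[1];
      } else {
        best.w2 = w[0]; best.mu1 = mu[1]; best.mu2 = mu[0];
        best.s1 = sg[1]; best.s2 = sg[0];
      }
    }
  }
  if (best.ok) {
    List fit = em_gaussian2_cpp(xv, best.w2, best.mu1, best.mu2,
                                best.s1, best.s2, var_floor, weight_floor,
                                max_iter, tol);
    if (fit.containsElementNamed("weight")) {
      double ll = as<double>(fit["loglik"]);
      if (std::isfinite(ll)) {
        NumericVector w = fit["weight"], mu = fit["mu"], sg = fit["sigma"];
        best.loglik = ll;
        if (mu[0] <= mu[1]) {
          best.w2 = w[1]; best.mu1 = mu[0]; best.mu2 = mu[1];
          best.s1 = sg[0]; best.s2 = sg[1];
        } else {
          best.w2 = w[0]; best.mu1 = mu[1]; best.mu2 = mu[0];
          best.s1 = sg[1]; best.s2 = sg[0];
        }
      }
    }
  }
  return best;
}

// Parametric-bootstrap KS statistics for a fitted two-component mixture:
// simulate n points from the fitted model, refit by EM, return the KS
// statistic of each bootstrap sample against its own refitted CDF.
// [[Rcpp::export(name = ".ks_boot_mixture_cpp")]]
NumericVector ks_boot_mixture_cpp(double w2, double mu1, double mu2,
                                  double s1, double s2,
                                  int n, int n_boot,
                                  double var_floor, double weight_floor,
                                  int max_iter, double tol) {
  RNGScope scope;
  NumericVector out(n_boot, NA_REAL);
  std::vector<double> xb(n), Fx(n);
  for (int b = 0; b < n_boot; ++b) {
    for (int i = 0; i < n; ++i) {
      double u = unif_rand();
      xb[i] = (u < w2) ? norm_rand() * s2 + mu2 : norm_rand() * s1 + mu1;
    }
    double vb = 0.0, mb = 0.0;
    for (double v : xb) mb += v;
    mb /= n;
    for (double v : xb) vb += (v - mb) * (v - mb);
    vb /= n;
    Mix fit = em_best_quantile_inits(xb, 1e-4 * vb * n / (n - 1.0),
                                     weight_floor, max_iter, tol);
    if (!fit.ok) continue;
    std::vector<double> xs(xb);
    std::sort(xs.begin(), xs.end());
    for (int i = 0; i < n; ++i) {
      Fx[i] = (1.0 - fit.w2) * R::pnorm(xs[i], fit.mu1, fit.s1, 1, 0) +
              fit.w2 * R::pnorm(xs[i], fit.mu2, fit.s2, 1, 0);
    }
    out[b] = ks_stat_sorted(xs, Fx);
  }
  return out;
}

// Parametric-bootstrap KS statistics for a fitted single Gaussian
// (Lilliefors-style: mean and sd re-estimated on each bootstrap sample).
// [[Rcpp::export(name = ".ks_boot_normal_cpp")]]
NumericVector ks_boot_normal_cpp(double mu, double sigma, int n, int n_boot) {
  RNGScope scope;
  NumericVector out(n_boot);
  std::vector<double> xb(n), Fx(n);
  for (int b = 0; b < n_boot; ++b) {
    double m = 0.0, v = 0.0;
    for (int i = 0; i < n; ++i) {
      xb[i] = norm_rand() * sigma + mu;
      m += xb[i];
    }
    m /= n;
    for (int i = 0; i < n; ++i) v += (xb[i] - m) * (xb[i] - m);
    double s = std::sqrt(v / n);
    std::sort(xb.begin(), xb.end());
    for (int i = 0; i < n; ++i) Fx[i] = R::pnorm(xb[i], m, s, 1, 0);
    out[b] = ks_stat_sorted(xb, Fx);
  }
  return out;
}
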