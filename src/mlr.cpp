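// Log-posterior, gradient, and pointwise log-likelihood for the four
// multinomial logistic model structures, on the unconstrained scale
// (non-centered hierarchical coefficients, log-transformed sds with
// Jacobian).  The parameter layout must match param_names() in R/model.R:
//   level 1:              b0[c], b1[c]                       (d = 4)
//   level 2 (G = n_roi) / level 3 (G = n_net):
//     mu0[c], mu1[c], log_sigma0[c], log_sigma1[c],
//     z0[c][g], z1[c][g]                                     (d = 8 + 4G)
//   level 4: level-3 block (G = n_net), then
//     log_tau0[c], log_tau1[c], zr0[c][u], zr1[c][u]
//                                     (d = 8 + 4 n_net + 4 + 4 n_roi)
// c = 0 (MCI), 1 (AD); the CN reference has lambda = 0.
// scales = (int, slope, gm0, gm1, gs0, gs1, nd0, nd1).

#include <Rcpp.h>
using namespace Rcpp;

static const double LOG2PI = 1.8378770664093454836;

static inline double norm_lpdf(double x, double m, double s) {
  double z = (x - m) / s;
  return -0.5 * LOG2PI - std::log(s) - 0.5 * z * z;
}

// Half-Normal(scale) log-density at s >= 0 plus the log-Jacobian of the
// log transform is added by the caller.
static inline double halfnorm_lpdf(double s, double scale) {
  return std::log(2.0) - std::log(scale) - 0.5 * LOG2PI -
         s * s / (2.0 * scale * scale);
}

struct Lambda {
  double l1, l2;  // propensities of MCI, AD (CN is 0)
};

// per-observation lambda under any level
static inline Lambda obs_lambda(const NumericVector &theta, int level,
                                int U, int V, double x, int ui, int vi) {
  Lambda lam;
  if (level == 1) {
    lam.l1 = theta[0] + theta[2] * x;
    lam.l2 = theta[1] + theta[3] * x;
    return lam;
  }
  int G = (level == 2) ? U : V;
  int g = (level == 2) ? ui : vi;
  double s0a = std::exp(theta[4]), s0b = std::exp(theta[5]);
  double s1a = std::exp(theta[6]), s1b = std::exp(theta[7]);
  double b0a = theta[0] + s0a * theta[8 + g];
  double b0b = theta[1] + s0b * theta[8 + G + g];
  double b1a = theta[2] + s1a * theta[8 + 2 * G + g];
  double b1b = theta[3] + s1b * theta[8 + 3 * G + g];
  if (level == 4) {
    int off = 8 + 4 * V;
    double t0a = std::exp(theta[off]), t0b = std::exp(theta[off + 1]);
    double t1a = std::exp(theta[off + 2]), t1b = std::exp(theta[off + 3]);
    b0a += t0a * theta[off + 4 + ui];
    b0b += t0b * theta[off + 4 + U + ui];
    b1a += t1a * theta[off + 4 + 2 * U + ui];
    b1b += t1b * theta[off + 4 + 3 * U + ui];
  }
  lam.l1 = b0a + b1a * x;
  lam.l2 = b0b + b1b * x;
  return lam;
}

// [[Rcpp::export]]
List mlr_lp_grad_cpp(NumericVector theta, int level, int U, int V,
                     IntegerVector y, NumericVector x,
                     IntegerVector u, IntegerVector v,
                     NumericVector scales) {
  const int n = y.size();
  const int d = theta.size();
  NumericVector grad(d);
  double lp = 0.0;

  const double s_int = scales[0], s_slope = scales[1];
  const double gm0 = scales[2], gm1 = scales[3];
  const double gs0 = scales[4], gs1 = scales[5];
  const double nd0 = scales[6], nd1 = scales[7];

  // likelihood accumulators with respect to the natural coefficients
  // A0/A1: per (category, group); D0/D1: per (category, ROI), level 4
  int G = (level == 1) ? 1 : ((level == 2) ? U : V);
  std::vector<double> A0(2 * G, 0.0), A1(2 * G, 0.0);
  std::vector<double> D0, D1;
  if (level == 4) {
    D0.assign(2 * U, 0.0);
    D1.assign(2 * U, 0.0);
  }

  for (int i = 0; i < n; ++i) {
    int ui = (level >= 2) ? (u[i] - 1) : 0;
    int vi = (level >= 3) ? (v[i] - 1) : 0;
    if (level >= 2 && (u[i] < 1 || u[i] > U))
      stop("roi index out of range");
    if (level >= 3 && (v[i] < 1 || v[i] > V))
      stop("network index out of range");
    Lambda lam = obs_lambda(theta, level, U, V, x[i], ui, vi);
    double m = std::max(0.0, std::max(lam.l1, lam.l2));
    double lse = m + std::log(std::exp(-m) + std::exp(lam.l1 - m) +
                              std::exp(lam.l2 - m));
    double ly = (y[i] == 2) ? lam.l1 : ((y[i] == 3) ? lam.l2 : 0.0);
    lp += ly - lse;
    double p1 = std::exp(lam.l1 - lse), p2 = std::exp(lam.l2 - lse);
    double g1 = (y[i] == 2 ? 1.0 : 0.0) - p1;
    double g2 = (y[i] == 3 ? 1.0 : 0.0) - p2;
    int g = (level == 1) ? 0 : ((level == 2) ? ui : vi);
    A0[g] += g1;           A0[G + g] += g2;
    A1[g] += g1 * x[i];    A1[G + g] += g2 * x[i];
    if (level == 4) {
      D0[ui] += g1;          D0[U + ui] += g2;
      D1[ui] += g1 * x[i];   D1[U + ui] += g2 * x[i];
    }
  }

  if (level == 1) {
    for (int c = 0; c < 2; ++c) {
      lp += norm_lpdf(theta[c], 0.0, s_int);
      lp += norm_lpdf(theta[2 + c], 0.0, s_slope);
      grad[c] = A0[c] - theta[c] / (s_int * s_int);
      grad[2 + c] = A1[c] - theta[2 + c] / (s_slope * s_slope);
    }
    return List::create(_["lp"] = lp, _["grad"] = grad);
  }

  for (int c = 0; c < 2; ++c) {
    double mu0 = theta[c], mu1 = theta[2 + c];
    double ls0 = theta[4 + c], ls1 = theta[6 + c];
    double sg0 = std::exp(ls0), sg1 = std::exp(ls1);
    lp += norm_lpdf(mu0, 0.0, gm0) + norm_lpdf(mu1, 0.0, gm1);
    lp += halfnorm_lpdf(sg0, gs0) + ls0;  // + Jacobian
    lp += halfnorm_lpdf(sg1, gs1) + ls1;
    double sumA0 = 0, sumA1 = 0, sumA0z = 0, sumA1z = 0;
    for (int g = 0; g < G; ++g) {
      double z0 = theta[8 + c * G + g];
      double z1 = theta[8 + 2 * G + c * G + g];
      lp += norm_lpdf(z0, 0.0, 1.0) + norm_lpdf(z1, 0.0, 1.0);
      double a0 = A0[c * G + g], a1 = A1[c * G + g];
      grad[8 + c * G + g] = a0 * sg0 - z0;
      grad[8 + 2 * G + c * G + g] = a1 * sg1 - z1;
      sumA0 += a0; sumA1 += a1;
      sumA0z += a0 * z0; sumA1z += a1 * z1;
    }
    grad[c] = sumA0 - mu0 / (gm0 * gm0);
    grad[2 + c] = sumA1 - mu1 / (gm1 * gm1);
    grad[4 + c] = sg0 * sumA0z - sg0 * sg0 / (gs0 * gs0) + 1.0;
    grad[6 + c] = sg1 * sumA1z - sg1 * sg1 / (gs1 * gs1) + 1.0;
  }

  if (level == 4) {
    int off = 8 + 4 * V;
    for (int c = 0; c < 2; ++c) {
      double lt0 = theta[off + c], lt1 = theta[off + 2 + c];
      double t0 = std::exp(lt0), t1 = std::exp(lt1);
      lp += halfnorm_lpdf(t0, nd0) + lt0;
      lp += halfnorm_lpdf(t1, nd1) + lt1;
      double sumD0z = 0, sumD1z = 0;
      for (int uu = 0; uu < U; ++uu) {
        double z0 = theta[off + 4 + c * U + uu];
        double z1 = theta[off + 4 + 2 * U + c * U + uu];
        lp += norm_lpdf(z0, 0.0, 1.0) + norm_lpdf(z1, 0.0, 1.0);
        double d0 = D0[c * U + uu], d1 = D1[c * U + uu];
        grad[off + 4 + c * U + uu] = d0 * t0 - z0;
        grad[off + 4 + 2 * U + c * U + uu] = d1 * t1 - z1;
        sumD0z += d0 * z0; sumD1z += d1 * z1;
      }
      grad[off + c] = t0 * sumD0z - t0 * t0 / (nd0 * nd0) + 1.0;
      grad[off + 2 + c] = t1 * sumD1z - t1 * t1 / (nd1 * nd1) + 1.0;
    }
  }

  return List::create(_["lp"] = lp, _["grad"] = grad);
}

// [[Rcpp::export]]
NumericMatrix mlr_pointwise_ll_cpp(NumericMatrix thetas, int level,
                                   int U, int V, IntegerVector y,
                                   NumericVector x, IntegerVector u,
                                   IntegerVector v) {
  const int S = thetas.nrow();
  const int n = y.size();
  NumericMatrix out(S, n);
  for (int s = 0; s < S; ++s) {
    NumericVector theta = thetas(s, _);
    for (int i = 0; i < n; ++i) {
      int ui = (level >= 2) ? (u[i] - 1) : 0;
      int vi = (level >= 3) ? (v[i] - 1) : 0;
      Lambda lam = obs_lambda(theta, level, U, V, x[i], ui, vi);
      double m = std::max(0.0, std::max(lam.l1, lam.l2));
      double lse = m + std::log(std::exp(-m) + std::exp(lam.l1 - m) +
                                std::exp(lam.l2 - m));
      double ly = (y[i] == 2) ? lam.l1 : ((y[i] == 3) ? lam.l2 : 0.0);
      out(s, i) = ly - lse;
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix mlr_probs_cpp(NumericVector theta, int level, int U, int V,
                            NumericVector x, IntegerVector u,
                            IntegerVector v) {
  const int n = x.size();
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i) {
    int ui = (level >= 2) ? (u[i] - 1) : 0;
    int vi = (level >= 3) ? (v[i] - 1) : 0;
    Lambda lam = obs_lambda(theta, level, U, V, x[i], ui, vi);
    double m = std::max(0.0, std::max(lam.l1, lam.l2));
    double e0 = std::exp(-m), e1 = std::exp(lam.l1 - m),
           e2 = std::exp(lam.l2 - m);
    double tot = e0 + e1 + e2;
    out(i, 0) = e0 / tot;
    out(i, 1) = e1 / tot;
    out(i, 2) = e2 / tot;
  }
  return out;
}
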