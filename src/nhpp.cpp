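// Log-likelihood machinery for the logistic-kernel non-homogeneous Poisson
// process.  The kernel factorises over axes, g(u) = prod_i a*b_i /
// (exp(b_i u_i) + 2 + exp(-b_i u_i)); each axis factor is a times a logistic
// density with scale 1/b_i, so the kernel's total mass over R^3 is a^3.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

// a * b / (e^t + 2 + e^-t) evaluated stably; t = b * u
inline double axis_factor(double a, double b, double t) {
  double at = std::fabs(t);
  if (at > 1400.0) return 0.0;  // underflows anyway
  double e = std::exp(at);
  return a * b / (e + 2.0 + 1.0 / e);
}

inline double logistic_cdf(double t) {
  if (t > 0) return 1.0 / (1.0 + std::exp(-t));
  double e = std::exp(t);
  return e / (1.0 + e);
}

}  // namespace

// leave-one-out intensity at every data point
// [[Rcpp::export]]
NumericVector nhpp_lambda_points_cpp(NumericMatrix X, double a,
                                     NumericVector b) {
  const int n = X.nrow();
  NumericVector lam(n, 0.0);
  for (int j = 0; j < n; ++j) {
    for (int k = j + 1; k < n; ++k) {
      double w = 1.0;
      for (int i = 0; i < 3; ++i) {
        double t = b[i] * (X(j, i) - X(k, i));
        w *= axis_factor(a, b[i], t);
        if (w == 0.0) break;
      }
      lam[j] += w;
      lam[k] += w;
    }
  }
  return lam;
}

// sum over points of the kernel mass inside the box (closed form)
// [[Rcpp::export]]
double nhpp_box_mass_cpp(NumericMatrix X, double a, NumericVector b,
                         NumericVector lo, NumericVector hi) {
  const int n = X.nrow();
  const double a3 = a * a * a;
  double total = 0.0;
  for (int j = 0; j < n; ++j) {
    double m = a3;
    for (int i = 0; i < 3; ++i)
      m *= logistic_cdf(b[i] * (hi[i] - X(j, i))) -
           logistic_cdf(b[i] * (lo[i] - X(j, i)));
    total += m;
  }
  return total;
}

// [[Rcpp::export]]
double nhpp_loglik_cpp(NumericMatrix X, double a, NumericVector b,
                       NumericVector lo, NumericVector hi) {
  NumericVector lam = nhpp_lambda_points_cpp(X, a, b);
  double s = 0.0;
  for (int j = 0; j < lam.size(); ++j) {
    if (lam[j] <= 0.0) return R_NegInf;
    s += std::log(lam[j]);
  }
  return s - nhpp_box_mass_cpp(X, a, b, lo, hi);
}

// Pieces of the profile log-likelihood over the concentration parameters:
// with lambda_j = a^3 S_j(b) and box integral a^3 K1(b), the strength
// maximising the likelihood is a^3 = n / K1, so only b needs searching.
// Returns sum_j log S_j (at a = 1) and K1; sum_log_S = -Inf flags a zero
// leave-one-out intensity.
// [[Rcpp::export]]
List nhpp_profile_parts_cpp(NumericMatrix X, NumericVector b,
                            NumericVector lo, NumericVector hi) {
  const int n = X.nrow();
  std::vector<double> lam((size_t)n, 0.0);
  const double* cx = &X(0, 0);
  const double* cy = &X(0, 1);
  const double* cz = &X(0, 2);
  const double bx = b[0], by = b[1], bz = b[2];
  const double bprod = bx * by * bz;
  for (int j = 0; j < n; ++j) {
    const double xj = cx[j], yj = cy[j], zj = cz[j];
    double acc = 0.0;
    for (int k = j + 1; k < n; ++k) {
      double tx = std::fabs(bx * (xj - cx[k]));
      double ty = std::fabs(by * (yj - cy[k]));
      double tz = std::fabs(bz * (zj - cz[k]));
      if (tx + ty + tz > 700.0) continue;  // below double underflow
      double ex = std::exp(tx), ey = std::exp(ty), ez = std::exp(tz);
      double w = bprod / ((ex + 2.0 + 1.0 / ex) * (ey + 2.0 + 1.0 / ey) *
                          (ez + 2.0 + 1.0 / ez));
      acc += w;
      lam[k] += w;
    }
    lam[j] += acc;
  }
  double sum_log = 0.0;
  for (int j = 0; j < n; ++j) {
    if (lam[j] <= 0.0) { sum_log = R_NegInf; break; }
    sum_log += std::log(lam[j]);
  }
  double K1 = 0.0;
  for (int j = 0; j < n; ++j) {
    double m = 1.0;
    for (int i = 0; i < 3; ++i)
      m *= logistic_cdf(b[i] * (hi[i] - X(j, i))) -
           logistic_cdf(b[i] * (lo[i] - X(j, i)));
    K1 += m;
  }
  return List::create(Named("sum_log_S") = sum_log, Named("K1") = K1);
}

// intensity at arbitrary locations U given data points X (no exclusion)
// [[Rcpp::export]]
NumericVector nhpp_lambda_at_cpp(NumericMatrix U, NumericMatrix X, double a,
                                 NumericVector b) {
  const int m = U.nrow(), n = X.nrow();
  NumericVector lam(m, 0.0);
  for (int q = 0; q < m; ++q)
    for (int k = 0; k < n; ++k) {
      double w = 1.0;
      for (int i = 0; i < 3; ++i) {
        double t = b[i] * (U(q, i) - X(k, i));
        w *= axis_factor(a, b[i], t);
        if (w == 0.0) break;
      }
      lam[q] += w;
    }
  return lam;
}
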