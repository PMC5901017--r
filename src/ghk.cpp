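// GHK simulator for trivariate normal rectangle probabilities and the
// simulated likelihood kernel of the correlated double-inflated ordered
// probit.  Scalar special functions are local so the per-draw recursion
// stays cheap on a single CPU; both are exercised against R's pnorm/qnorm
// in the test suite.
#include <Rcpp.h>
#include <cmath>
#include <limits>
using namespace Rcpp;

static const double SQRT2 = 1.4142135623730951;
static const double SQRT_2PI = 2.5066282746310002;

// standard normal CDF via erfc: accurate to ~1e-16 over the full range
static inline double phid(double x) {
  if (x == R_PosInf) return 1.0;
  if (x == R_NegInf) return 0.0;
  return 0.5 * std::erfc(-x / SQRT2);
}

// Acklam's rational approximation to the normal quantile (~1.2e-9 relative
// accuracy) -- used raw inside the GHK recursion where it is far below the
// simulation error, and polished with one Halley step for exported use.
static double qnorm_acklam(double p) {
  if (p <= 0.0) return R_NegInf;
  if (p >= 1.0) return R_PosInf;
  static const double a[6] = {
    -3.969683028665376e+01,  2.209460984245205e+02, -2.759285104469687e+02,
     1.383577518672690e+02, -3.066479806614716e+01,  2.506628277459239e+00 };
  static const double b[5] = {
    -5.447609879822406e+01,  1.615858368580409e+02, -1.556989798598866e+02,
     6.680131188771972e+01, -1.328068155288572e+01 };
  static const double c[6] = {
    -7.784894002430293e-03, -3.223964580411365e-01, -2.400758277161838e+00,
    -2.549732539343734e+00,  4.374664141464968e+00,  2.938163982698783e+00 };
  static const double d[4] = {
     7.784695709041462e-03,  3.224671290700398e-01,  2.445134137142996e+00,
     3.754408661907416e+00 };
  const double plow = 0.02425, phigh = 1.0 - plow;
  double x;
  if (p < plow) {
    double q = std::sqrt(-2.0 * std::log(p));
    x = (((((c[0]*q + c[1])*q + c[2])*q + c[3])*q + c[4])*q + c[5]) /
        ((((d[0]*q + d[1])*q + d[2])*q + d[3])*q + 1.0);
  } else if (p <= phigh) {
    double q = p - 0.5, r = q * q;
    x = (((((a[0]*r + a[1])*r + a[2])*r + a[3])*r + a[4])*r + a[5]) * q /
        (((((b[0]*r + b[1])*r + b[2])*r + b[3])*r + b[4])*r + 1.0);
  } else {
    double q = std::sqrt(-2.0 * std::log(1.0 - p));
    x = -(((((c[0]*q + c[1])*q + c[2])*q + c[3])*q + c[4])*q + c[5]) /
         ((((d[0]*q + d[1])*q + d[2])*q + d[3])*q + 1.0);
  }
  return x;
}

static double qnorm_fast(double p) {
  double x = qnorm_acklam(p);
  if (!std::isfinite(x) || std::fabs(x) > 36.0) return x;
  // Halley refinement
  double e = phid(x) - p;
  double u = e * SQRT_2PI * std::exp(0.5 * x * x);
  x = x - u / (1.0 + 0.5 * x * u);
  return x;
}

// radical-inverse (van der Corput) value of index i in the given base
static inline double radical_inverse(unsigned long i, int base) {
  double f = 1.0, r = 0.0;
  while (i > 0) {
    f /= base;
    r += f * (i % base);
    i /= base;
  }
  return r;
}

static inline double shifted_point(unsigned long i, int base, double shift) {
  double u = radical_inverse(i, base) + shift;
  u -= std::floor(u);
  const double eps = 1e-12;
  if (u < eps) u = eps;
  if (u > 1.0 - eps) u = 1.0 - eps;
  return u;
}

// [[Rcpp::export]]
NumericVector cpp_halton(int n, int base, double shift, int skip) {
  NumericVector out(n);
  for (int k = 0; k < n; ++k)
    out[k] = shifted_point((unsigned long)(k + 1 + skip), base, shift);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_pnorm_fast(NumericVector x) {
  int n = x.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = phid(x[i]);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_qnorm_fast(NumericVector p) {
  int n = p.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = qnorm_fast(p[i]);
  return out;
}

// Generic GHK rectangle probability P(V1<=a1, V2<=a2, V3<=a3) for V ~ N(0,R),
// L = lower Cholesky of R.  Rows of A are independent problems; row i uses
// its own contiguous Halton segment so draws are observation-specific and
// fixed across likelihood evaluations.  Returns prob and a draw-based
// standard error (conservative for scrambled Halton points).
// [[Rcpp::export]]
List cpp_ghk_rect(NumericMatrix A, NumericMatrix L, int m, double shift1,
                  double shift2, bool antithetic, bool segment_rows) {
  int n = A.nrow();
  NumericVector prob(n), se(n);
  double l11 = L(0, 0), l21 = L(1, 0), l22 = L(1, 1);
  double l31 = L(2, 0), l32 = L(2, 1), l33 = L(2, 2);
  for (int i = 0; i < n; ++i) {
    double a1 = A(i, 0), a2 = A(i, 1), a3 = A(i, 2);
    double e1 = phid(a1 / l11);
    if (e1 <= 0.0) { prob[i] = 0.0; se[i] = 0.0; continue; }
    double sum = 0.0, sumsq = 0.0;
    unsigned long off = segment_rows ? (unsigned long)i * (unsigned long)m : 0;
    for (int k = 0; k < m; ++k) {
      unsigned long idx = off + (unsigned long)k + 1;
      double u1 = shifted_point(idx, 2, shift1);
      double u2 = shifted_point(idx, 3, shift2);
      double pair = 0.0;
      int reps = antithetic ? 2 : 1;
      for (int s = 0; s < reps; ++s) {
        double v1 = (s == 0) ? u1 : 1.0 - u1;
        double v2 = (s == 0) ? u2 : 1.0 - u2;
        double z1 = qnorm_fast(v1 * e1);
        double e2 = phid((a2 - l21 * z1) / l22);
        double p;
        if (e2 <= 1e-300) {
          p = 0.0;
        } else {
          double z2 = qnorm_fast(v2 * e2);
          double e3 = phid((a3 - l31 * z1 - l32 * z2) / l33);
          p = e1 * e2 * e3;
        }
        pair += p;
      }
      pair /= reps;
      sum += pair;
      sumsq += pair * pair;
    }
    double mean = sum / m;
    double var = (m > 1) ? (sumsq - m * mean * mean) / (m - 1.0) / m : 0.0;
    if (var < 0.0) var = 0.0;
    prob[i] = mean;
    se[i] = std::sqrt(var);
  }
  return List::create(_["prob"] = prob, _["se"] = se);
}

// One-pass GHK for the correlated double-inflated ordered probit.
// Works in the transformed system (V1, V2, V3) = (-eps_r, -eps_m, eps_y),
// whose correlations are (rho_rm, -rho_ry, -rho_my); L is its lower
// Cholesky.  ar, am, ay are the row-level linear indices x'beta; mu the
// strictly increasing thresholds (mu_0 = 0 implicit).
//
// ycat empty: return an n x (J+4) matrix with category probabilities 0..J
// followed by the three zero components (nonparticipation, misreporting,
// true zero).  Otherwise ycat[i] in 0..J and an n-vector of the observed
// category's probability is returned.  Because every term is a product of
// the same recursive conditioning factors, rows sum to one exactly.
// u1, u2 are precomputed uniform draws of length n*m (row i owns the
// contiguous block i*m..(i+1)*m-1), fixed across likelihood evaluations.
// [[Rcpp::export]]
SEXP cpp_ghk_dziopc(NumericVector ar, NumericVector am, NumericVector ay,
                    NumericVector mu, NumericMatrix L, int m,
                    NumericVector u1, NumericVector u2,
                    bool antithetic, IntegerVector ycat) {
  int n = ar.size();
  int J = mu.size() + 1;           // highest category
  bool full = (ycat.size() == 0);
  double l21 = L(1, 0), l22 = L(1, 1);
  double l31 = L(2, 0), l32 = L(2, 1), l33 = L(2, 2);
  if ((R_xlen_t)n * m > u1.size() || (R_xlen_t)n * m > u2.size())
    stop("draw vectors shorter than n * m");
  NumericMatrix out_full(full ? n : 0, full ? (J + 4) : 0);
  NumericVector out_y(full ? 0 : n);
  // threshold vector including mu_0 = 0
  std::vector<double> thr(J);
  thr[0] = 0.0;
  for (int j = 1; j < J; ++j) thr[j] = mu[j - 1];
  std::vector<double> ef(J);       // running sums of e2 * e3^j products
  for (int i = 0; i < n; ++i) {
    double e1 = phid(ar[i]);
    double sum_e2 = 0.0;
    for (int j = 0; j < J; ++j) ef[j] = 0.0;
    int jlo = 0, jhi = J - 1;      // which e3 levels are needed
    if (!full) {
      int y = ycat[i];
      if (y == 0)       { jlo = 0;     jhi = 0; }
      else if (y == J)  { jlo = J - 1; jhi = J - 1; }
      else              { jlo = y - 1; jhi = y; }
    }
    R_xlen_t off = (R_xlen_t)i * m;
    int reps = antithetic ? 2 : 1;
    double w = 1.0 / reps;
    for (int k = 0; k < m; ++k) {
      double uu1 = u1[off + k];
      double uu2 = u2[off + k];
      for (int s = 0; s < reps; ++s) {
        double v1 = (s == 0) ? uu1 : 1.0 - uu1;
        double v2 = (s == 0) ? uu2 : 1.0 - uu2;
        if (e1 <= 0.0) continue;
        double z1 = qnorm_acklam(v1 * e1);
        double e2 = phid((am[i] - l21 * z1) / l22);
        sum_e2 += w * e2;
        if (e2 <= 1e-300) continue;
        double z2 = qnorm_acklam(v2 * e2);
        double base = ay[i] + l31 * z1 + l32 * z2;
        for (int j = jlo; j <= jhi; ++j)
          ef[j] += w * e2 * phid((thr[j] - base) / l33);
      }
    }
    double mbar_e2 = sum_e2 / m;
    if (full) {
      for (int j = 0; j < J; ++j) ef[j] /= m;
      double c1 = 1.0 - e1;                    // nonparticipation
      double c2 = e1 * (1.0 - mbar_e2);        // participant misreporter
      double c3 = e1 * ef[0];                  // truthful zero consumer
      out_full(i, 0) = c1 + c2 + c3;
      for (int j = 1; j < J; ++j)
        out_full(i, j) = e1 * (ef[j] - ef[j - 1]);
      out_full(i, J) = e1 * (mbar_e2 - ef[J - 1]);
      out_full(i, J + 1) = c1;
      out_full(i, J + 2) = c2;
      out_full(i, J + 3) = c3;
    } else {
      int y = ycat[i];
      double p;
      if (y == 0)
        p = (1.0 - e1) + e1 * (1.0 - mbar_e2) + e1 * ef[0] / m;
      else if (y == J)
        p = e1 * (mbar_e2 - ef[J - 1] / m);
      else
        p = e1 * (ef[y] - ef[y - 1]) / m;
      out_y[i] = p;
    }
  }
  if (full) return out_full;
  return out_y;
}

// Batched evaluation of the DZIOPC log-likelihood at a set of parameter
// configurations sharing the same draws -- the workhorse of the central
// finite-difference gradient.  Each configuration c has its own linear
// indices (columns of AR/AM/AY), thresholds (columns of MU) and Cholesky
// factor (columns of LV, the 3x3 lower factor stacked column-major).
// levels[c] says how much of the recursion the configuration shares with
// configuration 0 (the base point):
//   3: only ay/mu differ   -> reuse z1, e2, z2; recompute the last stage
//   2: am also differs     -> reuse z1
//   1: ar or L differ      -> full recomputation
// Returns the total log-likelihood (probabilities floored at 1e-300) for
// every configuration, or the n x C matrix of row-level log-probabilities
// when rowwise is true (used for per-row scores).
// [[Rcpp::export]]
SEXP cpp_ghk_dziopc_batch(NumericMatrix AR, NumericMatrix AM,
                          NumericMatrix AY, NumericMatrix MU,
                          NumericMatrix LV, IntegerVector levels,
                          int m, NumericVector u1, NumericVector u2,
                          bool antithetic, IntegerVector ycat,
                          bool rowwise = false) {
  int n = AR.nrow(), C = AR.ncol();
  int J = MU.nrow() + 1;
  if ((R_xlen_t)n * m > u1.size()) stop("draw vectors shorter than n * m");
  NumericVector ll(C);
  NumericMatrix LL(rowwise ? n : 0, rowwise ? C : 0);
  std::vector<double> l21(C), l22(C), l31(C), l32(C), l33(C);
  for (int c = 0; c < C; ++c) {
    l21[c] = LV(1, c); l22[c] = LV(4, c);
    l31[c] = LV(2, c); l32[c] = LV(5, c); l33[c] = LV(8, c);
  }
  std::vector<double> e1(C), sum_e2(C), ef(C * J), thr(C * J);
  for (int c = 0; c < C; ++c) {
    thr[c * J] = 0.0;
    for (int j = 1; j < J; ++j) thr[c * J + j] = MU(j - 1, c);
  }
  int reps = antithetic ? 2 : 1;
  double w = 1.0 / reps;
  for (int i = 0; i < n; ++i) {
    int y = ycat[i];
    int jlo, jhi;
    if (y == 0)      { jlo = 0;     jhi = 0; }
    else if (y == J) { jlo = J - 1; jhi = J - 1; }
    else             { jlo = y - 1; jhi = y; }
    for (int c = 0; c < C; ++c) {
      e1[c] = phid(AR(i, c));
      sum_e2[c] = 0.0;
      for (int j = jlo; j <= jhi; ++j) ef[c * J + j] = 0.0;
    }
    R_xlen_t off = (R_xlen_t)i * m;
    for (int k = 0; k < m; ++k) {
      double uu1 = u1[off + k], uu2 = u2[off + k];
      for (int s = 0; s < reps; ++s) {
        double v1 = (s == 0) ? uu1 : 1.0 - uu1;
        double v2 = (s == 0) ? uu2 : 1.0 - uu2;
        // base stages (configuration 0)
        double z1b = 0.0, e2b = 0.0, z2b = 0.0;
        bool base_ok = e1[0] > 0.0;
        if (base_ok) {
          z1b = qnorm_acklam(v1 * e1[0]);
          e2b = phid((AM(i, 0) - l21[0] * z1b) / l22[0]);
          z2b = (e2b > 1e-300) ? qnorm_acklam(v2 * e2b) : R_NegInf;
        }
        for (int c = 0; c < C; ++c) {
          int lev = (c == 0) ? 3 : levels[c];
          double z1, e2, z2;
          if (c == 0 || lev >= 2) {
            if (!base_ok) continue;
            z1 = z1b;
          } else {                     // level 1: own first stage
            if (e1[c] <= 0.0) continue;
            z1 = qnorm_acklam(v1 * e1[c]);
          }
          if (c == 0 || lev == 3) {
            e2 = e2b; z2 = z2b;
          } else {
            e2 = phid((AM(i, c) - l21[c] * z1) / l22[c]);
            z2 = (e2 > 1e-300) ? qnorm_acklam(v2 * e2) : R_NegInf;
          }
          sum_e2[c] += w * e2;
          if (e2 <= 1e-300) continue;
          double base = AY(i, c) + l31[c] * z1 + l32[c] * z2;
          for (int j = jlo; j <= jhi; ++j)
            ef[c * J + j] += w * e2 * phid((thr[c * J + j] - base) / l33[c]);
        }
      }
    }
    for (int c = 0; c < C; ++c) {
      double mbar = sum_e2[c] / m, p;
      if (y == 0)
        p = (1.0 - e1[c]) + e1[c] * (1.0 - mbar) + e1[c] * ef[c * J] / m;
      else if (y == J)
        p = e1[c] * (mbar - ef[c * J + J - 1] / m);
      else
        p = e1[c] * (ef[c * J + y] - ef[c * J + y - 1]) / m;
      if (p < 1e-300) p = 1e-300;
      if (rowwise) LL(i, c) = std::log(p);
      else ll[c] += std::log(p);
    }
  }
  if (rowwise) return LL;
  return ll;
}

// Brute-force Monte-Carlo oracle for a trivariate rectangle probability.
// Uses R's RNG stream (set the seed from R).  Returns the hit fraction and
// its binomial standard error.
// [[Rcpp::export]]
NumericVector cpp_mc_rect3(NumericVector a, NumericMatrix L, double ndraw) {
  double l11 = L(0, 0), l21 = L(1, 0), l22 = L(1, 1);
  double l31 = L(2, 0), l32 = L(2, 1), l33 = L(2, 2);
  RNGScope scope;
  double hits = 0.0;
  long nd = (long)ndraw;
  for (long k = 0; k < nd; ++k) {
    double z1 = norm_rand(), z2 = norm_rand(), z3 = norm_rand();
    double v1 = l11 * z1;
    double v2 = l21 * z1 + l22 * z2;
    double v3 = l31 * z1 + l32 * z2 + l33 * z3;
    if (v1 <= a[0] && v2 <= a[1] && v3 <= a[2]) hits += 1.0;
  }
  double p = hits / ndraw;
  double se = std::sqrt(p * (1.0 - p) / ndraw);
  NumericVector out = NumericVector::create(p, se);
  return out;
}
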