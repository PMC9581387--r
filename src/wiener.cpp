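// Wiener diffusion first-passage-time machinery.
//
// Density evaluation uses the classic pair of series expansions for the
// first-passage density of a drifted Brownian motion between two absorbing
// boundaries, with the number of terms chosen per evaluation from the
// standard error bounds so that the truncation error of the scaled density
// is below `err` (default 1e-7), switching automatically between the
// small-time and large-time regimes.
//
// Conventions: boundary separation a > 0, relative start w in (0,1) measured
// from the lower boundary, drift v toward the upper boundary, diffusion
// coefficient 1, decision time t > 0 (non-decision time already subtracted).
// The primitive is the LOWER-boundary density; the upper-boundary density is
// obtained by (v, w) -> (-v, 1-w).

#include <Rcpp.h>
#include <cmath>
#include <limits>
using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::infinity();

static inline double softplus_c(double x) {
  return (x > 0.0) ? x + std::log1p(std::exp(-x)) : std::log1p(std::exp(x));
}

// log of the scaled (a = 1, v = 0) lower-boundary density at scaled time t.
static double logf0(double t, double w, double err) {
  if (!(t > 0.0)) return NEG_INF;
  double ks, kl;
  if (2.0 * std::sqrt(2.0 * M_PI * t) * err < 1.0) {
    ks = 2.0 + std::sqrt(-2.0 * t * std::log(2.0 * err * std::sqrt(2.0 * M_PI * t)));
    ks = std::max(ks, std::sqrt(t) + 1.0);
  } else {
    ks = 2.0;
  }
  if (M_PI * t * err < 1.0) {
    kl = std::sqrt(-2.0 * std::log(M_PI * t * err) / (M_PI * M_PI * t));
    kl = std::max(kl, 1.0 / (M_PI * std::sqrt(t)));
  } else {
    kl = 1.0 / (M_PI * std::sqrt(t));
  }
  double f;
  if (ks < kl) {
    int K = (int)std::ceil(ks);
    int lo = -((K - 1) / 2);
    int hi = (K + 1) / 2;
    double s = 0.0;
    for (int k = lo; k <= hi; k++) {
      double wk = w + 2.0 * k;
      s += wk * std::exp(-wk * wk / (2.0 * t));
    }
    f = s / std::sqrt(2.0 * M_PI * t * t * t);
  } else {
    int K = (int)std::ceil(kl);
    double s = 0.0;
    for (int k = 1; k <= K; k++) {
      s += k * std::exp(-0.5 * k * k * M_PI * M_PI * t) * std::sin(k * M_PI * w);
    }
    f = M_PI * s;
  }
  return (f > 0.0) ? std::log(f) : NEG_INF;
}

// log lower-boundary first-passage density at decision time t.
static double log_fpt_lower(double t, double v, double a, double w, double err) {
  if (!(t > 0.0) || !(a > 0.0) || !(w > 0.0) || !(w < 1.0)) return NEG_INF;
  return logf0(t / (a * a), w, err) - 2.0 * std::log(a) - v * a * w - 0.5 * v * v * t;
}

// log density at the boundary matching the observed choice
// (is_stop = 1 -> upper boundary).
static double log_fpt_choice(double t, int is_stop, double v, double a,
                             double w, double err) {
  if (is_stop) return log_fpt_lower(t, -v, a, 1.0 - w, err);
  return log_fpt_lower(t, v, a, w, err);
}

// Probability of absorption at the upper boundary.
static double p_upper_c(double v, double a, double w) {
  double va = v * a;
  if (std::fabs(va) < 1e-10) return w;
  if (-2.0 * va > 500.0) return std::exp(2.0 * va * (1.0 - w));  // strong downward drift
  double num = -std::expm1(-2.0 * va * w);
  double den = -std::expm1(-2.0 * va);
  double p = num / den;
  if (p < 0.0) p = 0.0;
  if (p > 1.0) p = 1.0;
  return p;
}

//' @name wiener-internal
//' @keywords internal
// [[Rcpp::export]]
NumericVector wiener_logpdf_cpp(NumericVector t, IntegerVector is_stop,
                                NumericVector v, NumericVector a,
                                NumericVector w, double err = 1e-7) {
  int n = t.size();
  NumericVector out(n);
  for (int i = 0; i < n; i++) {
    out[i] = log_fpt_choice(t[i], is_stop[i], v[i], a[i], w[i], err);
  }
  return out;
}

// [[Rcpp::export]]
NumericVector wiener_p_upper_cpp(NumericVector v, NumericVector a,
                                 NumericVector w) {
  int n = v.size();
  NumericVector out(n);
  for (int i = 0; i < n; i++) out[i] = p_upper_c(v[i], a[i], w[i]);
  return out;
}

// Exact-in-distribution sampling of (choice, decision time): the boundary is
// drawn from its analytic probability, then the first-passage time from the
// conditional density by inverse-CDF on a quadratically spaced grid (finer
// near zero where the density peaks). Uses R's RNG.
// [[Rcpp::export]]
List wiener_sample_cpp(NumericVector v, NumericVector a, NumericVector w,
                       NumericVector t0, double err = 1e-7, int grid_n = 512) {
  int n = v.size();
  IntegerVector choice(n);
  NumericVector rt(n);
  std::vector<double> tg(grid_n + 1), fg(grid_n + 1), cg(grid_n + 1);
  for (int i = 0; i < n; i++) {
    double pu = p_upper_c(v[i], a[i], w[i]);
    int up = (unif_rand() < pu) ? 1 : 0;
    choice[i] = up;
    double vv = up ? -v[i] : v[i];
    double ww = up ? 1.0 - w[i] : w[i];
    double pb = up ? pu : 1.0 - pu;
    double lam = 0.5 * vv * vv + 0.5 * M_PI * M_PI / (a[i] * a[i]);
    double tmax = std::max(16.0 / lam, 2.0 * a[i] * a[i]);
    double mass = 0.0;
    for (int tries = 0; tries < 8; tries++) {
      tg[0] = 0.0; fg[0] = 0.0; cg[0] = 0.0;
      for (int j = 1; j <= grid_n; j++) {
        double frac = (double)j / grid_n;
        tg[j] = tmax * frac * frac;
        double lf = log_fpt_lower(tg[j], vv, a[i], ww, err);
        fg[j] = std::isfinite(lf) ? std::exp(lf) : 0.0;
        cg[j] = cg[j - 1] + 0.5 * (fg[j] + fg[j - 1]) * (tg[j] - tg[j - 1]);
      }
      mass = cg[grid_n];
      if (mass >= 0.9995 * pb || pb < 1e-12) break;
      tmax *= 2.0;
    }
    double u = unif_rand() * mass;
    int lo = 0, hi = grid_n;
    while (hi - lo > 1) {
      int mid = (lo + hi) / 2;
      if (cg[mid] < u) lo = mid; else hi = mid;
    }
    double seg = cg[hi] - cg[lo];
    double frac = (seg > 0.0) ? (u - cg[lo]) / seg : 0.5;
    rt[i] = t0[i] + tg[lo] + frac * (tg[hi] - tg[lo]);
  }
  return List::create(_["choice_upper"] = choice, _["rt"] = rt);
}

// Small-step Euler-Maruyama first-passage simulator. Kept deliberately
// simple and independent of the series density above so it can serve as a
// Monte-Carlo oracle. Uses R's RNG. Walks not absorbed by t_cap are
// returned with choice_upper = NA.
// [[Rcpp::export]]
List euler_fpt_oracle(int n, double v, double a, double w, double dt = 1e-4,
                      double t_cap = 200.0) {
  IntegerVector choice(n);
  NumericVector fpt(n);
  double sd = std::sqrt(dt);
  for (int i = 0; i < n; i++) {
    double x = w * a;
    double t = 0.0;
    int res = NA_INTEGER;
    while (t < t_cap) {
      x += v * dt + sd * norm_rand();
      t += dt;
      if (x >= a) { res = 1; break; }
      if (x <= 0.0) { res = 0; break; }
    }
    choice[i] = res;
    fpt[i] = t;
  }
  return List::create(_["choice_upper"] = choice, _["fpt"] = fpt);
}

// Summed log-likelihood of one participant's trials under trial-wise linked
// parameters: drift d0 + d1*xd, threshold softplus(a0 + a1*xa), start
// Phi(z0 + z1*xz), common non-decision time ter. Unmodulated parameters are
// encoded by a zero slope and zero covariate.
// [[Rcpp::export]]
double wiener_loglik_sum(NumericVector rt, IntegerVector is_stop,
                         NumericVector xd, NumericVector xa, NumericVector xz,
                         double d0, double d1, double a0, double a1,
                         double z0, double z1, double ter, double err = 1e-7) {
  int n = rt.size();
  double ll = 0.0;
  for (int i = 0; i < n; i++) {
    double t = rt[i] - ter;
    if (!(t > 0.0)) return NEG_INF;
    double v = d0 + d1 * xd[i];
    double a = softplus_c(a0 + a1 * xa[i]);
    double w = R::pnorm(z0 + z1 * xz[i], 0.0, 1.0, 1, 0);
    if (w < 1e-10) w = 1e-10;
    if (w > 1.0 - 1e-10) w = 1.0 - 1e-10;
    double lf = log_fpt_choice(t, is_stop[i], v, a, w, err);
    if (!std::isfinite(lf)) return NEG_INF;
    ll += lf;
  }
  return ll;
}

// Per-trial version of wiener_loglik_sum, for pointwise WAIC matrices.
// [[Rcpp::export]]
NumericVector wiener_loglik_vec(NumericVector rt, IntegerVector is_stop,
                                NumericVector xd, NumericVector xa,
                                NumericVector xz, double d0, double d1,
                                double a0, double a1, double z0, double z1,
                                double ter, double err = 1e-7) {
  int n = rt.size();
  NumericVector out(n);
  for (int i = 0; i < n; i++) {
    double t = rt[i] - ter;
    if (!(t > 0.0)) { out[i] = NEG_INF; continue; }
    double v = d0 + d1 * xd[i];
    double a = softplus_c(a0 + a1 * xa[i]);
    double w = R::pnorm(z0 + z1 * xz[i], 0.0, 1.0, 1, 0);
    if (w < 1e-10) w = 1e-10;
    if (w > 1.0 - 1e-10) w = 1.0 - 1e-10;
    out[i] = log_fpt_choice(t, is_stop[i], v, a, w, err);
  }
  return out;
}
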