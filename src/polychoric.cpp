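// Two-step maximum-likelihood polychoric correlation.
// Thresholds come from the contingency-table margins (inverse normal CDF of
// cumulative proportions); the latent correlation is then the 1-D maximizer
// of the bivariate-normal multinomial likelihood with thresholds held fixed.
#include <Rcpp.h>
#include <cmath>
#include <functional>
#include <vector>
using namespace Rcpp;

static inline double Phi(double x) { return R::pnorm(x, 0.0, 1.0, 1, 0); }
static inline double phi(double x) { return R::dnorm(x, 0.0, 1.0, 0); }

// Gauss-Legendre nodes/weights (positive half; symmetric rules).
static const double GLX6[3] = {0.9324695142031521, 0.6612093864662645,
                               0.2386191860831969};
static const double GLW6[3] = {0.1713244923791704, 0.3607615730481386,
                               0.4679139345726910};
static const double GLX12[6] = {0.9815606342467192, 0.9041172563704749,
                                0.7699026741943047, 0.5873179542866175,
                                0.3678314989981802, 0.1252334085114689};
static const double GLW12[6] = {0.04717533638651183, 0.10693932599531843,
                                0.16007832854334622, 0.20316742672306592,
                                0.23349253653835481, 0.24914704581340277};
static const double GLX20[10] = {0.9931285991850949, 0.9639719272779138,
                                 0.9122344282513259, 0.8391169718222188,
                                 0.7463319064601508, 0.6360536807265150,
                                 0.5108670019508271, 0.3737060887154195,
                                 0.2277858511416451, 0.07652652113349734};
static const double GLW20[10] = {0.01761400713915212, 0.04060142980038694,
                                 0.06267204833410907, 0.08327674157670475,
                                 0.10193011981724044, 0.11819453196151841,
                                 0.13168863844917663, 0.14209610931838205,
                                 0.14917298647260375, 0.15275338713072585};

// integral over [a, b] of phi(x) * Phi((k - r*x)/s) dx with 20-point GL
static double panel_int(double a, double b, double k, double r, double s) {
  if (b <= a) return 0.0;
  double c = 0.5 * (a + b), hw = 0.5 * (b - a), acc = 0.0;
  for (int i = 0; i < 10; i++) {
    double x1 = c - hw * GLX20[i], x2 = c + hw * GLX20[i];
    acc += GLW20[i] * (phi(x1) * Phi((k - r * x1) / s) +
                       phi(x2) * Phi((k - r * x2) / s));
  }
  return acc * hw;
}

// P(X <= h, Y <= k) under standard bivariate normal with correlation r.
// Moderate |r|: Gauss-Legendre on the asin-substituted Drezner-Wesolowsky
// integral. |r| > 0.925: panelled 1-D quadrature, panels split around the
// transition point of the inner conditional CDF.
double pbvn(double h, double k, double r) {
  if (ISNAN(h) || ISNAN(k) || ISNAN(r)) return NA_REAL;
  if (h <= -8.5 || k <= -8.5) return 0.0;
  if (h >= 8.5) return Phi(k);
  if (k >= 8.5) return Phi(h);
  if (r >= 1.0 - 1e-12) return Phi(std::min(h, k));
  if (r <= -1.0 + 1e-12) {
    double v = Phi(h) + Phi(k) - 1.0;
    return v > 0.0 ? v : 0.0;
  }
  double ar = std::fabs(r);
  if (ar <= 0.925) {
    const double *x;
    const double *w;
    int ng;
    if (ar < 0.3) { x = GLX6; w = GLW6; ng = 3; }
    else if (ar < 0.75) { x = GLX12; w = GLW12; ng = 6; }
    else { x = GLX20; w = GLW20; ng = 10; }
    double hk = h * k, hs = 0.5 * (h * h + k * k);
    double asr = std::asin(r), bvn = 0.0;
    for (int i = 0; i < ng; i++) {
      double sn = std::sin(asr * (1.0 - x[i]) * 0.5);
      bvn += w[i] * std::exp((sn * hk - hs) / (1.0 - sn * sn));
      sn = std::sin(asr * (1.0 + x[i]) * 0.5);
      bvn += w[i] * std::exp((sn * hk - hs) / (1.0 - sn * sn));
    }
    return bvn * asr / (4.0 * M_PI) + Phi(h) * Phi(k);
  }
  // high-|r| branch: integrate over x up to h
  double s = std::sqrt((1.0 - r) * (1.0 + r));
  double lo = -8.5, hi = std::min(h, 8.5);
  if (hi <= lo) return 0.0;
  double x0 = k / r;  // where the inner CDF transitions
  double wdt = 6.0 * s / ar;
  double b1 = std::min(std::max(x0 - wdt, lo), hi);
  double b2 = std::min(std::max(x0 + wdt, lo), hi);
  return panel_int(lo, b1, k, r, s) + panel_int(b1, b2, k, r, s) +
         panel_int(b2, hi, k, r, s);
}

// [[Rcpp::export(name = ".cppPbvn")]]
NumericVector cpp_pbvn(NumericVector h, NumericVector k, NumericVector r) {
  R_xlen_t n = std::max(h.size(), std::max(k.size(), r.size()));
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; i++)
    out[i] = pbvn(h[i % h.size()], k[i % k.size()], r[i % r.size()]);
  return out;
}

// Rectangle probabilities for every cell. ta/tb hold the K-1 (L-1)
// interior thresholds; cell (i, j) is the probability of the rectangle
// (ta[i-1], ta[i]] x (tb[j-1], tb[j]] with -Inf/+Inf at the ends.
static void cell_probs(const std::vector<double> &ta,
                       const std::vector<double> &tb, double r,
                       std::vector<double> &P) {
  size_t K = ta.size() + 1, L = tb.size() + 1;
  std::vector<double> F(K * L);  // CDF at upper corners
  for (size_t i = 0; i < K; i++)
    for (size_t j = 0; j < L; j++) {
      double v;
      if (i == K - 1 && j == L - 1) v = 1.0;
      else if (i == K - 1) v = Phi(tb[j]);
      else if (j == L - 1) v = Phi(ta[i]);
      else v = pbvn(ta[i], tb[j], r);
      F[i * L + j] = v;
    }
  for (size_t i = 0; i < K; i++)
    for (size_t j = 0; j < L; j++) {
      double v = F[i * L + j];
      if (i > 0) v -= F[(i - 1) * L + j];
      if (j > 0) v -= F[i * L + (j - 1)];
      if (i > 0 && j > 0) v += F[(i - 1) * L + (j - 1)];
      P[i * L + j] = v;
    }
}

// negative log-likelihood of the contingency table at correlation r
static double table_nll(const std::vector<double> &tab,
                        const std::vector<double> &ta,
                        const std::vector<double> &tb, double r) {
  size_t K = ta.size() + 1, L = tb.size() + 1;
  std::vector<double> P(K * L);
  cell_probs(ta, tb, r, P);
  double nll = 0.0;
  for (size_t c = 0; c < K * L; c++) {
    if (tab[c] > 0.0) {
      double p = P[c];
      if (p < 1e-12) p = 1e-12;
      nll -= tab[c] * std::log(p);
    }
  }
  return nll;
}

// Brent local minimizer on [lo, hi]
static double brent_min(double lo, double hi,
                        const std::function<double(double)> &f, double tol,
                        int maxit, bool *converged) {
  const double gold = 0.3819660112501051;
  double a = lo, b = hi;
  double x = a + gold * (b - a), w = x, v = x;
  double fx = f(x), fw = fx, fv = fx;
  double d = 0.0, e = 0.0;
  *converged = false;
  for (int it = 0; it < maxit; it++) {
    double m = 0.5 * (a + b);
    double tol1 = tol * std::fabs(x) + 1e-10, tol2 = 2.0 * tol1;
    if (std::fabs(x - m) <= tol2 - 0.5 * (b - a)) {
      *converged = true;
      return x;
    }
    double p = 0.0, q = 0.0, rr = 0.0;
    bool use_gold = true;
    if (std::fabs(e) > tol1) {
      rr = (x - w) * (fx - fv);
      q = (x - v) * (fx - fw);
      p = (x - v) * q - (x - w) * rr;
      q = 2.0 * (q - rr);
      if (q > 0.0) p = -p;
      q = std::fabs(q);
      double etmp = e;
      e = d;
      if (std::fabs(p) < std::fabs(0.5 * q * etmp) && p > q * (a - x) &&
          p < q * (b - x)) {
        use_gold = false;
        d = p / q;
        double u = x + d;
        if (u - a < tol2 || b - u < tol2) d = (x < m) ? tol1 : -tol1;
      }
    }
    if (use_gold) {
      e = (x < m) ? b - x : a - x;
      d = gold * e;
    }
    double u = (std::fabs(d) >= tol1) ? x + d : x + ((d > 0) ? tol1 : -tol1);
    double fu = f(u);
    if (fu <= fx) {
      if (u < x) b = x; else a = x;
      v = w; fv = fw; w = x; fw = fx; x = u; fx = fu;
    } else {
      if (u < x) a = u; else b = u;
      if (fu <= fw || w == x) { v = w; fv = fw; w = u; fw = fu; }
      else if (fu <= fv || v == x || v == w) { v = u; fv = fu; }
    }
  }
  return x;
}

// Estimate one polychoric correlation from a dense contingency table.
// tab is K x L (row-major), already continuity-corrected if requested.
static double poly_pair(const std::vector<double> &tab, size_t K, size_t L,
                        double rho_max, bool *converged) {
  double n = 0.0;
  std::vector<double> rowm(K, 0.0), colm(L, 0.0);
  for (size_t i = 0; i < K; i++)
    for (size_t j = 0; j < L; j++) {
      rowm[i] += tab[i * L + j];
      colm[j] += tab[i * L + j];
      n += tab[i * L + j];
    }
  // interior thresholds from the cumulative margins
  std::vector<double> ta(K - 1), tb(L - 1);
  double cum = 0.0;
  for (size_t i = 0; i + 1 < K; i++) {
    cum += rowm[i];
    ta[i] = R::qnorm(cum / n, 0.0, 1.0, 1, 0);
  }
  cum = 0.0;
  for (size_t j = 0; j + 1 < L; j++) {
    cum += colm[j];
    tb[j] = R::qnorm(cum / n, 0.0, 1.0, 1, 0);
  }
  std::function<double(double)> nll = [&](double r) {
    return table_nll(tab, ta, tb, r);
  };
  return brent_min(-rho_max, rho_max, nll, 1e-7, 500, converged);
}

// Build the contingency table for a pair of code vectors (codes 0-based,
// NA_INTEGER = missing), dropping categories unobserved within the pair.
static bool pair_table(const IntegerVector &x, const IntegerVector &y,
                       bool correction, std::vector<double> &tab, size_t *K,
                       size_t *L) {
  int mx = -1, my = -1;
  R_xlen_t n = x.size();
  for (R_xlen_t i = 0; i < n; i++) {
    if (x[i] == NA_INTEGER || y[i] == NA_INTEGER) continue;
    if (x[i] > mx) mx = x[i];
    if (y[i] > my) my = y[i];
  }
  if (mx < 0) return false;
  size_t K0 = (size_t)mx + 1, L0 = (size_t)my + 1;
  std::vector<double> full(K0 * L0, 0.0);
  for (R_xlen_t i = 0; i < n; i++) {
    if (x[i] == NA_INTEGER || y[i] == NA_INTEGER) continue;
    full[(size_t)x[i] * L0 + (size_t)y[i]] += 1.0;
  }
  std::vector<double> rowm(K0, 0.0), colm(L0, 0.0);
  for (size_t i = 0; i < K0; i++)
    for (size_t j = 0; j < L0; j++) {
      rowm[i] += full[i * L0 + j];
      colm[j] += full[i * L0 + j];
    }
  std::vector<size_t> ri, cj;
  for (size_t i = 0; i < K0; i++) if (rowm[i] > 0) ri.push_back(i);
  for (size_t j = 0; j < L0; j++) if (colm[j] > 0) cj.push_back(j);
  *K = ri.size();
  *L = cj.size();
  if (*K < 2 || *L < 2) return false;
  tab.assign((*K) * (*L), 0.0);
  bool zero = false;
  for (size_t i = 0; i < *K; i++)
    for (size_t j = 0; j < *L; j++) {
      double v = full[ri[i] * L0 + cj[j]];
      if (v == 0.0) zero = true;
      tab[i * (*L) + j] = v;
    }
  if (correction && zero)
    for (size_t c = 0; c < tab.size(); c++) tab[c] += 0.5;
  return true;
}

// [[Rcpp::export(name = ".cppPolychoricPair")]]
List cpp_polychoric_pair(IntegerVector x, IntegerVector y, bool correction,
                         double rho_max) {
  std::vector<double> tab;
  size_t K = 0, L = 0;
  if (!pair_table(x, y, correction, tab, &K, &L))
    return List::create(_["rho"] = NA_REAL, _["converged"] = false,
                        _["degenerate"] = true);
  bool conv = false;
  double rho = poly_pair(tab, K, L, rho_max, &conv);
  return List::create(_["rho"] = rho, _["converged"] = conv,
                      _["degenerate"] = false);
}

// [[Rcpp::export(name = ".cppPolychoricMatrix")]]
List cpp_polychoric_matrix(IntegerMatrix codes, bool correction,
                           double rho_max) {
  int p = codes.ncol();
  NumericMatrix R(p, p);
  IntegerVector badi, badj;
  for (int j = 0; j < p; j++) R(j, j) = 1.0;
  for (int i = 0; i < p - 1; i++) {
    IntegerVector xi = codes(_, i);
    for (int j = i + 1; j < p; j++) {
      IntegerVector yj = codes(_, j);
      std::vector<double> tab;
      size_t K = 0, L = 0;
      bool conv = false;
      double rho = NA_REAL;
      if (pair_table(xi, yj, correction, tab, &K, &L))
        rho = poly_pair(tab, K, L, rho_max, &conv);
      if (!conv) {
        badi.push_back(i + 1);
        badj.push_back(j + 1);
      }
      R(i, j) = rho;
      R(j, i) = rho;
    }
  }
  return List::create(_["rho"] = R, _["fail_i"] = badi, _["fail_j"] = badj);
}
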