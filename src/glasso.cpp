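// Graphical lasso (blockwise coordinate descent, Friedman-Hastie-Tibshirani)
// with an EBIC-selected penalty path. The diagonal is not penalized; the
// path is warm-started from the empty graph at lambda_max = max |off-diag|.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline double softt(double x, double t) {
  if (x > t) return x - t;
  if (x < -t) return x + t;
  return 0.0;
}

// One glasso solve; W and B are warm-start in/out arguments.
// W approximates the covariance estimate, B holds per-column lasso betas.
static void glasso_solve(const arma::mat &S, double rho, arma::mat &W,
                         arma::mat &B, double tol, int maxit) {
  int p = S.n_rows;
  double thr = tol * arma::mean(arma::mean(arma::abs(
                    S - arma::diagmat(S.diag()))));
  if (thr <= 0) thr = tol * 1e-4;
  for (int iter = 0; iter < maxit; iter++) {
    double dmax = 0.0;
    for (int j = 0; j < p; j++) {
      // coordinate descent for column j (indices k != j)
      for (int inner = 0; inner < 200; inner++) {
        double dlt = 0.0;
        for (int k = 0; k < p; k++) {
          if (k == j) continue;
          double x = S(k, j);
          for (int l = 0; l < p; l++) {
            if (l == j || l == k) continue;
            x -= W(k, l) * B(l, j);
          }
          double bnew = softt(x, rho) / W(k, k);
          double ch = std::fabs(bnew - B(k, j));
          if (ch > dlt) dlt = ch;
          B(k, j) = bnew;
        }
        if (dlt < thr * 0.1) break;
      }
      for (int k = 0; k < p; k++) {
        if (k == j) continue;
        double w = 0.0;
        for (int l = 0; l < p; l++) {
          if (l == j) continue;
          w += W(k, l) * B(l, j);
        }
        double ch = std::fabs(w - W(k, j));
        if (ch > dmax) dmax = ch;
        W(k, j) = w;
        W(j, k) = w;
      }
    }
    if (dmax < thr) break;
  }
}

// Precision matrix from the converged (W, B) pair
static arma::mat glasso_theta(const arma::mat &W, const arma::mat &B) {
  int p = W.n_rows;
  arma::mat Theta(p, p, arma::fill::zeros);
  for (int j = 0; j < p; j++) {
    double q = W(j, j);
    for (int l = 0; l < p; l++)
      if (l != j) q -= W(l, j) * B(l, j);
    double tjj = 1.0 / q;
    Theta(j, j) = tjj;
    for (int l = 0; l < p; l++)
      if (l != j) Theta(l, j) = -B(l, j) * tjj;
  }
  return 0.5 * (Theta + Theta.t());
}

static arma::mat theta_to_pcor(const arma::mat &Theta) {
  int p = Theta.n_rows;
  arma::mat P(p, p, arma::fill::zeros);
  for (int i = 0; i < p; i++)
    for (int j = 0; j < p; j++)
      if (i != j)
        P(i, j) = -Theta(i, j) / std::sqrt(Theta(i, i) * Theta(j, j));
  return 0.5 * (P + P.t());
}

// [[Rcpp::export(name = ".cppGlassoSingle")]]
List cpp_glasso_single(arma::mat S, double rho, double tol, int maxit) {
  int p = S.n_rows;
  arma::mat W = S, B(p, p, arma::fill::zeros);
  glasso_solve(S, rho, W, B, tol, maxit);
  arma::mat Theta = glasso_theta(W, B);
  return List::create(_["theta"] = Theta, _["w"] = W,
                      _["pcor"] = theta_to_pcor(Theta));
}

// [[Rcpp::export(name = ".cppGlassoPath")]]
List cpp_glasso_path(arma::mat S, double n, double gamma, int nlambda,
                     double ratio, double tol, int maxit) {
  int p = S.n_rows;
  double lmax = 0.0;
  for (int i = 0; i < p - 1; i++)
    for (int j = i + 1; j < p; j++)
      if (std::fabs(S(i, j)) > lmax) lmax = std::fabs(S(i, j));
  if (lmax <= 0) lmax = 1e-4;
  arma::vec lambdas(nlambda);
  double llo = std::log(lmax * ratio), lhi = std::log(lmax);
  for (int t = 0; t < nlambda; t++)
    lambdas[t] = std::exp(lhi + (llo - lhi) * t / (nlambda - 1.0));
  arma::vec ebic(nlambda), loglik(nlambda);
  arma::ivec edges(nlambda);
  arma::mat W = S, B(p, p, arma::fill::zeros);
  arma::cube pcors(p, p, nlambda);
  double best = R_PosInf;
  int bi = 0;
  for (int t = 0; t < nlambda; t++) {
    glasso_solve(S, lambdas[t], W, B, tol, maxit);
    arma::mat Theta = glasso_theta(W, B);
    arma::mat P = theta_to_pcor(Theta);
    pcors.slice(t) = P;
    int E = 0;
    for (int i = 0; i < p - 1; i++)
      for (int j = i + 1; j < p; j++)
        if (std::fabs(P(i, j)) > 1e-10) E++;
    double ld, sign;
    arma::log_det(ld, sign, Theta);
    double ll = 0.5 * n * (ld - arma::trace(S * Theta));
    loglik[t] = ll;
    edges[t] = E;
    ebic[t] = -2.0 * ll + E * std::log(n) + 4.0 * E * gamma * std::log((double)p);
    if (ebic[t] < best) {
      best = ebic[t];
      bi = t;
    }
  }
  return List::create(_["lambda"] = lambdas, _["ebic"] = ebic,
                      _["loglik"] = loglik, _["edges"] = edges,
                      _["selected"] = bi + 1,
                      _["pcor"] = pcors.slice(bi));
}
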