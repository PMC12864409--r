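// Graphical lasso by block coordinate descent (Friedman-style): each sweep
// solves one lasso subproblem per column of the working covariance W.
// The L1 penalty applies to off-diagonal precision entries only, so the
// diagonal of W stays fixed at diag(S).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static void glasso_solve(const mat& S, double lambda, int maxit, double thr,
                         mat& W, mat& B, int& iters, bool& converged) {
  const int p = S.n_rows;
  converged = false;
  iters = 0;
  for (int it = 0; it < maxit; ++it) {
    double maxdiff = 0.0;
    for (int j = 0; j < p; ++j) {
      // inner coordinate descent on beta = B(,j), the lasso fit of column j
      for (int inner = 0; inner < 200; ++inner) {
        double innermax = 0.0;
        for (int k = 0; k < p; ++k) {
          if (k == j) continue;
          double x = S(k, j);
          for (int l = 0; l < p; ++l) {
            if (l == j || l == k) continue;
            x -= W(k, l) * B(l, j);
          }
          double bnew = 0.0;
          const double ax = std::abs(x);
          if (ax > lambda) bnew = std::copysign(ax - lambda, x) / W(k, k);
          const double d = std::abs(bnew - B(k, j));
          if (d > innermax) innermax = d;
          B(k, j) = bnew;
        }
        if (innermax < 0.1 * thr) break;
      }
      // w12 = W11 * beta
      for (int k = 0; k < p; ++k) {
        if (k == j) continue;
        double w = 0.0;
        for (int l = 0; l < p; ++l) {
          if (l == j) continue;
          w += W(k, l) * B(l, j);
        }
        const double d = std::abs(w - W(k, j));
        if (d > maxdiff) maxdiff = d;
        W(k, j) = w;
        W(j, k) = w;
      }
    }
    iters = it + 1;
    if (maxdiff < thr) { converged = true; break; }
  }
}

static mat recover_theta(const mat& W, const mat& B) {
  const int p = W.n_rows;
  mat Th(p, p, fill::zeros);
  for (int j = 0; j < p; ++j) {
    double q = W(j, j);
    for (int k = 0; k < p; ++k) {
      if (k == j) continue;
      q -= W(k, j) * B(k, j);
    }
    const double tjj = 1.0 / q;
    Th(j, j) = tjj;
    for (int k = 0; k < p; ++k) {
      if (k == j) continue;
      Th(k, j) = -B(k, j) * tjj;
    }
  }
  return 0.5 * (Th + Th.t());
}

static double dual_gap(const mat& S, const mat& Th, double lambda) {
  const int p = S.n_rows;
  double l1off = accu(abs(Th)) - accu(abs(Th.diag()));
  return accu(S % Th) - (double)p + lambda * l1off;
}

// [[Rcpp::export]]
Rcpp::List glasso_fit_cpp(const arma::mat& S, double lambda,
                          int maxit = 10000, double tol = 1e-5) {
  const int p = S.n_rows;
  mat W = S;
  mat B(p, p, fill::zeros);
  double offmean = (accu(abs(S)) - accu(abs(S.diag()))) / std::max(1, p * (p - 1));
  double thr = tol * std::max(offmean, 1e-12);
  int iters = 0;
  bool conv = false;
  glasso_solve(S, lambda, maxit, thr, W, B, iters, conv);
  mat Th = recover_theta(W, B);
  return Rcpp::List::create(
    Rcpp::Named("theta") = Th,
    Rcpp::Named("w") = W,
    Rcpp::Named("iters") = iters,
    Rcpp::Named("converged") = conv,
    Rcpp::Named("dual_gap") = dual_gap(S, Th, lambda));
}

// Warm-started path over a decreasing penalty grid; returns per-penalty
// precision estimates plus the pieces of the Gaussian log-likelihood
// (log det and trace(S*Theta)) and off-diagonal support sizes.
// [[Rcpp::export]]
Rcpp::List glasso_path_cpp(const arma::mat& S, const arma::vec& lambdas,
                           int maxit = 10000, double tol = 1e-5) {
  const int p = S.n_rows;
  const int m = lambdas.n_elem;
  cube thetas(p, p, m);
  mat W = S;
  mat B(p, p, fill::zeros);
  double offmean = (accu(abs(S)) - accu(abs(S.diag()))) / std::max(1, p * (p - 1));
  double thr = tol * std::max(offmean, 1e-12);
  ivec edges(m), iters(m);
  vec logdets(m), traces(m);
  Rcpp::LogicalVector conv(m);
  for (int t = 0; t < m; ++t) {
    int it = 0;
    bool cv = false;
    glasso_solve(S, lambdas[t], maxit, thr, W, B, it, cv);
    mat Th = recover_theta(W, B);
    thetas.slice(t) = Th;
    iters[t] = it;
    conv[t] = cv;
    double ld, sign;
    log_det(ld, sign, Th);
    logdets[t] = (sign > 0) ? ld : datum::nan;
    traces[t] = accu(S % Th);
    int e = 0;
    for (int a = 0; a < p; ++a)
      for (int b = a + 1; b < p; ++b)
        if (std::abs(Th(a, b)) > 1e-10) ++e;
    edges[t] = e;
  }
  return Rcpp::List::create(
    Rcpp::Named("thetas") = thetas,
    Rcpp::Named("edges") = edges,
    Rcpp::Named("logdet") = logdets,
    Rcpp::Named("trace_s_theta") = traces,
    Rcpp::Named("iters") = iters,
    Rcpp::Named("converged") = conv);
}
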