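// Uncertainty-weighted positive matrix factorization by exact alternating
// nonnegative least squares. Each block update (all rows of G given F, all
// columns of F given G) solves its weighted NNLS subproblem to optimality
// with a Lawson-Hanson active-set solver on the normal equations, so the
// objective Q = sum((X - G F)^2 / U^2) is non-increasing across iterations
// and reaches machine precision on exact-rank noiseless data.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

namespace {

// Lawson-Hanson NNLS on normal equations: min ||A x - b||^2, x >= 0,
// given AtA = A'A (p x p) and Atb = A'b. p is small (number of factors).
vec nnls_normal(const mat& AtA, const vec& Atb) {
  const uword p = Atb.n_elem;
  vec x(p, fill::zeros);
  std::vector<bool> passive(p, false);
  const double tol = 1e-12 * std::max(1.0, arma::abs(Atb).max());

  for (uword outer = 0; outer < 30 * p + 30; ++outer) {
    vec w = Atb - AtA * x; // negative gradient / 2
    int j_best = -1;
    double w_best = tol;
    for (uword j = 0; j < p; ++j) {
      if (!passive[j] && w(j) > w_best) {
        w_best = w(j);
        j_best = (int)j;
      }
    }
    if (j_best < 0) break;
    passive[j_best] = true;

    for (uword inner = 0; inner < 30 * p + 30; ++inner) {
      uvec P(p);
      uword np = 0;
      for (uword j = 0; j < p; ++j)
        if (passive[j]) P(np++) = j;
      P.resize(np);

      vec z;
      const mat App = AtA.submat(P, P);
      const vec bp = Atb.elem(P);
      if (!solve(z, App, bp, solve_opts::likely_sympd + solve_opts::no_approx))
        z = pinv(App) * bp;

      if (z.min() > 0) {
        x.zeros();
        x.elem(P) = z;
        break;
      }
      // step toward z, dropping the first variable that hits zero
      double alpha = 1.0;
      for (uword k = 0; k < np; ++k) {
        const double xk = x(P(k));
        if (z(k) <= 0) {
          const double a = xk / (xk - z(k));
          if (a < alpha) alpha = a;
        }
      }
      for (uword k = 0; k < np; ++k) {
        const double nv = x(P(k)) + alpha * (z(k) - x(P(k)));
        x(P(k)) = (z(k) <= 0 && nv < 1e-14) ? 0.0 : std::max(nv, 0.0);
      }
      for (uword k = 0; k < np; ++k)
        if (x(P(k)) <= 0) passive[P(k)] = false;
    }
  }
  return x;
}

double q_value(const mat& X, const mat& W, const mat& G, const mat& F) {
  const mat E = X - G * F;
  return accu(square(E) % W);
}

} // namespace

// [[Rcpp::export]]
Rcpp::List cpp_pmf_fit(const arma::mat& X, const arma::mat& W, arma::mat G,
                       arma::mat F, int max_iter, double tol) {
  const uword n = X.n_rows, m = X.n_cols, p = G.n_cols;
  std::vector<double> q_hist;
  double q_prev = q_value(X, W, G, F);
  q_hist.push_back(q_prev);
  bool converged = false;

  for (int it = 0; it < max_iter; ++it) {
    // update rows of G given F
    for (uword i = 0; i < n; ++i) {
      const rowvec wi = W.row(i);
      const mat Fw = F.each_row() % wi;       // p x m
      const mat AtA = Fw * F.t();             // p x p
      const vec Atb = Fw * X.row(i).t();      // p
      G.row(i) = nnls_normal(AtA, Atb).t();
    }
    // update columns of F given G
    for (uword j = 0; j < m; ++j) {
      const vec wj = W.col(j);
      const mat Gw = G.each_col() % wj;       // n x p
      const mat AtA = Gw.t() * G;             // p x p
      const vec Atb = Gw.t() * X.col(j);      // p
      F.col(j) = nnls_normal(0.5 * (AtA + AtA.t()), Atb);
    }
    const double q = q_value(X, W, G, F);
    q_hist.push_back(q);
    if (q_prev - q <= tol * std::max(q_prev, 1e-300) || q <= 1e-14) {
      converged = true;
      q_prev = q;
      break;
    }
    q_prev = q;
  }

  return Rcpp::List::create(
      Rcpp::_["G"] = G, Rcpp::_["F"] = F, Rcpp::_["Q"] = q_prev,
      Rcpp::_["q_history"] = q_hist, Rcpp::_["converged"] = converged,
      Rcpp::_["iterations"] = (int)q_hist.size() - 1);
}
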