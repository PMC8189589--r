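// Fast kernel for the cross-validated canonical-mode statistic.
// Mirrors the R reference path exactly: per split, train-only column
// standardization (zero-variance columns keep sd 1), PCA via the Gram
// matrix of the standardized training rows, first canonical pair on the
// top-K scores, correlation of the projected test rows.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using arma::mat;
using arma::vec;
using arma::uvec;

// train/test PCA scores with Kmax components
static void pc_scores(const mat& X, const uvec& train, const uvec& test,
                      int Kmax, mat& tr_scores, mat& te_scores) {
  mat Xtr = X.rows(train);
  mat Xte = X.rows(test);
  arma::rowvec mu = arma::mean(Xtr, 0);
  arma::rowvec sd = arma::stddev(Xtr, 0, 0);  // n-1 denominator
  sd.elem(arma::find(sd <= 0)).ones();
  Xtr.each_row() -= mu;
  Xtr.each_row() /= sd;
  Xte.each_row() -= mu;
  Xte.each_row() /= sd;

  vec eval;
  mat evec;
  arma::eig_sym(eval, evec, Xtr * Xtr.t());  // ascending order
  const int n = Xtr.n_rows;
  mat U(n, Kmax);
  arma::rowvec d(Kmax);
  for (int k = 0; k < Kmax; ++k) {
    U.col(k) = evec.col(n - 1 - k);
    d(k) = std::sqrt(std::max(eval(n - 1 - k), 1e-12));
  }
  tr_scores = U;
  tr_scores.each_row() %= d;
  te_scores = Xte * (Xtr.t() * U);
  te_scores.each_row() /= d;
}

// out-of-sample correlation of the first canonical variate pair
static double cca_oos_r(const mat& Atr, const mat& Btr,
                        const mat& Ate, const mat& Bte) {
  mat A = Atr;
  A.each_row() -= arma::mean(Atr, 0);
  mat B = Btr;
  B.each_row() -= arma::mean(Btr, 0);
  mat Sa = A.t() * A, Sb = B.t() * B, Sab = A.t() * B;
  mat Ra, Rb;
  if (!arma::chol(Ra, Sa) || !arma::chol(Rb, Sb))
    Rcpp::stop("rank-deficient score matrix in CCA");
  mat M = arma::solve(arma::trimatl(Ra.t()), Sab);
  M = arma::solve(arma::trimatl(Rb.t()), M.t()).t();
  mat Us, Vs;
  vec s;
  arma::svd(Us, s, Vs, M);
  vec u = arma::solve(arma::trimatu(Ra), Us.col(0));
  vec v = arma::solve(arma::trimatu(Rb), Vs.col(0));
  if (arma::dot(A * u, B * v) < 0) v = -v;
  vec x = Ate * u, y = Bte * v;
  x -= arma::mean(x);
  y -= arma::mean(y);
  const double sx = arma::norm(x), sy = arma::norm(y);
  if (sx == 0.0 || sy == 0.0) return 0.0;
  return arma::dot(x, y) / (sx * sy);
}

// per-split, per-K out-of-sample first-canonical correlations;
// splits are 1-based index vectors from R
// [[Rcpp::export(name = ".mode_oos_matrix_cpp")]]
arma::mat mode_oos_matrix(const arma::mat& P, const arma::mat& C,
                          const Rcpp::List& train_list,
                          const Rcpp::List& test_list,
                          const arma::ivec& K_set) {
  const int n_splits = train_list.size();
  const int nK = K_set.n_elem;
  const int Kmax = K_set.max();
  mat out(n_splits, nK);
  for (int i = 0; i < n_splits; ++i) {
    uvec train = Rcpp::as<uvec>(train_list[i]) - 1;
    uvec test = Rcpp::as<uvec>(test_list[i]) - 1;
    mat ptr, pte, ctr, cte;
    pc_scores(P, train, test, Kmax, ptr, pte);
    pc_scores(C, train, test, Kmax, ctr, cte);
    for (int k = 0; k < nK; ++k) {
      const int K = K_set(k);
      out(i, k) = cca_oos_r(ptr.head_cols(K), ctr.head_cols(K),
                            pte.head_cols(K), cte.head_cols(K));
    }
  }
  return out;
}
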