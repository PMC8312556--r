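// Direct linear solve of the driven-equilibrium fixed point for spoiled EPG
// trains: builds the real-ified affine cycle map in place and solves
// (I - A) x = b with LAPACK via Armadillo. Shares the propagation primitives
// declared in kernels.cpp.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

List epg_cycle_map_cpp(NumericVector flips, NumericVector phases,
                       NumericVector trs, double te, double T1, double T2,
                       double M0, int K);

// [[Rcpp::export]]
List epg_de_direct_cpp(NumericVector flips, NumericVector phases,
                       NumericVector trs, double te, double T1, double T2,
                       double M0, int K) {
  List cm = epg_cycle_map_cpp(flips, phases, trs, te, T1, T2, M0, K);
  arma::mat A = as<arma::mat>(cm["A"]);
  arma::vec b = as<arma::vec>(cm["b"]);
  arma::mat I = arma::eye(A.n_rows, A.n_cols);
  arma::vec x;
  bool ok = arma::solve(x, I - A, b, arma::solve_opts::no_approx);
  if (!ok) return List::create(_["ok"] = false);
  arma::vec resid = A * x + b - x;
  return List::create(_["ok"] = true,
                      _["x"] = NumericVector(x.begin(), x.end()),
                      _["residual"] = arma::abs(resid).max());
}
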