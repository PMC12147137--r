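// Matrix-exponential propagation core for the Bloch-McConnell simulator.
// Kept deliberately small: assembly of the BM matrix lives in R
// (assemble_bm_matrix); this file only exponentiates and chains segments.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// [[Rcpp::export(name = ".expm_cpp")]]
arma::mat expm_cpp(const arma::mat& A) {
  return arma::expmat(A);
}

// [[Rcpp::export(name = ".propagate_cpp")]]
arma::vec propagate_cpp(const arma::vec& state, const arma::mat& A, double t) {
  if (t < 0.0) stop("propagation time must be non-negative");
  if (t == 0.0) return state;
  return arma::expmat(A * t) * state;
}

// Chain recovery + saturation segments over an ordered list of points and
// read out one magnetization component after each saturation block.
// Asat: n x n x P cube of per-point saturation matrices; tsat, trec: seconds;
// read_index: 0-based row of the component recorded (Mz of the free pool).
// [[Rcpp::export(name = ".trajectory_cpp")]]
arma::vec trajectory_cpp(const arma::cube& Asat, const arma::vec& tsat,
                         const arma::mat& Arec, const arma::vec& trec,
                         arma::vec state, int read_index) {
  const arma::uword P = Asat.n_slices;
  if (tsat.n_elem != P || trec.n_elem != P)
    stop("tsat/trec length must match the number of saturation points");
  arma::vec out(P);
  // recovery propagator is shared whenever consecutive delays are equal
  double trec_cached = -1.0;
  arma::mat Prec;
  for (arma::uword i = 0; i < P; ++i) {
    if (trec(i) > 0.0) {
      if (trec(i) != trec_cached) {
        Prec = arma::expmat(Arec * trec(i));
        trec_cached = trec(i);
      }
      state = Prec * state;
    }
    state = arma::expmat(Asat.slice(i) * tsat(i)) * state;
    out(i) = state(read_index);
  }
  return out;
}
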