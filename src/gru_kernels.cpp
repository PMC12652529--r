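// Batched GRU layer kernels for the BiGRU basecaller.
//
// Sequences are stored as (B*T) x dim matrices with row block t*B..t*B+B-1
// holding timestep t (0-based) for the whole minibatch. Gate blocks in the
// combined weight matrices are ordered [update z | reset r | candidate c].

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::mat;
using arma::vec;

static inline mat sigm(const mat& x) { return 1.0 / (1.0 + arma::exp(-x)); }

// [[Rcpp::export]]
List gru_layer_forward_cpp(const arma::mat& Xf, const arma::mat& W, const arma::mat& U,
                           const arma::vec& b, int B, int Tn, bool rev,
                           bool keep_cache) {
  const int u = U.n_cols / 3;
  mat A = Xf * W;
  A.each_row() += b.t();
  const mat Uzr = U.cols(0, 2 * u - 1);
  const mat Uc = U.cols(2 * u, 3 * u - 1);
  mat H(B * Tn, u, arma::fill::zeros);
  mat Z, R, C, HP, RH;
  if (keep_cache) {
    Z.set_size(B * Tn, u); R.set_size(B * Tn, u); C.set_size(B * Tn, u);
    HP.set_size(B * Tn, u); RH.set_size(B * Tn, u);
  }
  mat h(B, u, arma::fill::zeros);
  for (int k = 0; k < Tn; ++k) {
    const int t = rev ? (Tn - 1 - k) : k;
    const int r0 = t * B, r1 = t * B + B - 1;
    mat Azr = A.submat(r0, 0, r1, 2 * u - 1) + h * Uzr;
    mat z = sigm(Azr.cols(0, u - 1));
    mat r = sigm(Azr.cols(u, 2 * u - 1));
    mat rh = r % h;
    mat c = arma::tanh(A.submat(r0, 2 * u, r1, 3 * u - 1) + rh * Uc);
    mat hp = h;
    h = (1.0 - z) % hp + z % c;
    H.rows(r0, r1) = h;
    if (keep_cache) {
      Z.rows(r0, r1) = z; R.rows(r0, r1) = r; C.rows(r0, r1) = c;
      HP.rows(r0, r1) = hp; RH.rows(r0, r1) = rh;
    }
  }
  if (keep_cache)
    return List::create(_["H"] = H, _["h_final"] = h, _["Z"] = Z, _["R"] = R,
                        _["C"] = C, _["HP"] = HP, _["RH"] = RH);
  return List::create(_["H"] = H, _["h_final"] = h);
}

// [[Rcpp::export]]
List gru_layer_backward_cpp(const arma::mat& Xf, const arma::mat& W, const arma::mat& U,
                            const arma::mat& Z, const arma::mat& R, const arma::mat& C,
                            const arma::mat& HP, const arma::mat& RH,
                            Nullable<NumericMatrix> dHext_,
                            Nullable<NumericMatrix> dhFinal_,
                            int B, int Tn, bool rev) {
  const int u = U.n_cols / 3;
  const mat Uzr_t = U.cols(0, 2 * u - 1).t();
  const mat Uc_t = U.cols(2 * u, 3 * u - 1).t();
  mat dA(B * Tn, 3 * u, arma::fill::zeros);
  mat dU(u, 3 * u, arma::fill::zeros);
  mat dh(B, u, arma::fill::zeros);
  mat dHext;
  const bool has_ext = dHext_.isNotNull();
  if (has_ext) dHext = as<mat>(dHext_);
  if (dhFinal_.isNotNull()) dh = as<mat>(dhFinal_);
  for (int k = Tn - 1; k >= 0; --k) {
    const int t = rev ? (Tn - 1 - k) : k;
    const int r0 = t * B, r1 = t * B + B - 1;
    if (has_ext) dh += dHext.rows(r0, r1);
    const mat z = Z.rows(r0, r1), r = R.rows(r0, r1), c = C.rows(r0, r1);
    const mat hp = HP.rows(r0, r1), rh = RH.rows(r0, r1);
    mat dz = dh % (c - hp);
    mat dcc = dh % z;
    mat dhprev = dh % (1.0 - z);
    mat dac = dcc % (1.0 - c % c);
    mat drh = dac * Uc_t;
    mat dr = drh % hp;
    dhprev += drh % r;
    mat daz = dz % z % (1.0 - z);
    mat dar = dr % r % (1.0 - r);
    mat dzr = arma::join_rows(daz, dar);
    dhprev += dzr * Uzr_t;
    dA.submat(r0, 0, r1, 2 * u - 1) = dzr;
    dA.submat(r0, 2 * u, r1, 3 * u - 1) = dac;
    dU.cols(0, 2 * u - 1) += hp.t() * dzr;
    dU.cols(2 * u, 3 * u - 1) += rh.t() * dac;
    dh = dhprev;
  }
  mat dX = dA * W.t();
  mat dW = Xf.t() * dA;
  vec db = arma::sum(dA, 0).t();
  return List::create(_["dX"] = dX, _["dW"] = dW, _["dU"] = dU, _["db"] = db);
}
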