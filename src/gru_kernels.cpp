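// Batched GRU forward / backward-through-time kernels.
//
// Conventions: a batch of n sequences of length L with input dimension d and
// hidden dimension u. X is an n x d x L cube (slice t = inputs at step t),
// mask an n x L matrix with 1 for real tokens and 0 for padding. Weights are
// stored row-major ("output x input"): W* are u x d, U* are u x u, and the
// batch update uses x * W.t().
//
// Cell (no bias terms):
//   z_t = sigmoid(W_z x_t + U_z h_{t-1})
//   r_t = sigmoid(W_r x_t + U_r h_{t-1})
//   hc_t = tanh(W x_t + U (r_t o h_{t-1}))
//   h_t = (1 - z_t) o h_{t-1} + z_t o hc_t
// Masked (padded) steps pass the state through unchanged:
//   h_t = h_{t-1} + m_t o z_t o (hc_t - h_{t-1})  with m_t in {0,1}.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

// [[Rcpp::export]]
Rcpp::List gru_forward_cpp(const arma::cube& X, const arma::mat& mask,
                           const arma::mat& Wz, const arma::mat& Uz,
                           const arma::mat& Wr, const arma::mat& Ur,
                           const arma::mat& Wc, const arma::mat& Uc,
                           const bool keep_cache) {
  const uword n = X.n_rows, L = X.n_slices, u = Wz.n_rows;
  cube Z, R, HC, HP;
  if (keep_cache) {
    Z.set_size(n, u, L); R.set_size(n, u, L);
    HC.set_size(n, u, L); HP.set_size(n, u, L);
  }
  mat h(n, u, fill::zeros);
  const mat WzT = Wz.t(), UzT = Uz.t(), WrT = Wr.t(), UrT = Ur.t(),
            WcT = Wc.t(), UcT = Uc.t();
  for (uword t = 0; t < L; ++t) {
    const mat& x = X.slice(t);
    mat z = 1.0 / (1.0 + exp(-(x * WzT + h * UzT)));
    mat r = 1.0 / (1.0 + exp(-(x * WrT + h * UrT)));
    mat hc = tanh(x * WcT + (r % h) * UcT);
    if (keep_cache) {
      HP.slice(t) = h; Z.slice(t) = z; R.slice(t) = r; HC.slice(t) = hc;
    }
    const vec m = mask.col(t);
    h += ((z.each_col() % m)) % (hc - h);
  }
  if (keep_cache) {
    return Rcpp::List::create(
        Rcpp::Named("h") = h, Rcpp::Named("Z") = Z, Rcpp::Named("R") = R,
        Rcpp::Named("HC") = HC, Rcpp::Named("HP") = HP);
  }
  return Rcpp::List::create(Rcpp::Named("h") = h);
}

// Backward pass. dh_final is the loss gradient at the final hidden state.
// Returns gradients for the six weight matrices and, when want_dx is true,
// the gradient dX with respect to the inputs (for trainable embeddings).
// [[Rcpp::export]]
Rcpp::List gru_backward_cpp(const arma::cube& X, const arma::mat& mask,
                            const arma::mat& Wz, const arma::mat& Uz,
                            const arma::mat& Wr, const arma::mat& Ur,
                            const arma::mat& Wc, const arma::mat& Uc,
                            const arma::cube& Z, const arma::cube& R,
                            const arma::cube& HC, const arma::cube& HP,
                            const arma::mat& dh_final, const bool want_dx) {
  const uword n = X.n_rows, d = X.n_cols, L = X.n_slices, u = Wz.n_rows;
  mat dWz(u, d, fill::zeros), dUz(u, u, fill::zeros);
  mat dWr(u, d, fill::zeros), dUr(u, u, fill::zeros);
  mat dWc(u, d, fill::zeros), dUc(u, u, fill::zeros);
  cube dX;
  if (want_dx) dX.zeros(n, d, L);
  mat dh = dh_final;
  for (uword t = L; t-- > 0;) {
    const mat& x = X.slice(t);
    const mat& z = Z.slice(t);
    const mat& r = R.slice(t);
    const mat& hc = HC.slice(t);
    const mat& hp = HP.slice(t);
    const vec m = mask.col(t);
    const mat zm = z.each_col() % m;          // effective update gate
    const mat dhc = dh % zm;
    mat dz = dh % (hc - hp);
    dz.each_col() %= m;
    mat dhp = dh % (1.0 - zm);
    const mat dac = dhc % (1.0 - hc % hc);
    dWc += dac.t() * x;
    dUc += dac.t() * (r % hp);
    const mat drh = dac * Uc;
    const mat dr = drh % hp;
    dhp += drh % r;
    const mat dar = dr % r % (1.0 - r);
    dWr += dar.t() * x;
    dUr += dar.t() * hp;
    dhp += dar * Ur;
    const mat daz = dz % z % (1.0 - z);
    dWz += daz.t() * x;
    dUz += daz.t() * hp;
    dhp += daz * Uz;
    if (want_dx) dX.slice(t) = daz * Wz + dar * Wr + dac * Wc;
    dh = dhp;
  }
  Rcpp::List out = Rcpp::List::create(
      Rcpp::Named("dWz") = dWz, Rcpp::Named("dUz") = dUz,
      Rcpp::Named("dWr") = dWr, Rcpp::Named("dUr") = dUr,
      Rcpp::Named("dWc") = dWc, Rcpp::Named("dUc") = dUc);
  if (want_dx) out["dX"] = dX;
  return out;
}
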