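// Batched LSTM forward/backward used by the encoders. Activations arrive as
// a (B*T) x F matrix in t-major row layout (rows t*B .. t*B+B-1 hold the
// whole batch at sequence position t), which keeps the per-step slices
// contiguous. The backward pass is standard BPTT over the cached gates.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static inline mat sigm(const mat& x) { return 1.0 / (1.0 + exp(-x)); }

// [[Rcpp::export]]
Rcpp::List lstm_forward_cpp(const arma::mat& A, const arma::mat& Wx,
                            const arma::mat& Wh, const arma::vec& b,
                            int B, int T) {
  const int H = Wh.n_rows;
  mat XW = A * Wx;
  mat h(B, H, fill::zeros), c(B, H, fill::zeros);
  mat I(B * T, H), Fg(B * T, H), G(B * T, H), O(B * T, H);
  mat C(B * T, H), TC(B * T, H), Hprev(B * T, H), Cprev(B * T, H);
  rowvec br = b.t();
  for (int t = 0; t < T; ++t) {
    const span rows(t * B, t * B + B - 1);
    mat g = XW.rows(rows) + h * Wh;
    g.each_row() += br;
    mat i_ = sigm(g.cols(0, H - 1));
    mat f_ = sigm(g.cols(H, 2 * H - 1));
    mat g_ = tanh(g.cols(2 * H, 3 * H - 1));
    mat o_ = sigm(g.cols(3 * H, 4 * H - 1));
    Hprev.rows(rows) = h;
    Cprev.rows(rows) = c;
    c = f_ % c + i_ % g_;
    mat tc = tanh(c);
    h = o_ % tc;
    I.rows(rows) = i_; Fg.rows(rows) = f_; G.rows(rows) = g_;
    O.rows(rows) = o_; C.rows(rows) = c; TC.rows(rows) = tc;
  }
  return Rcpp::List::create(
      Rcpp::Named("h") = h, Rcpp::Named("I") = I, Rcpp::Named("F") = Fg,
      Rcpp::Named("G") = G, Rcpp::Named("O") = O, Rcpp::Named("C") = C,
      Rcpp::Named("TC") = TC, Rcpp::Named("Hprev") = Hprev,
      Rcpp::Named("Cprev") = Cprev);
}

// [[Rcpp::export]]
Rcpp::List lstm_backward_cpp(const arma::mat& dh_final, const arma::mat& A,
                             const arma::mat& Wx, const arma::mat& Wh,
                             const arma::mat& I, const arma::mat& Fg,
                             const arma::mat& G, const arma::mat& O,
                             const arma::mat& TC, const arma::mat& Hprev,
                             const arma::mat& Cprev, int B, int T) {
  const int H = Wh.n_rows;
  mat gWx(Wx.n_rows, 4 * H, fill::zeros), gWh(H, 4 * H, fill::zeros);
  rowvec gb(4 * H, fill::zeros);
  mat dA(A.n_rows, A.n_cols, fill::none);
  mat dh = dh_final;
  mat dc(B, H, fill::zeros);
  mat Gt(B, 4 * H, fill::none);
  for (int t = T - 1; t >= 0; --t) {
    const span rows(t * B, t * B + B - 1);
    const mat tc = TC.rows(rows), o_ = O.rows(rows), i_ = I.rows(rows);
    const mat f_ = Fg.rows(rows), g_ = G.rows(rows);
    mat do_ = dh % tc;
    dc += dh % o_ % (1.0 - tc % tc);
    mat di = dc % g_;
    mat df = dc % Cprev.rows(rows);
    mat dg = dc % i_;
    dc %= f_;
    Gt.cols(0, H - 1) = di % i_ % (1.0 - i_);
    Gt.cols(H, 2 * H - 1) = df % f_ % (1.0 - f_);
    Gt.cols(2 * H, 3 * H - 1) = dg % (1.0 - g_ % g_);
    Gt.cols(3 * H, 4 * H - 1) = do_ % o_ % (1.0 - o_);
    gWx += A.rows(rows).t() * Gt;
    gWh += Hprev.rows(rows).t() * Gt;
    gb += sum(Gt, 0);
    dA.rows(rows) = Gt * Wx.t();
    dh = Gt * Wh.t();
  }
  return Rcpp::List::create(
      Rcpp::Named("dA") = dA, Rcpp::Named("Wx") = gWx,
      Rcpp::Named("Wh") = gWh, Rcpp::Named("b") = gb);
}
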