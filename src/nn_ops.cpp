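// Low-level neural-network kernels: 3x3 same-padding convolution (im2col +
// GEMM) and a gated-recurrent-unit sequence pass with variational dropout on
// the recurrent connections. Layout conventions:
//   - image batches: cube H x W x (B*C), channel c of image b at slice b*C+c
//   - conv weights: mat C_out x (9*C_in), row-block order c_in*9 + k, with
//     kernel offset k = (dy+1)*3 + (dx+1)
//   - GRU gate stacking: [update z; reset r; candidate c], so Wx is 3H x d
// Gradients are exact; they are validated against central differences in the
// test suite.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static void im2col3(const cube& X, unsigned b, unsigned Cin, mat& col) {
  const unsigned H = X.n_rows, W = X.n_cols;
  col.zeros(9 * Cin, H * W);
  for (unsigned c = 0; c < Cin; ++c) {
    const mat& img = X.slice(b * Cin + c);
    for (int dy = -1; dy <= 1; ++dy) {
      for (int dx = -1; dx <= 1; ++dx) {
        const unsigned k = (dy + 1) * 3 + (dx + 1);
        const unsigned row = c * 9 + k;
        for (unsigned j = 0; j < W; ++j) {
          const int js = (int)j + dx;
          if (js < 0 || js >= (int)W) continue;
          const unsigned i0 = (dy < 0) ? 1 : 0;
          const unsigned i1 = (dy > 0) ? H - 1 : H;
          for (unsigned i = i0; i < i1; ++i)
            col(row, i + j * H) = img(i + dy, js);
        }
      }
    }
  }
}

static void col2im3(const mat& dcol, unsigned Cin, unsigned H, unsigned W,
                    cube& dX, unsigned b) {
  for (unsigned c = 0; c < Cin; ++c) {
    mat& img = dX.slice(b * Cin + c);
    for (int dy = -1; dy <= 1; ++dy) {
      for (int dx = -1; dx <= 1; ++dx) {
        const unsigned k = (dy + 1) * 3 + (dx + 1);
        const unsigned row = c * 9 + k;
        for (unsigned j = 0; j < W; ++j) {
          const int js = (int)j + dx;
          if (js < 0 || js >= (int)W) continue;
          const unsigned i0 = (dy < 0) ? 1 : 0;
          const unsigned i1 = (dy > 0) ? H - 1 : H;
          for (unsigned i = i0; i < i1; ++i)
            img(i + dy, js) += dcol(row, i + j * H);
        }
      }
    }
  }
}

// [[Rcpp::export]]
arma::cube cpp_conv3_forward(const arma::cube& X, int B, int Cin,
                             const arma::mat& Wt, const arma::vec& bias) {
  const unsigned H = X.n_rows, W = X.n_cols, Cout = Wt.n_rows;
  cube Y(H, W, B * Cout);
  mat col;
  for (int b = 0; b < B; ++b) {
    im2col3(X, b, Cin, col);
    mat out = Wt * col;            // Cout x (H*W)
    out.each_col() += bias;
    for (unsigned c = 0; c < Cout; ++c)
      Y.slice(b * Cout + c) = reshape(out.row(c).t(), H, W);
  }
  return Y;
}

// [[Rcpp::export]]
Rcpp::List cpp_conv3_backward(const arma::cube& X, int B, int Cin,
                              const arma::mat& Wt, const arma::cube& dY) {
  const unsigned H = X.n_rows, W = X.n_cols, Cout = Wt.n_rows;
  cube dX(H, W, X.n_slices, fill::zeros);
  mat dW(size(Wt), fill::zeros);
  vec db(Cout, fill::zeros);
  mat col, dYm(Cout, H * W);
  for (int b = 0; b < B; ++b) {
    im2col3(X, b, Cin, col);
    for (unsigned c = 0; c < Cout; ++c)
      dYm.row(c) = vectorise(dY.slice(b * Cout + c)).t();
    dW += dYm * col.t();
    db += sum(dYm, 1);
    mat dcol = Wt.t() * dYm;
    col2im3(dcol, Cin, H, W, dX, b);
  }
  return Rcpp::List::create(Rcpp::Named("dX") = dX,
                            Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db);
}

// [[Rcpp::export]]
arma::cube cpp_avgpool2_forward(const arma::cube& X) {
  const unsigned H = X.n_rows / 2, W = X.n_cols / 2;
  cube Y(H, W, X.n_slices);
  for (unsigned s = 0; s < X.n_slices; ++s)
    for (unsigned j = 0; j < W; ++j)
      for (unsigned i = 0; i < H; ++i)
        Y(i, j, s) = 0.25 * (X(2 * i, 2 * j, s) + X(2 * i + 1, 2 * j, s) +
                             X(2 * i, 2 * j + 1, s) + X(2 * i + 1, 2 * j + 1, s));
  return Y;
}

// [[Rcpp::export]]
arma::cube cpp_avgpool2_backward(const arma::cube& dY, int H, int W) {
  cube dX(H, W, dY.n_slices);
  for (unsigned s = 0; s < dY.n_slices; ++s)
    for (unsigned j = 0; j < dY.n_cols; ++j)
      for (unsigned i = 0; i < dY.n_rows; ++i) {
        const double g = 0.25 * dY(i, j, s);
        dX(2 * i, 2 * j, s) = g;
        dX(2 * i + 1, 2 * j, s) = g;
        dX(2 * i, 2 * j + 1, s) = g;
        dX(2 * i + 1, 2 * j + 1, s) = g;
      }
  return dX;
}

// 2x2 max pooling; `idx` records the argmax corner (0..3) for the backward
// scatter. Ties take the first corner scanned (row-major within the window).
// [[Rcpp::export]]
Rcpp::List cpp_maxpool2_forward(const arma::cube& X) {
  const unsigned H = X.n_rows / 2, W = X.n_cols / 2;
  cube Y(H, W, X.n_slices);
  cube idx(H, W, X.n_slices);
  for (unsigned s = 0; s < X.n_slices; ++s)
    for (unsigned j = 0; j < W; ++j)
      for (unsigned i = 0; i < H; ++i) {
        double best = X(2 * i, 2 * j, s);
        unsigned bi = 0;
        const double cand[3] = {X(2 * i + 1, 2 * j, s),
                                X(2 * i, 2 * j + 1, s),
                                X(2 * i + 1, 2 * j + 1, s)};
        for (unsigned k = 0; k < 3; ++k)
          if (cand[k] > best) { best = cand[k]; bi = k + 1; }
        Y(i, j, s) = best;
        idx(i, j, s) = bi;
      }
  return Rcpp::List::create(Rcpp::Named("Y") = Y, Rcpp::Named("idx") = idx);
}

// [[Rcpp::export]]
arma::cube cpp_maxpool2_backward(const arma::cube& dY, const arma::cube& idx,
                                 int H, int W) {
  cube dX(H, W, dY.n_slices, fill::zeros);
  for (unsigned s = 0; s < dY.n_slices; ++s)
    for (unsigned j = 0; j < dY.n_cols; ++j)
      for (unsigned i = 0; i < dY.n_rows; ++i) {
        const unsigned k = (unsigned)idx(i, j, s);
        dX(2 * i + (k & 1u), 2 * j + (k >> 1u), s) = dY(i, j, s);
      }
  return dX;
}

static inline vec sigmoid(const vec& x) { return 1.0 / (1.0 + exp(-x)); }

// Variational dropout: `dropmask` multiplies h_{t-1} on its way into the
// gates (identical mask at every step); the additive carry (1-z)*h_{t-1}
// stays undropped.
// [[Rcpp::export]]
Rcpp::List cpp_gru_forward(const arma::mat& X, const arma::mat& Wx,
                           const arma::mat& Wh, const arma::vec& b,
                           const arma::vec& h0, const arma::vec& dropmask) {
  const unsigned N = X.n_cols, Hd = Wh.n_cols;
  mat PreX = Wx * X;               // 3H x N
  PreX.each_col() += b;
  mat Hs(Hd, N), Z(Hd, N), R(Hd, N), C(Hd, N), Hpd(Hd, N), RHd(Hd, N);
  vec h = h0;
  for (unsigned t = 0; t < N; ++t) {
    vec hpd = dropmask % h;
    vec z = sigmoid(PreX.submat(0, t, Hd - 1, t) + Wh.rows(0, Hd - 1) * hpd);
    vec r = sigmoid(PreX.submat(Hd, t, 2 * Hd - 1, t) + Wh.rows(Hd, 2 * Hd - 1) * hpd);
    vec rhd = r % hpd;
    vec c = tanh(PreX.submat(2 * Hd, t, 3 * Hd - 1, t) + Wh.rows(2 * Hd, 3 * Hd - 1) * rhd);
    vec hn = (1.0 - z) % h + z % c;
    Hpd.col(t) = hpd; RHd.col(t) = rhd;
    Z.col(t) = z; R.col(t) = r; C.col(t) = c; Hs.col(t) = hn;
    h = hn;
  }
  return Rcpp::List::create(
    Rcpp::Named("H") = Hs, Rcpp::Named("Z") = Z, Rcpp::Named("R") = R,
    Rcpp::Named("C") = C, Rcpp::Named("Hpd") = Hpd, Rcpp::Named("RHd") = RHd);
}

// [[Rcpp::export]]
Rcpp::List cpp_gru_backward(const arma::mat& X, const arma::mat& Wx,
                            const arma::mat& Wh, const arma::vec& h0,
                            const arma::vec& dropmask, const Rcpp::List& fwd,
                            const arma::mat& dH) {
  const mat Hs = fwd["H"], Z = fwd["Z"], R = fwd["R"], C = fwd["C"],
            Hpd = fwd["Hpd"], RHd = fwd["RHd"];
  const unsigned N = X.n_cols, Hd = Wh.n_cols;
  const mat Whz = Wh.rows(0, Hd - 1), Whr = Wh.rows(Hd, 2 * Hd - 1),
            Whc = Wh.rows(2 * Hd, 3 * Hd - 1);
  mat dPre(3 * Hd, N, fill::zeros);
  vec carry(Hd, fill::zeros);
  for (int t = N - 1; t >= 0; --t) {
    vec dh = dH.col(t) + carry;
    vec hprev = (t > 0) ? vec(Hs.col(t - 1)) : h0;
    vec z = Z.col(t), r = R.col(t), c = C.col(t), hpd = Hpd.col(t);
    vec dz = dh % (c - hprev);
    vec dc = dh % z;
    vec dhprev = dh % (1.0 - z);
    vec dc_pre = dc % (1.0 - c % c);
    vec dz_pre = dz % z % (1.0 - z);
    vec drhd = Whc.t() * dc_pre;
    vec dr = drhd % hpd;
    vec dhpd = drhd % r;
    vec dr_pre = dr % r % (1.0 - r);
    dhpd += Whz.t() * dz_pre + Whr.t() * dr_pre;
    carry = dhprev + dropmask % dhpd;
    dPre.submat(0, t, Hd - 1, t) = dz_pre;
    dPre.submat(Hd, t, 2 * Hd - 1, t) = dr_pre;
    dPre.submat(2 * Hd, t, 3 * Hd - 1, t) = dc_pre;
  }
  mat dWx = dPre * X.t();
  vec db = sum(dPre, 1);
  mat dX = Wx.t() * dPre;
  // recurrent weight gradients batch over time
  mat dWh(3 * Hd, Hd, fill::zeros);
  dWh.rows(0, Hd - 1) = dPre.rows(0, Hd - 1) * Hpd.t();
  dWh.rows(Hd, 2 * Hd - 1) = dPre.rows(Hd, 2 * Hd - 1) * Hpd.t();
  dWh.rows(2 * Hd, 3 * Hd - 1) = dPre.rows(2 * Hd, 3 * Hd - 1) * RHd.t();
  return Rcpp::List::create(
    Rcpp::Named("dX") = dX, Rcpp::Named("dWx") = dWx,
    Rcpp::Named("dWh") = dWh, Rcpp::Named("db") = db,
    Rcpp::Named("dh0") = carry);
}
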