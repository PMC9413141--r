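// Low-level numerical kernels for the network layers.
//
// Feature maps are arma::cube with dims (H, W, C), matching an R array
// dim c(H, W, C).  Convolution weights are flattened to a matrix of dim
// (kh*kw*Cin) x Cout with column index  ki + kh*(kj + kw*c)  so that the
// same layout is shared by the forward im2col product and the backward
// col2im scatter.  All convolutions are stride-1, zero same-padding.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// im2col for odd kernels with dilation; rows indexed by output pixel
// (i + j*H, column-major), columns by (ki, kj, c).
static mat im2col(const cube& x, int kh, int kw, int dh, int dw) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int ph = ((kh - 1) * dh) / 2, pw = ((kw - 1) * dw) / 2;
  mat out(H * W, kh * kw * C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const int col = ki + kh * (kj + kw * c);
        const int di = ki * dh - ph, dj = kj * dw - pw;
        for (int j = 0; j < W; ++j) {
          const int sj = j + dj;
          if (sj < 0 || sj >= W) continue;
          for (int i = 0; i < H; ++i) {
            const int si = i + di;
            if (si < 0 || si >= H) continue;
            out(i + j * H, col) = x(si, sj, c);
          }
        }
      }
    }
  }
  return out;
}

// scatter-add counterpart of im2col
static void col2im_add(cube& gx, const mat& gcol, int kh, int kw, int dh, int dw) {
  const int H = gx.n_rows, W = gx.n_cols, C = gx.n_slices;
  const int ph = ((kh - 1) * dh) / 2, pw = ((kw - 1) * dw) / 2;
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const int col = ki + kh * (kj + kw * c);
        const int di = ki * dh - ph, dj = kj * dw - pw;
        for (int j = 0; j < W; ++j) {
          const int sj = j + dj;
          if (sj < 0 || sj >= W) continue;
          for (int i = 0; i < H; ++i) {
            const int si = i + di;
            if (si < 0 || si >= H) continue;
            gx(si, sj, c) += gcol(i + j * H, col);
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
arma::cube cpp_conv2d_fwd(const arma::cube& x, const arma::mat& w,
                          const arma::vec& b, int kh, int kw,
                          int dh, int dw, bool has_bias) {
  const int H = x.n_rows, W = x.n_cols;
  const int Cout = w.n_cols;
  mat y;
  if (kh == 1 && kw == 1) {  // 1x1: plain channel mixing, no im2col
    mat xm(const_cast<double*>(x.memptr()), H * W, x.n_slices, false, true);
    y = xm * w;
  } else {
    mat xc = im2col(x, kh, kw, dh, dw);
    y = xc * w;
  }
  if (has_bias) y.each_row() += b.t();
  cube out(H, W, Cout);
  std::memcpy(out.memptr(), y.memptr(), sizeof(double) * y.n_elem);
  return out;
}

// forward that keeps the im2col matrix on the C++ heap (as an external
// pointer) so the backward pass can reuse it without an R round-trip
// [[Rcpp::export]]
Rcpp::List cpp_conv2d_fwd_cache(const arma::cube& x, const arma::mat& w,
                                const arma::vec& b, int kh, int kw,
                                int dh, int dw, bool has_bias) {
  const int H = x.n_rows, W = x.n_cols;
  const int Cout = w.n_cols;
  mat* xc = new mat(im2col(x, kh, kw, dh, dw));
  mat y = (*xc) * w;
  if (has_bias) y.each_row() += b.t();
  cube out(H, W, Cout);
  std::memcpy(out.memptr(), y.memptr(), sizeof(double) * y.n_elem);
  Rcpp::XPtr<mat> px(xc, true);
  return Rcpp::List::create(Rcpp::Named("y") = out, Rcpp::Named("xc") = px);
}

// backward given the cached im2col pointer
// [[Rcpp::export]]
Rcpp::List cpp_conv2d_bwd_cached(SEXP xc_ptr, const arma::mat& w,
                                 const arma::cube& gy, int H, int W, int C,
                                 int kh, int kw, int dh, int dw) {
  Rcpp::XPtr<mat> xc(xc_ptr);
  const int Cout = w.n_cols;
  mat gym(const_cast<double*>(gy.memptr()), H * W, Cout, false, true);
  vec gb = sum(gym, 0).t();
  mat gw = xc->t() * gym;
  mat gcol = gym * w.t();
  cube gx(H, W, C, fill::zeros);
  col2im_add(gx, gcol, kh, kw, dh, dw);
  return Rcpp::List::create(Rcpp::Named("gx") = gx,
                            Rcpp::Named("gw") = gw,
                            Rcpp::Named("gb") = gb);
}

// [[Rcpp::export]]
Rcpp::List cpp_conv2d_bwd(const arma::cube& x, const arma::mat& w,
                          const arma::cube& gy, int kh, int kw,
                          int dh, int dw) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Cout = w.n_cols;
  mat gym(const_cast<double*>(gy.memptr()), H * W, Cout, false, true);
  vec gb = sum(gym, 0).t();
  mat gw;
  cube gx(H, W, C, fill::zeros);
  if (kh == 1 && kw == 1) {
    mat xm(const_cast<double*>(x.memptr()), H * W, C, false, true);
    gw = xm.t() * gym;
    mat gxm = gym * w.t();
    std::memcpy(gx.memptr(), gxm.memptr(), sizeof(double) * gxm.n_elem);
  } else {
    mat xc = im2col(x, kh, kw, dh, dw);
    gw = xc.t() * gym;
    mat gcol = gym * w.t();
    col2im_add(gx, gcol, kh, kw, dh, dw);
  }
  return Rcpp::List::create(Rcpp::Named("gx") = gx,
                            Rcpp::Named("gw") = gw,
                            Rcpp::Named("gb") = gb);
}

// 2x2 max-pool, stride 2; H and W must be even.  Returns pooled map and
// flat argmax index into the input of each pooled cell.
// [[Rcpp::export]]
Rcpp::List cpp_maxpool2_fwd(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = H / 2, Wo = W / 2;
  cube y(Ho, Wo, C);
  arma::umat idx(Ho * Wo, C);
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < Wo; ++j) {
      for (int i = 0; i < Ho; ++i) {
        double best = -datum::inf; int bi = 0, bj = 0;
        for (int dj = 0; dj < 2; ++dj)
          for (int di = 0; di < 2; ++di) {
            double v = x(2 * i + di, 2 * j + dj, c);
            if (v > best) { best = v; bi = 2 * i + di; bj = 2 * j + dj; }
          }
        y(i, j, c) = best;
        idx(i + j * Ho, c) = bi + bj * H;
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("y") = y, Rcpp::Named("idx") = idx);
}

// [[Rcpp::export]]
arma::cube cpp_maxpool2_bwd(const arma::cube& gy, const arma::umat& idx,
                            int H, int W) {
  const int Ho = gy.n_rows, Wo = gy.n_cols, C = gy.n_slices;
  cube gx(H, W, C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    const double* g = gy.slice(c).memptr();
    double* o = gx.slice(c).memptr();
    for (int p = 0; p < Ho * Wo; ++p) o[idx(p, c)] += g[p];
  }
  return gx;
}

// --- scaled-dot-product attention with relative position bias -------------
//
// Q: M1 x C', K/V: M2 x C'; qpos/kpos: 0-based (row, col) positions of each
// flattened pixel on the padded map; table: (2r+1) x (2r+1) learned bias
// indexed by the clipped offset (q - k).  Computed in row blocks so the full
// M1 x M2 matrix is never materialised for large maps; the backward pass
// recomputes the softmax rows.

static mat block_logits(const mat& Q, const mat& K,
                        const imat& qpos, const imat& kpos,
                        const mat& table, const vec& logmult,
                        int r, double scale, int a, int b) {
  mat L = Q.rows(a, b) * K.t() * scale;
  const int M2 = K.n_rows, nr = b - a + 1, tnr = table.n_rows;
  const double* tab = table.memptr();
  for (int j = 0; j < M2; ++j) {
    const int kr = kpos(j, 0), kc = kpos(j, 1);
    const double lm = logmult(j);
    double* col = L.colptr(j);
    for (int i = 0; i < nr; ++i) {
      int dr = qpos(a + i, 0) - kr, dc = qpos(a + i, 1) - kc;
      if (dr < -r) dr = -r; else if (dr > r) dr = r;
      if (dc < -r) dc = -r; else if (dc > r) dc = r;
      col[i] += tab[(dr + r) + tnr * (dc + r)] + lm;
    }
  }
  return L;
}

static void softmax_rows(mat& L) {
  vec m = max(L, 1);
  L.each_col() -= m;
  L = exp(L);
  vec s = sum(L, 1);
  L.each_col() /= s;
}

static int pick_block(int M1, int M2) {
  int blk = std::max(1, (int)(4000000 / std::max(1, M2)));
  return std::min(blk, M1);
}

// [[Rcpp::export]]
arma::mat cpp_attn_fwd(const arma::mat& Q, const arma::mat& K,
                       const arma::mat& V, const arma::imat& qpos,
                       const arma::imat& kpos, const arma::mat& table,
                       const arma::vec& logmult, int radius) {
  const int M1 = Q.n_rows, C = Q.n_cols;
  const double scale = 1.0 / std::sqrt((double)C);
  mat out(M1, C);
  const int blk = pick_block(M1, K.n_rows);
  for (int a = 0; a < M1; a += blk) {
    int b = std::min(a + blk, M1) - 1;
    mat P = block_logits(Q, K, qpos, kpos, table, logmult, radius, scale, a, b);
    if (!P.is_finite()) Rcpp::stop("non-finite attention logits");
    softmax_rows(P);
    out.rows(a, b) = P * V;
  }
  return out;
}

// [[Rcpp::export]]
Rcpp::List cpp_attn_bwd(const arma::mat& Q, const arma::mat& K,
                        const arma::mat& V, const arma::imat& qpos,
                        const arma::imat& kpos, const arma::mat& table,
                        const arma::vec& logmult, int radius,
                        const arma::mat& gOut) {
  const int M1 = Q.n_rows, M2 = K.n_rows, C = Q.n_cols;
  const double scale = 1.0 / std::sqrt((double)C);
  const int r = radius;
  mat gQ(M1, C, fill::zeros), gK(M2, C, fill::zeros), gV(M2, C, fill::zeros);
  mat gT(table.n_rows, table.n_cols, fill::zeros);
  const int blk = pick_block(M1, M2);
  for (int a = 0; a < M1; a += blk) {
    int b = std::min(a + blk, M1) - 1;
    mat P = block_logits(Q, K, qpos, kpos, table, logmult, r, scale, a, b);
    softmax_rows(P);
    mat gO = gOut.rows(a, b);
    gV += P.t() * gO;
    mat dP = gO * V.t();
    vec rd = sum(dP % P, 1);
    mat dL = P % (dP.each_col() - rd);
    gQ.rows(a, b) = dL * K * scale;
    gK += dL.t() * Q.rows(a, b) * scale;
    const int tnr = gT.n_rows, nr = b - a + 1;
    double* gt = gT.memptr();
    for (int j = 0; j < M2; ++j) {
      const int kr = kpos(j, 0), kc = kpos(j, 1);
      const double* col = dL.colptr(j);
      for (int i = 0; i < nr; ++i) {
        int dr = qpos(a + i, 0) - kr, dc = qpos(a + i, 1) - kc;
        if (dr < -r) dr = -r; else if (dr > r) dr = r;
        if (dc < -r) dc = -r; else if (dc > r) dc = r;
        gt[(dr + r) + tnr * (dc + r)] += col[i];
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("gQ") = gQ, Rcpp::Named("gK") = gK,
                            Rcpp::Named("gV") = gV, Rcpp::Named("gTable") = gT);
}

// Full softmax probability matrix; intended for small maps in tests.
// [[Rcpp::export]]
arma::mat cpp_attn_probs(const arma::mat& Q, const arma::mat& K,
                         const arma::imat& qpos, const arma::imat& kpos,
                         const arma::mat& table, const arma::vec& logmult,
                         int radius) {
  const double scale = 1.0 / std::sqrt((double)Q.n_cols);
  mat P = block_logits(Q, K, qpos, kpos, table, logmult, radius, scale, 0, Q.n_rows - 1);
  softmax_rows(P);
  return P;
}

// Mish activation and its derivative. tanh(softplus(x)) is rewritten with
// a single exp: with u = exp(x), tanh(log(1+u)) = (u^2 + 2u)/(u^2 + 2u + 2),
// a cancellation-free form accurate for both tails.
// [[Rcpp::export]]
arma::vec cpp_mish(const arma::vec& x) {
  vec y(x.n_elem);
  for (uword i = 0; i < x.n_elem; ++i) {
    double xi = x(i);
    if (xi > 30) { y(i) = xi; continue; }
    double u = std::exp(xi);
    double a = u * u + 2.0 * u;
    y(i) = xi * a / (a + 2.0);
  }
  return y;
}

// [[Rcpp::export]]
arma::vec cpp_mish_grad(const arma::vec& x) {
  vec y(x.n_elem);
  for (uword i = 0; i < x.n_elem; ++i) {
    double xi = x(i);
    if (xi > 30) { y(i) = 1.0; continue; }
    double u = std::exp(xi);
    double a = u * u + 2.0 * u;
    double t = a / (a + 2.0);
    double sig = u / (1.0 + u);
    y(i) = t + xi * (1.0 - t * t) * sig;
  }
  return y;
}
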