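// Dense kernels for the convolutional backbone: im2col convolution
// (stride 1, zero "same" padding), 2x2 max pooling, block average pooling,
// nearest-neighbour upsampling and a fused per-pixel softmax cross-entropy.
// Feature volumes are H x W x C arma::cubes (R arrays dim c(H, W, C)).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// im2col for stride-1 same-padded convolution.
// Column index q = ((c * kw + kj) * kh + ki); row index = output pixel
// (column-major over H x W). Weight matrices are (kh*kw*Cin) x Cout.
static mat im2col_same(const cube& x, const int kh, const int kw) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int ph = kh / 2, pw = kw / 2;
  mat out(H * W, kh * kw * C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    const mat& xc = x.slice(c);
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const int q = (c * kw + kj) * kh + ki;
        const int di = ki - ph, dj = kj - pw;
        const int i0 = std::max(0, -di), i1 = std::min(H, H - di);
        const int j0 = std::max(0, -dj), j1 = std::min(W, W - dj);
        for (int j = j0; j < j1; ++j) {
          double* dst = out.colptr(q) + (size_t)j * H;
          const double* src = xc.colptr(j + dj) + di;
          std::copy(src + i0, src + (i1 - i0) + i0, dst + i0);
        }
      }
    }
  }
  return out;
}

// Scatter-add of a column matrix back to an input-shaped cube (adjoint of
// im2col_same).
static cube col2im_same(const mat& cols, const int H, const int W,
                        const int C, const int kh, const int kw) {
  const int ph = kh / 2, pw = kw / 2;
  cube gx(H, W, C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    mat& gc = gx.slice(c);
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const int q = (c * kw + kj) * kh + ki;
        const int di = ki - ph, dj = kj - pw;
        const int i0 = std::max(0, -di), i1 = std::min(H, H - di);
        const int j0 = std::max(0, -dj), j1 = std::min(W, W - dj);
        for (int j = j0; j < j1; ++j) {
          double* dst = gc.colptr(j + dj) + di;
          const double* src = cols.colptr(q) + (size_t)j * H;
          for (int i = i0; i < i1; ++i) dst[i] += src[i];
        }
      }
    }
  }
  return gx;
}

// [[Rcpp::export]]
arma::cube cpp_conv2d_fw(const arma::cube& x, const arma::mat& w,
                         const arma::vec& b, const int kh, const int kw) {
  const int H = x.n_rows, W = x.n_cols;
  mat cols = im2col_same(x, kh, kw);
  mat y = cols * w;
  y.each_row() += b.t();
  cube out(y.memptr(), H, W, w.n_cols);
  return out;
}

// [[Rcpp::export]]
Rcpp::List cpp_conv2d_bw(const arma::cube& x, const arma::mat& w,
                         const arma::cube& gy, const int kh, const int kw) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Cout = gy.n_slices;
  mat gym(const_cast<double*>(gy.memptr()), (size_t)H * W, Cout, false, true);
  mat cols = im2col_same(x, kh, kw);
  mat gw = cols.t() * gym;
  vec gb = sum(gym, 0).t();
  mat gcols = gym * w.t();
  cube gx = col2im_same(gcols, H, W, C, kh, kw);
  return Rcpp::List::create(Rcpp::Named("gx") = gx,
                            Rcpp::Named("gw") = gw,
                            Rcpp::Named("gb") = gb);
}

// [[Rcpp::export]]
Rcpp::List cpp_maxpool2_fw(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = H / 2, Wo = W / 2;
  cube y(Ho, Wo, C);
  umat idx(Ho * Wo, C); // linear index within each H x W slice
  for (int c = 0; c < C; ++c) {
    const mat& xc = x.slice(c);
    for (int j = 0; j < Wo; ++j) {
      for (int i = 0; i < Ho; ++i) {
        const int i2 = 2 * i, j2 = 2 * j;
        double best = xc(i2, j2);
        int bi = i2, bj = j2;
        if (xc(i2 + 1, j2) > best) { best = xc(i2 + 1, j2); bi = i2 + 1; }
        if (xc(i2, j2 + 1) > best) { best = xc(i2, j2 + 1); bi = i2; bj = j2 + 1; }
        if (xc(i2 + 1, j2 + 1) > best) { best = xc(i2 + 1, j2 + 1); bi = i2 + 1; bj = j2 + 1; }
        y(i, j, c) = best;
        idx((size_t)j * Ho + i, c) = (size_t)bj * H + bi;
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("y") = y, Rcpp::Named("idx") = idx);
}

// [[Rcpp::export]]
arma::cube cpp_maxpool2_bw(const arma::umat& idx, const arma::cube& gy,
                           const int H, const int W) {
  const int C = gy.n_slices;
  cube gx(H, W, C, fill::zeros);
  const size_t n = idx.n_rows;
  for (int c = 0; c < C; ++c) {
    double* g = gx.slice_memptr(c);
    const double* gyp = gy.slice_memptr(c);
    const uword* ip = idx.colptr(c);
    for (size_t k = 0; k < n; ++k) g[ip[k]] += gyp[k];
  }
  return gx;
}

// [[Rcpp::export]]
arma::cube cpp_block_mean(const arma::cube& x, const int k) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = H / k, Wo = W / k;
  cube y(Ho, Wo, C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    const mat& xc = x.slice(c);
    mat& yc = y.slice(c);
    for (int j = 0; j < W; ++j) {
      const int jo = j / k;
      for (int i = 0; i < H; ++i) yc(i / k, jo) += xc(i, j);
    }
  }
  y /= (double)(k * k);
  return y;
}

// [[Rcpp::export]]
arma::cube cpp_replicate(const arma::cube& x, const int k) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  cube y(H * k, W * k, C);
  for (int c = 0; c < C; ++c) {
    const mat& xc = x.slice(c);
    mat& yc = y.slice(c);
    for (int j = 0; j < W * k; ++j) {
      const int js = j / k;
      for (int i = 0; i < H * k; ++i) yc(i, j) = xc(i / k, js);
    }
  }
  return y;
}

// Fused per-pixel softmax + cross-entropy against an integer class map
// (0-based; -1 marks pixels excluded from the loss). Returns the mean
// negative log-likelihood over included pixels and its gradient w.r.t. the
// logits.
// [[Rcpp::export]]
Rcpp::List cpp_softmax_ce_spatial(const arma::cube& logits,
                                  const arma::imat& target,
                                  const double eps) {
  const int H = logits.n_rows, W = logits.n_cols, M = logits.n_slices;
  cube g(H, W, M, fill::zeros);
  double loss = 0.0;
  long n = 0;
  std::vector<double> z(M);
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      const int t = target(i, j);
      if (t < 0) continue;
      double mx = -datum::inf;
      for (int m = 0; m < M; ++m) { z[m] = logits(i, j, m); if (z[m] > mx) mx = z[m]; }
      double se = 0.0;
      for (int m = 0; m < M; ++m) { z[m] = std::exp(z[m] - mx); se += z[m]; }
      double pt = z[t] / se;
      loss += -std::log(pt < eps ? eps : pt);
      for (int m = 0; m < M; ++m) g(i, j, m) = z[m] / se;
      g(i, j, t) -= 1.0;
      ++n;
    }
  }
  if (n > 0) { loss /= n; g /= (double)n; }
  return Rcpp::List::create(Rcpp::Named("loss") = loss, Rcpp::Named("grad") = g);
}

// Per-pixel softmax over channels (probabilities only; no gradient).
// [[Rcpp::export]]
arma::cube cpp_softmax_spatial(const arma::cube& logits) {
  const int H = logits.n_rows, W = logits.n_cols, M = logits.n_slices;
  cube p(H, W, M);
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      double mx = -datum::inf;
      for (int m = 0; m < M; ++m) mx = std::max(mx, logits(i, j, m));
      double se = 0.0;
      for (int m = 0; m < M; ++m) { double e = std::exp(logits(i, j, m) - mx); p(i, j, m) = e; se += e; }
      for (int m = 0; m < M; ++m) p(i, j, m) /= se;
    }
  }
  return p;
}

// Pixel-overlap contingency table between two integer label maps.
// Returns a 3-column matrix (label_a, label_b, n_pixels) over co-occurring
// positive labels; used by the nucleus matcher.
// [[Rcpp::export]]
arma::imat cpp_label_overlap(const arma::imat& a, const arma::imat& b) {
  std::map<std::pair<int, int>, int> tab;
  const size_t n = a.n_elem;
  for (size_t k = 0; k < n; ++k) {
    const int la = a(k), lb = b(k);
    if (la > 0 && lb > 0) tab[std::make_pair(la, lb)]++;
  }
  imat out(tab.size(), 3);
  size_t r = 0;
  for (auto& kv : tab) {
    out(r, 0) = kv.first.first;
    out(r, 1) = kv.first.second;
    out(r, 2) = kv.second;
    ++r;
  }
  return out;
}
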