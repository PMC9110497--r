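#define ARMA_NO_DEBUG
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// Map a (possibly out-of-range) spatial index into [0, n) under zero or
// reflect padding.  Reflection mirrors about the border pixel (no edge
// repeat); valid while pad < n.  Returns -1 for "outside" under zero pad.
static inline int map_idx(int i, int n, bool reflect) {
  if (i >= 0 && i < n) return i;
  if (!reflect) return -1;
  if (i < 0) i = -i;
  if (i >= n) i = 2 * n - 2 - i;
  if (i < 0 || i >= n) return -1;
  return i;
}

// Unfold image patches into columns: result is (C*k*k) x (Ho*Wo),
// row index c*k*k + kj*k + ki, column index wo*Ho + ho.
static mat im2col(const cube& x, int k, int stride, int pad, bool reflect,
                  int Ho, int Wo) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  mat cols(C * k * k, Ho * Wo, fill::zeros);
  const double* xp = x.memptr();
  double* cp = cols.memptr();
  const int rows = C * k * k;
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      double* col = cp + (std::size_t)(wo * Ho + ho) * rows;
      const int hb = ho * stride - pad, wb = wo * stride - pad;
      if (hb >= 0 && wb >= 0 && hb + k <= H && wb + k <= W) {
        // window fully interior: straight copies
        for (int c = 0; c < C; ++c) {
          const double* slice = xp + (std::size_t)c * H * W;
          for (int kj = 0; kj < k; ++kj) {
            const double* src = slice + (std::size_t)(wb + kj) * H + hb;
            double* dst = col + c * k * k + kj * k;
            for (int ki = 0; ki < k; ++ki) dst[ki] = src[ki];
          }
        }
      } else {
        for (int c = 0; c < C; ++c) {
          const double* slice = xp + (std::size_t)c * H * W;
          for (int kj = 0; kj < k; ++kj) {
            const int wi = map_idx(wb + kj, W, reflect);
            if (wi < 0) continue;
            const double* src = slice + (std::size_t)wi * H;
            double* dst = col + c * k * k + kj * k;
            for (int ki = 0; ki < k; ++ki) {
              const int hi = map_idx(hb + ki, H, reflect);
              if (hi >= 0) dst[ki] = src[hi];
            }
          }
        }
      }
    }
  }
  return cols;
}

// 2-D convolution (cross-correlation) of an H x W x C cube with Cout
// filters given as a (Cout) x (C*k*k) matrix.
// [[Rcpp::export]]
arma::cube conv2d_fwd(const arma::cube& x, const arma::mat& w,
                      const arma::vec& b, int k, int stride, int pad,
                      bool reflect) {
  const int H = x.n_rows, W = x.n_cols;
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  mat cols = im2col(x, k, stride, pad, reflect, Ho, Wo);
  mat out = w * cols;  // Cout x (Ho*Wo)
  out.each_col() += b;
  cube y(Ho, Wo, w.n_rows);
  mat outT = out.t();  // (Ho*Wo) x Cout, matching the cube's slice layout
  std::memcpy(y.memptr(), outT.memptr(), sizeof(double) * outT.n_elem);
  return y;
}

// Gradients of conv2d_fwd w.r.t. input, weights and bias.
// [[Rcpp::export]]
Rcpp::List conv2d_bwd(const arma::cube& x, const arma::mat& w,
                      const arma::cube& gy, int k, int stride, int pad,
                      bool reflect) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = gy.n_rows, Wo = gy.n_cols, Cout = gy.n_slices;
  mat gyM(Cout, Ho * Wo);
  {
    // gy cube memory is (Ho*Wo) blocks per slice: transpose into Cout rows
    const double* gp = gy.memptr();
    for (int c = 0; c < Cout; ++c)
      for (int p = 0; p < Ho * Wo; ++p)
        gyM(c, p) = gp[(std::size_t)c * Ho * Wo + p];
  }
  mat cols = im2col(x, k, stride, pad, reflect, Ho, Wo);
  mat gW = gyM * cols.t();
  vec gb = sum(gyM, 1);
  mat gcols = w.t() * gyM;  // (C*k*k) x (Ho*Wo)
  cube gx(H, W, C, fill::zeros);
  double* gxp = gx.memptr();
  const double* gc = gcols.memptr();
  const int rows = C * k * k;
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      const double* col = gc + (std::size_t)(wo * Ho + ho) * rows;
      const int hb = ho * stride - pad, wb = wo * stride - pad;
      if (hb >= 0 && wb >= 0 && hb + k <= H && wb + k <= W) {
        for (int c = 0; c < C; ++c) {
          double* slice = gxp + (std::size_t)c * H * W;
          for (int kj = 0; kj < k; ++kj) {
            double* dst = slice + (std::size_t)(wb + kj) * H + hb;
            const double* src = col + c * k * k + kj * k;
            for (int ki = 0; ki < k; ++ki) dst[ki] += src[ki];
          }
        }
      } else {
        for (int c = 0; c < C; ++c) {
          double* slice = gxp + (std::size_t)c * H * W;
          for (int kj = 0; kj < k; ++kj) {
            const int wi = map_idx(wb + kj, W, reflect);
            if (wi < 0) continue;
            double* dst = slice + (std::size_t)wi * H;
            const double* src = col + c * k * k + kj * k;
            for (int ki = 0; ki < k; ++ki) {
              const int hi = map_idx(hb + ki, H, reflect);
              if (hi >= 0) dst[hi] += src[ki];
            }
          }
        }
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("gx") = gx,
                            Rcpp::Named("gW") = gW,
                            Rcpp::Named("gb") = gb);
}

// Subgradient of the patch-min dark channel: each output pixel routes its
// incoming gradient to the first (scan-order) minimising (pixel, channel)
// in its clamped window.  gmap is H x W on the dark-channel output grid.
// [[Rcpp::export]]
arma::cube dark_channel_grad(const arma::cube& img, const arma::mat& gmap,
                             int patch) {
  const int H = img.n_rows, W = img.n_cols, C = img.n_slices;
  const int r = patch / 2;
  cube g(H, W, C, fill::zeros);
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      const double gv = gmap(i, j);
      if (gv == 0.0) continue;
      double best = datum::inf;
      int bi = 0, bj = 0, bc = 0;
      const int j0 = std::max(0, j - r), j1 = std::min(W - 1, j + r);
      const int i0 = std::max(0, i - r), i1 = std::min(H - 1, i + r);
      for (int jj = j0; jj <= j1; ++jj)
        for (int ii = i0; ii <= i1; ++ii)
          for (int c = 0; c < C; ++c) {
            const double v = img(ii, jj, c);
            if (v < best) { best = v; bi = ii; bj = jj; bc = c; }
          }
      g(bi, bj, bc) += gv;
    }
  }
  return g;
}
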