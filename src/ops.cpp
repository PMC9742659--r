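// Low-level numerical kernels: 2D convolution (im2col + GEMM) with analytic
// gradients, 2x2 max pooling, bilinear resizing and its adjoint, and the
// ray-marched angular-mean attenuation survival factors.
//
// Feature maps are arma::cube with dimensions (H, W, C); convolution weights
// are (kh*kw*Cin) x Cout matrices whose row order matches im2col below
// (kh fastest, then kw, then input channel). Stride is always 1; "same"
// padding is pad = dilation * (k - 1) / 2 for odd k.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Feature maps may carry a batch of samples: a cube with B*C slices,
// sample-major (slices [b*C, (b+1)*C) belong to sample b). All spatial
// operators below act slice-wise, so only the convolution needs to know B.

// Build the im2col matrix for one sample: rows = H*W output pixels
// (column-major order), cols = kh*kw*Cin. Zero padding outside the input.
static void im2col_into(arma::mat& col, arma::uword row0, const arma::cube& x,
                        int c0, int C, int kh, int kw, int pad, int dil) {
  const int H = x.n_rows, W = x.n_cols;
  for (int c = 0; c < C; ++c) {
    const double* xc = x.slice_memptr(c0 + c);
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        const int kidx = c * kh * kw + j * kh + i;
        const int di = i * dil - pad, dj = j * dil - pad;
        // valid output range: oh in [max(0,-di), min(H, H-di)), contiguous
        const int oh0 = std::max(0, -di), oh1 = std::min(H, H - di);
        const int ow0 = std::max(0, -dj), ow1 = std::min(W, W - dj);
        if (oh1 <= oh0) continue;
        double* dst0 = col.colptr(kidx) + row0;
        for (int ow = ow0; ow < ow1; ++ow) {
          std::memcpy(dst0 + (size_t)ow * H + oh0,
                      xc + (size_t)(ow + dj) * H + (oh0 + di),
                      sizeof(double) * (oh1 - oh0));
        }
      }
    }
  }
}

// Adjoint of im2col for one sample: scatter-add rows back into the cube.
static void col2im_into(arma::cube& dx, int c0, const arma::mat& dcol,
                        arma::uword row0, int C, int kh, int kw, int pad,
                        int dil) {
  const int H = dx.n_rows, W = dx.n_cols;
  for (int c = 0; c < C; ++c) {
    double* dxc = dx.slice_memptr(c0 + c);
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        const int kidx = c * kh * kw + j * kh + i;
        const int di = i * dil - pad, dj = j * dil - pad;
        const int oh0 = std::max(0, -di), oh1 = std::min(H, H - di);
        const int ow0 = std::max(0, -dj), ow1 = std::min(W, W - dj);
        if (oh1 <= oh0) continue;
        const double* src0 = dcol.colptr(kidx) + row0;
        for (int ow = ow0; ow < ow1; ++ow) {
          double* d = dxc + (size_t)(ow + dj) * H + (oh0 + di);
          const double* s = src0 + (size_t)ow * H + oh0;
          for (int t = 0; t < oh1 - oh0; ++t) d[t] += s[t];
        }
      }
    }
  }
}

// Batched convolution: x has nb*Cin slices, output nb*Cout slices. One GEMM
// serves the whole batch.
// [[Rcpp::export]]
arma::cube cpp_conv2d_fwd(const arma::cube& x, const arma::mat& w,
                          const arma::vec& b, int kh, int kw, int dil,
                          int nb = 1, bool relu = false) {
  const int H = x.n_rows, W = x.n_cols;
  const int C = x.n_slices / nb, Cout = w.n_cols;
  const int pad = dil * (kh - 1) / 2;
  arma::mat col((arma::uword)nb * H * W, kh * kw * C, arma::fill::zeros);
  for (int bb = 0; bb < nb; ++bb)
    im2col_into(col, (arma::uword)bb * H * W, x, bb * C, C, kh, kw, pad, dil);
  arma::mat y = col * w;           // (nb*H*W) x Cout
  y.each_row() += b.t();
  if (relu) y.clamp(0.0, arma::datum::inf);
  arma::cube out(H, W, (arma::uword)nb * Cout);
  for (int bb = 0; bb < nb; ++bb)
    for (int c = 0; c < Cout; ++c)
      std::memcpy(out.slice_memptr(bb * Cout + c),
                  y.colptr(c) + (arma::uword)bb * H * W,
                  sizeof(double) * H * W);
  return out;
}

// [[Rcpp::export]]
List cpp_conv2d_bwd(const arma::cube& x, const arma::mat& w,
                    const arma::cube& dy, int kh, int kw, int dil,
                    int nb = 1, Rcpp::Nullable<Rcpp::NumericVector> relu_y =
                      R_NilValue) {
  const int H = x.n_rows, W = x.n_cols;
  const int C = x.n_slices / nb, Cout = dy.n_slices / nb;
  const int pad = dil * (kh - 1) / 2;
  arma::mat dymat((arma::uword)nb * H * W, Cout);
  for (int bb = 0; bb < nb; ++bb)
    for (int c = 0; c < Cout; ++c)
      std::memcpy(dymat.colptr(c) + (arma::uword)bb * H * W,
                  dy.slice_memptr(bb * Cout + c), sizeof(double) * H * W);
  if (relu_y.isNotNull()) {
    // mask the upstream gradient where the forward ReLU output was zero
    Rcpp::NumericVector yv(relu_y);
    const double* yp = yv.begin();
    const size_t npl = (size_t)H * W;
    for (int bb = 0; bb < nb; ++bb)
      for (int c = 0; c < Cout; ++c) {
        double* d = dymat.colptr(c) + (arma::uword)bb * H * W;
        const double* ys = yp + (size_t)(bb * Cout + c) * npl;
        for (size_t t = 0; t < npl; ++t)
          if (ys[t] <= 0.0) d[t] = 0.0;
      }
  }
  arma::mat col((arma::uword)nb * H * W, kh * kw * C, arma::fill::zeros);
  for (int bb = 0; bb < nb; ++bb)
    im2col_into(col, (arma::uword)bb * H * W, x, bb * C, C, kh, kw, pad, dil);
  arma::mat dw = col.t() * dymat;
  arma::vec db = arma::sum(dymat, 0).t();
  arma::mat dcol = dymat * w.t();
  arma::cube dx(H, W, (arma::uword)nb * C, arma::fill::zeros);
  for (int bb = 0; bb < nb; ++bb)
    col2im_into(dx, bb * C, dcol, (arma::uword)bb * H * W, C, kh, kw, pad, dil);
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// Interleaved channel concatenation for batched maps: per sample, the Ca
// channels of `a` then the Cb channels of `b`.
// [[Rcpp::export]]
arma::cube cpp_cat_channels(const arma::cube& a, const arma::cube& b, int nb) {
  const int Ca = a.n_slices / nb, Cb = b.n_slices / nb;
  arma::cube out(a.n_rows, a.n_cols, (arma::uword)nb * (Ca + Cb));
  const size_t ns = sizeof(double) * a.n_rows * a.n_cols;
  for (int bb = 0; bb < nb; ++bb) {
    for (int c = 0; c < Ca; ++c)
      std::memcpy(out.slice_memptr(bb * (Ca + Cb) + c),
                  a.slice_memptr(bb * Ca + c), ns);
    for (int c = 0; c < Cb; ++c)
      std::memcpy(out.slice_memptr(bb * (Ca + Cb) + Ca + c),
                  b.slice_memptr(bb * Cb + c), ns);
  }
  return out;
}

// 2x2 max pooling, stride 2. Returns pooled cube and flat argmax indices
// (0-based into each input slice) for the backward pass.
// [[Rcpp::export]]
List cpp_maxpool2_fwd(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = H / 2, Wo = W / 2;
  arma::cube y(Ho, Wo, C);
  arma::ucube idx(Ho, Wo, C);
  for (int c = 0; c < C; ++c) {
    for (int ow = 0; ow < Wo; ++ow) {
      for (int oh = 0; oh < Ho; ++oh) {
        double best = -arma::datum::inf; arma::uword bi = 0;
        for (int dj = 0; dj < 2; ++dj) {
          for (int di = 0; di < 2; ++di) {
            const int i = 2 * oh + di, j = 2 * ow + dj;
            const double v = x(i, j, c);
            if (v > best) { best = v; bi = (arma::uword)(j * H + i); }
          }
        }
        y(oh, ow, c) = best;
        idx(oh, ow, c) = bi;
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
arma::cube cpp_maxpool2_bwd(const arma::cube& dy, const arma::ucube& idx,
                            int H, int W) {
  const int C = dy.n_slices;
  arma::cube dx(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    double* dxc = dx.slice_memptr(c);
    const double* dyc = dy.slice_memptr(c);
    const arma::uword* ic = idx.slice_memptr(c);
    for (arma::uword k = 0; k < dy.n_rows * dy.n_cols; ++k) dxc[ic[k]] += dyc[k];
  }
  return dx;
}

struct BilinTap { int i0, i1; double w0, w1; };

static std::vector<BilinTap> bilin_taps(int n_out, int n_in) {
  std::vector<BilinTap> t(n_out);
  const double scale = (double)n_in / (double)n_out;
  for (int o = 0; o < n_out; ++o) {
    double s = (o + 0.5) * scale - 0.5;
    if (s < 0) s = 0;
    if (s > n_in - 1) s = n_in - 1;
    int i0 = (int)std::floor(s);
    int i1 = std::min(i0 + 1, n_in - 1);
    double f = s - i0;
    t[o] = {i0, i1, 1.0 - f, f};
  }
  return t;
}

// Bilinear resize (pixel-centre alignment) of every channel to (Ho, Wo).
// [[Rcpp::export]]
arma::cube cpp_resize_bilinear(const arma::cube& x, int Ho, int Wo) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  std::vector<BilinTap> ti = bilin_taps(Ho, H), tj = bilin_taps(Wo, W);
  arma::cube y(Ho, Wo, C);
  for (int c = 0; c < C; ++c) {
    const arma::mat& xc = x.slice(c);
    arma::mat& yc = y.slice(c);
    for (int j = 0; j < Wo; ++j) {
      for (int i = 0; i < Ho; ++i) {
        yc(i, j) = tj[j].w0 * (ti[i].w0 * xc(ti[i].i0, tj[j].i0) + ti[i].w1 * xc(ti[i].i1, tj[j].i0))
                 + tj[j].w1 * (ti[i].w0 * xc(ti[i].i0, tj[j].i1) + ti[i].w1 * xc(ti[i].i1, tj[j].i1));
      }
    }
  }
  return y;
}

// Adjoint of cpp_resize_bilinear: maps a gradient on the (Ho, Wo) output back
// to the (H, W) input grid.
// [[Rcpp::export]]
arma::cube cpp_resize_bilinear_adj(const arma::cube& dy, int H, int W) {
  const int Ho = dy.n_rows, Wo = dy.n_cols, C = dy.n_slices;
  std::vector<BilinTap> ti = bilin_taps(Ho, H), tj = bilin_taps(Wo, W);
  arma::cube dx(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const arma::mat& gc = dy.slice(c);
    arma::mat& dxc = dx.slice(c);
    for (int j = 0; j < Wo; ++j) {
      for (int i = 0; i < Ho; ++i) {
        const double g = gc(i, j);
        dxc(ti[i].i0, tj[j].i0) += ti[i].w0 * tj[j].w0 * g;
        dxc(ti[i].i1, tj[j].i0) += ti[i].w1 * tj[j].w0 * g;
        dxc(ti[i].i0, tj[j].i1) += ti[i].w0 * tj[j].w1 * g;
        dxc(ti[i].i1, tj[j].i1) += ti[i].w1 * tj[j].w1 * g;
      }
    }
  }
  return dx;
}

static double bilin_mu(const arma::mat& mu, double i, double j) {
  const int H = mu.n_rows, W = mu.n_cols;
  if (i < 0 || j < 0 || i > H - 1 || j > W - 1) return 0.0;
  int i0 = (int)std::floor(i), j0 = (int)std::floor(j);
  int i1 = std::min(i0 + 1, H - 1), j1 = std::min(j0 + 1, W - 1);
  double fi = i - i0, fj = j - j0;
  return (1 - fi) * ((1 - fj) * mu(i0, j0) + fj * mu(i0, j1))
       + fi * ((1 - fj) * mu(i1, j0) + fj * mu(i1, j1));
}

// Angular-mean survival factor per pixel:
//   f(v) = (1/n_angles) * sum_a exp(-integral of mu along the full chord
//          through v at angle a),
// with the line integral evaluated by equal-step ray marching at
// step = pixel_mm / 2 (midpoint rule in both directions from the pixel
// centre). mu is in 1/mm; distances in mm.
// [[Rcpp::export]]
arma::mat cpp_atten_factors(const arma::mat& mu, double pixel_mm, int n_angles) {
  const int H = mu.n_rows, W = mu.n_cols;
  const double step = pixel_mm / 2.0;
  const double diag = std::sqrt((double)H * H + (double)W * W) * pixel_mm;
  const int max_steps = (int)std::ceil(diag / step) + 2;
  arma::mat out(H, W);
  std::vector<double> ci(n_angles), cj(n_angles);
  for (int a = 0; a < n_angles; ++a) {
    const double th = M_PI * a / n_angles;   // full chord covers both ray directions
    ci[a] = std::cos(th);
    cj[a] = std::sin(th);
  }
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      double acc = 0.0;
      for (int a = 0; a < n_angles; ++a) {
        double integ = 0.0;
        for (int dir = -1; dir <= 1; dir += 2) {
          for (int s = 0; s < max_steps; ++s) {
            const double t = dir * (s + 0.5) * step / pixel_mm; // in pixels
            const double pi_ = i + t * ci[a], pj = j + t * cj[a];
            if (pi_ < -1 || pj < -1 || pi_ > H || pj > W) break;
            integ += bilin_mu(mu, pi_, pj) * step;
          }
        }
        acc += std::exp(-integ);
      }
      out(i, j) = acc / n_angles;
    }
  }
  return out;
}
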