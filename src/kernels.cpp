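// Low-level neural-network and warping kernels with hand-derived backward
// passes.  Array layouts follow R's column-major convention:
//   2D feature maps: (H, W, C)       3D feature maps: (H, W, D, C)
//   conv2d weights:  (3, 3, Cin, Cout)   conv3d weights: (3, 3, 3, Cin, Cout)
//   displacement fields: (H, W, 2) with component 1 = row, 2 = column, in px.
// Convolutions are "same" with zero padding; convolution is implemented as
// im2col + GEMM so the heavy lifting lands in BLAS.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline IntegerVector dims_of(const NumericVector& x) {
  return x.attr("dim");
}

// ---------------------------------------------------------------------------
// im2col helpers
// ---------------------------------------------------------------------------

// 2D: cols is (H*W) x (9*Cin); column index q = ki + 3*kj + 9*ci matches the
// column-major flattening of a (3,3,Cin,Cout) weight array into (9*Cin, Cout).
static void im2col2d(const double* x, int H, int W, int Cin, arma::mat& cols) {
  cols.zeros(static_cast<arma::uword>(H) * W, 9 * static_cast<arma::uword>(Cin));
  for (int ci = 0; ci < Cin; ++ci) {
    const double* xc = x + static_cast<size_t>(ci) * H * W;
    for (int kj = 0; kj < 3; ++kj) {
      for (int ki = 0; ki < 3; ++ki) {
        int q = ki + 3 * kj + 9 * ci;
        double* col = cols.colptr(q);
        for (int j = 0; j < W; ++j) {
          int jj = j + kj - 1;
          if (jj < 0 || jj >= W) continue;
          int i_lo = std::max(0, 1 - ki);
          int i_hi = std::min(H - 1, H - ki);  // i + ki - 1 <= H-1
          const double* src = xc + static_cast<size_t>(jj) * H + (i_lo + ki - 1);
          double* dst = col + static_cast<size_t>(j) * H + i_lo;
          for (int i = i_lo; i <= i_hi; ++i) *dst++ = *src++;
        }
      }
    }
  }
}

static void col2im2d(const arma::mat& cols, int H, int W, int Cin, double* gx) {
  for (int ci = 0; ci < Cin; ++ci) {
    double* xc = gx + static_cast<size_t>(ci) * H * W;
    for (int kj = 0; kj < 3; ++kj) {
      for (int ki = 0; ki < 3; ++ki) {
        int q = ki + 3 * kj + 9 * ci;
        const double* col = cols.colptr(q);
        for (int j = 0; j < W; ++j) {
          int jj = j + kj - 1;
          if (jj < 0 || jj >= W) continue;
          int i_lo = std::max(0, 1 - ki);
          int i_hi = std::min(H - 1, H - ki);
          double* dst = xc + static_cast<size_t>(jj) * H + (i_lo + ki - 1);
          const double* src = col + static_cast<size_t>(j) * H + i_lo;
          for (int i = i_lo; i <= i_hi; ++i) *dst++ += *src++;
        }
      }
    }
  }
}

// 3D: cols is (H*W*D) x (27*Cin); q = ki + 3*kj + 9*kd + 27*ci.
static void im2col3d(const double* x, int H, int W, int D, int Cin,
                     arma::mat& cols) {
  size_t vol = static_cast<size_t>(H) * W * D;
  cols.zeros(vol, 27 * static_cast<arma::uword>(Cin));
  for (int ci = 0; ci < Cin; ++ci) {
    const double* xc = x + static_cast<size_t>(ci) * vol;
    for (int kd = 0; kd < 3; ++kd) {
      for (int kj = 0; kj < 3; ++kj) {
        for (int ki = 0; ki < 3; ++ki) {
          int q = ki + 3 * kj + 9 * kd + 27 * ci;
          double* col = cols.colptr(q);
          for (int d = 0; d < D; ++d) {
            int dd = d + kd - 1;
            if (dd < 0 || dd >= D) continue;
            for (int j = 0; j < W; ++j) {
              int jj = j + kj - 1;
              if (jj < 0 || jj >= W) continue;
              int i_lo = std::max(0, 1 - ki);
              int i_hi = std::min(H - 1, H - ki);
              const double* src = xc + (static_cast<size_t>(dd) * W + jj) * H +
                                  (i_lo + ki - 1);
              double* dst = col + (static_cast<size_t>(d) * W + j) * H + i_lo;
              for (int i = i_lo; i <= i_hi; ++i) *dst++ = *src++;
            }
          }
        }
      }
    }
  }
}

static void col2im3d(const arma::mat& cols, int H, int W, int D, int Cin,
                     double* gx) {
  size_t vol = static_cast<size_t>(H) * W * D;
  for (int ci = 0; ci < Cin; ++ci) {
    double* xc = gx + static_cast<size_t>(ci) * vol;
    for (int kd = 0; kd < 3; ++kd) {
      for (int kj = 0; kj < 3; ++kj) {
        for (int ki = 0; ki < 3; ++ki) {
          int q = ki + 3 * kj + 9 * kd + 27 * ci;
          const double* col = cols.colptr(q);
          for (int d = 0; d < D; ++d) {
            int dd = d + kd - 1;
            if (dd < 0 || dd >= D) continue;
            for (int j = 0; j < W; ++j) {
              int jj = j + kj - 1;
              if (jj < 0 || jj >= W) continue;
              int i_lo = std::max(0, 1 - ki);
              int i_hi = std::min(H - 1, H - ki);
              double* dst = xc + (static_cast<size_t>(dd) * W + jj) * H +
                            (i_lo + ki - 1);
              const double* src = col + (static_cast<size_t>(d) * W + j) * H + i_lo;
              for (int i = i_lo; i <= i_hi; ++i) *dst++ += *src++;
            }
          }
        }
      }
    }
  }
}

// ---------------------------------------------------------------------------
// conv2d
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_conv2d_fwd(NumericVector x, NumericVector w, NumericVector b) {
  IntegerVector dx = dims_of(x), dw = dims_of(w);
  int H = dx[0], W = dx[1], Cin = dx[2], Cout = dw[3];
  arma::mat cols;
  im2col2d(x.begin(), H, W, Cin, cols);
  arma::mat wm(w.begin(), 9 * Cin, Cout, false, true);
  arma::mat out = cols * wm;
  out.each_row() += arma::rowvec(b.begin(), Cout, false, true);
  NumericVector res(out.begin(), out.end());
  res.attr("dim") = IntegerVector::create(H, W, Cout);
  return res;
}

// [[Rcpp::export]]
List cpp_conv2d_bwd(NumericVector x, NumericVector w, NumericVector gout) {
  IntegerVector dx = dims_of(x), dw = dims_of(w);
  int H = dx[0], W = dx[1], Cin = dx[2], Cout = dw[3];
  arma::mat cols;
  im2col2d(x.begin(), H, W, Cin, cols);
  arma::mat gm(gout.begin(), static_cast<arma::uword>(H) * W, Cout, false, true);
  arma::mat wm(w.begin(), 9 * Cin, Cout, false, true);
  arma::mat gw = cols.t() * gm;
  arma::rowvec gb = arma::sum(gm, 0);
  arma::mat gcols = gm * wm.t();
  NumericVector gx(x.size());
  col2im2d(gcols, H, W, Cin, gx.begin());
  gx.attr("dim") = dx;
  NumericVector gwv(gw.begin(), gw.end());
  gwv.attr("dim") = dw;
  return List::create(_["gx"] = gx, _["gw"] = gwv,
                      _["gb"] = NumericVector(gb.begin(), gb.end()));
}

// ---------------------------------------------------------------------------
// conv3d (kernel 3x3x3, zero padding in all three axes)
// ---------------------------------------------------------------------------

// single-precision im2col / col2im twins of the 3D helpers above.  The 3D
// convolutions dominate a training step and are bandwidth/GEMM bound, so the
// fast path runs the im2col matrix and GEMMs in float32 (weights and
// activations are O(1); the ~1e-7 relative rounding is far below the
// optimisation noise floor).  The double-precision entry points remain the
// reference implementation and are used wherever exact gradients matter.

static void im2col3d_f(const double* x, int H, int W, int D, int Cin,
                       arma::fmat& cols) {
  size_t vol = static_cast<size_t>(H) * W * D;
  cols.zeros(vol, 27 * static_cast<arma::uword>(Cin));
  for (int ci = 0; ci < Cin; ++ci) {
    const double* xc = x + static_cast<size_t>(ci) * vol;
    for (int kd = 0; kd < 3; ++kd)
      for (int kj = 0; kj < 3; ++kj)
        for (int ki = 0; ki < 3; ++ki) {
          int q = ki + 3 * kj + 9 * kd + 27 * ci;
          float* col = cols.colptr(q);
          for (int d = 0; d < D; ++d) {
            int dd = d + kd - 1;
            if (dd < 0 || dd >= D) continue;
            for (int j = 0; j < W; ++j) {
              int jj = j + kj - 1;
              if (jj < 0 || jj >= W) continue;
              int i_lo = std::max(0, 1 - ki);
              int i_hi = std::min(H - 1, H - ki);
              const double* src = xc + (static_cast<size_t>(dd) * W + jj) * H +
                                  (i_lo + ki - 1);
              float* dst = col + (static_cast<size_t>(d) * W + j) * H + i_lo;
              for (int i = i_lo; i <= i_hi; ++i)
                *dst++ = static_cast<float>(*src++);
            }
          }
        }
  }
}

static void col2im3d_f(const arma::fmat& cols, int H, int W, int D, int Cin,
                       double* gx) {
  size_t vol = static_cast<size_t>(H) * W * D;
  for (int ci = 0; ci < Cin; ++ci) {
    double* xc = gx + static_cast<size_t>(ci) * vol;
    for (int kd = 0; kd < 3; ++kd)
      for (int kj = 0; kj < 3; ++kj)
        for (int ki = 0; ki < 3; ++ki) {
          int q = ki + 3 * kj + 9 * kd + 27 * ci;
          const float* col = cols.colptr(q);
          for (int d = 0; d < D; ++d) {
            int dd = d + kd - 1;
            if (dd < 0 || dd >= D) continue;
            for (int j = 0; j < W; ++j) {
              int jj = j + kj - 1;
              if (jj < 0 || jj >= W) continue;
              int i_lo = std::max(0, 1 - ki);
              int i_hi = std::min(H - 1, H - ki);
              double* dst = xc + (static_cast<size_t>(dd) * W + jj) * H +
                            (i_lo + ki - 1);
              const float* src = col + (static_cast<size_t>(d) * W + j) * H + i_lo;
              for (int i = i_lo; i <= i_hi; ++i) *dst++ += *src++;
            }
          }
        }
  }
}

// [[Rcpp::export]]
List cpp_conv3d_fwd_cached(NumericVector x, NumericVector w, NumericVector b) {
  IntegerVector dx = dims_of(x), dw = dims_of(w);
  int H = dx[0], W = dx[1], D = dx[2], Cin = dx[3], Cout = dw[4];
  arma::fmat* colsp = new arma::fmat();
  im2col3d_f(x.begin(), H, W, D, Cin, *colsp);
  arma::fmat wm = arma::conv_to<arma::fmat>::from(
      arma::mat(w.begin(), 27 * Cin, Cout, false, true));
  arma::fmat out = (*colsp) * wm;
  NumericVector res(out.size());
  std::copy(out.begin(), out.end(), res.begin());
  double* rp = res.begin();
  size_t vol = static_cast<size_t>(H) * W * D;
  for (int co = 0; co < Cout; ++co) {
    double bias = b[co];
    for (size_t p = 0; p < vol; ++p) rp[co * vol + p] += bias;
  }
  res.attr("dim") = IntegerVector::create(H, W, D, Cout);
  XPtr<arma::fmat> cache(colsp, true);
  return List::create(_["out"] = res, _["cache"] = cache);
}

// [[Rcpp::export]]
NumericVector cpp_conv3d_fwd(NumericVector x, NumericVector w, NumericVector b) {
  IntegerVector dx = dims_of(x), dw = dims_of(w);
  int H = dx[0], W = dx[1], D = dx[2], Cin = dx[3], Cout = dw[4];
  arma::mat cols;
  im2col3d(x.begin(), H, W, D, Cin, cols);
  arma::mat wm(w.begin(), 27 * Cin, Cout, false, true);
  arma::mat out = cols * wm;
  out.each_row() += arma::rowvec(b.begin(), Cout, false, true);
  NumericVector res(out.begin(), out.end());
  res.attr("dim") = IntegerVector::create(H, W, D, Cout);
  return res;
}

// gradient using the float32 im2col matrix cached at forward time; the
// cache is released afterwards to keep peak memory flat across a step.
// [[Rcpp::export]]
List cpp_conv3d_bwd_cached(SEXP cache, NumericVector w, NumericVector gout,
                           IntegerVector dx) {
  XPtr<arma::fmat> xp(cache);
  arma::fmat& cols = *xp;
  IntegerVector dw = dims_of(w);
  int H = dx[0], W = dx[1], D = dx[2], Cin = dx[3], Cout = dw[4];
  size_t vol = static_cast<size_t>(H) * W * D;
  arma::fmat gm = arma::conv_to<arma::fmat>::from(
      arma::mat(gout.begin(), vol, Cout, false, true));
  arma::fmat wm = arma::conv_to<arma::fmat>::from(
      arma::mat(w.begin(), 27 * Cin, Cout, false, true));
  arma::fmat gw = cols.t() * gm;
  arma::frowvec gb = arma::sum(gm, 0);
  arma::fmat gcols = gm * wm.t();
  cols.reset();
  NumericVector gx(static_cast<R_xlen_t>(vol) * Cin);
  col2im3d_f(gcols, H, W, D, Cin, gx.begin());
  gx.attr("dim") = dx;
  NumericVector gwv(gw.size());
  std::copy(gw.begin(), gw.end(), gwv.begin());
  gwv.attr("dim") = dw;
  NumericVector gbv(Cout);
  std::copy(gb.begin(), gb.end(), gbv.begin());
  return List::create(_["gx"] = gx, _["gw"] = gwv, _["gb"] = gbv);
}

// [[Rcpp::export]]
List cpp_conv3d_bwd(NumericVector x, NumericVector w, NumericVector gout) {
  IntegerVector dx = dims_of(x), dw = dims_of(w);
  int H = dx[0], W = dx[1], D = dx[2], Cin = dx[3], Cout = dw[4];
  arma::mat cols;
  im2col3d(x.begin(), H, W, D, Cin, cols);
  size_t vol = static_cast<size_t>(H) * W * D;
  arma::mat gm(gout.begin(), vol, Cout, false, true);
  arma::mat wm(w.begin(), 27 * Cin, Cout, false, true);
  arma::mat gw = cols.t() * gm;
  arma::rowvec gb = arma::sum(gm, 0);
  arma::mat gcols = gm * wm.t();
  NumericVector gx(x.size());
  col2im3d(gcols, H, W, D, Cin, gx.begin());
  gx.attr("dim") = dx;
  NumericVector gwv(gw.begin(), gw.end());
  gwv.attr("dim") = dw;
  return List::create(_["gx"] = gx, _["gw"] = gwv,
                      _["gb"] = NumericVector(gb.begin(), gb.end()));
}

// ---------------------------------------------------------------------------
// max pooling, factor 2 (spatial axes only for the 3D variant)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_maxpool2d_fwd(NumericVector x) {
  IntegerVector dx = dims_of(x);
  int H = dx[0], W = dx[1], C = dx[2], H2 = H / 2, W2 = W / 2;
  NumericVector out(static_cast<R_xlen_t>(H2) * W2 * C);
  IntegerVector idx(out.size());
  const double* xp = x.begin();
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < W2; ++j)
      for (int i = 0; i < H2; ++i) {
        size_t best = 0; double bv = -std::numeric_limits<double>::infinity();
        for (int dj = 0; dj < 2; ++dj)
          for (int di = 0; di < 2; ++di) {
            size_t p = (static_cast<size_t>(c) * W + (2 * j + dj)) * H + 2 * i + di;
            if (xp[p] > bv) { bv = xp[p]; best = p; }
          }
        size_t q = (static_cast<size_t>(c) * W2 + j) * H2 + i;
        out[q] = bv; idx[q] = static_cast<int>(best);
      }
  out.attr("dim") = IntegerVector::create(H2, W2, C);
  return List::create(_["out"] = out, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bwd(IntegerVector idx, NumericVector gout, int n_in) {
  NumericVector gx(n_in);
  for (R_xlen_t q = 0; q < gout.size(); ++q) gx[idx[q]] += gout[q];
  return gx;
}

// [[Rcpp::export]]
List cpp_maxpool3d_fwd(NumericVector x) {
  IntegerVector dx = dims_of(x);
  int H = dx[0], W = dx[1], D = dx[2], C = dx[3], H2 = H / 2, W2 = W / 2;
  NumericVector out(static_cast<R_xlen_t>(H2) * W2 * D * C);
  IntegerVector idx(out.size());
  const double* xp = x.begin();
  for (int c = 0; c < C; ++c)
    for (int d = 0; d < D; ++d)
      for (int j = 0; j < W2; ++j)
        for (int i = 0; i < H2; ++i) {
          size_t best = 0; double bv = -std::numeric_limits<double>::infinity();
          for (int dj = 0; dj < 2; ++dj)
            for (int di = 0; di < 2; ++di) {
              size_t p = ((static_cast<size_t>(c) * D + d) * W + (2 * j + dj)) * H +
                         2 * i + di;
              if (xp[p] > bv) { bv = xp[p]; best = p; }
            }
          size_t q = ((static_cast<size_t>(c) * D + d) * W2 + j) * H2 + i;
          out[q] = bv; idx[q] = static_cast<int>(best);
        }
  out.attr("dim") = IntegerVector::create(H2, W2, D, C);
  return List::create(_["out"] = out, _["idx"] = idx);
}

// ---------------------------------------------------------------------------
// transposed convolution, kernel 2, stride 2 (spatial upscaling)
// weights: (2, 2, Cin, Cout)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_upconv2d_fwd(NumericVector x, NumericVector w, NumericVector b) {
  IntegerVector dx = dims_of(x), dw = dims_of(w);
  int h = dx[0], wd = dx[1], Cin = dx[2], Cout = dw[3];
  int H = 2 * h, W = 2 * wd;
  NumericVector out(static_cast<R_xlen_t>(H) * W * Cout);
  const double* xp = x.begin(); const double* wp = w.begin();
  double* op = out.begin();
  for (int co = 0; co < Cout; ++co) {
    double bias = b[co];
    double* oc = op + static_cast<size_t>(co) * H * W;
    for (size_t p = 0; p < static_cast<size_t>(H) * W; ++p) oc[p] = bias;
    for (int ci = 0; ci < Cin; ++ci) {
      const double* xc = xp + static_cast<size_t>(ci) * h * wd;
      const double* wk = wp + 4 * (static_cast<size_t>(ci) + static_cast<size_t>(Cin) * co);
      for (int j = 0; j < wd; ++j)
        for (int i = 0; i < h; ++i) {
          double v = xc[static_cast<size_t>(j) * h + i];
          for (int dj = 0; dj < 2; ++dj)
            for (int di = 0; di < 2; ++di)
              oc[(static_cast<size_t>(2 * j + dj)) * H + 2 * i + di] +=
                  v * wk[di + 2 * dj];
        }
    }
  }
  out.attr("dim") = IntegerVector::create(H, W, Cout);
  return out;
}

// [[Rcpp::export]]
List cpp_upconv2d_bwd(NumericVector x, NumericVector w, NumericVector gout) {
  IntegerVector dx = dims_of(x), dw = dims_of(w);
  int h = dx[0], wd = dx[1], Cin = dx[2], Cout = dw[3];
  int H = 2 * h;
  NumericVector gx(x.size()), gw(w.size()), gb(Cout);
  const double* xp = x.begin(); const double* wp = w.begin();
  const double* gp = gout.begin();
  for (int co = 0; co < Cout; ++co) {
    const double* gc = gp + static_cast<size_t>(co) * H * 2 * wd;
    double s = 0;
    for (size_t p = 0; p < static_cast<size_t>(H) * 2 * wd; ++p) s += gc[p];
    gb[co] = s;
    for (int ci = 0; ci < Cin; ++ci) {
      const double* xc = xp + static_cast<size_t>(ci) * h * wd;
      double* gxc = gx.begin() + static_cast<size_t>(ci) * h * wd;
      const double* wk = wp + 4 * (static_cast<size_t>(ci) + static_cast<size_t>(Cin) * co);
      double* gwk = gw.begin() + 4 * (static_cast<size_t>(ci) + static_cast<size_t>(Cin) * co);
      for (int j = 0; j < wd; ++j)
        for (int i = 0; i < h; ++i) {
          double xv = xc[static_cast<size_t>(j) * h + i];
          double acc = 0;
          for (int dj = 0; dj < 2; ++dj)
            for (int di = 0; di < 2; ++di) {
              double g = gc[(static_cast<size_t>(2 * j + dj)) * H + 2 * i + di];
              acc += g * wk[di + 2 * dj];
              gwk[di + 2 * dj] += g * xv;
            }
          gxc[static_cast<size_t>(j) * h + i] += acc;
        }
    }
  }
  gx.attr("dim") = dx; gw.attr("dim") = dw;
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// 3D variant: the same 2x2 spatial kernel applied independently to each depth
// slice (temporal resolution is preserved through the decoder).

// [[Rcpp::export]]
NumericVector cpp_upconv3d_fwd(NumericVector x, NumericVector w, NumericVector b) {
  IntegerVector dx = dims_of(x), dw = dims_of(w);
  int h = dx[0], wd = dx[1], D = dx[2], Cin = dx[3], Cout = dw[3];
  int H = 2 * h, W = 2 * wd;
  NumericVector out(static_cast<R_xlen_t>(H) * W * D * Cout);
  const double* xp = x.begin(); const double* wp = w.begin();
  double* op = out.begin();
  for (int co = 0; co < Cout; ++co) {
    double bias = b[co];
    for (int d = 0; d < D; ++d) {
      double* oc = op + (static_cast<size_t>(co) * D + d) * H * W;
      for (size_t p = 0; p < static_cast<size_t>(H) * W; ++p) oc[p] = bias;
      for (int ci = 0; ci < Cin; ++ci) {
        const double* xc = xp + (static_cast<size_t>(ci) * D + d) * h * wd;
        const double* wk = wp + 4 * (static_cast<size_t>(ci) + static_cast<size_t>(Cin) * co);
        for (int j = 0; j < wd; ++j)
          for (int i = 0; i < h; ++i) {
            double v = xc[static_cast<size_t>(j) * h + i];
            for (int dj = 0; dj < 2; ++dj)
              for (int di = 0; di < 2; ++di)
                oc[(static_cast<size_t>(2 * j + dj)) * H + 2 * i + di] +=
                    v * wk[di + 2 * dj];
          }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(H, W, D, Cout);
  return out;
}

// [[Rcpp::export]]
List cpp_upconv3d_bwd(NumericVector x, NumericVector w, NumericVector gout) {
  IntegerVector dx = dims_of(x), dw = dims_of(w);
  int h = dx[0], wd = dx[1], D = dx[2], Cin = dx[3], Cout = dw[3];
  int H = 2 * h, W = 2 * wd;
  NumericVector gx(x.size()), gw(w.size()), gb(Cout);
  const double* xp = x.begin(); const double* wp = w.begin();
  const double* gp = gout.begin();
  for (int co = 0; co < Cout; ++co) {
    double s = 0;
    for (int d = 0; d < D; ++d) {
      const double* gc = gp + (static_cast<size_t>(co) * D + d) * H * W;
      for (size_t p = 0; p < static_cast<size_t>(H) * W; ++p) s += gc[p];
      for (int ci = 0; ci < Cin; ++ci) {
        const double* xc = xp + (static_cast<size_t>(ci) * D + d) * h * wd;
        double* gxc = gx.begin() + (static_cast<size_t>(ci) * D + d) * h * wd;
        const double* wk = wp + 4 * (static_cast<size_t>(ci) + static_cast<size_t>(Cin) * co);
        double* gwk = gw.begin() + 4 * (static_cast<size_t>(ci) + static_cast<size_t>(Cin) * co);
        for (int j = 0; j < wd; ++j)
          for (int i = 0; i < h; ++i) {
            double xv = xc[static_cast<size_t>(j) * h + i];
            double acc = 0;
            for (int dj = 0; dj < 2; ++dj)
              for (int di = 0; di < 2; ++di) {
                double g = gc[(static_cast<size_t>(2 * j + dj)) * H + 2 * i + di];
                acc += g * wk[di + 2 * dj];
                gwk[di + 2 * dj] += g * xv;
              }
            gxc[static_cast<size_t>(j) * h + i] += acc;
          }
      }
    }
    gb[co] = s;
  }
  gx.attr("dim") = dx; gw.attr("dim") = dw;
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// ---------------------------------------------------------------------------
// bilinear warping (backward mapping, border replication)
// out(i,j,c) = img(i + d0(i,j), j + d1(i,j), c), sampled bilinearly.
// The displacement gradient is zeroed where the unclamped coordinate falls
// outside the image, matching the flat extrapolation of the clamp.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_warp_fwd(NumericVector img, NumericVector disp) {
  IntegerVector di_ = dims_of(img);
  int H = di_[0], W = di_[1], C = di_[2];
  const double* ip = img.begin(); const double* dp = disp.begin();
  NumericVector out(img.size());
  double* op = out.begin();
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      size_t p = static_cast<size_t>(j) * H + i;
      double py = i + dp[p];
      double px = j + dp[p + static_cast<size_t>(H) * W];
      if (py < 0) py = 0; if (py > H - 1) py = H - 1;
      if (px < 0) px = 0; if (px > W - 1) px = W - 1;
      int i0 = static_cast<int>(std::floor(py)); if (i0 > H - 2) i0 = H - 2;
      int j0 = static_cast<int>(std::floor(px)); if (j0 > W - 2) j0 = W - 2;
      if (H == 1) i0 = 0;
      if (W == 1) j0 = 0;
      double fy = py - i0, fx = px - j0;
      double w00 = (1 - fy) * (1 - fx), w10 = fy * (1 - fx);
      double w01 = (1 - fy) * fx, w11 = fy * fx;
      int i1 = std::min(i0 + 1, H - 1), j1 = std::min(j0 + 1, W - 1);
      for (int c = 0; c < C; ++c) {
        const double* ic = ip + static_cast<size_t>(c) * H * W;
        op[p + static_cast<size_t>(c) * H * W] =
            w00 * ic[static_cast<size_t>(j0) * H + i0] +
            w10 * ic[static_cast<size_t>(j0) * H + i1] +
            w01 * ic[static_cast<size_t>(j1) * H + i0] +
            w11 * ic[static_cast<size_t>(j1) * H + i1];
      }
    }
  out.attr("dim") = di_;
  return out;
}

// [[Rcpp::export]]
List cpp_warp_bwd(NumericVector img, NumericVector disp, NumericVector gout) {
  IntegerVector di_ = dims_of(img);
  int H = di_[0], W = di_[1], C = di_[2];
  const double* ip = img.begin(); const double* dp = disp.begin();
  const double* gp = gout.begin();
  NumericVector gimg(img.size()), gdisp(disp.size());
  double* gi = gimg.begin(); double* gd = gdisp.begin();
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      size_t p = static_cast<size_t>(j) * H + i;
      double py = i + dp[p];
      double px = j + dp[p + static_cast<size_t>(H) * W];
      bool iny = (py >= 0 && py <= H - 1), inx = (px >= 0 && px <= W - 1);
      if (py < 0) py = 0; if (py > H - 1) py = H - 1;
      if (px < 0) px = 0; if (px > W - 1) px = W - 1;
      int i0 = static_cast<int>(std::floor(py)); if (i0 > H - 2) i0 = H - 2;
      int j0 = static_cast<int>(std::floor(px)); if (j0 > W - 2) j0 = W - 2;
      if (H == 1) i0 = 0;
      if (W == 1) j0 = 0;
      double fy = py - i0, fx = px - j0;
      int i1 = std::min(i0 + 1, H - 1), j1 = std::min(j0 + 1, W - 1);
      double gy = 0, gx = 0;
      for (int c = 0; c < C; ++c) {
        const double* ic = ip + static_cast<size_t>(c) * H * W;
        double* gc = gi + static_cast<size_t>(c) * H * W;
        double g = gp[p + static_cast<size_t>(c) * H * W];
        double v00 = ic[static_cast<size_t>(j0) * H + i0];
        double v10 = ic[static_cast<size_t>(j0) * H + i1];
        double v01 = ic[static_cast<size_t>(j1) * H + i0];
        double v11 = ic[static_cast<size_t>(j1) * H + i1];
        gc[static_cast<size_t>(j0) * H + i0] += g * (1 - fy) * (1 - fx);
        gc[static_cast<size_t>(j0) * H + i1] += g * fy * (1 - fx);
        gc[static_cast<size_t>(j1) * H + i0] += g * (1 - fy) * fx;
        gc[static_cast<size_t>(j1) * H + i1] += g * fy * fx;
        gy += g * ((v10 - v00) * (1 - fx) + (v11 - v01) * fx);
        gx += g * ((v01 - v00) * (1 - fy) + (v11 - v10) * fy);
      }
      if (iny) gd[p] = gy;
      if (inx) gd[p + static_cast<size_t>(H) * W] = gx;
    }
  gimg.attr("dim") = di_;
  gdisp.attr("dim") = dims_of(disp);
  return List::create(_["gimg"] = gimg, _["gdisp"] = gdisp);
}
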