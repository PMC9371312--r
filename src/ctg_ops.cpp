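#include <Rcpp.h>
using namespace Rcpp;

// Feature maps are D x (H*W*B) matrices, column-major spatial layout
// (pixel n = r + c*H, 0-based) with images stacked along columns.

// Run-loop helpers: fixed-size variants let the compiler fully unroll and
// vectorise the channel loops, which dominates at the decoder tail where
// feature maps are large (up to 16x the encoder grid) but shallow.
template <int DOUT>
static inline void conv_run_fixed(const double* src, double* dst, int nrun,
                                  int Din, const double* wt) {
  for (int r = 0; r < nrun; ++r) {
    for (int di = 0; di < Din; ++di) {
      const double v = src[di];
      const double* __restrict wcol = wt + (R_xlen_t)di * DOUT;
      for (int d = 0; d < DOUT; ++d) dst[d] += wcol[d] * v;
    }
    src += Din;
    dst += DOUT;
  }
}

static inline void conv_run_gen(const double* src, double* dst, int nrun,
                                int Din, int Dout, const double* wt) {
  for (int r = 0; r < nrun; ++r) {
    for (int di = 0; di < Din; ++di) {
      const double v = src[di];
      const double* __restrict wcol = wt + (R_xlen_t)di * Dout;
      double* __restrict dstr = dst;
      for (int d = 0; d < Dout; ++d) dstr[d] += wcol[d] * v;
    }
    src += Din;
    dst += Dout;
  }
}

template <int DOUT>
static inline void convbw_run_fixed(const double* xsrc, double* dxdst,
                                    const double* dsrc, int nrun, int Din,
                                    const double* wt, double* dWt) {
  for (int r = 0; r < nrun; ++r) {
    for (int di = 0; di < Din; ++di) {
      const double xv = xsrc[di];
      const double* __restrict wcol = wt + (R_xlen_t)di * DOUT;
      double* __restrict dWcol = dWt + (R_xlen_t)di * DOUT;
      double acc = 0.0;
      for (int d = 0; d < DOUT; ++d) {
        const double g = dsrc[d];
        acc += wcol[d] * g;
        dWcol[d] += g * xv;
      }
      dxdst[di] += acc;
    }
    xsrc += Din;
    dxdst += Din;
    dsrc += DOUT;
  }
}

static inline void convbw_run_gen(const double* xsrc, double* dxdst,
                                  const double* dsrc, int nrun, int Din,
                                  int Dout, const double* wt, double* dWt) {
  for (int r = 0; r < nrun; ++r) {
    for (int di = 0; di < Din; ++di) {
      const double xv = xsrc[di];
      const double* __restrict wcol = wt + (R_xlen_t)di * Dout;
      double* __restrict dWcol = dWt + (R_xlen_t)di * Dout;
      double acc = 0.0;
      for (int d = 0; d < Dout; ++d) {
        const double g = dsrc[d];
        acc += wcol[d] * g;
        dWcol[d] += g * xv;
      }
      dxdst[di] += acc;
    }
    xsrc += Din;
    dxdst += Din;
    dsrc += Dout;
  }
}

// Direct (fused) same-padding 3x3 convolution: out = W (*) x + b, with
// W of shape Dout x (9*Din), tap layout column (kj*3+ki)*Din + di.
// [[Rcpp::export]]
NumericMatrix cpp_conv3_fw(const NumericMatrix& x, const NumericMatrix& Wm,
                           const NumericVector& bias, int H, int W, int B,
                           int dil) {
  const int Din = x.nrow();
  const int Dout = Wm.nrow();
  const int N = H * W;
  const int pad = dil;
  NumericMatrix out(Dout, (R_xlen_t)N * B);
  double* op = out.begin();
  const double* xp = x.begin();
  const double* wp0 = Wm.begin();
  const double* bp = bias.begin();
  for (R_xlen_t n = 0; n < (R_xlen_t)N * B; ++n)
    for (int d = 0; d < Dout; ++d) op[n * Dout + d] = bp[d];
  for (int b = 0; b < B; ++b) {
    const R_xlen_t off = (R_xlen_t)b * N;
    for (int kj = 0; kj < 3; ++kj) {
      for (int ki = 0; ki < 3; ++ki) {
        const int roff = ki * dil - pad;
        const int coff = kj * dil - pad;
        const int r0 = std::max(0, -roff), r1 = std::min(H, H - roff);
        const double* wt = wp0 + (R_xlen_t)(kj * 3 + ki) * Din * Dout;
        for (int c = 0; c < W; ++c) {
          const int cc = c + coff;
          if (cc < 0 || cc >= W) continue;
          const double* src = xp + (off + (R_xlen_t)cc * H + r0 + roff) * Din;
          double* dst = op + (off + (R_xlen_t)c * H + r0) * Dout;
          const int nrun = r1 - r0;
          switch (Dout) {
          case 2: conv_run_fixed<2>(src, dst, nrun, Din, wt); break;
          case 3: conv_run_fixed<3>(src, dst, nrun, Din, wt); break;
          case 4: conv_run_fixed<4>(src, dst, nrun, Din, wt); break;
          case 6: conv_run_fixed<6>(src, dst, nrun, Din, wt); break;
          case 8: conv_run_fixed<8>(src, dst, nrun, Din, wt); break;
          case 12: conv_run_fixed<12>(src, dst, nrun, Din, wt); break;
          case 16: conv_run_fixed<16>(src, dst, nrun, Din, wt); break;
          default: conv_run_gen(src, dst, nrun, Din, Dout, wt);
          }
        }
      }
    }
  }
  return out;
}

// Gradients of the fused 3x3 convolution: returns dW (Dout x 9*Din) and
// dx (Din x N*B); db is a simple row sum done by the caller.
// [[Rcpp::export]]
List cpp_conv3_bw(const NumericMatrix& dout, const NumericMatrix& x,
                  const NumericMatrix& Wm, int H, int W, int B, int dil) {
  const int Din = x.nrow();
  const int Dout = Wm.nrow();
  const int N = H * W;
  const int pad = dil;
  NumericMatrix dW(Dout, 9 * Din);
  NumericMatrix dx(Din, (R_xlen_t)N * B);
  const double* dop = dout.begin();
  const double* xp = x.begin();
  const double* wp0 = Wm.begin();
  double* dWp0 = dW.begin();
  double* dxp = dx.begin();
  for (int b = 0; b < B; ++b) {
    const R_xlen_t off = (R_xlen_t)b * N;
    for (int kj = 0; kj < 3; ++kj) {
      for (int ki = 0; ki < 3; ++ki) {
        const int roff = ki * dil - pad;
        const int coff = kj * dil - pad;
        const int r0 = std::max(0, -roff), r1 = std::min(H, H - roff);
        const double* wt = wp0 + (R_xlen_t)(kj * 3 + ki) * Din * Dout;
        double* dWt = dWp0 + (R_xlen_t)(kj * 3 + ki) * Din * Dout;
        for (int c = 0; c < W; ++c) {
          const int cc = c + coff;
          if (cc < 0 || cc >= W) continue;
          const double* xsrc = xp + (off + (R_xlen_t)cc * H + r0 + roff) * Din;
          double* dxdst = dxp + (off + (R_xlen_t)cc * H + r0 + roff) * Din;
          const double* dsrc = dop + (off + (R_xlen_t)c * H + r0) * Dout;
          const int nrun = r1 - r0;
          switch (Dout) {
          case 2: convbw_run_fixed<2>(xsrc, dxdst, dsrc, nrun, Din, wt, dWt); break;
          case 3: convbw_run_fixed<3>(xsrc, dxdst, dsrc, nrun, Din, wt, dWt); break;
          case 4: convbw_run_fixed<4>(xsrc, dxdst, dsrc, nrun, Din, wt, dWt); break;
          case 6: convbw_run_fixed<6>(xsrc, dxdst, dsrc, nrun, Din, wt, dWt); break;
          case 8: convbw_run_fixed<8>(xsrc, dxdst, dsrc, nrun, Din, wt, dWt); break;
          case 12: convbw_run_fixed<12>(xsrc, dxdst, dsrc, nrun, Din, wt, dWt); break;
          case 16: convbw_run_fixed<16>(xsrc, dxdst, dsrc, nrun, Din, wt, dWt); break;
          default: convbw_run_gen(xsrc, dxdst, dsrc, nrun, Din, Dout, wt, dWt);
          }
        }
      }
    }
  }
  return List::create(_["dW"] = dW, _["dx"] = dx);
}

// [[Rcpp::export]]
NumericMatrix cpp_im2col(const NumericMatrix& x, int H, int W, int B,
                         int k, int dil) {
  const int D = x.nrow();
  const int N = H * W;
  const int pad = dil * (k - 1) / 2;
  const int KR = D * k * k;
  NumericMatrix cols(KR, N * B);
  const double* xp = x.begin();
  double* cp = cols.begin();
  for (int b = 0; b < B; ++b) {
    const R_xlen_t off = (R_xlen_t)b * N;
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const int rowbase = (kj * k + ki) * D;
        const int roff = ki * dil - pad;
        const int coff = kj * dil - pad;
        const int r0 = std::max(0, -roff), r1 = std::min(H, H - roff);
        for (int c = 0; c < W; ++c) {
          const int cc = c + coff;
          if (cc < 0 || cc >= W) continue;
          const double* src = xp + (off + (R_xlen_t)cc * H + r0 + roff) * D;
          double* dst = cp + (off + (R_xlen_t)c * H + r0) * KR + rowbase;
          for (int r = r0; r < r1; ++r) {
            for (int d = 0; d < D; ++d) dst[d] = src[d];
            src += D;
            dst += KR;
          }
        }
      }
    }
  }
  return cols;
}

// [[Rcpp::export]]
NumericMatrix cpp_col2im(const NumericMatrix& cols, int D, int H, int W,
                         int B, int k, int dil) {
  const int N = H * W;
  const int pad = dil * (k - 1) / 2;
  const int KR = D * k * k;
  NumericMatrix x(D, (R_xlen_t)N * B);
  const double* cp = cols.begin();
  double* xp = x.begin();
  for (int b = 0; b < B; ++b) {
    const R_xlen_t off = (R_xlen_t)b * N;
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const int rowbase = (kj * k + ki) * D;
        const int roff = ki * dil - pad;
        const int coff = kj * dil - pad;
        const int r0 = std::max(0, -roff), r1 = std::min(H, H - roff);
        for (int c = 0; c < W; ++c) {
          const int cc = c + coff;
          if (cc < 0 || cc >= W) continue;
          double* dst = xp + (off + (R_xlen_t)cc * H + r0 + roff) * D;
          const double* src = cp + (off + (R_xlen_t)c * H + r0) * KR + rowbase;
          for (int r = r0; r < r1; ++r) {
            for (int d = 0; d < D; ++d) dst[d] += src[d];
            dst += D;
            src += KR;
          }
        }
      }
    }
  }
  return x;
}

// 2x2 max pooling, stride 2; H and W must be even.
// [[Rcpp::export]]
List cpp_maxpool_fw(const NumericMatrix& x, int H, int W, int B) {
  const int D = x.nrow();
  const int Ho = H / 2, Wo = W / 2;
  const int N = H * W, No = Ho * Wo;
  NumericMatrix out(D, No * B);
  IntegerMatrix idx(D, No * B);
  for (int b = 0; b < B; ++b) {
    for (int c = 0; c < Wo; ++c) {
      for (int r = 0; r < Ho; ++r) {
        const int oc = b * No + c * Ho + r;
        const int base = b * N + (2 * c) * H + 2 * r;
        const int cand[4] = { base, base + 1, base + H, base + H + 1 };
        for (int d = 0; d < D; ++d) {
          double best = x(d, cand[0]);
          int bi = cand[0];
          for (int t = 1; t < 4; ++t) {
            if (x(d, cand[t]) > best) { best = x(d, cand[t]); bi = cand[t]; }
          }
          out(d, oc) = best;
          idx(d, oc) = bi;
        }
      }
    }
  }
  return List::create(_["out"] = out, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericMatrix cpp_maxpool_bw(const NumericMatrix& g, const IntegerMatrix& idx,
                             int ncol_in) {
  const int D = g.nrow();
  NumericMatrix dx(D, ncol_in);
  for (int j = 0; j < g.ncol(); ++j)
    for (int d = 0; d < D; ++d)
      dx(d, idx(d, j)) += g(d, j);
  return dx;
}

static inline void bilin_coef(int i, int Hin, int Hout,
                              int& i0, int& i1, double& w1) {
  // half-pixel-centre mapping, clamped at borders
  double s = (i + 0.5) * (double)Hin / (double)Hout - 0.5;
  if (s < 0) s = 0;
  if (s > Hin - 1) s = Hin - 1;
  i0 = (int)std::floor(s);
  i1 = i0 + 1 < Hin ? i0 + 1 : i0;
  w1 = s - i0;
}

// [[Rcpp::export]]
NumericMatrix cpp_bilinear_fw(const NumericMatrix& x, int H, int W, int B,
                              int Ho, int Wo) {
  const int D = x.nrow();
  const int N = H * W, No = Ho * Wo;
  NumericMatrix out(D, No * B);
  std::vector<int> r0(Ho), r1(Ho), c0(Wo), c1(Wo);
  std::vector<double> wr(Ho), wc(Wo);
  for (int r = 0; r < Ho; ++r) bilin_coef(r, H, Ho, r0[r], r1[r], wr[r]);
  for (int c = 0; c < Wo; ++c) bilin_coef(c, W, Wo, c0[c], c1[c], wc[c]);
  for (int b = 0; b < B; ++b) {
    for (int c = 0; c < Wo; ++c) {
      for (int r = 0; r < Ho; ++r) {
        const int oc = b * No + c * Ho + r;
        const int p00 = b * N + c0[c] * H + r0[r];
        const int p10 = b * N + c0[c] * H + r1[r];
        const int p01 = b * N + c1[c] * H + r0[r];
        const int p11 = b * N + c1[c] * H + r1[r];
        const double w00 = (1 - wr[r]) * (1 - wc[c]);
        const double w10 = wr[r] * (1 - wc[c]);
        const double w01 = (1 - wr[r]) * wc[c];
        const double w11 = wr[r] * wc[c];
        for (int d = 0; d < D; ++d)
          out(d, oc) = w00 * x(d, p00) + w10 * x(d, p10) +
                       w01 * x(d, p01) + w11 * x(d, p11);
      }
    }
  }
  return out;
}

// Exact transpose of cpp_bilinear_fw.
// [[Rcpp::export]]
NumericMatrix cpp_bilinear_bw(const NumericMatrix& g, int H, int W, int B,
                              int Ho, int Wo) {
  const int D = g.nrow();
  const int N = H * W, No = Ho * Wo;
  NumericMatrix dx(D, N * B);
  std::vector<int> r0(Ho), r1(Ho), c0(Wo), c1(Wo);
  std::vector<double> wr(Ho), wc(Wo);
  for (int r = 0; r < Ho; ++r) bilin_coef(r, H, Ho, r0[r], r1[r], wr[r]);
  for (int c = 0; c < Wo; ++c) bilin_coef(c, W, Wo, c0[c], c1[c], wc[c]);
  for (int b = 0; b < B; ++b) {
    for (int c = 0; c < Wo; ++c) {
      for (int r = 0; r < Ho; ++r) {
        const int oc = b * No + c * Ho + r;
        const int p00 = b * N + c0[c] * H + r0[r];
        const int p10 = b * N + c0[c] * H + r1[r];
        const int p01 = b * N + c1[c] * H + r0[r];
        const int p11 = b * N + c1[c] * H + r1[r];
        const double w00 = (1 - wr[r]) * (1 - wc[c]);
        const double w10 = wr[r] * (1 - wc[c]);
        const double w01 = (1 - wr[r]) * wc[c];
        const double w11 = wr[r] * wc[c];
        for (int d = 0; d < D; ++d) {
          const double v = g(d, oc);
          dx(d, p00) += w00 * v;
          dx(d, p10) += w10 * v;
          dx(d, p01) += w01 * v;
          dx(d, p11) += w11 * v;
        }
      }
    }
  }
  return dx;
}
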