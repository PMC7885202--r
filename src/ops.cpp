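// Low-level feature-map kernels.
//
// All tensors are dense double arrays in R's column-major layout with
// dimensions (H, W, C, N): flat index h + H*(w + W*(c + C*n)).
// Convolution weights are (kh, kw, Cin/groups, Cout).
// Padding is always "same": Hout = ceil(H/stride), pad split evenly with the
// extra cell at the bottom/right (TensorFlow SAME convention).
//
// Full (groups == 1) convolutions run as im2col + BLAS dgemm with the patch
// matrix in (M x K) layout, M = Ho*Wo*N, K = C*kh*kw, so that both the patch
// build and the GEMM stream contiguously.  Depthwise/grouped convolutions
// use a direct shift-and-accumulate kernel (their arithmetic intensity is
// too low for im2col to pay off).  Batch norm, ReLU and the softmax-mixture
// reductions have single-pass kernels so the R layer stays allocation-light.

#define USE_FC_LEN_T
#include <Rcpp.h>
#include <R_ext/BLAS.h>
#include <algorithm>
#include <vector>
#ifndef FCONE
#define FCONE
#endif
using namespace Rcpp;

struct SameDims {
  int Ho, Wo, pt, pl;
};

static SameDims same_dims(int H, int W, int kh, int kw,
                          int sh, int sw, int dh, int dw) {
  SameDims d;
  d.Ho = (H + sh - 1) / sh;
  d.Wo = (W + sw - 1) / sw;
  int eh = (kh - 1) * dh + 1;
  int ew = (kw - 1) * dw + 1;
  int ph = std::max((d.Ho - 1) * sh + eh - H, 0);
  int pw = std::max((d.Wo - 1) * sw + ew - W, 0);
  d.pt = ph / 2;
  d.pl = pw / 2;
  return d;
}

// valid output range [ho0, ho1) for input offset `off`: hi = ho*s + off
static inline void valid_range(int off, int s, int H, int Ho,
                               int& ho0, int& ho1) {
  ho0 = off >= 0 ? 0 : (-off + s - 1) / s;
  int top = H - 1 - off;
  ho1 = top < 0 ? 0 : std::min(Ho, top / s + 1);
}

// ---- im2col (patch-major) ---------------------------------------------------

// PT is (M x K): PT[m + M*r], column index r = ki + kh*(kj + kw*ic) matching
// the column-major weight layout, row index m = ho + Ho*(wo + Wo*n).
static void im2col_pt(const double* xp, int H, int W, int C, int N,
                      int kh, int kw, int sh, int sw, int dh, int dw,
                      const SameDims& d, double* PT) {
  const int Ho = d.Ho, Wo = d.Wo;
  const size_t M = static_cast<size_t>(Ho) * Wo * N;
  for (int ic = 0; ic < C; ++ic) {
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const int r = ki + kh * (kj + kw * ic);
        double* Pr = PT + M * r;
        const int off = ki * dh - d.pt;
        int ho0, ho1;
        valid_range(off, sh, H, Ho, ho0, ho1);
        for (int n = 0; n < N; ++n) {
          const double* xch = xp + static_cast<size_t>(H) * W *
                                       (ic + static_cast<size_t>(C) * n);
          for (int wo = 0; wo < Wo; ++wo) {
            const int wi = wo * sw - d.pl + kj * dw;
            double* __restrict__ dst =
                Pr + static_cast<size_t>(Ho) * (wo + static_cast<size_t>(Wo) * n);
            if (wi < 0 || wi >= W) {
              std::fill(dst, dst + Ho, 0.0);
              continue;
            }
            std::fill(dst, dst + ho0, 0.0);
            std::fill(dst + ho1, dst + Ho, 0.0);
            const double* __restrict__ xi =
                xch + static_cast<size_t>(H) * wi + ho0 * sh + off;
            if (sh == 1) {
              for (int ho = ho0; ho < ho1; ++ho) dst[ho] = xi[ho - ho0];
            } else {
              for (int ho = ho0; ho < ho1; ++ho, xi += sh) dst[ho] = *xi;
            }
          }
        }
      }
    }
  }
}

// transpose of im2col_pt: scatter-add patch gradients into gx
static void col2im_pt_add(const double* PT, int H, int W, int C, int N,
                          int kh, int kw, int sh, int sw, int dh, int dw,
                          const SameDims& d, double* gxp) {
  const int Ho = d.Ho, Wo = d.Wo;
  const size_t M = static_cast<size_t>(Ho) * Wo * N;
  for (int ic = 0; ic < C; ++ic) {
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const int r = ki + kh * (kj + kw * ic);
        const double* Pr = PT + M * r;
        const int off = ki * dh - d.pt;
        int ho0, ho1;
        valid_range(off, sh, H, Ho, ho0, ho1);
        for (int n = 0; n < N; ++n) {
          double* gxch = gxp + static_cast<size_t>(H) * W *
                                   (ic + static_cast<size_t>(C) * n);
          for (int wo = 0; wo < Wo; ++wo) {
            const int wi = wo * sw - d.pl + kj * dw;
            if (wi < 0 || wi >= W) continue;
            double* __restrict__ gi =
                gxch + static_cast<size_t>(H) * wi + ho0 * sh + off;
            const double* __restrict__ src =
                Pr + ho0 + static_cast<size_t>(Ho) * (wo + static_cast<size_t>(Wo) * n);
            if (sh == 1) {
              for (int ho = ho0; ho < ho1; ++ho) gi[ho - ho0] += src[ho - ho0];
            } else {
              for (int ho = ho0; ho < ho1; ++ho, gi += sh) *gi += src[ho - ho0];
            }
          }
        }
      }
    }
  }
}

// ---- direct grouped/depthwise kernels ---------------------------------------

static void conv_fwd_direct(const double* xp, int H, int W, int C, int N,
                            const double* wp, int kh, int kw, int Cg, int Cout,
                            int sh, int sw, int dh, int dw, int groups,
                            const SameDims& d, double* yp) {
  const int Cout_g = Cout / groups;
  const int Ho = d.Ho, Wo = d.Wo;
  for (int n = 0; n < N; ++n) {
    for (int oc = 0; oc < Cout; ++oc) {
      const int ic0 = (oc / Cout_g) * Cg;
      double* yslab = yp + static_cast<size_t>(Ho) * Wo *
                               (oc + static_cast<size_t>(Cout) * n);
      for (int icl = 0; icl < Cg; ++icl) {
        const double* xch = xp + static_cast<size_t>(H) * W *
                                     ((ic0 + icl) + static_cast<size_t>(C) * n);
        const double* wch = wp + static_cast<size_t>(kh) * kw *
                                     (icl + static_cast<size_t>(Cg) * oc);
        for (int kj = 0; kj < kw; ++kj) {
          for (int wo = 0; wo < Wo; ++wo) {
            const int wi = wo * sw - d.pl + kj * dw;
            if (wi < 0 || wi >= W) continue;
            const double* xcol = xch + static_cast<size_t>(H) * wi;
            double* __restrict__ ycol = yslab + static_cast<size_t>(Ho) * wo;
            for (int ki = 0; ki < kh; ++ki) {
              const double wval = wch[ki + kh * kj];
              const int off = ki * dh - d.pt;
              int ho0, ho1;
              valid_range(off, sh, H, Ho, ho0, ho1);
              const double* __restrict__ xi = xcol + ho0 * sh + off;
              if (sh == 1) {
                for (int ho = ho0; ho < ho1; ++ho)
                  ycol[ho] += wval * xi[ho - ho0];
              } else {
                for (int ho = ho0; ho < ho1; ++ho, xi += sh)
                  ycol[ho] += wval * *xi;
              }
            }
          }
        }
      }
    }
  }
}

static void conv_bwd_direct(const double* xp, int H, int W, int C, int N,
                            const double* wp, int kh, int kw, int Cg, int Cout,
                            const double* gp,
                            int sh, int sw, int dh, int dw, int groups,
                            const SameDims& d, double* gxp, double* gwp,
                            bool need_gw) {
  const int Cout_g = Cout / groups;
  const int Ho = d.Ho, Wo = d.Wo;
  for (int n = 0; n < N; ++n) {
    for (int oc = 0; oc < Cout; ++oc) {
      const int ic0 = (oc / Cout_g) * Cg;
      const double* gslab = gp + static_cast<size_t>(Ho) * Wo *
                                     (oc + static_cast<size_t>(Cout) * n);
      for (int icl = 0; icl < Cg; ++icl) {
        const size_t choff = static_cast<size_t>(H) * W *
            ((ic0 + icl) + static_cast<size_t>(C) * n);
        const double* xch = xp + choff;
        double* gxch = gxp + choff;
        const size_t woff = static_cast<size_t>(kh) * kw *
            (icl + static_cast<size_t>(Cg) * oc);
        const double* wch = wp + woff;
        double* gwch = need_gw ? gwp + woff : nullptr;
        for (int kj = 0; kj < kw; ++kj) {
          for (int wo = 0; wo < Wo; ++wo) {
            const int wi = wo * sw - d.pl + kj * dw;
            if (wi < 0 || wi >= W) continue;
            const double* __restrict__ xcol = xch + static_cast<size_t>(H) * wi;
            double* __restrict__ gxcol = gxch + static_cast<size_t>(H) * wi;
            const double* __restrict__ gcol = gslab + static_cast<size_t>(Ho) * wo;
            for (int ki = 0; ki < kh; ++ki) {
              const double wval = wch[ki + kh * kj];
              const int off = ki * dh - d.pt;
              int ho0, ho1;
              valid_range(off, sh, H, Ho, ho0, ho1);
              double acc = 0.0;
              if (sh == 1) {
                double* __restrict__ gi = gxcol + off + ho0;
                const double* __restrict__ xi = xcol + off + ho0;
                const double* __restrict__ gc = gcol + ho0;
                const int len = ho1 - ho0;
                for (int t = 0; t < len; ++t) {
                  gi[t] += wval * gc[t];
                  acc += gc[t] * xi[t];
                }
              } else {
                int hi = ho0 * sh + off;
                for (int ho = ho0; ho < ho1; ++ho, hi += sh) {
                  const double g = gcol[ho];
                  gxcol[hi] += wval * g;
                  acc += g * xcol[hi];
                }
              }
              if (need_gw) gwch[ki + kh * kj] += acc;
            }
          }
        }
      }
    }
  }
}

// ---- exported convolution entry points --------------------------------------

// [[Rcpp::export(name = ".conv2d_fwd")]]
NumericVector conv2d_fwd(NumericVector x, IntegerVector xdim,
                         NumericVector wt, IntegerVector wdim,
                         int sh, int sw, int dh, int dw, int groups) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int kh = wdim[0], kw = wdim[1], Cg = wdim[2], Cout = wdim[3];
  if (C % groups != 0 || Cout % groups != 0 || Cg != C / groups)
    stop("inconsistent channel/group configuration");
  SameDims d = same_dims(H, W, kh, kw, sh, sw, dh, dw);
  const int Ho = d.Ho, Wo = d.Wo;
  NumericVector y(groups > 1
                      ? NumericVector(static_cast<R_xlen_t>(Ho) * Wo * Cout * N)
                      : NumericVector(no_init(static_cast<R_xlen_t>(Ho) * Wo * Cout * N)));
  if (groups > 1) {
    conv_fwd_direct(x.begin(), H, W, C, N, wt.begin(), kh, kw, Cg, Cout,
                    sh, sw, dh, dw, groups, d, y.begin());
  } else {
    int K = C * kh * kw;
    int M = Ho * Wo * N;
    int Cout_v = Cout;
    std::vector<double> PT(static_cast<size_t>(M) * K);
    std::vector<double> Yg(static_cast<size_t>(M) * Cout);
    im2col_pt(x.begin(), H, W, C, N, kh, kw, sh, sw, dh, dw, d, PT.data());
    const double one = 1.0, zero = 0.0;
    // Yg (M x Cout) = PT (M x K) * W (K x Cout)
    F77_CALL(dgemm)("N", "N", &M, &Cout_v, &K,
                    &one, PT.data(), &M, wt.begin(), &K,
                    &zero, Yg.data(), &M FCONE FCONE);
    // permute (hw-n major, oc minor) -> (Ho, Wo, Cout, N)
    const int HoWo = Ho * Wo;
    for (int oc = 0; oc < Cout; ++oc) {
      const double* src = Yg.data() + static_cast<size_t>(M) * oc;
      double* dst = y.begin() + static_cast<size_t>(HoWo) * oc;
      for (int n = 0; n < N; ++n)
        std::copy(src + static_cast<size_t>(HoWo) * n,
                  src + static_cast<size_t>(HoWo) * (n + 1),
                  dst + static_cast<size_t>(HoWo) * Cout * n);
    }
  }
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  return y;
}

// [[Rcpp::export(name = ".conv2d_bwd")]]
List conv2d_bwd(NumericVector x, IntegerVector xdim,
                NumericVector wt, IntegerVector wdim,
                NumericVector gy,
                int sh, int sw, int dh, int dw, int groups,
                bool need_gw) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int kh = wdim[0], kw = wdim[1], Cg = wdim[2], Cout = wdim[3];
  SameDims d = same_dims(H, W, kh, kw, sh, sw, dh, dw);
  const int Ho = d.Ho, Wo = d.Wo;
  NumericVector gx(x.size());
  NumericVector gw(need_gw ? wt.size() : 0);
  if (groups > 1) {
    conv_bwd_direct(x.begin(), H, W, C, N, wt.begin(), kh, kw, Cg, Cout,
                    gy.begin(), sh, sw, dh, dw, groups, d,
                    gx.begin(), need_gw ? gw.begin() : nullptr, need_gw);
  } else {
    int K = C * kh * kw;
    int M = Ho * Wo * N;
    int Cout_v = Cout;
    const int HoWo = Ho * Wo;
    std::vector<double> PT(static_cast<size_t>(M) * K);
    std::vector<double> G(static_cast<size_t>(M) * Cout);
    // gather gy into (hw-n major, oc minor) order
    for (int oc = 0; oc < Cout; ++oc) {
      const double* src = gy.begin() + static_cast<size_t>(HoWo) * oc;
      double* dst = G.data() + static_cast<size_t>(M) * oc;
      for (int n = 0; n < N; ++n)
        std::copy(src + static_cast<size_t>(HoWo) * Cout * n,
                  src + static_cast<size_t>(HoWo) * Cout * n + HoWo,
                  dst + static_cast<size_t>(HoWo) * n);
    }
    const double one = 1.0, zero = 0.0;
    if (need_gw) {
      im2col_pt(x.begin(), H, W, C, N, kh, kw, sh, sw, dh, dw, d, PT.data());
      // gW (K x Cout) = PT' (K x M) * G (M x Cout)
      F77_CALL(dgemm)("T", "N", &K, &Cout_v, &M, &one, PT.data(), &M,
                      G.data(), &M, &zero, gw.begin(), &K FCONE FCONE);
    }
    // gPT (M x K) = G (M x Cout) * W' (Cout x K), then scatter-add
    F77_CALL(dgemm)("N", "T", &M, &K, &Cout_v, &one, G.data(), &M,
                    wt.begin(), &K, &zero, PT.data(), &M FCONE FCONE);
    col2im_pt_add(PT.data(), H, W, C, N, kh, kw, sh, sw, dh, dw, d,
                  gx.begin());
  }
  gx.attr("dim") = xdim;
  if (need_gw) gw.attr("dim") = wdim;
  return List::create(_["gx"] = gx, _["gw"] = gw);
}

// ---- pooling ----------------------------------------------------------------

// [[Rcpp::export(name = ".maxpool_fwd")]]
NumericVector maxpool_fwd(NumericVector x, IntegerVector xdim, int k, int sh, int sw) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  SameDims d = same_dims(H, W, k, k, sh, sw, 1, 1);
  const int Ho = d.Ho, Wo = d.Wo;
  NumericVector y(no_init(static_cast<R_xlen_t>(Ho) * Wo * C * N));
  const double* xp = x.begin();
  double* yp = y.begin();
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const size_t xoff = static_cast<size_t>(H) * W * (c + static_cast<size_t>(C) * n);
      for (int wo = 0; wo < Wo; ++wo) {
        double* __restrict__ ycol = yp + static_cast<size_t>(Ho) *
            (wo + static_cast<size_t>(Wo) * (c + static_cast<size_t>(C) * n));
        std::fill(ycol, ycol + Ho, R_NegInf);
        for (int kj = 0; kj < k; ++kj) {
          const int wi = wo * sw - d.pl + kj;
          if (wi < 0 || wi >= W) continue;
          const double* xcol = xp + xoff + static_cast<size_t>(H) * wi;
          for (int ki = 0; ki < k; ++ki) {
            const int off = ki - d.pt;
            int ho0, ho1;
            valid_range(off, sh, H, Ho, ho0, ho1);
            const double* __restrict__ xi = xcol + ho0 * sh + off;
            if (sh == 1) {
              for (int ho = ho0; ho < ho1; ++ho)
                ycol[ho] = std::max(ycol[ho], xi[ho - ho0]);
            } else {
              for (int ho = ho0; ho < ho1; ++ho, xi += sh)
                ycol[ho] = std::max(ycol[ho], *xi);
            }
          }
        }
      }
    }
  }
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  return y;
}

// Routes each output gradient to the first window position (in kj-major,
// ki-minor scan order) whose input equals the pooled maximum.
// [[Rcpp::export(name = ".maxpool_bwd")]]
NumericVector maxpool_bwd(NumericVector x, IntegerVector xdim,
                          NumericVector y, NumericVector gy,
                          int k, int sh, int sw) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  SameDims d = same_dims(H, W, k, k, sh, sw, 1, 1);
  const int Ho = d.Ho, Wo = d.Wo;
  NumericVector gx(x.size());
  const double* xp = x.begin();
  const double* yp = y.begin();
  const double* gp = gy.begin();
  double* gxp = gx.begin();
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const size_t xoff = static_cast<size_t>(H) * W * (c + static_cast<size_t>(C) * n);
      for (int wo = 0; wo < Wo; ++wo) {
        const size_t ycoff = static_cast<size_t>(Ho) *
            (wo + static_cast<size_t>(Wo) * (c + static_cast<size_t>(C) * n));
        const double* __restrict__ ycol = yp + ycoff;
        const double* __restrict__ gcol = gp + ycoff;
        for (int ho = 0; ho < Ho; ++ho) {
          const double target = ycol[ho];
          bool done = false;
          for (int kj = 0; kj < k && !done; ++kj) {
            const int wi = wo * sw - d.pl + kj;
            if (wi < 0 || wi >= W) continue;
            for (int ki = 0; ki < k; ++ki) {
              const int hi = ho * sh - d.pt + ki;
              if (hi < 0 || hi >= H) continue;
              const size_t xi = xoff + hi + static_cast<size_t>(H) * wi;
              if (xp[xi] == target) { gxp[xi] += gcol[ho]; done = true; break; }
            }
          }
        }
      }
    }
  }
  gx.attr("dim") = xdim;
  return gx;
}

// [[Rcpp::export(name = ".avgpool_fwd")]]
NumericVector avgpool_fwd(NumericVector x, IntegerVector xdim, int k, int sh, int sw) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  SameDims d = same_dims(H, W, k, k, sh, sw, 1, 1);
  const int Ho = d.Ho, Wo = d.Wo;
  NumericVector y(static_cast<R_xlen_t>(Ho) * Wo * C * N);
  const double* xp = x.begin();
  double* yp = y.begin();
  // valid-count map per output position (shared by all channels/samples)
  std::vector<double> inv_cnt(static_cast<size_t>(Ho) * Wo);
  for (int wo = 0; wo < Wo; ++wo) {
    int cw = 0;
    for (int kj = 0; kj < k; ++kj) {
      const int wi = wo * sw - d.pl + kj;
      if (wi >= 0 && wi < W) ++cw;
    }
    for (int ho = 0; ho < Ho; ++ho) {
      int ch = 0;
      for (int ki = 0; ki < k; ++ki) {
        const int hi = ho * sh - d.pt + ki;
        if (hi >= 0 && hi < H) ++ch;
      }
      inv_cnt[ho + static_cast<size_t>(Ho) * wo] = 1.0 / (cw * ch);
    }
  }
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const size_t xoff = static_cast<size_t>(H) * W * (c + static_cast<size_t>(C) * n);
      for (int wo = 0; wo < Wo; ++wo) {
        double* __restrict__ ycol = yp + static_cast<size_t>(Ho) *
            (wo + static_cast<size_t>(Wo) * (c + static_cast<size_t>(C) * n));
        std::fill(ycol, ycol + Ho, 0.0);
        for (int kj = 0; kj < k; ++kj) {
          const int wi = wo * sw - d.pl + kj;
          if (wi < 0 || wi >= W) continue;
          const double* xcol = xp + xoff + static_cast<size_t>(H) * wi;
          for (int ki = 0; ki < k; ++ki) {
            const int off = ki - d.pt;
            int ho0, ho1;
            valid_range(off, sh, H, Ho, ho0, ho1);
            const double* __restrict__ xi = xcol + ho0 * sh + off;
            if (sh == 1) {
              for (int ho = ho0; ho < ho1; ++ho) ycol[ho] += xi[ho - ho0];
            } else {
              for (int ho = ho0; ho < ho1; ++ho, xi += sh) ycol[ho] += *xi;
            }
          }
        }
        const double* ic = inv_cnt.data() + static_cast<size_t>(Ho) * wo;
        for (int ho = 0; ho < Ho; ++ho) ycol[ho] *= ic[ho];
      }
    }
  }
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  return y;
}

// [[Rcpp::export(name = ".avgpool_bwd")]]
NumericVector avgpool_bwd(NumericVector gy, IntegerVector xdim, int k, int sh, int sw) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  SameDims d = same_dims(H, W, k, k, sh, sw, 1, 1);
  const int Ho = d.Ho, Wo = d.Wo;
  NumericVector gx(static_cast<R_xlen_t>(H) * W * C * N);
  const double* gp = gy.begin();
  double* gxp = gx.begin();
  std::vector<double> inv_cnt(static_cast<size_t>(Ho) * Wo);
  for (int wo = 0; wo < Wo; ++wo) {
    int cw = 0;
    for (int kj = 0; kj < k; ++kj) {
      const int wi = wo * sw - d.pl + kj;
      if (wi >= 0 && wi < W) ++cw;
    }
    for (int ho = 0; ho < Ho; ++ho) {
      int ch = 0;
      for (int ki = 0; ki < k; ++ki) {
        const int hi = ho * sh - d.pt + ki;
        if (hi >= 0 && hi < H) ++ch;
      }
      inv_cnt[ho + static_cast<size_t>(Ho) * wo] = 1.0 / (cw * ch);
    }
  }
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const size_t xoff = static_cast<size_t>(H) * W * (c + static_cast<size_t>(C) * n);
      for (int wo = 0; wo < Wo; ++wo) {
        const double* __restrict__ gcol = gp + static_cast<size_t>(Ho) *
            (wo + static_cast<size_t>(Wo) * (c + static_cast<size_t>(C) * n));
        const double* ic = inv_cnt.data() + static_cast<size_t>(Ho) * wo;
        for (int kj = 0; kj < k; ++kj) {
          const int wi = wo * sw - d.pl + kj;
          if (wi < 0 || wi >= W) continue;
          double* gxcol = gxp + xoff + static_cast<size_t>(H) * wi;
          for (int ki = 0; ki < k; ++ki) {
            const int off = ki - d.pt;
            int ho0, ho1;
            valid_range(off, sh, H, Ho, ho0, ho1);
            double* __restrict__ gi = gxcol + ho0 * sh + off;
            if (sh == 1) {
              for (int ho = ho0; ho < ho1; ++ho)
                gi[ho - ho0] += gcol[ho] * ic[ho];
            } else {
              for (int ho = ho0; ho < ho1; ++ho, gi += sh)
                *gi += gcol[ho] * ic[ho];
            }
          }
        }
      }
    }
  }
  gx.attr("dim") = xdim;
  return gx;
}

// ---- batch norm -------------------------------------------------------------

// train mode: batch statistics; eval mode: supplied running statistics.
// Returns y plus the per-channel mean/var actually used.
// [[Rcpp::export(name = ".bn_fwd")]]
List bn_fwd(NumericVector x, IntegerVector xdim,
            NumericVector gamma, NumericVector beta,
            NumericVector mean_in, NumericVector var_in,
            bool train, double eps) {
  const int HW = xdim[0] * xdim[1], C = xdim[2], N = xdim[3];
  const double m = static_cast<double>(HW) * N;
  NumericVector y(no_init(x.size()));
  NumericVector mu(C), var(C);
  const double* xp = x.begin();
  double* yp = y.begin();
  for (int c = 0; c < C; ++c) {
    if (train) {
      double s = 0.0, s2 = 0.0;
      for (int n = 0; n < N; ++n) {
        const double* __restrict__ xc =
            xp + static_cast<size_t>(HW) * (c + static_cast<size_t>(C) * n);
        for (int i = 0; i < HW; ++i) { s += xc[i]; s2 += xc[i] * xc[i]; }
      }
      mu[c] = s / m;
      var[c] = std::max(s2 / m - mu[c] * mu[c], 0.0);
    } else {
      mu[c] = mean_in[c];
      var[c] = var_in[c];
    }
    const double a = gamma[c] / std::sqrt(var[c] + eps);
    const double b = beta[c] - a * mu[c];
    for (int n = 0; n < N; ++n) {
      const size_t off = static_cast<size_t>(HW) * (c + static_cast<size_t>(C) * n);
      const double* __restrict__ xc = xp + off;
      double* __restrict__ yc = yp + off;
      for (int i = 0; i < HW; ++i) yc[i] = a * xc[i] + b;
    }
  }
  y.attr("dim") = xdim;
  return List::create(_["y"] = y, _["mean"] = mu, _["var"] = var);
}

// [[Rcpp::export(name = ".bn_bwd")]]
List bn_bwd(NumericVector x, IntegerVector xdim, NumericVector gy,
            NumericVector gamma, NumericVector mu, NumericVector var,
            bool train, double eps, double gscale) {
  const int HW = xdim[0] * xdim[1], C = xdim[2], N = xdim[3];
  const double m = static_cast<double>(HW) * N;
  NumericVector gx(no_init(x.size()));
  NumericVector ggamma(C), gbeta(C);
  const double* xp = x.begin();
  const double* gp = gy.begin();
  double* gxp = gx.begin();
  for (int c = 0; c < C; ++c) {
    const double inv = 1.0 / std::sqrt(var[c] + eps);
    double sg = 0.0, sgx = 0.0;
    for (int n = 0; n < N; ++n) {
      const size_t off = static_cast<size_t>(HW) * (c + static_cast<size_t>(C) * n);
      const double* __restrict__ xc = xp + off;
      const double* __restrict__ gc = gp + off;
      for (int i = 0; i < HW; ++i) {
        sg += gc[i];
        sgx += gc[i] * (xc[i] - mu[c]);
      }
    }
    sg *= gscale;
    sgx *= inv * gscale;
    gbeta[c] = sg;
    ggamma[c] = sgx;
    const double a = gamma[c] * inv * gscale;
    if (train) {
      const double t1 = sg / (m * gscale), t2 = sgx / (m * gscale);
      for (int n = 0; n < N; ++n) {
        const size_t off = static_cast<size_t>(HW) * (c + static_cast<size_t>(C) * n);
        const double* __restrict__ xc = xp + off;
        const double* __restrict__ gc = gp + off;
        double* __restrict__ gxc = gxp + off;
        for (int i = 0; i < HW; ++i)
          gxc[i] = a * (gc[i] - t1 - (xc[i] - mu[c]) * inv * t2);
      }
    } else {
      for (int n = 0; n < N; ++n) {
        const size_t off = static_cast<size_t>(HW) * (c + static_cast<size_t>(C) * n);
        const double* __restrict__ gc = gp + off;
        double* __restrict__ gxc = gxp + off;
        for (int i = 0; i < HW; ++i) gxc[i] = a * gc[i];
      }
    }
  }
  gx.attr("dim") = xdim;
  return List::create(_["gx"] = gx, _["ggamma"] = ggamma, _["gbeta"] = gbeta);
}

// ---- elementwise helpers ----------------------------------------------------

// [[Rcpp::export(name = ".relu_fwd")]]
NumericVector relu_fwd(NumericVector x) {
  NumericVector y(no_init(x.size()));
  const double* __restrict__ xp = x.begin();
  double* __restrict__ yp = y.begin();
  for (R_xlen_t i = 0; i < x.size(); ++i) yp[i] = std::max(xp[i], 0.0);
  y.attr("dim") = x.attr("dim");
  return y;
}

// gradient masked by the forward output (y > 0 <=> x > 0)
// [[Rcpp::export(name = ".relu_bwd")]]
NumericVector relu_bwd(NumericVector y, NumericVector gy) {
  NumericVector gx(no_init(y.size()));
  const double* __restrict__ yp = y.begin();
  const double* __restrict__ gp = gy.begin();
  double* __restrict__ gxp = gx.begin();
  for (R_xlen_t i = 0; i < y.size(); ++i) gxp[i] = yp[i] > 0 ? gp[i] : 0.0;
  gx.attr("dim") = gy.attr("dim");
  return gx;
}

// weighted sum of equal-shaped arrays: sum_i w[i] * xs[[i]]
// [[Rcpp::export(name = ".wsum")]]
NumericVector wsum(List xs, NumericVector w) {
  NumericVector x0 = xs[0];
  NumericVector y(no_init(x0.size()));
  double* __restrict__ yp = y.begin();
  bool first = true;
  for (int j = 0; j < xs.size(); ++j) {
    NumericVector xj = xs[j];
    if (xj.size() != y.size()) stop("wsum: shape mismatch");
    const double wj = w[j];
    const double* __restrict__ xp = xj.begin();
    if (first) {
      if (wj == 1.0) {
        std::copy(xp, xp + y.size(), yp);
      } else {
        for (R_xlen_t i = 0; i < y.size(); ++i) yp[i] = wj * xp[i];
      }
      first = false;
      continue;
    }
    if (wj == 0.0) continue;
    if (wj == 1.0) {
      for (R_xlen_t i = 0; i < y.size(); ++i) yp[i] += xp[i];
    } else {
      for (R_xlen_t i = 0; i < y.size(); ++i) yp[i] += wj * xp[i];
    }
  }
  y.attr("dim") = x0.attr("dim");
  return y;
}

// per-array inner products with a common gradient: out[j] = sum(g * xs[[j]])
// [[Rcpp::export(name = ".dots")]]
NumericVector dots(NumericVector g, List xs) {
  NumericVector out(xs.size());
  const double* __restrict__ gp = g.begin();
  for (int j = 0; j < xs.size(); ++j) {
    NumericVector xj = xs[j];
    if (xj.size() != g.size()) stop("dots: shape mismatch");
    const double* __restrict__ xp = xj.begin();
    double acc = 0.0;
    for (R_xlen_t i = 0; i < g.size(); ++i) acc += gp[i] * xp[i];
    out[j] = acc;
  }
  return out;
}

// [[Rcpp::export(name = ".scale_arr")]]
NumericVector scale_arr(NumericVector x, double s) {
  NumericVector y(no_init(x.size()));
  const double* __restrict__ xp = x.begin();
  double* __restrict__ yp = y.begin();
  for (R_xlen_t i = 0; i < x.size(); ++i) yp[i] = s * xp[i];
  y.attr("dim") = x.attr("dim");
  return y;
}
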