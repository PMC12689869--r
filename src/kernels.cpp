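#include <Rcpp.h>
#include <cmath>
#include <limits>
#include <vector>

using namespace Rcpp;

// Tensors use an (H, W, C, N) column-major layout throughout the package:
// the spatial height index runs fastest, which makes im2col columns
// contiguous per output pixel and lets convolution reduce to one GEMM.

// Unfold a batch of feature maps into the im2col matrix for a stride-1
// convolution with symmetric zero padding `ph`/`pw` and dilation `dh`/`dw`.
// Output: (kh*kw*C) x (H*W*N); row order is (kh fastest, then kw, then c),
// matching the column-major flattening of a (kh, kw, C, Cout) weight array.
// [[Rcpp::export]]
NumericMatrix im2col_cpp(NumericVector x, int H, int W, int C, int N,
                         int kh, int kw, int ph, int pw, int dh, int dw) {
  const int K = kh * kw * C;
  const int HW = H * W;
  NumericMatrix out(K, HW * N);
  const double *xp = x.begin();
  double *op = out.begin();
  for (int n = 0; n < N; ++n) {
    const double *xn = xp + (R_xlen_t)n * HW * C;
    for (int wo = 0; wo < W; ++wo) {
      for (int ho = 0; ho < H; ++ho) {
        double *col = op + (R_xlen_t)(n * HW + wo * H + ho) * K;
        for (int c = 0; c < C; ++c) {
          const double *xc = xn + (R_xlen_t)c * HW;
          for (int kj = 0; kj < kw; ++kj) {
            int wi = wo - pw + kj * dw;
            if (wi < 0 || wi >= W) {
              for (int ki = 0; ki < kh; ++ki)
                col[c * kh * kw + kj * kh + ki] = 0.0;
              continue;
            }
            const double *xw = xc + (R_xlen_t)wi * H;
            for (int ki = 0; ki < kh; ++ki) {
              int hi = ho - ph + ki * dh;
              col[c * kh * kw + kj * kh + ki] =
                  (hi < 0 || hi >= H) ? 0.0 : xw[hi];
            }
          }
        }
      }
    }
  }
  return out;
}

// Adjoint of im2col_cpp: scatter-add a column matrix back onto the padded
// input grid. Used for the convolution input gradient.
// [[Rcpp::export]]
NumericVector col2im_cpp(NumericMatrix col, int H, int W, int C, int N,
                         int kh, int kw, int ph, int pw, int dh, int dw) {
  const int K = kh * kw * C;
  const int HW = H * W;
  NumericVector out((R_xlen_t)HW * C * N);
  double *op = out.begin();
  const double *cp = col.begin();
  for (int n = 0; n < N; ++n) {
    double *xn = op + (R_xlen_t)n * HW * C;
    for (int wo = 0; wo < W; ++wo) {
      for (int ho = 0; ho < H; ++ho) {
        const double *cc = cp + (R_xlen_t)(n * HW + wo * H + ho) * K;
        for (int c = 0; c < C; ++c) {
          double *xc = xn + (R_xlen_t)c * HW;
          for (int kj = 0; kj < kw; ++kj) {
            int wi = wo - pw + kj * dw;
            if (wi < 0 || wi >= W) continue;
            double *xw = xc + (R_xlen_t)wi * H;
            for (int ki = 0; ki < kh; ++ki) {
              int hi = ho - ph + ki * dh;
              if (hi < 0 || hi >= H) continue;
              xw[hi] += cc[c * kh * kw + kj * kh + ki];
            }
          }
        }
      }
    }
  }
  return out;
}

// One-dimensional squared distance transform (lower envelope of parabolas,
// Felzenszwalb & Huttenlocher) with physical sample positions i * s.
static void dt1d(const double *f, double *d, int n, double s) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double xq = q * s;
    double fq = f[q];
    while (true) {
      double xv = v[k] * s;
      double sden = 2.0 * (xq - xv);
      double sp = (fq + xq * xq - (f[v[k]] + xv * xv)) / sden;
      if (sp <= z[k]) {
        --k;
      } else {
        ++k;
        v[k] = q;
        z[k] = sp;
        z[k + 1] = std::numeric_limits<double>::infinity();
        break;
      }
    }
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double xq = q * s;
    while (z[k + 1] < xq) ++k;
    double xv = v[k] * s;
    d[q] = (xq - xv) * (xq - xv) + f[v[k]];
  }
}

// Exact Euclidean distance (in physical units) from every voxel to the
// nearest TRUE voxel of a 3D mask with anisotropic spacing. 2D masks pass
// D = 1. Returns +Inf everywhere when the mask is empty.
// [[Rcpp::export]]
NumericVector edt_cpp(LogicalVector mask, int H, int W, int D,
                      NumericVector spacing) {
  // A large finite stand-in for +Inf keeps the parabola intersections
  // well-defined on lines that mix reached and unreached samples.
  const double INF = 1e15;
  R_xlen_t len = (R_xlen_t)H * W * D;
  bool nonempty = false;
  std::vector<double> f(len);
  for (R_xlen_t i = 0; i < len; ++i) {
    f[i] = mask[i] ? 0.0 : INF;
    if (mask[i]) nonempty = true;
  }
  if (!nonempty) {
    NumericVector out(len);
    for (R_xlen_t i = 0; i < len; ++i) out[i] = R_PosInf;
    return out;
  }

  std::vector<double> line, dist;
  // axis 1 (H, stride 1)
  line.resize(H); dist.resize(H);
  for (int d3 = 0; d3 < D; ++d3)
    for (int w = 0; w < W; ++w) {
      double *base = f.data() + (R_xlen_t)(d3 * W + w) * H;
      bool any = false;
      for (int h = 0; h < H; ++h) { line[h] = base[h]; if (base[h] < INF) any = true; }
      if (!any) continue;
      dt1d(line.data(), dist.data(), H, spacing[0]);
      for (int h = 0; h < H; ++h) base[h] = dist[h];
    }
  // axis 2 (W, stride H)
  line.resize(W); dist.resize(W);
  for (int d3 = 0; d3 < D; ++d3)
    for (int h = 0; h < H; ++h) {
      double *base = f.data() + (R_xlen_t)d3 * W * H + h;
      bool any = false;
      for (int w = 0; w < W; ++w) { line[w] = base[(R_xlen_t)w * H]; if (line[w] < INF) any = true; }
      if (!any) continue;
      dt1d(line.data(), dist.data(), W, spacing[1]);
      for (int w = 0; w < W; ++w) base[(R_xlen_t)w * H] = dist[w];
    }
  // axis 3 (D, stride H*W)
  if (D > 1) {
    line.resize(D); dist.resize(D);
    for (int w = 0; w < W; ++w)
      for (int h = 0; h < H; ++h) {
        double *base = f.data() + (R_xlen_t)w * H + h;
        bool any = false;
        for (int d3 = 0; d3 < D; ++d3) { line[d3] = base[(R_xlen_t)d3 * W * H]; if (line[d3] < INF) any = true; }
        if (!any) continue;
        dt1d(line.data(), dist.data(), D, spacing[2]);
        for (int d3 = 0; d3 < D; ++d3) base[(R_xlen_t)d3 * W * H] = dist[d3];
      }
  }
  NumericVector out(len);
  for (R_xlen_t i = 0; i < len; ++i) out[i] = std::sqrt(f[i]);
  return out;
}

#define USE_FC_LEN_T
#include <Rconfig.h>
#include <R_ext/BLAS.h>
#ifndef FCONE
#define FCONE
#endif

// Fused convolution forward: im2col + GEMM, writing the output directly in
// (H, W, Cout, N) order. Returns list(y, col); `col` is reused by the
// backward pass.
// [[Rcpp::export]]
List conv_fwd_cpp(NumericVector x, NumericVector w, int H, int W, int C,
                  int N, int kh, int kw, int cout, int pad, int dil) {
  NumericMatrix col = im2col_cpp(x, H, W, C, N, kh, kw, pad, pad, dil, dil);
  const int K = kh * kw * C;
  const int HW = H * W;
  const R_xlen_t M = (R_xlen_t)HW * N;
  // ym (cout x M) = t(wm) %*% col, wm is (K x cout)
  std::vector<double> ym((size_t)cout * M);
  {
    const double one = 1.0, zero = 0.0;
    const int m = cout, n = (int)M, k = K;
    F77_CALL(dgemm)("T", "N", &m, &n, &k, &one, w.begin(), &k, col.begin(),
                    &k, &zero, ym.data(), &m FCONE FCONE);
  }
  NumericVector y((R_xlen_t)HW * cout * N);
  double *yp = y.begin();
  for (int nn = 0; nn < N; ++nn)
    for (int c = 0; c < cout; ++c) {
      double *dst = yp + ((R_xlen_t)nn * cout + c) * HW;
      const double *src = ym.data() + (R_xlen_t)nn * HW * cout + c;
      for (int i = 0; i < HW; ++i) dst[i] = src[(R_xlen_t)i * cout];
    }
  return List::create(_["y"] = y, _["col"] = col);
}

// Convolution backward: given the cached column matrix, the kernel and the
// output gradient (H, W, Cout, N), returns dx and dw.
// [[Rcpp::export]]
List conv_bwd_cpp(NumericMatrix col, NumericVector w, NumericVector g, int H,
                  int W, int C, int N, int kh, int kw, int cout, int pad,
                  int dil) {
  const int K = kh * kw * C;
  const int HW = H * W;
  const R_xlen_t M = (R_xlen_t)HW * N;
  // reorder g (H,W,Cout,N) -> gm (cout x M)
  std::vector<double> gm((size_t)cout * M);
  const double *gp = g.begin();
  for (int nn = 0; nn < N; ++nn)
    for (int c = 0; c < cout; ++c) {
      const double *src = gp + ((R_xlen_t)nn * cout + c) * HW;
      double *dst = gm.data() + (R_xlen_t)nn * HW * cout + c;
      for (int i = 0; i < HW; ++i) dst[(R_xlen_t)i * cout] = src[i];
    }
  const double one = 1.0, zero = 0.0;
  // dw (K x cout) = col %*% t(gm)
  NumericVector dw((R_xlen_t)K * cout);
  {
    const int m = K, n = cout, k = (int)M;
    F77_CALL(dgemm)("N", "T", &m, &n, &k, &one, col.begin(), &m, gm.data(),
                    &n, &zero, dw.begin(), &m FCONE FCONE);
  }
  // dcol (K x M) = wm %*% gm
  NumericMatrix dcol(K, (int)M);
  {
    const int m = K, n = (int)M, k = cout;
    F77_CALL(dgemm)("N", "N", &m, &n, &k, &one, w.begin(), &m, gm.data(), &k,
                    &zero, dcol.begin(), &m FCONE FCONE);
  }
  NumericVector dx = col2im_cpp(dcol, H, W, C, N, kh, kw, pad, pad, dil, dil);
  return List::create(_["dx"] = dx, _["dw"] = dw);
}

// 1x1 convolution fast path: per-sample GEMM on the (H*W, C) slab, no
// im2col. y[(hw), cout, n] = x[(hw), c, n] %*% w[c, cout].
// [[Rcpp::export]]
NumericVector conv1x1_fwd_cpp(NumericVector x, NumericVector w, int H, int W,
                              int C, int N, int cout) {
  const int HW = H * W;
  NumericVector y((R_xlen_t)HW * cout * N);
  const double one = 1.0, zero = 0.0;
  for (int n = 0; n < N; ++n) {
    const int m = HW, nn = cout, k = C;
    F77_CALL(dgemm)("N", "N", &m, &nn, &k, &one,
                    x.begin() + (R_xlen_t)n * HW * C, &m, w.begin(), &k,
                    &zero, y.begin() + (R_xlen_t)n * HW * cout, &m FCONE FCONE);
  }
  return y;
}

// Backward of the 1x1 fast path: dx = g %*% t(w); dw = sum_n t(x_n) %*% g_n.
// [[Rcpp::export]]
List conv1x1_bwd_cpp(NumericVector x, NumericVector w, NumericVector g, int H,
                     int W, int C, int N, int cout) {
  const int HW = H * W;
  NumericVector dx((R_xlen_t)HW * C * N);
  NumericVector dw((R_xlen_t)C * cout);
  const double one = 1.0, zero = 0.0;
  for (int n = 0; n < N; ++n) {
    {
      const int m = HW, nn = C, k = cout;
      F77_CALL(dgemm)("N", "T", &m, &nn, &k, &one,
                      g.begin() + (R_xlen_t)n * HW * cout, &m, w.begin(), &nn,
                      &zero, dx.begin() + (R_xlen_t)n * HW * C, &m FCONE FCONE);
    }
    {
      const int m = C, nn = cout, k = HW;
      const double beta = (n == 0) ? 0.0 : 1.0;
      F77_CALL(dgemm)("T", "N", &m, &nn, &k, &one,
                      x.begin() + (R_xlen_t)n * HW * C, &k,
                      g.begin() + (R_xlen_t)n * HW * cout, &k, &beta,
                      dw.begin(), &m FCONE FCONE);
    }
  }
  (void)zero;
  return List::create(_["dx"] = dx, _["dw"] = dw);
}

// Direct (no-im2col) stride-1 convolution: shifted column-wise fused
// multiply-adds. Lower memory traffic than the im2col route, which matters
// on the single-core CPU budget this package targets.
static void direct_conv_accum(const double *x, const double *w, double *y,
                              int H, int W, int C, int N, int kh, int kw,
                              int cout, int pad, int dil) {
  const int HW = H * W;
  for (int n = 0; n < N; ++n) {
    const double *xn = x + (R_xlen_t)n * HW * C;
    double *yn = y + (R_xlen_t)n * HW * cout;
    for (int co = 0; co < cout; ++co) {
      double *ys = yn + (R_xlen_t)co * HW;
      for (int ci = 0; ci < C; ++ci) {
        const double *xs = xn + (R_xlen_t)ci * HW;
        for (int kj = 0; kj < kw; ++kj) {
          const int wioff = -pad + kj * dil;
          const int wo_lo = std::max(0, -wioff);
          const int wo_hi = std::min(W, W - wioff);
          for (int ki = 0; ki < kh; ++ki) {
            const int hioff = -pad + ki * dil;
            const double wv = w[ki + kh * (kj + kw * (ci + (R_xlen_t)C * co))];
            if (wv == 0.0) continue;
            const int ho_lo = std::max(0, -hioff);
            const int ho_hi = std::min(H, H - hioff);
            for (int wo = wo_lo; wo < wo_hi; ++wo) {
              const double *xc = xs + (R_xlen_t)(wo + wioff) * H + hioff;
              double *yc = ys + (R_xlen_t)wo * H;
              for (int ho = ho_lo; ho < ho_hi; ++ho) yc[ho] += wv * xc[ho];
            }
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector direct_conv_fwd_cpp(NumericVector x, NumericVector w, int H,
                                  int W, int C, int N, int kh, int kw,
                                  int cout, int pad, int dil) {
  NumericVector y((R_xlen_t)H * W * cout * N);
  direct_conv_accum(x.begin(), w.begin(), y.begin(), H, W, C, N, kh, kw,
                    cout, pad, dil);
  return y;
}

// Backward of the direct convolution: dx via the adjoint (flipped kernel
// with swapped channel roles; same padding because pad = dil*(k-1)/2 for odd
// kernels), dw via windowed dot products.
// [[Rcpp::export]]
List direct_conv_bwd_cpp(NumericVector x, NumericVector w, NumericVector g,
                         int H, int W, int C, int N, int kh, int kw, int cout,
                         int pad, int dil) {
  const int HW = H * W;
  // flipped/transposed kernel: wf[ki,kj,co,ci] = w[kh-1-ki, kw-1-kj, ci, co]
  std::vector<double> wf((size_t)kh * kw * cout * C);
  for (int co = 0; co < cout; ++co)
    for (int ci = 0; ci < C; ++ci)
      for (int kj = 0; kj < kw; ++kj)
        for (int ki = 0; ki < kh; ++ki)
          wf[(kh - 1 - ki) + kh * ((kw - 1 - kj) + kw * (co + (R_xlen_t)cout * ci))] =
              w[ki + kh * (kj + kw * (ci + (R_xlen_t)C * co))];
  NumericVector dx((R_xlen_t)HW * C * N);
  direct_conv_accum(g.begin(), wf.data(), dx.begin(), H, W, cout, N, kh, kw,
                    C, pad, dil);
  NumericVector dw((R_xlen_t)kh * kw * C * cout);
  double *dwp = dw.begin();
  const double *xp = x.begin();
  const double *gp = g.begin();
  for (int n = 0; n < N; ++n) {
    const double *xn = xp + (R_xlen_t)n * HW * C;
    const double *gn = gp + (R_xlen_t)n * HW * cout;
    for (int co = 0; co < cout; ++co) {
      const double *gs = gn + (R_xlen_t)co * HW;
      for (int ci = 0; ci < C; ++ci) {
        const double *xs = xn + (R_xlen_t)ci * HW;
        for (int kj = 0; kj < kw; ++kj) {
          const int wioff = -pad + kj * dil;
          const int wo_lo = std::max(0, -wioff);
          const int wo_hi = std::min(W, W - wioff);
          for (int ki = 0; ki < kh; ++ki) {
            const int hioff = -pad + ki * dil;
            const int ho_lo = std::max(0, -hioff);
            const int ho_hi = std::min(H, H - hioff);
            double acc = 0.0;
            for (int wo = wo_lo; wo < wo_hi; ++wo) {
              const double *xc = xs + (R_xlen_t)(wo + wioff) * H + hioff;
              const double *gc = gs + (R_xlen_t)wo * H;
              for (int ho = ho_lo; ho < ho_hi; ++ho) acc += xc[ho] * gc[ho];
            }
            dwp[ki + kh * (kj + kw * (ci + (R_xlen_t)C * co))] += acc;
          }
        }
      }
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw);
}
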