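#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Array layout convention shared with the R side: feature maps are numeric
// arrays [H, W, C, N] in R's column-major order, so
// index(h, w, c, n) = h + H*(w + W*(c + C*n)).

// im2col: unfold k x k patches (stride `stride`, zero padding padTop/padLeft)
// into a matrix with rows indexed by (oh, ow, n) (oh fastest, n slowest) and
// columns indexed by (kh, kw, c).
// [[Rcpp::export]]
NumericMatrix im2col_cpp(NumericVector x, int H, int W, int C, int N,
                         int k, int stride, int padTop, int padLeft,
                         int outH, int outW) {
  NumericMatrix out(outH * outW * N, k * k * C);
  const double *px = x.begin();
  double *po = out.begin();
  const R_xlen_t nrow = (R_xlen_t)outH * outW * N;
  for (int c = 0; c < C; ++c) {
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh) {
        const R_xlen_t col = kh + (R_xlen_t)k * (kw + (R_xlen_t)k * c);
        double *dst = po + col * nrow;
        for (int n = 0; n < N; ++n) {
          const R_xlen_t base_in = ((R_xlen_t)n * C + c) * W;
          for (int ow = 0; ow < outW; ++ow) {
            const int iw = ow * stride - padLeft + kw;
            const bool wok = (iw >= 0 && iw < W);
            const double *src = wok ? px + (base_in + iw) * H : NULL;
            R_xlen_t r = (R_xlen_t)outH * (ow + (R_xlen_t)outW * n);
            for (int oh = 0; oh < outH; ++oh, ++r) {
              const int ih = oh * stride - padTop + kh;
              dst[r] = (wok && ih >= 0 && ih < H) ? src[ih] : 0.0;
            }
          }
        }
      }
    }
  }
  return out;
}

// col2im: adjoint of im2col; scatter-add patch-gradient columns back to the
// input gradient array [H, W, C, N].
// [[Rcpp::export]]
NumericVector col2im_cpp(NumericMatrix cols, int H, int W, int C, int N,
                         int k, int stride, int padTop, int padLeft,
                         int outH, int outW) {
  NumericVector dx((R_xlen_t)H * W * C * N);
  const double *pc = cols.begin();
  double *pdx = dx.begin();
  const R_xlen_t nrow = (R_xlen_t)outH * outW * N;
  for (int c = 0; c < C; ++c) {
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh) {
        const R_xlen_t col = kh + (R_xlen_t)k * (kw + (R_xlen_t)k * c);
        const double *src = pc + col * nrow;
        for (int n = 0; n < N; ++n) {
          const R_xlen_t base_in = ((R_xlen_t)n * C + c) * W;
          for (int ow = 0; ow < outW; ++ow) {
            const int iw = ow * stride - padLeft + kw;
            if (iw < 0 || iw >= W) continue;
            double *dst = pdx + (base_in + iw) * H;
            R_xlen_t r = (R_xlen_t)outH * (ow + (R_xlen_t)outW * n);
            for (int oh = 0; oh < outH; ++oh, ++r) {
              const int ih = oh * stride - padTop + kh;
              if (ih >= 0 && ih < H) dst[ih] += src[r];
            }
          }
        }
      }
    }
  }
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  return dx;
}

// Depthwise convolution, stride 1, odd kernel k, "same" zero padding.
// x [H,W,C,N], w [k,k,C], b [C] -> out [H,W,C,N]
// [[Rcpp::export]]
NumericVector depthwise_forward_cpp(NumericVector x, int H, int W, int C,
                                    int N, NumericVector w, NumericVector b,
                                    int k) {
  const int p = k / 2;
  NumericVector out((R_xlen_t)H * W * C * N);
  const double *px = x.begin(), *pw = w.begin(), *pb = b.begin();
  double *po = out.begin();
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double *xin = px + ((R_xlen_t)n * C + c) * W * H;
      double *xout = po + ((R_xlen_t)n * C + c) * W * H;
      const double *wc = pw + (R_xlen_t)k * k * c;
      const double bias = pb[c];
      for (int ow = 0; ow < W; ++ow) {
        for (int oh = 0; oh < H; ++oh) {
          double acc = bias;
          for (int kw = 0; kw < k; ++kw) {
            const int iw = ow - p + kw;
            if (iw < 0 || iw >= W) continue;
            for (int kh = 0; kh < k; ++kh) {
              const int ih = oh - p + kh;
              if (ih < 0 || ih >= H) continue;
              acc += xin[ih + (R_xlen_t)iw * H] * wc[kh + k * kw];
            }
          }
          xout[oh + (R_xlen_t)ow * H] = acc;
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(H, W, C, N);
  return out;
}

// Backward pass of the depthwise convolution above.
// [[Rcpp::export]]
List depthwise_backward_cpp(NumericVector x, NumericVector w, NumericVector dout,
                            int H, int W, int C, int N, int k) {
  const int p = k / 2;
  NumericVector dx((R_xlen_t)H * W * C * N);
  NumericVector dw((R_xlen_t)k * k * C);
  NumericVector db((R_xlen_t)C);
  const double *px = x.begin(), *pw = w.begin(), *pd = dout.begin();
  double *pdx = dx.begin(), *pdw = dw.begin(), *pdb = db.begin();
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double *xin = px + ((R_xlen_t)n * C + c) * W * H;
      const double *g = pd + ((R_xlen_t)n * C + c) * W * H;
      double *dxin = pdx + ((R_xlen_t)n * C + c) * W * H;
      const double *wc = pw + (R_xlen_t)k * k * c;
      double *dwc = pdw + (R_xlen_t)k * k * c;
      for (int ow = 0; ow < W; ++ow) {
        for (int oh = 0; oh < H; ++oh) {
          const double gv = g[oh + (R_xlen_t)ow * H];
          pdb[c] += gv;
          for (int kw = 0; kw < k; ++kw) {
            const int iw = ow - p + kw;
            if (iw < 0 || iw >= W) continue;
            for (int kh = 0; kh < k; ++kh) {
              const int ih = oh - p + kh;
              if (ih < 0 || ih >= H) continue;
              const double xv = xin[ih + (R_xlen_t)iw * H];
              dwc[kh + k * kw] += gv * xv;
              dxin[ih + (R_xlen_t)iw * H] += gv * wc[kh + k * kw];
            }
          }
        }
      }
    }
  }
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  dw.attr("dim") = IntegerVector::create(k, k, C);
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

static inline int reflect_idx(int i, int n) {
  // scipy-style "reflect" (edge value included): ... 1 0 | 0 1 2 | 2 1 ...
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - 1 - i;
  }
  return i;
}

// Sliding-window median over a 3-D array [d1, d2, d3] with odd kernel
// (k1, k2, k3); edges handled by reflection.
// [[Rcpp::export]]
NumericVector median3d_cpp(NumericVector x, int d1, int d2, int d3,
                           int k1, int k2, int k3) {
  NumericVector out((R_xlen_t)d1 * d2 * d3);
  const double *px = x.begin();
  double *po = out.begin();
  const int h1 = k1 / 2, h2 = k2 / 2, h3 = k3 / 2;
  const int wlen = k1 * k2 * k3;
  std::vector<double> buf(wlen);
  const int mid = wlen / 2;
  const bool even = (wlen % 2) == 0;
  for (int c = 0; c < d3; ++c) {
    for (int b = 0; b < d2; ++b) {
      for (int a = 0; a < d1; ++a) {
        int m = 0;
        for (int dc = -h3; dc <= h3; ++dc) {
          const int cc = reflect_idx(c + dc, d3);
          for (int db = -h2; db <= h2; ++db) {
            const int bb = reflect_idx(b + db, d2);
            const R_xlen_t base = ((R_xlen_t)cc * d2 + bb) * d1;
            for (int da = -h1; da <= h1; ++da) {
              buf[m++] = px[base + reflect_idx(a + da, d1)];
            }
          }
        }
        std::nth_element(buf.begin(), buf.begin() + mid, buf.end());
        double med = buf[mid];
        if (even) {
          std::nth_element(buf.begin(), buf.begin() + mid - 1,
                           buf.begin() + mid);
          med = 0.5 * (med + buf[mid - 1]);
        }
        po[a + ((R_xlen_t)c * d2 + b) * d1] = med;
      }
    }
  }
  out.attr("dim") = IntegerVector::create(d1, d2, d3);
  return out;
}

// IIR filter (direct form II transposed) applied along the second axis
// (time) of a [lateral x time] matrix, one pass. `zi` is the steady-state
// initial condition for a unit-amplitude input (lfilter_zi construction);
// it is scaled by each row's first sample so constant signals pass
// exactly and start-up transients are minimized.
// [[Rcpp::export]]
NumericMatrix iir_rows_cpp(NumericMatrix x, NumericVector b, NumericVector a,
                           NumericVector zi) {
  const int L = x.nrow(), T = x.ncol();
  const int nb = b.size(), na = a.size();
  const int nord = std::max(nb, na) - 1;
  std::vector<double> bb(nord + 1, 0.0), aa(nord + 1, 0.0);
  const double a0 = a[0];
  for (int i = 0; i < nb; ++i) bb[i] = b[i] / a0;
  for (int i = 0; i < na; ++i) aa[i] = a[i] / a0;
  NumericMatrix y(L, T);
  std::vector<double> z(nord);
  for (int r = 0; r < L; ++r) {
    const double x0 = x(r, 0);
    for (int i = 0; i < nord; ++i) z[i] = zi[i] * x0;
    for (int t = 0; t < T; ++t) {
      const double xin = x(r, t);
      const double yout = bb[0] * xin + (nord > 0 ? z[0] : 0.0);
      for (int i = 0; i < nord - 1; ++i)
        z[i] = bb[i + 1] * xin + z[i + 1] - aa[i + 1] * yout;
      if (nord > 0) z[nord - 1] = bb[nord] * xin - aa[nord] * yout;
      y(r, t) = yout;
    }
  }
  return y;
}

// --- fused per-channel helpers for the layer engine ---------------------
// x is [H, W, C, N] flattened; hw = H*W. "cn" vectors have length C*N
// (channel fastest), "channel" vectors length C.

// Sum of x over (H, W, N) for each channel.
// [[Rcpp::export]]
NumericVector channel_sums_cpp(NumericVector x, int hw, int C, int N) {
  NumericVector out(C);
  const double *px = x.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      double s = 0.0;
      const double *p = px + ((R_xlen_t)n * C + c) * hw;
      for (int i = 0; i < hw; ++i) s += p[i];
      out[c] += s;
    }
  return out;
}

// Sum of x*y over (H, W, N) for each channel, without materializing x*y.
// [[Rcpp::export]]
NumericVector channel_dot_cpp(NumericVector x, NumericVector y, int hw,
                              int C, int N) {
  NumericVector out(C);
  const double *px = x.begin(), *py = y.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      double s = 0.0;
      const R_xlen_t off = ((R_xlen_t)n * C + c) * hw;
      for (int i = 0; i < hw; ++i) s += px[off + i] * py[off + i];
      out[c] += s;
    }
  return out;
}

// Per-(channel, sample) block sums: colSums of matrix(x, hw, C*N).
// [[Rcpp::export]]
NumericVector cn_sums_cpp(NumericVector x, int hw) {
  const R_xlen_t ncn = x.size() / hw;
  NumericVector out(ncn);
  const double *px = x.begin();
  for (R_xlen_t j = 0; j < ncn; ++j) {
    double s = 0.0;
    const double *p = px + j * hw;
    for (int i = 0; i < hw; ++i) s += p[i];
    out[j] = s;
  }
  return out;
}

// Per-(channel, sample) block dot products: colSums of x*y blocks.
// [[Rcpp::export]]
NumericVector cn_dots_cpp(NumericVector x, NumericVector y, int hw) {
  const R_xlen_t ncn = x.size() / hw;
  NumericVector out(ncn);
  const double *px = x.begin(), *py = y.begin();
  for (R_xlen_t j = 0; j < ncn; ++j) {
    double s = 0.0;
    const R_xlen_t off = j * hw;
    for (int i = 0; i < hw; ++i) s += px[off + i] * py[off + i];
    out[j] = s;
  }
  return out;
}

// out = x * a_bc + b_bc with per-channel a, b broadcast over (H, W, N).
// [[Rcpp::export]]
NumericVector channel_affine_cpp(NumericVector x, NumericVector a,
                                 NumericVector b, int hw, int C, int N) {
  NumericVector out(x.size());
  const double *px = x.begin(), *pa = a.begin(), *pb = b.begin();
  double *po = out.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const R_xlen_t off = ((R_xlen_t)n * C + c) * hw;
      const double av = pa[c], bv = pb[c];
      for (int i = 0; i < hw; ++i) po[off + i] = px[off + i] * av + bv;
    }
  return out;
}

// out = x * a_bc + y * c_bc + b_bc (fused batch-norm backward combine).
// [[Rcpp::export]]
NumericVector channel_affine2_cpp(NumericVector x, NumericVector y,
                                  NumericVector a, NumericVector b,
                                  NumericVector c, int hw, int C, int N) {
  NumericVector out(x.size());
  const double *px = x.begin(), *py = y.begin();
  const double *pa = a.begin(), *pb = b.begin(), *pc = c.begin();
  double *po = out.begin();
  for (int n = 0; n < N; ++n)
    for (int ch = 0; ch < C; ++ch) {
      const R_xlen_t off = ((R_xlen_t)n * C + ch) * hw;
      const double av = pa[ch], bv = pb[ch], cv = pc[ch];
      for (int i = 0; i < hw; ++i)
        po[off + i] = px[off + i] * av + py[off + i] * cv + bv;
    }
  return out;
}

// out = x * s_bc with per-(channel, sample) s broadcast over (H, W).
// [[Rcpp::export]]
NumericVector cn_scale_cpp(NumericVector x, NumericVector s, int hw) {
  NumericVector out(x.size());
  const double *px = x.begin(), *ps = s.begin();
  double *po = out.begin();
  const R_xlen_t ncn = x.size() / hw;
  for (R_xlen_t j = 0; j < ncn; ++j) {
    const double sv = ps[j];
    const R_xlen_t off = j * hw;
    for (int i = 0; i < hw; ++i) po[off + i] = px[off + i] * sv;
  }
  return out;
}

// out = x * s_bc + t_bc (scale plus per-(channel, sample) shift).
// [[Rcpp::export]]
NumericVector cn_scale_add_cpp(NumericVector x, NumericVector s,
                               NumericVector t, int hw) {
  NumericVector out(x.size());
  const double *px = x.begin(), *ps = s.begin(), *pt = t.begin();
  double *po = out.begin();
  const R_xlen_t ncn = x.size() / hw;
  for (R_xlen_t j = 0; j < ncn; ++j) {
    const double sv = ps[j], tv = pt[j];
    const R_xlen_t off = j * hw;
    for (int i = 0; i < hw; ++i) po[off + i] = px[off + i] * sv + tv;
  }
  return out;
}
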