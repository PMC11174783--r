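// Low-level numeric kernels for the network blocks.
//
// Feature maps are R arrays with dim (B, C, H, W), column-major, so the
// element (b, c, h, w) lives at b + B*(c + C*(h + H*w)).  Convolution weights
// use dim (KH, KW, Cin_per_group, Cout) so that the flattened (kh, kw, cin)
// index coincides with the im2col row index.

#include <RcppArmadillo.h>
using namespace Rcpp;

static inline R_xlen_t idx4(R_xlen_t b, R_xlen_t c, R_xlen_t h, R_xlen_t w,
                            R_xlen_t B, R_xlen_t C, R_xlen_t H) {
  return b + B * (c + C * (h + H * w));
}

// Maximum number of doubles held in one im2col buffer (~32 MB).
static const R_xlen_t COL_MAX_ELEMS = 4000000;

static IntegerVector dims_of(const NumericVector& x) {
  return x.attr("dim");
}

// ---------------------------------------------------------------------------
// Grouped 2-D convolution, "same"/valid padding via explicit pad argument.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_conv2d_fw(NumericVector x, NumericVector w,
                            NumericVector bias, int stride, int pad,
                            int groups) {
  IntegerVector xd = dims_of(x), wd = dims_of(w);
  const R_xlen_t B = xd[0], C = xd[1], H = xd[2], W = xd[3];
  const R_xlen_t KH = wd[0], KW = wd[1], Cg = wd[2], Cout = wd[3];
  if (C % groups != 0 || Cout % groups != 0)
    stop("channel counts not divisible by groups");
  if (C / groups != Cg) stop("weight in-channel count mismatch");
  const R_xlen_t Ho = (H + 2 * pad - KH) / stride + 1;
  const R_xlen_t Wo = (W + 2 * pad - KW) / stride + 1;
  const R_xlen_t rows = Cg * KH * KW, Coutg = Cout / groups;
  const R_xlen_t N = B * Ho * Wo;  // columns span the whole batch

  NumericVector y(B * Cout * Ho * Wo);
  y.attr("dim") = IntegerVector::create((int)B, (int)Cout, (int)Ho, (int)Wo);

  R_xlen_t chunk = std::max((R_xlen_t)64, COL_MAX_ELEMS / rows);
  if (chunk > N) chunk = N;
  arma::mat col(rows, chunk);
  const double* xp = x.begin();
  double* yp = y.begin();

  for (R_xlen_t n0 = 0; n0 < N; n0 += chunk) {
    const R_xlen_t nc = std::min(chunk, N - n0);
    for (R_xlen_t g = 0; g < groups; ++g) {
      const R_xlen_t c0 = g * Cg;
      for (R_xlen_t cc = 0; cc < nc; ++cc) {
        const R_xlen_t n = n0 + cc;
        const R_xlen_t b = n % B, l = n / B;
        const R_xlen_t ho = l % Ho, wo = l / Ho;
        const R_xlen_t hbase = ho * stride - pad, wbase = wo * stride - pad;
        double* colc = col.colptr(cc);
        R_xlen_t r = 0;
        for (R_xlen_t cl = 0; cl < Cg; ++cl) {
          const double* xc = xp + b + B * (c0 + cl) ;
          for (R_xlen_t kw = 0; kw < KW; ++kw) {
            const R_xlen_t wi = wbase + kw;
            const bool wok = (wi >= 0 && wi < W);
            for (R_xlen_t kh = 0; kh < KH; ++kh, ++r) {
              const R_xlen_t hi = hbase + kh;
              colc[r] = (wok && hi >= 0 && hi < H)
                            ? xc[B * C * (hi + H * wi)]
                            : 0.0;
            }
          }
        }
      }
      arma::mat Wm(const_cast<double*>(w.begin()) + g * Coutg * rows, rows,
                   Coutg, false, true);
      arma::mat out = Wm.t() * col.cols(0, nc - 1);  // Coutg x nc
      for (R_xlen_t cc = 0; cc < nc; ++cc) {
        const R_xlen_t n = n0 + cc;
        const R_xlen_t b = n % B, l = n / B;
        const R_xlen_t ho = l % Ho, wo = l / Ho;
        for (R_xlen_t co = 0; co < Coutg; ++co) {
          yp[idx4(b, g * Coutg + co, ho, wo, B, Cout, Ho)] = out(co, cc);
        }
      }
    }
  }
  if (bias.size() == Cout) {
    for (R_xlen_t wo = 0; wo < Wo; ++wo)
      for (R_xlen_t ho = 0; ho < Ho; ++ho)
        for (R_xlen_t c = 0; c < Cout; ++c) {
          const double bv = bias[c];
          double* p = yp + idx4(0, c, ho, wo, B, Cout, Ho);
          for (R_xlen_t b = 0; b < B; ++b) p[b] += bv;
        }
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_bw(NumericVector x, NumericVector w, NumericVector dy,
                   int stride, int pad, int groups, bool has_bias) {
  IntegerVector xd = dims_of(x), wd = dims_of(w), yd = dims_of(dy);
  const R_xlen_t B = xd[0], C = xd[1], H = xd[2], W = xd[3];
  const R_xlen_t KH = wd[0], KW = wd[1], Cg = wd[2], Cout = wd[3];
  const R_xlen_t Ho = yd[2], Wo = yd[3];
  const R_xlen_t rows = Cg * KH * KW, Coutg = Cout / groups;
  const R_xlen_t N = B * Ho * Wo;

  NumericVector dx(x.size());
  dx.attr("dim") = xd;
  NumericVector dw(w.size());
  dw.attr("dim") = wd;
  NumericVector db(has_bias ? Cout : 0);

  R_xlen_t chunk = std::max((R_xlen_t)64, COL_MAX_ELEMS / rows);
  if (chunk > N) chunk = N;
  arma::mat col(rows, chunk), dyg(Coutg, chunk);
  const double* xp = x.begin();
  const double* dyp = dy.begin();
  double* dxp = dx.begin();

  for (R_xlen_t n0 = 0; n0 < N; n0 += chunk) {
    const R_xlen_t nc = std::min(chunk, N - n0);
    for (R_xlen_t g = 0; g < groups; ++g) {
      const R_xlen_t c0 = g * Cg;
      for (R_xlen_t cc = 0; cc < nc; ++cc) {
        const R_xlen_t n = n0 + cc;
        const R_xlen_t b = n % B, l = n / B;
        const R_xlen_t ho = l % Ho, wo = l / Ho;
        const R_xlen_t hbase = ho * stride - pad, wbase = wo * stride - pad;
        double* colc = col.colptr(cc);
        R_xlen_t r = 0;
        for (R_xlen_t cl = 0; cl < Cg; ++cl) {
          const double* xc = xp + b + B * (c0 + cl);
          for (R_xlen_t kw = 0; kw < KW; ++kw) {
            const R_xlen_t wi = wbase + kw;
            const bool wok = (wi >= 0 && wi < W);
            for (R_xlen_t kh = 0; kh < KH; ++kh, ++r) {
              const R_xlen_t hi = hbase + kh;
              colc[r] = (wok && hi >= 0 && hi < H)
                            ? xc[B * C * (hi + H * wi)]
                            : 0.0;
            }
          }
        }
        for (R_xlen_t co = 0; co < Coutg; ++co)
          dyg(co, cc) = dyp[idx4(b, g * Coutg + co, ho, wo, B, Cout, Ho)];
      }
      arma::mat Wm(const_cast<double*>(w.begin()) + g * Coutg * rows, rows,
                   Coutg, false, true);
      arma::mat dWm(dw.begin() + g * Coutg * rows, rows, Coutg, false, true);
      dWm += col.cols(0, nc - 1) * dyg.cols(0, nc - 1).t();
      arma::mat dcol = Wm * dyg.cols(0, nc - 1);  // rows x nc
      for (R_xlen_t cc = 0; cc < nc; ++cc) {
        const R_xlen_t n = n0 + cc;
        const R_xlen_t b = n % B, l = n / B;
        const R_xlen_t ho = l % Ho, wo = l / Ho;
        const R_xlen_t hbase = ho * stride - pad, wbase = wo * stride - pad;
        const double* dcolc = dcol.colptr(cc);
        R_xlen_t r = 0;
        for (R_xlen_t cl = 0; cl < Cg; ++cl) {
          double* dxc = dxp + b + B * (c0 + cl);
          for (R_xlen_t kw = 0; kw < KW; ++kw) {
            const R_xlen_t wi = wbase + kw;
            const bool wok = (wi >= 0 && wi < W);
            for (R_xlen_t kh = 0; kh < KH; ++kh, ++r) {
              const R_xlen_t hi = hbase + kh;
              if (wok && hi >= 0 && hi < H)
                dxc[B * C * (hi + H * wi)] += dcolc[r];
            }
          }
        }
      }
    }
  }
  if (has_bias) {
    for (R_xlen_t wo = 0; wo < Wo; ++wo)
      for (R_xlen_t ho = 0; ho < Ho; ++ho)
        for (R_xlen_t c = 0; c < Cout; ++c) {
          const double* p = dyp + idx4(0, c, ho, wo, B, Cout, Ho);
          double s = 0.0;
          for (R_xlen_t b = 0; b < B; ++b) s += p[b];
          db[c] += s;
        }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// ---------------------------------------------------------------------------
// Max pooling
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_maxpool_fw(NumericVector x, int k, int stride, int pad) {
  IntegerVector xd = dims_of(x);
  const R_xlen_t B = xd[0], C = xd[1], H = xd[2], W = xd[3];
  const R_xlen_t Ho = (H + 2 * pad - k) / stride + 1;
  const R_xlen_t Wo = (W + 2 * pad - k) / stride + 1;
  NumericVector y(B * C * Ho * Wo);
  y.attr("dim") = IntegerVector::create((int)B, (int)C, (int)Ho, (int)Wo);
  NumericVector idx(y.size());  // 1-based linear index into x (double-safe)
  const double* xp = x.begin();
  double* yp = y.begin();
  double* ip = idx.begin();
  R_xlen_t o = 0;
  for (R_xlen_t wo = 0; wo < Wo; ++wo)
    for (R_xlen_t ho = 0; ho < Ho; ++ho)
      for (R_xlen_t c = 0; c < C; ++c)
        for (R_xlen_t b = 0; b < B; ++b) {
          double best = -INFINITY;
          R_xlen_t besti = -1;
          for (R_xlen_t kw = 0; kw < k; ++kw) {
            const R_xlen_t wi = wo * stride - pad + kw;
            if (wi < 0 || wi >= W) continue;
            for (R_xlen_t kh = 0; kh < k; ++kh) {
              const R_xlen_t hi = ho * stride - pad + kh;
              if (hi < 0 || hi >= H) continue;
              const R_xlen_t ii = idx4(b, c, hi, wi, B, C, H);
              if (xp[ii] > best) { best = xp[ii]; besti = ii; }
            }
          }
          o = idx4(b, c, ho, wo, B, C, Ho);
          yp[o] = best;
          ip[o] = (double)(besti + 1);
        }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bw(NumericVector idx, NumericVector dy,
                             IntegerVector xdim) {
  R_xlen_t n = (R_xlen_t)xdim[0] * xdim[1] * xdim[2] * xdim[3];
  NumericVector dx(n);
  dx.attr("dim") = xdim;
  const double* ip = idx.begin();
  const double* dyp = dy.begin();
  double* dxp = dx.begin();
  for (R_xlen_t i = 0; i < dy.size(); ++i)
    dxp[(R_xlen_t)ip[i] - 1] += dyp[i];
  return dx;
}

// ---------------------------------------------------------------------------
// Stride-1 "same" average pooling (count includes only in-bounds taps, so a
// constant map stays constant).  The operator is symmetric up to the count
// normalisation, so backward reuses the same loop on dy.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_avgpool_same(NumericVector x, int k, bool backward) {
  IntegerVector xd = dims_of(x);
  const R_xlen_t B = xd[0], C = xd[1], H = xd[2], W = xd[3];
  const int pad = (k - 1) / 2;
  NumericVector y(x.size());
  y.attr("dim") = xd;
  const double* xp = x.begin();
  double* yp = y.begin();
  if (!backward) {
    for (R_xlen_t wo = 0; wo < W; ++wo)
      for (R_xlen_t ho = 0; ho < H; ++ho)
        for (R_xlen_t c = 0; c < C; ++c)
          for (R_xlen_t b = 0; b < B; ++b) {
            double s = 0.0;
            int cnt = 0;
            for (R_xlen_t kw = 0; kw < k; ++kw) {
              const R_xlen_t wi = wo - pad + kw;
              if (wi < 0 || wi >= W) continue;
              for (R_xlen_t kh = 0; kh < k; ++kh) {
                const R_xlen_t hi = ho - pad + kh;
                if (hi < 0 || hi >= H) continue;
                ++cnt;
                s += xp[idx4(b, c, hi, wi, B, C, H)];
              }
            }
            yp[idx4(b, c, ho, wo, B, C, H)] = s / cnt;
          }
  } else {
    // dx[h',w'] = sum over outputs (h,w) whose window covers (h',w') of
    // dy[h,w]/count(h,w).  Scatter from each output.
    for (R_xlen_t wo = 0; wo < W; ++wo)
      for (R_xlen_t ho = 0; ho < H; ++ho) {
        int cnt = 0;
        for (R_xlen_t kw = 0; kw < k; ++kw) {
          const R_xlen_t wi = wo - pad + kw;
          if (wi < 0 || wi >= W) continue;
          for (R_xlen_t kh = 0; kh < k; ++kh) {
            const R_xlen_t hi = ho - pad + kh;
            if (hi >= 0 && hi < H) ++cnt;
          }
        }
        for (R_xlen_t c = 0; c < C; ++c)
          for (R_xlen_t b = 0; b < B; ++b) {
            const double g = xp[idx4(b, c, ho, wo, B, C, H)] / cnt;
            for (R_xlen_t kw = 0; kw < k; ++kw) {
              const R_xlen_t wi = wo - pad + kw;
              if (wi < 0 || wi >= W) continue;
              for (R_xlen_t kh = 0; kh < k; ++kh) {
                const R_xlen_t hi = ho - pad + kh;
                if (hi < 0 || hi >= H) continue;
                yp[idx4(b, c, hi, wi, B, C, H)] += g;
              }
            }
          }
      }
  }
  return y;
}

// ---------------------------------------------------------------------------
// Unfold / fold for local-window attention.  Stride 1, padding (k-1)/2.
// Output rows are ordered offset-fastest: row = j + k2*c with window offset
// j = kh + k*kw.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_unfold(NumericVector x, int k) {
  IntegerVector xd = dims_of(x);
  const R_xlen_t B = xd[0], C = xd[1], H = xd[2], W = xd[3];
  const int pad = (k - 1) / 2;
  const R_xlen_t k2 = (R_xlen_t)k * k, L = H * W;
  NumericVector out(B * C * k2 * L);
  out.attr("dim") = IntegerVector::create((int)B, (int)(C * k2), (int)L);
  const double* xp = x.begin();
  double* op = out.begin();
  const R_xlen_t Crow = C * k2;
  for (R_xlen_t l = 0; l < L; ++l) {
    const R_xlen_t h = l % H, w = l / H;
    for (R_xlen_t c = 0; c < C; ++c)
      for (int kw = 0; kw < k; ++kw) {
        const R_xlen_t wi = w - pad + kw;
        for (int kh = 0; kh < k; ++kh) {
          const R_xlen_t hi = h - pad + kh;
          const R_xlen_t row = (R_xlen_t)(kh + k * kw) + k2 * c;
          double* dst = op + (0 + B * (row + Crow * l));
          if (hi >= 0 && hi < H && wi >= 0 && wi < W) {
            const double* src = xp + idx4(0, c, hi, wi, B, C, H);
            for (R_xlen_t b = 0; b < B; ++b) dst[b] = src[b];
          } else {
            for (R_xlen_t b = 0; b < B; ++b) dst[b] = 0.0;
          }
        }
      }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_fold_raw(NumericVector col, int C, int H, int W, int k) {
  IntegerVector cd = dims_of(col);
  const R_xlen_t B = cd[0];
  const int pad = (k - 1) / 2;
  const R_xlen_t k2 = (R_xlen_t)k * k, L = (R_xlen_t)H * W, Crow = C * k2;
  NumericVector y((R_xlen_t)B * C * H * W);
  y.attr("dim") = IntegerVector::create((int)B, C, H, W);
  const double* cp = col.begin();
  double* yp = y.begin();
  for (R_xlen_t l = 0; l < L; ++l) {
    const R_xlen_t h = l % H, w = l / H;
    for (R_xlen_t c = 0; c < C; ++c)
      for (int kw = 0; kw < k; ++kw) {
        const R_xlen_t wi = w - pad + kw;
        if (wi < 0 || wi >= W) continue;
        for (int kh = 0; kh < k; ++kh) {
          const R_xlen_t hi = h - pad + kh;
          if (hi < 0 || hi >= H) continue;
          const R_xlen_t row = (R_xlen_t)(kh + k * kw) + k2 * c;
          const double* src = cp + (0 + B * (row + Crow * l));
          double* dst = yp + idx4(0, c, hi, wi, B, C, H);
          for (R_xlen_t b = 0; b < B; ++b) dst[b] += src[b];
        }
      }
  }
  return y;
}

// [[Rcpp::export]]
NumericMatrix cpp_overlap_count(int H, int W, int k) {
  const int pad = (k - 1) / 2;
  NumericMatrix cnt(H, W);
  for (int w = 0; w < W; ++w)
    for (int h = 0; h < H; ++h)
      for (int kw = 0; kw < k; ++kw) {
        const int wi = w - pad + kw;
        if (wi < 0 || wi >= W) continue;
        for (int kh = 0; kh < k; ++kh) {
          const int hi = h - pad + kh;
          if (hi >= 0 && hi < H) cnt(hi, wi) += 1.0;
        }
      }
  return cnt;
}

// ---------------------------------------------------------------------------
// Local-window attention aggregation: per (batch, position, head),
// OUT = A^T V with A (k2 x k2, source offset fastest) and V (k2 x head_dim).
// A is a matrix (k2*k2*heads, B*L) with column n = b + B*l.
// V and OUT are unfold buffers (B, C*k2, L) with row = j + k2*(head*hd + d).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_attn_agg_fw(NumericMatrix A, NumericVector V, int k2,
                              int heads, int hd) {
  IntegerVector vd = dims_of(V);
  const R_xlen_t B = vd[0], Crow = vd[1], L = vd[2];
  NumericVector out(V.size());
  out.attr("dim") = vd;
  const double* ap = A.begin();
  const double* vp = V.begin();
  double* op = out.begin();
  const R_xlen_t Arows = (R_xlen_t)k2 * k2 * heads;
  for (R_xlen_t l = 0; l < L; ++l)
    for (R_xlen_t b = 0; b < B; ++b) {
      const double* Acol = ap + Arows * (b + B * l);
      for (int h = 0; h < heads; ++h) {
        const double* Ah = Acol + (R_xlen_t)h * k2 * k2;
        for (int d = 0; d < hd; ++d) {
          const R_xlen_t rbase = (R_xlen_t)k2 * (h * hd + d);
          for (int i = 0; i < k2; ++i) {
            double s = 0.0;
            const double* Ai = Ah + (R_xlen_t)i * k2;  // column i: entries A(j,i)
            for (int j = 0; j < k2; ++j)
              s += Ai[j] * vp[b + B * ((rbase + j) + Crow * l)];
            op[b + B * ((rbase + i) + Crow * l)] = s;
          }
        }
      }
    }
  return out;
}

// [[Rcpp::export]]
List cpp_attn_agg_bw(NumericMatrix A, NumericVector V, NumericVector dOut,
                     int k2, int heads, int hd) {
  IntegerVector vd = dims_of(V);
  const R_xlen_t B = vd[0], Crow = vd[1], L = vd[2];
  NumericMatrix dA(A.nrow(), A.ncol());
  NumericVector dV(V.size());
  dV.attr("dim") = vd;
  const double* ap = A.begin();
  const double* vp = V.begin();
  const double* gp = dOut.begin();
  double* dap = dA.begin();
  double* dvp = dV.begin();
  const R_xlen_t Arows = (R_xlen_t)k2 * k2 * heads;
  for (R_xlen_t l = 0; l < L; ++l)
    for (R_xlen_t b = 0; b < B; ++b) {
      const R_xlen_t acol = Arows * (b + B * l);
      for (int h = 0; h < heads; ++h) {
        const R_xlen_t ah = acol + (R_xlen_t)h * k2 * k2;
        for (int d = 0; d < hd; ++d) {
          const R_xlen_t rbase = (R_xlen_t)k2 * (h * hd + d);
          for (int i = 0; i < k2; ++i) {
            const double g = gp[b + B * ((rbase + i) + Crow * l)];
            if (g == 0.0) continue;
            const R_xlen_t ai = ah + (R_xlen_t)i * k2;
            for (int j = 0; j < k2; ++j) {
              dap[ai + j] += g * vp[b + B * ((rbase + j) + Crow * l)];
              dvp[b + B * ((rbase + j) + Crow * l)] += g * ap[ai + j];
            }
          }
        }
      }
    }
  return List::create(_["dA"] = dA, _["dV"] = dV);
}

// ---------------------------------------------------------------------------
// Channel / spatial broadcast helpers (BN, SE gating, attention gates).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_channel_sums(NumericVector x, bool squared) {
  IntegerVector xd = dims_of(x);
  const R_xlen_t B = xd[0], C = xd[1], HW = (R_xlen_t)xd[2] * xd[3];
  NumericVector s(C);
  const double* xp = x.begin();
  for (R_xlen_t p = 0; p < HW; ++p)
    for (R_xlen_t c = 0; c < C; ++c) {
      const double* col = xp + B * (c + C * p);
      double acc = 0.0;
      if (squared)
        for (R_xlen_t b = 0; b < B; ++b) acc += col[b] * col[b];
      else
        for (R_xlen_t b = 0; b < B; ++b) acc += col[b];
      s[c] += acc;
    }
  return s;
}

// [[Rcpp::export]]
NumericVector cpp_channel_sum_prod(NumericVector x, NumericVector y) {
  IntegerVector xd = dims_of(x);
  const R_xlen_t B = xd[0], C = xd[1], HW = (R_xlen_t)xd[2] * xd[3];
  NumericVector s(C);
  const double* xp = x.begin();
  const double* yp = y.begin();
  for (R_xlen_t p = 0; p < HW; ++p)
    for (R_xlen_t c = 0; c < C; ++c) {
      const double* cx = xp + B * (c + C * p);
      const double* cy = yp + B * (c + C * p);
      double acc = 0.0;
      for (R_xlen_t b = 0; b < B; ++b) acc += cx[b] * cy[b];
      s[c] += acc;
    }
  return s;
}

// y = a[c] * x + b[c]
// [[Rcpp::export]]
NumericVector cpp_channel_affine(NumericVector x, NumericVector a,
                                 NumericVector bvec) {
  IntegerVector xd = dims_of(x);
  const R_xlen_t B = xd[0], C = xd[1], HW = (R_xlen_t)xd[2] * xd[3];
  NumericVector y(x.size());
  y.attr("dim") = xd;
  const double* xp = x.begin();
  double* yp = y.begin();
  for (R_xlen_t p = 0; p < HW; ++p)
    for (R_xlen_t c = 0; c < C; ++c) {
      const double av = a[c], bv = bvec[c];
      const double* cx = xp + B * (c + C * p);
      double* cy = yp + B * (c + C * p);
      for (R_xlen_t b = 0; b < B; ++b) cy[b] = av * cx[b] + bv;
    }
  return y;
}

// y[b,c,h,w] = x[b,c,h,w] * g[b,c]   (g is B x C)
// [[Rcpp::export]]
NumericVector cpp_scale_bc(NumericVector x, NumericMatrix g) {
  IntegerVector xd = dims_of(x);
  const R_xlen_t B = xd[0], C = xd[1], HW = (R_xlen_t)xd[2] * xd[3];
  NumericVector y(x.size());
  y.attr("dim") = xd;
  const double* xp = x.begin();
  const double* gp = g.begin();
  double* yp = y.begin();
  for (R_xlen_t p = 0; p < HW; ++p) {
    const R_xlen_t off = B * C * p;
    for (R_xlen_t i = 0; i < B * C; ++i) yp[off + i] = xp[off + i] * gp[i];
  }
  return y;
}

// out[b,c] = sum_{h,w} x[b,c,h,w] * y[b,c,h,w]
// [[Rcpp::export]]
NumericMatrix cpp_dot_bc(NumericVector x, NumericVector y) {
  IntegerVector xd = dims_of(x);
  const R_xlen_t B = xd[0], C = xd[1], HW = (R_xlen_t)xd[2] * xd[3];
  NumericMatrix s((int)B, (int)C);
  const double* xp = x.begin();
  const double* yp = y.begin();
  double* sp = s.begin();
  for (R_xlen_t p = 0; p < HW; ++p) {
    const R_xlen_t off = B * C * p;
    for (R_xlen_t i = 0; i < B * C; ++i) sp[i] += xp[off + i] * yp[off + i];
  }
  return s;
}

// y[b,c,h,w] = x[b,c,h,w] * wmap[b,1,h,w]
// [[Rcpp::export]]
NumericVector cpp_scale_spatial(NumericVector x, NumericVector wmap) {
  IntegerVector xd = dims_of(x);
  const R_xlen_t B = xd[0], C = xd[1], HW = (R_xlen_t)xd[2] * xd[3];
  NumericVector y(x.size());
  y.attr("dim") = xd;
  const double* xp = x.begin();
  const double* wp = wmap.begin();
  double* yp = y.begin();
  for (R_xlen_t p = 0; p < HW; ++p)
    for (R_xlen_t c = 0; c < C; ++c) {
      const double* cx = xp + B * (c + C * p);
      const double* cw = wp + B * p;
      double* cy = yp + B * (c + C * p);
      for (R_xlen_t b = 0; b < B; ++b) cy[b] = cx[b] * cw[b];
    }
  return y;
}

// out[b,1,h,w] = sum_c x[b,c,h,w] * y[b,c,h,w]
// [[Rcpp::export]]
NumericVector cpp_dot_spatial(NumericVector x, NumericVector y) {
  IntegerVector xd = dims_of(x);
  const R_xlen_t B = xd[0], C = xd[1], HW = (R_xlen_t)xd[2] * xd[3];
  NumericVector s(B * HW);
  s.attr("dim") = IntegerVector::create(xd[0], 1, xd[2], xd[3]);
  const double* xp = x.begin();
  const double* yp = y.begin();
  double* sp = s.begin();
  for (R_xlen_t p = 0; p < HW; ++p)
    for (R_xlen_t c = 0; c < C; ++c) {
      const double* cx = xp + B * (c + C * p);
      const double* cy = yp + B * (c + C * p);
      for (R_xlen_t b = 0; b < B; ++b) sp[B * p + b] += cx[b] * cy[b];
    }
  return s;
}

// ---------------------------------------------------------------------------
// Channel-axis compressions for S-Pool: max and softmax-weighted average.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_chanmax_fw(NumericVector x) {
  IntegerVector xd = dims_of(x);
  const R_xlen_t B = xd[0], C = xd[1], HW = (R_xlen_t)xd[2] * xd[3];
  NumericVector y(B * HW), idx(B * HW);
  y.attr("dim") = IntegerVector::create(xd[0], 1, xd[2], xd[3]);
  const double* xp = x.begin();
  for (R_xlen_t p = 0; p < HW; ++p)
    for (R_xlen_t b = 0; b < B; ++b) {
      double best = -INFINITY;
      R_xlen_t bi = -1;
      for (R_xlen_t c = 0; c < C; ++c) {
        const double v = xp[b + B * (c + C * p)];
        if (v > best) { best = v; bi = b + B * (c + C * p); }
      }
      y[b + B * p] = best;
      idx[b + B * p] = (double)(bi + 1);
    }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_softpool_fw(NumericVector x) {
  IntegerVector xd = dims_of(x);
  const R_xlen_t B = xd[0], C = xd[1], HW = (R_xlen_t)xd[2] * xd[3];
  NumericVector y(B * HW);
  y.attr("dim") = IntegerVector::create(xd[0], 1, xd[2], xd[3]);
  const double* xp = x.begin();
  for (R_xlen_t p = 0; p < HW; ++p)
    for (R_xlen_t b = 0; b < B; ++b) {
      double mx = -INFINITY;
      for (R_xlen_t c = 0; c < C; ++c)
        mx = std::max(mx, xp[b + B * (c + C * p)]);
      double den = 0.0, num = 0.0;
      for (R_xlen_t c = 0; c < C; ++c) {
        const double a = xp[b + B * (c + C * p)];
        const double e = std::exp(a - mx);
        den += e;
        num += e * a;
      }
      y[b + B * p] = num / den;
    }
  return y;
}

// d soft_pool / d a_j = p_j * (1 + a_j - sum_i p_i a_i)
// [[Rcpp::export]]
NumericVector cpp_softpool_bw(NumericVector x, NumericVector dy) {
  IntegerVector xd = dims_of(x);
  const R_xlen_t B = xd[0], C = xd[1], HW = (R_xlen_t)xd[2] * xd[3];
  NumericVector dx(x.size());
  dx.attr("dim") = xd;
  const double* xp = x.begin();
  const double* gp = dy.begin();
  double* dp = dx.begin();
  for (R_xlen_t p = 0; p < HW; ++p)
    for (R_xlen_t b = 0; b < B; ++b) {
      double mx = -INFINITY;
      for (R_xlen_t c = 0; c < C; ++c)
        mx = std::max(mx, xp[b + B * (c + C * p)]);
      double den = 0.0, num = 0.0;
      for (R_xlen_t c = 0; c < C; ++c) {
        const double a = xp[b + B * (c + C * p)];
        const double e = std::exp(a - mx);
        den += e;
        num += e * a;
      }
      const double sp = num / den, g = gp[b + B * p];
      for (R_xlen_t c = 0; c < C; ++c) {
        const double a = xp[b + B * (c + C * p)];
        const double pj = std::exp(a - mx) / den;
        dp[b + B * (c + C * p)] = g * pj * (1.0 + a - sp);
      }
    }
  return dx;
}

// ---------------------------------------------------------------------------
// (B,C,H,W) <-> (C, B*H*W) matrix views for per-position linear maps.
// Column n = b + B*l with l = h + H*w.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericMatrix cpp_nchw_to_cmat(NumericVector x) {
  IntegerVector xd = dims_of(x);
  const R_xlen_t B = xd[0], C = xd[1], HW = (R_xlen_t)xd[2] * xd[3];
  NumericMatrix m((int)C, (int)(B * HW));
  const double* xp = x.begin();
  double* mp = m.begin();
  for (R_xlen_t p = 0; p < HW; ++p)
    for (R_xlen_t c = 0; c < C; ++c) {
      const double* src = xp + B * (c + C * p);
      for (R_xlen_t b = 0; b < B; ++b) mp[c + C * (b + B * p)] = src[b];
    }
  return m;
}

// [[Rcpp::export]]
NumericVector cpp_cmat_to_nchw(NumericMatrix m, int B, int H, int W) {
  const R_xlen_t C = m.nrow(), HW = (R_xlen_t)H * W;
  NumericVector x((R_xlen_t)B * C * HW);
  x.attr("dim") = IntegerVector::create(B, (int)C, H, W);
  const double* mp = m.begin();
  double* xp = x.begin();
  for (R_xlen_t p = 0; p < HW; ++p)
    for (R_xlen_t c = 0; c < C; ++c) {
      double* dst = xp + B * (c + C * p);
      for (R_xlen_t b = 0; b < B; ++b) dst[b] = mp[c + C * (b + (R_xlen_t)B * p)];
    }
  return x;
}

// ---------------------------------------------------------------------------
// Bilinear resize of an (H, W, C) image in [0,1] (png layout).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_resize_bilinear(NumericVector img, int out_h, int out_w) {
  IntegerVector d = dims_of(img);
  const int H = d[0], W = d[1], C = d[2];
  NumericVector out((R_xlen_t)out_h * out_w * C);
  out.attr("dim") = IntegerVector::create(out_h, out_w, C);
  const double sh = (double)H / out_h, sw = (double)W / out_w;
  const double* ip = img.begin();
  double* op = out.begin();
  for (int c = 0; c < C; ++c)
    for (int w = 0; w < out_w; ++w) {
      double sx = (w + 0.5) * sw - 0.5;
      if (sx < 0) sx = 0;
      if (sx > W - 1) sx = W - 1;
      const int x0 = (int)sx, x1 = std::min(x0 + 1, W - 1);
      const double fx = sx - x0;
      for (int h = 0; h < out_h; ++h) {
        double sy = (h + 0.5) * sh - 0.5;
        if (sy < 0) sy = 0;
        if (sy > H - 1) sy = H - 1;
        const int y0 = (int)sy, y1 = std::min(y0 + 1, H - 1);
        const double fy = sy - y0;
        const double v =
            (1 - fy) * ((1 - fx) * ip[y0 + H * (x0 + (R_xlen_t)W * c)] +
                        fx * ip[y0 + H * (x1 + (R_xlen_t)W * c)]) +
            fy * ((1 - fx) * ip[y1 + H * (x0 + (R_xlen_t)W * c)] +
                  fx * ip[y1 + H * (x1 + (R_xlen_t)W * c)]);
        op[h + out_h * (w + (R_xlen_t)out_w * c)] = v;
      }
    }
  return out;
}

// Global average pool: (B,C,H,W) -> (B,C)
// [[Rcpp::export]]
NumericMatrix cpp_gap_fw(NumericVector x) {
  IntegerVector xd = dims_of(x);
  const R_xlen_t B = xd[0], C = xd[1], HW = (R_xlen_t)xd[2] * xd[3];
  NumericMatrix y((int)B, (int)C);
  const double* xp = x.begin();
  double* yp = y.begin();
  for (R_xlen_t p = 0; p < HW; ++p) {
    const R_xlen_t off = B * C * p;
    for (R_xlen_t i = 0; i < B * C; ++i) yp[i] += xp[off + i];
  }
  for (R_xlen_t i = 0; i < B * C; ++i) yp[i] /= (double)HW;
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_gap_bw(NumericMatrix dy, int H, int W) {
  const R_xlen_t B = dy.nrow(), C = dy.ncol(), HW = (R_xlen_t)H * W;
  NumericVector dx(B * C * HW);
  dx.attr("dim") = IntegerVector::create((int)B, (int)C, H, W);
  const double* gp = dy.begin();
  double* dp = dx.begin();
  const double inv = 1.0 / (double)HW;
  for (R_xlen_t p = 0; p < HW; ++p) {
    const R_xlen_t off = B * C * p;
    for (R_xlen_t i = 0; i < B * C; ++i) dp[off + i] = gp[i] * inv;
  }
  return dx;
}

// ---------------------------------------------------------------------------
// Fused elementwise kernels
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_relu_fw(NumericVector x) {
  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  const double* xp = x.begin();
  double* yp = y.begin();
  for (R_xlen_t i = 0; i < x.size(); ++i) yp[i] = xp[i] > 0 ? xp[i] : 0.0;
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_relu_bw(NumericVector x, NumericVector g) {
  NumericVector dx(x.size());
  dx.attr("dim") = g.attr("dim");
  const double* xp = x.begin();
  const double* gp = g.begin();
  double* dp = dx.begin();
  for (R_xlen_t i = 0; i < x.size(); ++i) dp[i] = xp[i] > 0 ? gp[i] : 0.0;
  return dx;
}

// Column-wise softmax of a (k, N) matrix, k small.
// [[Rcpp::export]]
NumericMatrix cpp_softmax_cols_fw(NumericMatrix x) {
  const R_xlen_t k = x.nrow(), N = x.ncol();
  NumericMatrix y(k, N);
  const double* xp = x.begin();
  double* yp = y.begin();
  for (R_xlen_t n = 0; n < N; ++n) {
    const double* xc = xp + k * n;
    double* yc = yp + k * n;
    double mx = xc[0];
    for (R_xlen_t r = 1; r < k; ++r) mx = std::max(mx, xc[r]);
    double s = 0.0;
    for (R_xlen_t r = 0; r < k; ++r) { yc[r] = std::exp(xc[r] - mx); s += yc[r]; }
    const double inv = 1.0 / s;
    for (R_xlen_t r = 0; r < k; ++r) yc[r] *= inv;
  }
  return y;
}

// [[Rcpp::export]]
NumericMatrix cpp_softmax_cols_bw(NumericMatrix y, NumericMatrix g) {
  const R_xlen_t k = y.nrow(), N = y.ncol();
  NumericMatrix dz(k, N);
  const double* yp = y.begin();
  const double* gp = g.begin();
  double* dp = dz.begin();
  for (R_xlen_t n = 0; n < N; ++n) {
    const double* yc = yp + k * n;
    const double* gc = gp + k * n;
    double* dc = dp + k * n;
    double s = 0.0;
    for (R_xlen_t r = 0; r < k; ++r) s += gc[r] * yc[r];
    for (R_xlen_t r = 0; r < k; ++r) dc[r] = yc[r] * (gc[r] - s);
  }
  return dz;
}

// 1x1 stride-1 ungrouped convolution as a single GEMM on the (C, B*H*W)
// matrix view.
// [[Rcpp::export]]
NumericVector cpp_conv1x1_fw(NumericVector x, NumericVector w,
                             NumericVector bias) {
  IntegerVector xd = dims_of(x), wd = dims_of(w);
  const R_xlen_t B = xd[0], C = xd[1], HW = (R_xlen_t)xd[2] * xd[3];
  const R_xlen_t Cout = wd[3], N = B * HW;
  NumericVector y(B * Cout * HW);
  y.attr("dim") = IntegerVector::create(xd[0], (int)Cout, xd[2], xd[3]);
  const double* xp = x.begin();
  double* yp = y.begin();
  arma::mat Wm(const_cast<double*>(w.begin()), C, Cout, false, true);
  arma::mat xmat(C, N);
  for (R_xlen_t p = 0; p < HW; ++p) {
    const double* blk = xp + B * C * p;
    for (R_xlen_t c = 0; c < C; ++c)
      for (R_xlen_t b = 0; b < B; ++b) xmat(c, b + B * p) = blk[b + B * c];
  }
  arma::mat ymat = Wm.t() * xmat;  // Cout x N
  for (R_xlen_t p = 0; p < HW; ++p) {
    double* oblk = yp + B * Cout * p;
    for (R_xlen_t c = 0; c < Cout; ++c) {
      const double bv = bias.size() == Cout ? bias[c] : 0.0;
      for (R_xlen_t b = 0; b < B; ++b)
        oblk[b + B * c] = ymat(c, b + B * p) + bv;
    }
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv1x1_bw(NumericVector x, NumericVector w, NumericVector dy,
                    bool has_bias) {
  IntegerVector xd = dims_of(x), wd = dims_of(w);
  const R_xlen_t B = xd[0], C = xd[1], HW = (R_xlen_t)xd[2] * xd[3];
  const R_xlen_t Cout = wd[3], N = B * HW;
  NumericVector dx(x.size());
  dx.attr("dim") = xd;
  NumericVector dw(w.size());
  dw.attr("dim") = wd;
  NumericVector db(has_bias ? Cout : 0);
  const double* xp = x.begin();
  const double* gp = dy.begin();
  double* dxp = dx.begin();
  arma::mat Wm(const_cast<double*>(w.begin()), C, Cout, false, true);
  arma::mat dWm(dw.begin(), C, Cout, false, true);
  arma::mat xmat(C, N), gmat(Cout, N);
  for (R_xlen_t p = 0; p < HW; ++p) {
    const double* blk = xp + B * C * p;
    const double* gblk = gp + B * Cout * p;
    for (R_xlen_t c = 0; c < C; ++c)
      for (R_xlen_t b = 0; b < B; ++b) xmat(c, b + B * p) = blk[b + B * c];
    for (R_xlen_t c = 0; c < Cout; ++c)
      for (R_xlen_t b = 0; b < B; ++b) gmat(c, b + B * p) = gblk[b + B * c];
  }
  dWm += xmat * gmat.t();
  arma::mat dxm = Wm * gmat;  // C x N
  for (R_xlen_t p = 0; p < HW; ++p) {
    double* dblk = dxp + B * C * p;
    for (R_xlen_t c = 0; c < C; ++c)
      for (R_xlen_t b = 0; b < B; ++b) dblk[b + B * c] = dxm(c, b + B * p);
  }
  if (has_bias) {
    for (R_xlen_t n = 0; n < N; ++n)
      for (R_xlen_t c = 0; c < Cout; ++c) db[c] += gmat(c, n);
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// Softmax over contiguous row blocks of size k of a (R, N) matrix (column-
// major, so blocks are contiguous in memory).
// [[Rcpp::export]]
NumericMatrix cpp_softmax_groups_fw(NumericMatrix x, int k) {
  NumericMatrix y(x.nrow(), x.ncol());
  const R_xlen_t M = x.size() / k;
  const double* xp = x.begin();
  double* yp = y.begin();
  for (R_xlen_t m = 0; m < M; ++m) {
    const double* xc = xp + (R_xlen_t)k * m;
    double* yc = yp + (R_xlen_t)k * m;
    double mx = xc[0];
    for (int r = 1; r < k; ++r) mx = std::max(mx, xc[r]);
    double s = 0.0;
    for (int r = 0; r < k; ++r) { yc[r] = std::exp(xc[r] - mx); s += yc[r]; }
    const double inv = 1.0 / s;
    for (int r = 0; r < k; ++r) yc[r] *= inv;
  }
  return y;
}

// [[Rcpp::export]]
NumericMatrix cpp_softmax_groups_bw(NumericMatrix y, NumericMatrix g, int k) {
  NumericMatrix dz(y.nrow(), y.ncol());
  const R_xlen_t M = y.size() / k;
  const double* yp = y.begin();
  const double* gp = g.begin();
  double* dp = dz.begin();
  for (R_xlen_t m = 0; m < M; ++m) {
    const double* yc = yp + (R_xlen_t)k * m;
    const double* gc = gp + (R_xlen_t)k * m;
    double* dc = dp + (R_xlen_t)k * m;
    double s = 0.0;
    for (int r = 0; r < k; ++r) s += gc[r] * yc[r];
    for (int r = 0; r < k; ++r) dc[r] = yc[r] * (gc[r] - s);
  }
  return dz;
}
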