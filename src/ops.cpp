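// Low-level numeric kernels: grouped 2-D convolution (im2col + GEMM),
// max pooling with argmax tracking, and IEEE-754 half-precision codec
// used by the weight serializer. Feature maps are R arrays with
// dim = c(H, W, C), column-major, so element (i,j,c) sits at i + H*(j + W*c).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int out_side(int in, int k, int stride, int pad) {
  return (in + 2 * pad - k) / stride + 1;
}

// Build the im2col matrix for one channel group.
// Rows index output pixels (oi + Ho*oj), columns index (ki + k*(kj + k*ci)).
static void im2col_group(const double* x, int H, int W, int cpg, int c0,
                         int k, int stride, int pad, arma::mat& A) {
  const int Ho = out_side(H, k, stride, pad);
  const int Wo = out_side(W, k, stride, pad);
  for (int ci = 0; ci < cpg; ++ci) {
    const double* xc = x + (size_t)(c0 + ci) * H * W;
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const int q = ki + k * (kj + k * ci);
        for (int oj = 0; oj < Wo; ++oj) {
          const int j = oj * stride + kj - pad;
          for (int oi = 0; oi < Ho; ++oi) {
            const int i = oi * stride + ki - pad;
            double v = 0.0;
            if (i >= 0 && i < H && j >= 0 && j < W) v = xc[i + (size_t)H * j];
            A(oi + (size_t)Ho * oj, q) = v;
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv2d_fw(NumericVector x, NumericVector w, SEXP bias,
                        int stride, int pad, int groups) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  const int H = xd[0], W = xd[1], Cin = xd[2];
  const int k = wd[0], cpg = wd[2], Cout = wd[3];
  if (Cin % groups != 0 || Cout % groups != 0 || Cin / groups != cpg)
    stop("conv2d: channel/group mismatch");
  const int Ho = out_side(H, k, stride, pad);
  const int Wo = out_side(W, k, stride, pad);
  if (Ho <= 0 || Wo <= 0) stop("conv2d: non-positive output size");
  const int copg = Cout / groups;

  NumericVector y(((size_t)Ho) * Wo * Cout);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout);

  arma::mat A(((size_t)Ho) * Wo, (size_t)k * k * cpg);
  for (int g = 0; g < groups; ++g) {
    im2col_group(x.begin(), H, W, cpg, g * cpg, k, stride, pad, A);
    arma::mat Wg((size_t)k * k * cpg, copg);
    for (int co = 0; co < copg; ++co) {
      const double* wsl = w.begin() + ((size_t)(g * copg + co)) * k * k * cpg;
      std::copy(wsl, wsl + (size_t)k * k * cpg, Wg.colptr(co));
    }
    arma::mat Y = A * Wg;  // (Ho*Wo) x copg
    std::copy(Y.begin(), Y.end(), y.begin() + ((size_t)g * copg) * Ho * Wo);
  }
  if (bias != R_NilValue) {
    NumericVector b(bias);
    double* yp = y.begin();
    for (int c = 0; c < Cout; ++c) {
      const double bc = b[c];
      for (size_t p = 0; p < (size_t)Ho * Wo; ++p) yp[(size_t)c * Ho * Wo + p] += bc;
    }
  }
  return y;
}

// [[Rcpp::export]]
List conv2d_bw(NumericVector x, NumericVector w, NumericVector gy,
               int stride, int pad, int groups, bool has_bias) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  const int H = xd[0], W = xd[1], Cin = xd[2];
  const int k = wd[0], cpg = wd[2], Cout = wd[3];
  const int Ho = out_side(H, k, stride, pad);
  const int Wo = out_side(W, k, stride, pad);
  const int copg = Cout / groups;

  NumericVector gx(((size_t)H) * W * Cin);
  gx.attr("dim") = IntegerVector::create(H, W, Cin);
  NumericVector gw(w.size());
  gw.attr("dim") = wd;

  arma::mat A(((size_t)Ho) * Wo, (size_t)k * k * cpg);
  for (int g = 0; g < groups; ++g) {
    im2col_group(x.begin(), H, W, cpg, g * cpg, k, stride, pad, A);
    arma::mat Gy(((size_t)Ho) * Wo, copg);
    std::copy(gy.begin() + ((size_t)g * copg) * Ho * Wo,
              gy.begin() + ((size_t)(g + 1) * copg) * Ho * Wo, Gy.begin());
    arma::mat Wg((size_t)k * k * cpg, copg);
    for (int co = 0; co < copg; ++co) {
      const double* wsl = w.begin() + ((size_t)(g * copg + co)) * k * k * cpg;
      std::copy(wsl, wsl + (size_t)k * k * cpg, Wg.colptr(co));
    }
    arma::mat GW = A.t() * Gy;            // (k*k*cpg) x copg
    for (int co = 0; co < copg; ++co) {
      double* gsl = gw.begin() + ((size_t)(g * copg + co)) * k * k * cpg;
      const double* src = GW.colptr(co);
      for (size_t q = 0; q < (size_t)k * k * cpg; ++q) gsl[q] += src[q];
    }
    arma::mat GA = Gy * Wg.t();           // (Ho*Wo) x (k*k*cpg): col2im scatter
    for (int ci = 0; ci < cpg; ++ci) {
      double* gxc = gx.begin() + (size_t)(g * cpg + ci) * H * W;
      for (int kj = 0; kj < k; ++kj) {
        for (int ki = 0; ki < k; ++ki) {
          const int q = ki + k * (kj + k * ci);
          const double* ga = GA.colptr(q);
          for (int oj = 0; oj < Wo; ++oj) {
            const int j = oj * stride + kj - pad;
            if (j < 0 || j >= W) continue;
            for (int oi = 0; oi < Ho; ++oi) {
              const int i = oi * stride + ki - pad;
              if (i < 0 || i >= H) continue;
              gxc[i + (size_t)H * j] += ga[oi + (size_t)Ho * oj];
            }
          }
        }
      }
    }
  }
  SEXP gb = R_NilValue;
  if (has_bias) {
    NumericVector gbv(Cout);
    for (int c = 0; c < Cout; ++c) {
      double s = 0.0;
      const double* gp = gy.begin() + (size_t)c * Ho * Wo;
      for (size_t p = 0; p < (size_t)Ho * Wo; ++p) s += gp[p];
      gbv[c] = s;
    }
    gb = gbv;
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// [[Rcpp::export]]
List maxpool_fw(NumericVector x, int k, int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2];
  const int Ho = out_side(H, k, stride, pad);
  const int Wo = out_side(W, k, stride, pad);
  NumericVector y(((size_t)Ho) * Wo * C);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C);
  IntegerVector idx(y.size());  // 1-based linear index into x of the argmax
  for (int c = 0; c < C; ++c) {
    const double* xc = x.begin() + (size_t)c * H * W;
    for (int oj = 0; oj < Wo; ++oj) {
      for (int oi = 0; oi < Ho; ++oi) {
        double best = -INFINITY; long besti = -1;
        for (int kj = 0; kj < k; ++kj) {
          const int j = oj * stride + kj - pad;
          if (j < 0 || j >= W) continue;
          for (int ki = 0; ki < k; ++ki) {
            const int i = oi * stride + ki - pad;
            if (i < 0 || i >= H) continue;
            const double v = xc[i + (size_t)H * j];
            if (v > best) { best = v; besti = i + (size_t)H * j; }
          }
        }
        const size_t p = oi + (size_t)Ho * (oj + (size_t)Wo * c);
        y[p] = best;
        idx[p] = (int)((size_t)c * H * W + besti + 1);
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector maxpool_bw(NumericVector gy, IntegerVector idx, IntegerVector xdim) {
  NumericVector gx(((size_t)xdim[0]) * xdim[1] * xdim[2]);
  gx.attr("dim") = xdim;
  for (R_xlen_t p = 0; p < gy.size(); ++p) gx[idx[p] - 1] += gy[p];
  return gx;
}

// ---- IEEE 754 binary16 codec (round to nearest even) ----

static uint16_t f32_to_f16(float f) {
  uint32_t x; std::memcpy(&x, &f, 4);
  const uint32_t sign = (x >> 16) & 0x8000u;
  uint32_t mant = x & 0x007FFFFFu;
  int32_t  exp  = (int32_t)((x >> 23) & 0xFFu) - 127 + 15;
  if (((x >> 23) & 0xFFu) == 0xFFu)  // inf / nan
    return (uint16_t)(sign | 0x7C00u | (mant ? 0x200u : 0u));
  if (exp >= 31) return (uint16_t)(sign | 0x7C00u);  // overflow -> inf
  if (exp <= 0) {                                    // subnormal / underflow
    if (exp < -10) return (uint16_t)sign;
    mant |= 0x00800000u;
    const int shift = 14 - exp;
    uint32_t half = mant >> shift;
    const uint32_t rem = mant & ((1u << shift) - 1u);
    const uint32_t halfway = 1u << (shift - 1);
    if (rem > halfway || (rem == halfway && (half & 1u))) half++;
    return (uint16_t)(sign | half);
  }
  uint32_t half = (uint32_t)(exp << 10) | (mant >> 13);
  const uint32_t rem = mant & 0x1FFFu;
  if (rem > 0x1000u || (rem == 0x1000u && (half & 1u))) half++;
  return (uint16_t)(sign | half);
}

static float f16_to_f32(uint16_t h) {
  const uint32_t sign = (uint32_t)(h & 0x8000u) << 16;
  uint32_t exp = (h >> 10) & 0x1Fu;
  uint32_t mant = h & 0x3FFu;
  uint32_t x;
  if (exp == 0) {
    if (mant == 0) { x = sign; }
    else {
      exp = 1;
      while (!(mant & 0x400u)) { mant <<= 1; exp--; }
      mant &= 0x3FFu;
      x = sign | ((exp + 112u) << 23) | (mant << 13);
    }
  } else if (exp == 31) {
    x = sign | 0x7F800000u | (mant << 13);
  } else {
    x = sign | ((exp + 112u) << 23) | (mant << 13);
  }
  float f; std::memcpy(&f, &x, 4);
  return f;
}

// [[Rcpp::export]]
RawVector double_to_half(NumericVector v) {
  RawVector out(v.size() * 2);
  for (R_xlen_t i = 0; i < v.size(); ++i) {
    const uint16_t h = f32_to_f16((float)v[i]);
    out[2 * i]     = (Rbyte)(h & 0xFFu);
    out[2 * i + 1] = (Rbyte)(h >> 8);
  }
  return out;
}

// [[Rcpp::export]]
NumericVector half_to_double(RawVector r) {
  NumericVector out(r.size() / 2);
  for (R_xlen_t i = 0; i < out.size(); ++i) {
    const uint16_t h = (uint16_t)r[2 * i] | ((uint16_t)r[2 * i + 1] << 8);
    out[i] = (double)f16_to_f32(h);
  }
  return out;
}
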