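#include <Rcpp.h>
using namespace Rcpp;

// Heterogeneous dilated convolution, forward pass.
//
// x      : H x W x C input activations (column-major R array)
// wl     : K x K x C x N large-kernel weights (entries only read where mask==1)
// wp     : C x N pointwise weights (entries only read where mask==0)
// bias   : length-N filter biases
// mask   : C x N integer, 1 = LARGE (K x K dilated), 0 = POINTWISE (1 x 1)
//
// Same-padding contract: the dilated branch is padded by r*(K-1)/2 per side,
// the pointwise branch by 0, so both branches produce floor((dim-1)/stride)+1
// outputs and stay spatially aligned for summation.
// Convolution is the cross-correlation convention (no kernel flip).
// [[Rcpp::export]]
NumericVector cpp_dhconv_forward(NumericVector x, IntegerVector xdim,
                                 NumericVector wl, NumericVector wp,
                                 NumericVector bias, IntegerVector mask,
                                 int K, int r, int stride, bool use_bias) {
  const int H = xdim[0], W = xdim[1], C = xdim[2];
  const int N = bias.size();
  const int pad = r * (K - 1) / 2;
  const int Ho = (H - 1) / stride + 1;
  const int Wo = (W - 1) / stride + 1;
  NumericVector out(static_cast<R_xlen_t>(Ho) * Wo * N);

  for (int f = 0; f < N; ++f) {
    const R_xlen_t obase = static_cast<R_xlen_t>(Ho) * Wo * f;
    for (int c = 0; c < C; ++c) {
      const R_xlen_t xbase = static_cast<R_xlen_t>(H) * W * c;
      if (mask[c + C * f] == 1) {
        const R_xlen_t wbase = static_cast<R_xlen_t>(K) * K * (c + static_cast<R_xlen_t>(C) * f);
        for (int oj = 0; oj < Wo; ++oj) {
          const int bx = oj * stride - pad;
          for (int oi = 0; oi < Ho; ++oi) {
            const int by = oi * stride - pad;
            double acc = 0.0;
            for (int kj = 0; kj < K; ++kj) {
              const int xj = bx + kj * r;
              if (xj < 0 || xj >= W) continue;
              for (int ki = 0; ki < K; ++ki) {
                const int xi = by + ki * r;
                if (xi < 0 || xi >= H) continue;
                acc += x[xbase + xi + static_cast<R_xlen_t>(H) * xj] * wl[wbase + ki + K * kj];
              }
            }
            out[obase + oi + static_cast<R_xlen_t>(Ho) * oj] += acc;
          }
        }
      } else {
        const double w = wp[c + C * f];
        for (int oj = 0; oj < Wo; ++oj) {
          const int xj = oj * stride;
          for (int oi = 0; oi < Ho; ++oi) {
            const int xi = oi * stride;
            out[obase + oi + static_cast<R_xlen_t>(Ho) * oj] +=
              w * x[xbase + xi + static_cast<R_xlen_t>(H) * xj];
          }
        }
      }
    }
    if (use_bias) {
      const double b = bias[f];
      for (R_xlen_t k = 0; k < static_cast<R_xlen_t>(Ho) * Wo; ++k) out[obase + k] += b;
    }
  }
  out.attr("dim") = IntegerVector::create(Ho, Wo, N);
  return out;
}

// Backward pass: gradients w.r.t. input, both weight banks and bias given the
// gradient of the loss w.r.t. the layer output.
// [[Rcpp::export]]
List cpp_dhconv_backward(NumericVector x, IntegerVector xdim, NumericVector gout,
                         NumericVector wl, NumericVector wp, IntegerVector mask,
                         int K, int r, int stride, bool use_bias, int N) {
  const int H = xdim[0], W = xdim[1], C = xdim[2];
  const int pad = r * (K - 1) / 2;
  const int Ho = (H - 1) / stride + 1;
  const int Wo = (W - 1) / stride + 1;

  NumericVector gx(static_cast<R_xlen_t>(H) * W * C);
  NumericVector gwl(static_cast<R_xlen_t>(K) * K * C * N);
  NumericVector gwp(static_cast<R_xlen_t>(C) * N);
  NumericVector gbias(N);

  for (int f = 0; f < N; ++f) {
    const R_xlen_t obase = static_cast<R_xlen_t>(Ho) * Wo * f;
    for (int c = 0; c < C; ++c) {
      const R_xlen_t xbase = static_cast<R_xlen_t>(H) * W * c;
      if (mask[c + C * f] == 1) {
        const R_xlen_t wbase = static_cast<R_xlen_t>(K) * K * (c + static_cast<R_xlen_t>(C) * f);
        for (int oj = 0; oj < Wo; ++oj) {
          const int bx = oj * stride - pad;
          for (int oi = 0; oi < Ho; ++oi) {
            const int by = oi * stride - pad;
            const double g = gout[obase + oi + static_cast<R_xlen_t>(Ho) * oj];
            if (g == 0.0) continue;
            for (int kj = 0; kj < K; ++kj) {
              const int xj = bx + kj * r;
              if (xj < 0 || xj >= W) continue;
              for (int ki = 0; ki < K; ++ki) {
                const int xi = by + ki * r;
                if (xi < 0 || xi >= H) continue;
                const R_xlen_t xoff = xbase + xi + static_cast<R_xlen_t>(H) * xj;
                gwl[wbase + ki + K * kj] += g * x[xoff];
                gx[xoff] += g * wl[wbase + ki + K * kj];
              }
            }
          }
        }
      } else {
        const double w = wp[c + C * f];
        double gw = 0.0;
        for (int oj = 0; oj < Wo; ++oj) {
          const int xj = oj * stride;
          for (int oi = 0; oi < Ho; ++oi) {
            const int xi = oi * stride;
            const double g = gout[obase + oi + static_cast<R_xlen_t>(Ho) * oj];
            const R_xlen_t xoff = xbase + xi + static_cast<R_xlen_t>(H) * xj;
            gw += g * x[xoff];
            gx[xoff] += g * w;
          }
        }
        gwp[c + static_cast<R_xlen_t>(C) * f] += gw;
      }
    }
    if (use_bias) {
      double gb = 0.0;
      for (R_xlen_t k = 0; k < static_cast<R_xlen_t>(Ho) * Wo; ++k) gb += gout[obase + k];
      gbias[f] = gb;
    }
  }
  gx.attr("dim") = IntegerVector::create(H, W, C);
  gwl.attr("dim") = IntegerVector::create(K, K, C, N);
  gwp.attr("dim") = IntegerVector::create(C, N);
  return List::create(_["gx"] = gx, _["gwl"] = gwl, _["gwp"] = gwp, _["gbias"] = gbias);
}
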