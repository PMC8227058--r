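// Minimal convolutional-regression kernels: im2col/col2im convolution,
// non-overlapping average/max pooling, and per-channel batch
// normalization. Batches are R arrays H x W x C x N (column-major);
// convolution weights are F x (k*k*C) matrices with row-filter layout
// (kh fastest, then kw, then channel).
//
// The unfolded patch matrix is kept TRANSPOSED, (Ho*Wo*N) x (k*k*C), so
// that for stride-1 convolutions every (c, kw, kh) column is filled with
// contiguous runs along ho (memcpy), and the forward/backward products
// reduce to plain BLAS GEMMs on that layout.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int outdim(int n, int k, int stride, int pad) {
  return (n + 2 * pad - k) / stride + 1;
}

// Fill colsT ((Ho*Wo*N) x (k*k*C)) from the input batch.
static void im2colT(const double* xp, int H, int W, int C, int N,
                    int k, int stride, int pad, int Ho, int Wo,
                    arma::mat& colsT) {
  const size_t HoWo = (size_t)Ho * Wo;
  if (stride == 1) {
    for (int c = 0; c < C; ++c) {
      for (int kw = 0; kw < k; ++kw) {
        for (int kh = 0; kh < k; ++kh) {
          double* col = colsT.colptr(kh + k * kw + k * k * c);
          // valid ho range: 0 <= ho - pad + kh < H
          const int ho_lo = std::max(0, pad - kh);
          const int ho_hi = std::min(Ho, H + pad - kh); // exclusive
          for (int n = 0; n < N; ++n) {
            const double* xc = xp + (size_t)H * W * ((size_t)c + (size_t)C * n);
            for (int wo = 0; wo < Wo; ++wo) {
              double* dst = col + (size_t)Ho * wo + HoWo * n;
              const int wi = wo - pad + kw;
              if (wi < 0 || wi >= W) {
                std::memset(dst, 0, sizeof(double) * Ho);
                continue;
              }
              if (ho_lo > 0) std::memset(dst, 0, sizeof(double) * ho_lo);
              if (ho_hi < Ho) {
                std::memset(dst + ho_hi, 0, sizeof(double) * (Ho - ho_hi));
              }
              if (ho_hi > ho_lo) {
                std::memcpy(dst + ho_lo,
                            xc + (ho_lo - pad + kh) + (size_t)H * wi,
                            sizeof(double) * (ho_hi - ho_lo));
              }
            }
          }
        }
      }
    }
  } else {
    colsT.zeros();
    for (int c = 0; c < C; ++c) {
      for (int kw = 0; kw < k; ++kw) {
        for (int kh = 0; kh < k; ++kh) {
          double* col = colsT.colptr(kh + k * kw + k * k * c);
          for (int n = 0; n < N; ++n) {
            const double* xc = xp + (size_t)H * W * ((size_t)c + (size_t)C * n);
            for (int wo = 0; wo < Wo; ++wo) {
              const int wi = wo * stride - pad + kw;
              if (wi < 0 || wi >= W) continue;
              double* dst = col + (size_t)Ho * wo + HoWo * n;
              for (int ho = 0; ho < Ho; ++ho) {
                const int hi = ho * stride - pad + kh;
                if (hi >= 0 && hi < H) dst[ho] = xc[hi + (size_t)H * wi];
              }
            }
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
List conv_forward_cpp(NumericVector x, IntegerVector dims,
                      NumericMatrix Wm, NumericVector b,
                      int k, int stride, int pad) {
  const int H = dims[0], W = dims[1], C = dims[2], N = dims[3];
  const int Ho = outdim(H, k, stride, pad), Wo = outdim(W, k, stride, pad);
  const int F = Wm.nrow();
  if (Ho < 1 || Wo < 1) stop("Convolution output would be empty.");
  if (Wm.ncol() != k * k * C) stop("Weight matrix does not match k*k*C.");
  const size_t HoWo = (size_t)Ho * Wo;

  arma::mat colsT(HoWo * N, (size_t)k * k * C, arma::fill::none);
  im2colT(x.begin(), H, W, C, N, k, stride, pad, Ho, Wo, colsT);

  const arma::mat Wa(Wm.begin(), F, Wm.ncol(), false);
  arma::mat outT = colsT * Wa.t(); // (Ho*Wo*N) x F
  const arma::vec bv(b.begin(), F);
  outT.each_row() += bv.t();

  NumericVector out(HoWo * F * N);
  double* op = out.begin();
  for (int f = 0; f < F; ++f) {
    const double* src = outT.colptr(f);
    for (int n = 0; n < N; ++n) {
      std::memcpy(op + HoWo * ((size_t)f + (size_t)F * n),
                  src + HoWo * n, sizeof(double) * HoWo);
    }
  }
  out.attr("dim") = IntegerVector::create(Ho, Wo, F, N);
  return List::create(_["out"] = out);
}

// [[Rcpp::export]]
List conv_backward_cpp(NumericVector dout, IntegerVector dout_dims,
                       NumericVector x, NumericMatrix Wm,
                       IntegerVector in_dims, int k, int stride, int pad,
                       bool need_dx) {
  const int Ho = dout_dims[0], Wo = dout_dims[1], F = dout_dims[2], N = dout_dims[3];
  const int H = in_dims[0], W = in_dims[1], C = in_dims[2];
  const int N_in = in_dims[3];
  const size_t HoWo = (size_t)Ho * Wo;

  // rebuild the unfolded input (cheaper than round-tripping it through R)
  arma::mat colsT(HoWo * N, (size_t)k * k * C, arma::fill::none);
  im2colT(x.begin(), H, W, C, N_in, k, stride, pad, Ho, Wo, colsT);

  arma::mat doutT(HoWo * N, F, arma::fill::none);
  const double* dp = dout.begin();
  for (int f = 0; f < F; ++f) {
    double* dst = doutT.colptr(f);
    for (int n = 0; n < N; ++n) {
      std::memcpy(dst + HoWo * n, dp + HoWo * ((size_t)f + (size_t)F * n),
                  sizeof(double) * HoWo);
    }
  }

  const arma::mat Wa(Wm.begin(), F, Wm.ncol(), false);
  arma::mat dW = doutT.t() * colsT;       // F x (k*k*C)
  arma::vec db = arma::sum(doutT, 0).t(); // F
  if (!need_dx) {
    return List::create(_["dW"] = dW, _["db"] = db, _["dx"] = R_NilValue);
  }
  arma::mat dcolsT = doutT * Wa;          // (Ho*Wo*N) x (k*k*C)

  NumericVector dx((size_t)H * W * C * N); // zero-initialized
  double* xp = dx.begin();
  for (int c = 0; c < C; ++c) {
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh) {
        const double* col = dcolsT.colptr(kh + k * kw + k * k * c);
        for (int n = 0; n < N; ++n) {
          double* xc = xp + (size_t)H * W * ((size_t)c + (size_t)C * n);
          for (int wo = 0; wo < Wo; ++wo) {
            const int wi = wo * stride - pad + kw;
            if (wi < 0 || wi >= W) continue;
            const double* src = col + (size_t)Ho * wo + HoWo * n;
            for (int ho = 0; ho < Ho; ++ho) {
              const int hi = ho * stride - pad + kh;
              if (hi >= 0 && hi < H) xc[hi + (size_t)H * wi] += src[ho];
            }
          }
        }
      }
    }
  }
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  return List::create(_["dW"] = dW, _["db"] = db, _["dx"] = dx);
}

// Non-overlapping pooling (stride == size). type: 0 = avg, 1 = max.
// [[Rcpp::export]]
List pool_forward_cpp(NumericVector x, IntegerVector dims, int size, int type) {
  const int H = dims[0], W = dims[1], C = dims[2], N = dims[3];
  const int Ho = H / size, Wo = W / size;
  if (Ho < 1 || Wo < 1) stop("Pooling output would be empty.");
  NumericVector out((size_t)Ho * Wo * C * N);
  IntegerVector idx(type == 1 ? (size_t)Ho * Wo * C * N : 0);
  const double* xp = x.begin();
  double* op = out.begin();
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* xc = xp + (size_t)H * W * ((size_t)c + (size_t)C * n);
      double* oc = op + (size_t)Ho * Wo * ((size_t)c + (size_t)C * n);
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          double best = -1e300, acc = 0.0;
          int besti = 0;
          for (int dw = 0; dw < size; ++dw) {
            for (int dh = 0; dh < size; ++dh) {
              const int hi = ho * size + dh, wi = wo * size + dw;
              const double v = xc[hi + (size_t)H * wi];
              if (type == 0) acc += v;
              else if (v > best) { best = v; besti = hi + H * wi; }
            }
          }
          const size_t oi = (size_t)ho + (size_t)Ho * wo;
          oc[oi] = (type == 0) ? acc / (size * size) : best;
          if (type == 1) {
            idx[(size_t)Ho * Wo * ((size_t)c + (size_t)C * n) + oi] = besti;
          }
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  return List::create(_["out"] = out, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector pool_backward_cpp(NumericVector dout, IntegerVector out_dims,
                                IntegerVector in_dims, int size, int type,
                                IntegerVector idx) {
  const int Ho = out_dims[0], Wo = out_dims[1], C = out_dims[2], N = out_dims[3];
  const int H = in_dims[0], W = in_dims[1];
  NumericVector dx((size_t)H * W * C * N);
  const double* dp = dout.begin();
  double* xp = dx.begin();
  const double inv = 1.0 / (size * size);
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* dc = dp + (size_t)Ho * Wo * ((size_t)c + (size_t)C * n);
      double* xc = xp + (size_t)H * W * ((size_t)c + (size_t)C * n);
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          const size_t oi = (size_t)ho + (size_t)Ho * wo;
          const double g = dc[oi];
          if (type == 0) {
            for (int dw = 0; dw < size; ++dw) {
              for (int dh = 0; dh < size; ++dh) {
                xc[(ho * size + dh) + (size_t)H * (wo * size + dw)] += g * inv;
              }
            }
          } else {
            xc[idx[(size_t)Ho * Wo * ((size_t)c + (size_t)C * n) + oi]] += g;
          }
        }
      }
    }
  }
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  return dx;
}

// Batch normalization over (H, W, N) per channel.
// [[Rcpp::export]]
List bn_forward_cpp(NumericVector x, IntegerVector dims,
                    NumericVector gamma, NumericVector beta, double eps) {
  const int H = dims[0], W = dims[1], C = dims[2], N = dims[3];
  const size_t plane = (size_t)H * W;
  const double m = (double)plane * N;
  NumericVector out(x.size());
  NumericVector xhat(x.size());
  NumericVector mean_c(C), invstd_c(C), var_c(C);
  const double* xp = x.begin();
  for (int c = 0; c < C; ++c) {
    double s = 0.0, s2 = 0.0;
    for (int n = 0; n < N; ++n) {
      const double* xc = xp + plane * ((size_t)c + (size_t)C * n);
      for (size_t i = 0; i < plane; ++i) { s += xc[i]; s2 += xc[i] * xc[i]; }
    }
    const double mu = s / m;
    const double var = std::max(s2 / m - mu * mu, 0.0);
    const double inv = 1.0 / std::sqrt(var + eps);
    mean_c[c] = mu; invstd_c[c] = inv; var_c[c] = var;
    for (int n = 0; n < N; ++n) {
      const size_t off = plane * ((size_t)c + (size_t)C * n);
      const double* xc = xp + off;
      double* oc = out.begin() + off;
      double* hc = xhat.begin() + off;
      for (size_t i = 0; i < plane; ++i) {
        const double h = (xc[i] - mu) * inv;
        hc[i] = h;
        oc[i] = gamma[c] * h + beta[c];
      }
    }
  }
  out.attr("dim") = dims;
  xhat.attr("dim") = dims;
  return List::create(_["out"] = out, _["xhat"] = xhat,
                      _["mean"] = mean_c, _["var"] = var_c,
                      _["invstd"] = invstd_c);
}

// [[Rcpp::export]]
List bn_backward_cpp(NumericVector dout, NumericVector xhat,
                     IntegerVector dims, NumericVector gamma,
                     NumericVector invstd) {
  const int H = dims[0], W = dims[1], C = dims[2], N = dims[3];
  const size_t plane = (size_t)H * W;
  const double m = (double)plane * N;
  NumericVector dx(dout.size());
  NumericVector dgamma(C), dbeta(C);
  const double* dp = dout.begin();
  const double* hp = xhat.begin();
  for (int c = 0; c < C; ++c) {
    double sg = 0.0, sb = 0.0;
    for (int n = 0; n < N; ++n) {
      const size_t off = plane * ((size_t)c + (size_t)C * n);
      for (size_t i = 0; i < plane; ++i) {
        sg += dp[off + i] * hp[off + i];
        sb += dp[off + i];
      }
    }
    dgamma[c] = sg; dbeta[c] = sb;
    const double g = gamma[c] * invstd[c];
    for (int n = 0; n < N; ++n) {
      const size_t off = plane * ((size_t)c + (size_t)C * n);
      double* xc = dx.begin() + off;
      for (size_t i = 0; i < plane; ++i) {
        xc[i] = g * (dp[off + i] - sb / m - hp[off + i] * sg / m);
      }
    }
  }
  dx.attr("dim") = dims;
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// Inference-mode batch norm with fixed (running) statistics.
// [[Rcpp::export]]
NumericVector bn_infer_cpp(NumericVector x, IntegerVector dims,
                           NumericVector gamma, NumericVector beta,
                           NumericVector rmean, NumericVector rvar,
                           double eps) {
  const int H = dims[0], W = dims[1], C = dims[2], N = dims[3];
  const size_t plane = (size_t)H * W;
  NumericVector out(x.size());
  const double* xp = x.begin();
  for (int c = 0; c < C; ++c) {
    const double inv = 1.0 / std::sqrt(rvar[c] + eps);
    for (int n = 0; n < N; ++n) {
      const size_t off = plane * ((size_t)c + (size_t)C * n);
      double* oc = out.begin() + off;
      const double* xc = xp + off;
      for (size_t i = 0; i < plane; ++i) {
        oc[i] = gamma[c] * (xc[i] - rmean[c]) * inv + beta[c];
      }
    }
  }
  out.attr("dim") = dims;
  return out;
}
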