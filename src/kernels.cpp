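// Hot numeric kernels for the CNN engine. Layer orchestration and the dense
// matrix products live in R; these routines cover the memory-bound gather,
// scatter, depthwise and normalization steps.

#include <Rcpp.h>
using namespace Rcpp;

// expand a per-sample gather map (P_out x K, 0 = padding) to batch rows;
// padding entries become 0 in the result
// [[Rcpp::export]]
IntegerMatrix cpp_expand_gather(const IntegerMatrix& idx, int B, int P_in) {
  const int P = idx.nrow(), K = idx.ncol();
  IntegerMatrix G(B * P, K);
  for (int k = 0; k < K; ++k) {
    for (int b = 0; b < B; ++b) {
      const int off_in = b * P_in, off_out = b * P;
      for (int r = 0; r < P; ++r) {
        const int v = idx(r, k);
        G(off_out + r, k) = v == 0 ? 0 : v + off_in;
      }
    }
  }
  return G;
}

// patches(r, (k-1)*C + c) = A(G(r,k), c), zero at padding
// [[Rcpp::export]]
NumericMatrix cpp_gather_patches(const NumericMatrix& A,
                                 const IntegerMatrix& G) {
  const int R = G.nrow(), K = G.ncol(), C = A.ncol();
  NumericMatrix P(R, K * C);
  for (int k = 0; k < K; ++k) {
    for (int c = 0; c < C; ++c) {
      const int pc = k * C + c;
      for (int r = 0; r < R; ++r) {
        const int g = G(r, k);
        if (g > 0) P(r, pc) = A(g - 1, c);
      }
    }
  }
  return P;
}

// accumulate patch gradients back onto input rows
// [[Rcpp::export]]
NumericMatrix cpp_scatter_patches(const NumericMatrix& dP,
                                  const IntegerMatrix& G, int n_in, int C) {
  const int R = G.nrow(), K = G.ncol();
  NumericMatrix dA(n_in, C);
  for (int k = 0; k < K; ++k) {
    for (int c = 0; c < C; ++c) {
      const int pc = k * C + c;
      for (int r = 0; r < R; ++r) {
        const int g = G(r, k);
        if (g > 0) dA(g - 1, c) += dP(r, pc);
      }
    }
  }
  return dA;
}

// depthwise convolution: Y(r, c) = sum_k A(G(r,k), c) * W(k, c)
// [[Rcpp::export]]
NumericMatrix cpp_dwconv_fwd(const NumericMatrix& A, const IntegerMatrix& G,
                             const NumericMatrix& W) {
  const int R = G.nrow(), K = G.ncol(), C = A.ncol();
  NumericMatrix Y(R, C);
  for (int c = 0; c < C; ++c) {
    for (int k = 0; k < K; ++k) {
      const double w = W(k, c);
      if (w == 0.0) continue;
      for (int r = 0; r < R; ++r) {
        const int g = G(r, k);
        if (g > 0) Y(r, c) += A(g - 1, c) * w;
      }
    }
  }
  return Y;
}

// gradients of the depthwise convolution
// [[Rcpp::export]]
List cpp_dwconv_bwd(const NumericMatrix& A, const IntegerMatrix& G,
                    const NumericMatrix& W, const NumericMatrix& dY,
                    int n_in) {
  const int R = G.nrow(), K = G.ncol(), C = A.ncol();
  NumericMatrix dW(K, C), dA(n_in, C);
  for (int c = 0; c < C; ++c) {
    for (int k = 0; k < K; ++k) {
      const double w = W(k, c);
      double acc = 0.0;
      for (int r = 0; r < R; ++r) {
        const int g = G(r, k);
        if (g > 0) {
          const double d = dY(r, c);
          acc += A(g - 1, c) * d;
          dA(g - 1, c) += w * d;
        }
      }
      dW(k, c) = acc;
    }
  }
  return List::create(_["W"] = dW, _["dA"] = dA);
}

// column-wise affine: Y = X * scale[col] + shift[col]
// [[Rcpp::export]]
NumericMatrix cpp_col_affine(const NumericMatrix& X,
                             const NumericVector& scale,
                             const NumericVector& shift) {
  const int n = X.nrow(), C = X.ncol();
  NumericMatrix Y(n, C);
  for (int c = 0; c < C; ++c) {
    const double s = scale[c], t = shift[c];
    for (int r = 0; r < n; ++r) Y(r, c) = X(r, c) * s + t;
  }
  return Y;
}

// batch-norm forward: returns xhat and the affine output in one pass
// [[Rcpp::export]]
List cpp_bn_fwd(const NumericMatrix& A, const NumericVector& mu,
                const NumericVector& inv_sd, const NumericVector& gamma,
                const NumericVector& beta) {
  const int n = A.nrow(), C = A.ncol();
  NumericMatrix xhat(n, C), Y(n, C);
  for (int c = 0; c < C; ++c) {
    const double m = mu[c], s = inv_sd[c], g = gamma[c], b = beta[c];
    for (int r = 0; r < n; ++r) {
      const double xh = (A(r, c) - m) * s;
      xhat(r, c) = xh;
      Y(r, c) = xh * g + b;
    }
  }
  return List::create(_["xhat"] = xhat, _["y"] = Y);
}

// batch-norm backward (training statistics)
// [[Rcpp::export]]
List cpp_bn_bwd(const NumericMatrix& dY, const NumericMatrix& xhat,
                const NumericVector& gamma, const NumericVector& inv_sd) {
  const int n = dY.nrow(), C = dY.ncol();
  NumericVector dgamma(C), dbeta(C);
  NumericMatrix dA(n, C);
  for (int c = 0; c < C; ++c) {
    double s1 = 0.0, s2 = 0.0, dg = 0.0, db = 0.0;
    const double g = gamma[c];
    for (int r = 0; r < n; ++r) {
      const double d = dY(r, c), xh = xhat(r, c);
      dg += d * xh;
      db += d;
      const double dxh = d * g;
      s1 += dxh;
      s2 += dxh * xh;
    }
    dgamma[c] = dg;
    dbeta[c] = db;
    const double m1 = s1 / n, m2 = s2 / n, s = inv_sd[c];
    for (int r = 0; r < n; ++r) {
      dA(r, c) = (dY(r, c) * g - m1 - xhat(r, c) * m2) * s;
    }
  }
  return List::create(_["dgamma"] = dgamma, _["dbeta"] = dbeta,
                      _["dA"] = dA);
}

// clipped rectifier min(max(x, 0), 6)
// [[Rcpp::export]]
NumericMatrix cpp_relu6_fwd(const NumericMatrix& A) {
  const int n = A.nrow(), C = A.ncol();
  NumericMatrix Y(n, C);
  for (int c = 0; c < C; ++c) {
    for (int r = 0; r < n; ++r) {
      const double v = A(r, c);
      Y(r, c) = v <= 0.0 ? 0.0 : (v >= 6.0 ? 6.0 : v);
    }
  }
  return Y;
}

// gradient mask derived from the forward output (strictly inside (0, 6))
// [[Rcpp::export]]
NumericMatrix cpp_relu6_bwd(const NumericMatrix& dY, const NumericMatrix& Y) {
  const int n = dY.nrow(), C = dY.ncol();
  NumericMatrix dA(n, C);
  for (int c = 0; c < C; ++c) {
    for (int r = 0; r < n; ++r) {
      const double y = Y(r, c);
      dA(r, c) = (y > 0.0 && y < 6.0) ? dY(r, c) : 0.0;
    }
  }
  return dA;
}

// fused batch-norm + clipped rectifier forward
// [[Rcpp::export]]
List cpp_bnact_fwd(const NumericMatrix& A, const NumericVector& mu,
                   const NumericVector& inv_sd, const NumericVector& gamma,
                   const NumericVector& beta) {
  const int n = A.nrow(), C = A.ncol();
  NumericMatrix xhat(n, C), Y(n, C);
  for (int c = 0; c < C; ++c) {
    const double m = mu[c], s = inv_sd[c], g = gamma[c], b = beta[c];
    for (int r = 0; r < n; ++r) {
      const double xh = (A(r, c) - m) * s;
      xhat(r, c) = xh;
      const double v = xh * g + b;
      Y(r, c) = v <= 0.0 ? 0.0 : (v >= 6.0 ? 6.0 : v);
    }
  }
  return List::create(_["xhat"] = xhat, _["y"] = Y);
}

// fused backward: rectifier mask (from the clipped output) then batch-norm
// [[Rcpp::export]]
List cpp_bnact_bwd(const NumericMatrix& dY, const NumericMatrix& Y,
                   const NumericMatrix& xhat, const NumericVector& gamma,
                   const NumericVector& inv_sd) {
  const int n = dY.nrow(), C = dY.ncol();
  NumericVector dgamma(C), dbeta(C);
  NumericMatrix dA(n, C);
  for (int c = 0; c < C; ++c) {
    double s1 = 0.0, s2 = 0.0, dg = 0.0, db = 0.0;
    const double g = gamma[c];
    for (int r = 0; r < n; ++r) {
      const double y = Y(r, c);
      const double d = (y > 0.0 && y < 6.0) ? dY(r, c) : 0.0;
      const double xh = xhat(r, c);
      dA(r, c) = d;  // temporarily store masked dY
      dg += d * xh;
      db += d;
      const double dxh = d * g;
      s1 += dxh;
      s2 += dxh * xh;
    }
    dgamma[c] = dg;
    dbeta[c] = db;
    const double m1 = s1 / n, m2 = s2 / n, s = inv_sd[c];
    for (int r = 0; r < n; ++r) {
      dA(r, c) = (dA(r, c) * g - m1 - xhat(r, c) * m2) * s;
    }
  }
  return List::create(_["dgamma"] = dgamma, _["dbeta"] = dbeta,
                      _["dA"] = dA);
}

// inference-mode fused affine + clip
// [[Rcpp::export]]
NumericMatrix cpp_affine_relu6(const NumericMatrix& X,
                               const NumericVector& scale,
                               const NumericVector& shift) {
  const int n = X.nrow(), C = X.ncol();
  NumericMatrix Y(n, C);
  for (int c = 0; c < C; ++c) {
    const double s = scale[c], t = shift[c];
    for (int r = 0; r < n; ++r) {
      const double v = X(r, c) * s + t;
      Y(r, c) = v <= 0.0 ? 0.0 : (v >= 6.0 ? 6.0 : v);
    }
  }
  return Y;
}
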