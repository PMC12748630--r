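// Layer kernels for the six-branch 1-D CNN.
//
// Activations are (channels, time * batch) matrices in column-major,
// time-fastest order. One convolutional block (convolution -> ReLU ->
// batch normalization -> max pool 2/2) is fused into a single forward and
// a single backward kernel: convolution is stride-1 with
// length-preserving padding, computed as a sum of time-shifted matrix
// products (BLAS), and the element-wise stages are explicit pointer loops
// so only the caches the backward pass needs cross the R boundary.
// Randomness (dropout, shuffling) stays on the R side so the training RNG
// contract is governed by R's seed alone.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// shift each sample's time axis by o (o = -1: value at t-1, zero-padded)
static arma::mat time_shift(const arma::mat& A, int o, int T, int N) {
  arma::mat S(A.n_rows, A.n_cols, arma::fill::zeros);
  int a = std::abs(o);
  if (a >= T) return S;
  for (int n = 0; n < N; ++n) {
    int base = n * T;
    if (o < 0) {
      S.cols(base + a, base + T - 1) = A.cols(base, base + T - 1 - a);
    } else {
      S.cols(base, base + T - 1 - a) = A.cols(base + a, base + T - 1);
    }
  }
  return S;
}

static arma::mat conv_core(const arma::mat& A, const arma::mat& W,
                           const arma::vec& b, int kernel, int pad,
                           int T, int N) {
  int C = A.n_rows;
  arma::mat Z(W.n_rows, A.n_cols, arma::fill::zeros);
  for (int j = 0; j < kernel; ++j) {
    int o = j - pad;
    const arma::mat Wj = W.cols(j * C, (j + 1) * C - 1);
    if (o == 0) {
      Z += Wj * A;
    } else {
      Z += Wj * time_shift(A, o, T, N);
    }
  }
  return Z;  // bias is folded into the element-wise pass
}

// Fused conv -> ReLU -> batch norm -> max pool(2, 2) forward.
// Training normalizes with the biased batch variance and keeps an
// unbiased estimate in the running averages; evaluation uses the running
// statistics. Pool ties take the earlier sample. Returns the pooled
// output plus the caches the backward kernel needs.
// [[Rcpp::export(name = ".cpp_block_fwd")]]
List cpp_block_fwd(const arma::mat& A, const arma::mat& W,
                   const arma::vec& b, const NumericVector& gamma,
                   const NumericVector& beta, const NumericVector& rm,
                   const NumericVector& rv, bool train, double eps,
                   double momentum, int kernel, int pad, int T, int N) {
  arma::mat Z = conv_core(A, W, b, kernel, pad, T, N);
  int C = Z.n_rows;
  R_xlen_t M = Z.n_cols;
  const double* z = Z.memptr();
  const double* bi = b.memptr();
  NumericVector mu(C), s(C), rm_new(C), rv_new(C);
  if (train) {
    std::vector<double> sum(C, 0.0), sumsq(C, 0.0);
    const double* p = z;
    for (R_xlen_t j = 0; j < M; ++j, p += C) {
      for (int c = 0; c < C; ++c) {
        double zz = p[c] + bi[c];
        double r = zz > 0 ? zz : 0.0;
        sum[c] += r;
        sumsq[c] += r * r;
      }
    }
    for (int c = 0; c < C; ++c) {
      mu[c] = sum[c] / M;
      double v = sumsq[c] / M - mu[c] * mu[c];
      if (v < 0) v = 0;
      s[c] = std::sqrt(v + eps);
      double unb = (M > 1) ? v * ((double)M / (M - 1)) : v;
      rm_new[c] = (1 - momentum) * rm[c] + momentum * mu[c];
      rv_new[c] = (1 - momentum) * rv[c] + momentum * unb;
    }
  } else {
    for (int c = 0; c < C; ++c) {
      mu[c] = rm[c];
      s[c] = std::sqrt(rv[c] + eps);
      rm_new[c] = rm[c];
      rv_new[c] = rv[c];
    }
  }
  NumericMatrix xhat(C, M);
  LogicalMatrix mask(C, M);
  NumericMatrix out(C, M / 2);
  LogicalMatrix first(C, M / 2);
  double* xh = xhat.begin();
  int* mk = mask.begin();
  double* o = out.begin();
  int* fs = first.begin();
  for (R_xlen_t j = 0; j < M / 2; ++j) {
    const double* z1 = z + 2 * j * C;
    const double* z2 = z1 + C;
    double* x1 = xh + 2 * j * C;
    double* x2 = x1 + C;
    int* m1 = mk + 2 * j * C;
    int* m2 = m1 + C;
    double* oc = o + j * C;
    int* fc = fs + j * C;
    for (int c = 0; c < C; ++c) {
      double za = z1[c] + bi[c], zb = z2[c] + bi[c];
      bool p1 = za > 0, p2 = zb > 0;
      m1[c] = p1;
      m2[c] = p2;
      double xa = ((p1 ? za : 0.0) - mu[c]) / s[c];
      double xb = ((p2 ? zb : 0.0) - mu[c]) / s[c];
      x1[c] = xa;
      x2[c] = xb;
      double y1 = gamma[c] * xa + beta[c];
      double y2 = gamma[c] * xb + beta[c];
      bool take1 = y1 >= y2;
      fc[c] = take1;
      oc[c] = take1 ? y1 : y2;
    }
  }
  return List::create(_["out"] = out, _["xhat"] = xhat, _["s"] = s,
                      _["mask"] = mask, _["first"] = first,
                      _["rm"] = rm_new, _["rv"] = rv_new);
}

// Fused backward of one convolutional block. G is the gradient at the
// pooled output (C x M/2); returns gradients for the block input and all
// block parameters. In training mode the batch-normalization backward
// couples every position through the batch statistics, so the gradient is
// expanded over the full pre-pool extent before the convolution backward.
// [[Rcpp::export(name = ".cpp_block_bwd")]]
List cpp_block_bwd(const NumericMatrix& G, const NumericMatrix& xhat,
                   const NumericVector& s, const NumericVector& gamma,
                   const LogicalMatrix& mask, const LogicalMatrix& first,
                   bool train, const arma::mat& W, const arma::mat& A,
                   int kernel, int pad, int T, int N) {
  int C = G.nrow();
  R_xlen_t Mo = G.ncol();
  R_xlen_t M = 2 * Mo;
  const double* g = G.begin();
  const double* xh = xhat.begin();
  const int* mk = mask.begin();
  const int* fs = first.begin();
  NumericVector dgamma(C), dbeta(C);
  // accumulate bn sums over the unpooled gradient (zero off the argmax)
  std::vector<double> sg(C, 0.0), sgx(C, 0.0);
  for (R_xlen_t j = 0; j < Mo; ++j) {
    const double* gc = g + j * C;
    const int* fc = fs + j * C;
    const double* x1 = xh + 2 * j * C;
    const double* x2 = x1 + C;
    for (int c = 0; c < C; ++c) {
      sg[c] += gc[c];
      sgx[c] += gc[c] * (fc[c] ? x1[c] : x2[c]);
    }
  }
  std::vector<double> a1(C), a2(C), gs(C);
  for (int c = 0; c < C; ++c) {
    dgamma[c] = sgx[c];
    dbeta[c] = sg[c];
    a1[c] = train ? sg[c] / M : 0.0;
    a2[c] = train ? sgx[c] / M : 0.0;
    gs[c] = gamma[c] / s[c];
  }
  arma::mat dZ(C, M);
  double* d = dZ.memptr();
  for (R_xlen_t j = 0; j < Mo; ++j) {
    const double* gc = g + j * C;
    const int* fc = fs + j * C;
    const double* x1 = xh + 2 * j * C;
    const double* x2 = x1 + C;
    const int* m1 = mk + 2 * j * C;
    const int* m2 = m1 + C;
    double* d1 = d + 2 * j * C;
    double* d2 = d1 + C;
    for (int c = 0; c < C; ++c) {
      double dy1 = fc[c] ? gc[c] : 0.0;
      double dy2 = fc[c] ? 0.0 : gc[c];
      d1[c] = m1[c] ? gs[c] * (dy1 - a1[c] - x1[c] * a2[c]) : 0.0;
      d2[c] = m2[c] ? gs[c] * (dy2 - a1[c] - x2[c] * a2[c]) : 0.0;
    }
  }
  // convolution backward
  int Ci = A.n_rows;
  arma::mat dW(W.n_rows, W.n_cols, arma::fill::zeros);
  arma::mat dA(A.n_rows, A.n_cols, arma::fill::zeros);
  for (int j = 0; j < kernel; ++j) {
    int o = j - pad;
    const arma::mat Wj = W.cols(j * Ci, (j + 1) * Ci - 1);
    if (o == 0) {
      dW.cols(j * Ci, (j + 1) * Ci - 1) = dZ * A.t();
      dA += Wj.t() * dZ;
    } else {
      dW.cols(j * Ci, (j + 1) * Ci - 1) = dZ * time_shift(A, o, T, N).t();
      dA += time_shift(Wj.t() * dZ, -o, T, N);
    }
  }
  arma::vec db = arma::sum(dZ, 1);
  return List::create(_["dA"] = dA, _["dW"] = dW, _["db"] = db,
                      _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// Fused ReLU -> batch normalization (dense stage; no pooling).
// [[Rcpp::export(name = ".cpp_relu_bn_fwd")]]
List cpp_relu_bn_fwd(const NumericMatrix& Z, const NumericVector& gamma,
                     const NumericVector& beta, const NumericVector& rm,
                     const NumericVector& rv, bool train, double eps,
                     double momentum) {
  int C = Z.nrow();
  R_xlen_t M = Z.ncol();
  NumericVector mu(C), s(C), rm_new(C), rv_new(C);
  NumericMatrix xhat(C, M), out(C, M);
  LogicalMatrix mask(C, M);
  const double* z = Z.begin();
  double* xh = xhat.begin();
  double* o = out.begin();
  int* mk = mask.begin();
  if (train) {
    std::vector<double> sum(C, 0.0), sumsq(C, 0.0);
    const double* p = z;
    for (R_xlen_t j = 0; j < M; ++j, p += C) {
      for (int c = 0; c < C; ++c) {
        double r = p[c] > 0 ? p[c] : 0.0;
        sum[c] += r;
        sumsq[c] += r * r;
      }
    }
    for (int c = 0; c < C; ++c) {
      mu[c] = sum[c] / M;
      double v = sumsq[c] / M - mu[c] * mu[c];
      if (v < 0) v = 0;
      s[c] = std::sqrt(v + eps);
      double unb = (M > 1) ? v * ((double)M / (M - 1)) : v;
      rm_new[c] = (1 - momentum) * rm[c] + momentum * mu[c];
      rv_new[c] = (1 - momentum) * rv[c] + momentum * unb;
    }
  } else {
    for (int c = 0; c < C; ++c) {
      mu[c] = rm[c];
      s[c] = std::sqrt(rv[c] + eps);
      rm_new[c] = rm[c];
      rv_new[c] = rv[c];
    }
  }
  const double* p = z;
  double* xp = xh;
  double* op = o;
  int* mp = mk;
  for (R_xlen_t j = 0; j < M; ++j, p += C, xp += C, op += C, mp += C) {
    for (int c = 0; c < C; ++c) {
      bool pos = p[c] > 0;
      mp[c] = pos;
      double x = ((pos ? p[c] : 0.0) - mu[c]) / s[c];
      xp[c] = x;
      op[c] = gamma[c] * x + beta[c];
    }
  }
  return List::create(_["out"] = out, _["xhat"] = xhat, _["s"] = s,
                      _["mask"] = mask, _["rm"] = rm_new, _["rv"] = rv_new);
}

// [[Rcpp::export(name = ".cpp_relu_bn_bwd")]]
List cpp_relu_bn_bwd(const NumericMatrix& G, const NumericMatrix& xhat,
                     const NumericVector& s, const NumericVector& gamma,
                     const LogicalMatrix& mask, bool train) {
  int C = G.nrow();
  R_xlen_t M = G.ncol();
  const double* g = G.begin();
  const double* xh = xhat.begin();
  const int* mk = mask.begin();
  NumericVector dgamma(C), dbeta(C);
  NumericMatrix dx(C, M);
  double* d = dx.begin();
  std::vector<double> sg(C, 0.0), sgx(C, 0.0);
  {
    const double* gp = g;
    const double* xp = xh;
    for (R_xlen_t j = 0; j < M; ++j, gp += C, xp += C) {
      for (int c = 0; c < C; ++c) {
        sg[c] += gp[c];
        sgx[c] += gp[c] * xp[c];
      }
    }
  }
  std::vector<double> a1(C), a2(C), gs(C);
  for (int c = 0; c < C; ++c) {
    dgamma[c] = sgx[c];
    dbeta[c] = sg[c];
    a1[c] = train ? sg[c] / M : 0.0;
    a2[c] = train ? sgx[c] / M : 0.0;
    gs[c] = gamma[c] / s[c];
  }
  const double* gp = g;
  const double* xp = xh;
  const int* mp = mk;
  double* dp = d;
  for (R_xlen_t j = 0; j < M; ++j, gp += C, xp += C, mp += C, dp += C) {
    for (int c = 0; c < C; ++c) {
      dp[c] = mp[c] ? gs[c] * (gp[c] - a1[c] - xp[c] * a2[c]) : 0.0;
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}
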