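// Compute kernels for the convolutional feature extractor: 3x3 stride-1
// "same" convolution with fused exact-erf GELU (forward and backward via
// im2col + GEMM), 2x2 stride-2 max pooling with ceil-mode windows, and the
// 3x3 stride-1 average pool used before global average pooling.
//
// Tensors are R arrays in column-major (H, W, C, N) layout throughout.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline double gelu_val(double x) {
  return 0.5 * x * (1.0 + std::erf(x * M_SQRT1_2));
}
static inline double gelu_grad(double x) {
  double Phi = 0.5 * (1.0 + std::erf(x * M_SQRT1_2));
  double phi = std::exp(-0.5 * x * x) / std::sqrt(2.0 * M_PI);
  return Phi + x * phi;
}

static IntegerVector tensor_dims(const NumericVector& x) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("expected a 4-d (H, W, C, N) tensor");
  return d;
}

// im2col for 3x3 / pad 1: rows r = i + H*j + H*W*n, cols q = di + 3*dj + 9*c
static void im2col3(const double* x, int H, int W, int C, int N, arma::mat& M) {
  M.zeros();
  const size_t HW = static_cast<size_t>(H) * W;
  for (int c = 0; c < C; ++c) {
    for (int dj = 0; dj < 3; ++dj) {
      for (int di = 0; di < 3; ++di) {
        double* col = M.colptr(di + 3 * dj + 9 * c);
        for (int n = 0; n < N; ++n) {
          const double* xs = x + HW * (c + static_cast<size_t>(C) * n);
          double* cs = col + HW * n;
          for (int j = 0; j < W; ++j) {
            int sj = j + dj - 1;
            if (sj < 0 || sj >= W) continue;
            int i0 = std::max(0, 1 - di), i1 = std::min(H, H + 1 - di);
            const double* src = xs + static_cast<size_t>(sj) * H + (i0 + di - 1);
            std::copy(src, src + (i1 - i0), cs + static_cast<size_t>(j) * H + i0);
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
List conv_gelu_forward(NumericVector x, NumericVector w, NumericVector b) {
  IntegerVector dx = tensor_dims(x), dw = tensor_dims(w);
  int H = dx[0], W = dx[1], C = dx[2], N = dx[3], K = dw[3];
  if (dw[0] != 3 || dw[1] != 3 || dw[2] != C) stop("weight/input channel mismatch");
  const size_t HW = static_cast<size_t>(H) * W;
  NumericMatrix Mout(HW * N, 9 * C);
  arma::mat M(Mout.begin(), HW * N, 9 * C, false, true);
  im2col3(x.begin(), H, W, C, N, M);
  arma::mat Wm(const_cast<double*>(w.begin()), 9 * C, K, false, true);
  arma::mat P = M * Wm;
  P.each_row() += arma::rowvec(const_cast<double*>(b.begin()), K, false, true);

  // act = x * Phi(x); Phi is kept so the backward pass only needs exp()
  NumericVector pre(HW * K * N), act(HW * K * N), Phi(HW * K * N);
  pre.attr("dim") = IntegerVector::create(H, W, K, N);
  act.attr("dim") = IntegerVector::create(H, W, K, N);
  Phi.attr("dim") = IntegerVector::create(H, W, K, N);
  for (int n = 0; n < N; ++n) {
    for (int k = 0; k < K; ++k) {
      const double* src = P.colptr(k) + HW * n;
      double* pd = pre.begin() + HW * (k + static_cast<size_t>(K) * n);
      double* ad = act.begin() + HW * (k + static_cast<size_t>(K) * n);
      double* fd = Phi.begin() + HW * (k + static_cast<size_t>(K) * n);
      for (size_t t = 0; t < HW; ++t) {
        pd[t] = src[t];
        fd[t] = 0.5 * (1.0 + std::erf(src[t] * M_SQRT1_2));
        ad[t] = src[t] * fd[t];
      }
    }
  }
  return List::create(_["pre"] = pre, _["act"] = act, _["Phi"] = Phi,
                      _["im2col"] = Mout);
}

// [[Rcpp::export]]
List conv_gelu_backward(NumericVector x, NumericVector w, NumericVector pre,
                        NumericVector Phi, NumericMatrix Mcache,
                        NumericVector dact) {
  IntegerVector dx_ = tensor_dims(x), dw_ = tensor_dims(w);
  int H = dx_[0], W = dx_[1], C = dx_[2], N = dx_[3], K = dw_[3];
  const size_t HW = static_cast<size_t>(H) * W;
  const double inv_sqrt2pi = 1.0 / std::sqrt(2.0 * M_PI);

  // dpre = dact * (Phi(pre) + pre * phi(pre)), gathered into (R x K)
  arma::mat dP(HW * N, K);
  for (int n = 0; n < N; ++n) {
    for (int k = 0; k < K; ++k) {
      const double* pd = pre.begin() + HW * (k + static_cast<size_t>(K) * n);
      const double* fd = Phi.begin() + HW * (k + static_cast<size_t>(K) * n);
      const double* gd = dact.begin() + HW * (k + static_cast<size_t>(K) * n);
      double* dst = dP.colptr(k) + HW * n;
      for (size_t t = 0; t < HW; ++t) {
        double g = fd[t] + pd[t] * std::exp(-0.5 * pd[t] * pd[t]) * inv_sqrt2pi;
        dst[t] = gd[t] * g;
      }
    }
  }

  arma::mat M(Mcache.begin(), HW * N, 9 * C, false, true);
  arma::mat Wm(const_cast<double*>(w.begin()), 9 * C, K, false, true);
  arma::mat dWm = M.t() * dP;                 // (9C x K)
  arma::rowvec db = arma::sum(dP, 0);
  arma::mat dM = dP * Wm.t();                 // (R x 9C)

  // col2im scatter-add
  NumericVector dxv(static_cast<size_t>(HW) * C * N);
  dxv.attr("dim") = IntegerVector::create(H, W, C, N);
  for (int c = 0; c < C; ++c) {
    for (int dj = 0; dj < 3; ++dj) {
      for (int di = 0; di < 3; ++di) {
        const double* col = dM.colptr(di + 3 * dj + 9 * c);
        for (int n = 0; n < N; ++n) {
          double* xs = dxv.begin() + HW * (c + static_cast<size_t>(C) * n);
          const double* cs = col + HW * n;
          for (int j = 0; j < W; ++j) {
            int sj = j + dj - 1;
            if (sj < 0 || sj >= W) continue;
            int i0 = std::max(0, 1 - di), i1 = std::min(H, H + 1 - di);
            double* dst = xs + static_cast<size_t>(sj) * H + (i0 + di - 1);
            const double* src = cs + static_cast<size_t>(j) * H + i0;
            for (int t = 0; t < i1 - i0; ++t) dst[t] += src[t];
          }
        }
      }
    }
  }

  NumericVector dwv(9 * C * K), dbv(K);
  dwv.attr("dim") = IntegerVector::create(3, 3, C, K);
  std::copy(dWm.begin(), dWm.end(), dwv.begin());
  std::copy(db.begin(), db.end(), dbv.begin());
  return List::create(_["dx"] = dxv, _["dw"] = dwv, _["db"] = dbv);
}

// [[Rcpp::export]]
List maxpool2_forward(NumericVector x) {
  IntegerVector d = tensor_dims(x);
  int H = d[0], W = d[1], C = d[2], N = d[3];
  int Ho = (H + 1) / 2, Wo = (W + 1) / 2;
  size_t no = static_cast<size_t>(Ho) * Wo * C * N;
  NumericVector y(no);
  IntegerVector idx(no);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  const double* xp = x.begin();
  size_t o = 0;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      size_t base = (static_cast<size_t>(c) + static_cast<size_t>(C) * n) * H * W;
      for (int j = 0; j < Wo; ++j) {
        for (int i = 0; i < Ho; ++i, ++o) {
          double best = -std::numeric_limits<double>::infinity();
          size_t bidx = 0;
          for (int jj = 2 * j; jj < std::min(2 * j + 2, W); ++jj) {
            for (int ii = 2 * i; ii < std::min(2 * i + 2, H); ++ii) {
              size_t p = base + static_cast<size_t>(jj) * H + ii;
              if (xp[p] > best) { best = xp[p]; bidx = p; }
            }
          }
          y[o] = best;
          idx[o] = static_cast<int>(bidx);
        }
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector maxpool2_backward(IntegerVector idx, NumericVector dy,
                                IntegerVector in_dim) {
  size_t n = static_cast<size_t>(in_dim[0]) * in_dim[1] * in_dim[2] * in_dim[3];
  NumericVector dx(n);
  dx.attr("dim") = in_dim;
  for (R_xlen_t o = 0; o < dy.size(); ++o) dx[idx[o]] += dy[o];
  return dx;
}

// [[Rcpp::export]]
NumericVector avgpool3_forward(NumericVector x) {
  IntegerVector d = tensor_dims(x);
  int H = d[0], W = d[1], C = d[2], N = d[3];
  NumericVector y(x.size());
  y.attr("dim") = d;
  const size_t HW = static_cast<size_t>(H) * W;
  for (int s = 0; s < C * N; ++s) {
    const double* xs = x.begin() + HW * s;
    double* ys = y.begin() + HW * s;
    for (int j = 0; j < W; ++j) {
      for (int i = 0; i < H; ++i) {
        double acc = 0; int cnt = 0;
        for (int jj = std::max(0, j - 1); jj < std::min(W, j + 2); ++jj)
          for (int ii = std::max(0, i - 1); ii < std::min(H, i + 2); ++ii) {
            acc += xs[static_cast<size_t>(jj) * H + ii];
            ++cnt;
          }
        ys[static_cast<size_t>(j) * H + i] = acc / cnt;
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector avgpool3_backward(NumericVector dy) {
  IntegerVector d = tensor_dims(dy);
  int H = d[0], W = d[1], C = d[2], N = d[3];
  NumericVector dx(dy.size());
  dx.attr("dim") = d;
  const size_t HW = static_cast<size_t>(H) * W;
  for (int s = 0; s < C * N; ++s) {
    const double* gs = dy.begin() + HW * s;
    double* xs = dx.begin() + HW * s;
    for (int j = 0; j < W; ++j) {
      for (int i = 0; i < H; ++i) {
        int cnt = (std::min(W, j + 2) - std::max(0, j - 1)) *
                  (std::min(H, i + 2) - std::max(0, i - 1));
        double g = gs[static_cast<size_t>(j) * H + i] / cnt;
        for (int jj = std::max(0, j - 1); jj < std::min(W, j + 2); ++jj)
          for (int ii = std::max(0, i - 1); ii < std::min(H, i + 2); ++ii)
            xs[static_cast<size_t>(jj) * H + ii] += g;
      }
    }
  }
  return dx;
}
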