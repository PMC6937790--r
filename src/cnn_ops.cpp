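#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Valid (no padding, stride 1) convolution layers expressed as im2col + GEMM.
// Tensors are column-major R arrays: images (H, W, C, N), filters (k, k, C, F).
// im2col column order matches the column-major flattening of a (k, k, C)
// filter block, so the GEMM weight matrix is just dim(w) <- c(k*k*C, F).

static void im2col_one(const double *xp, int H, int W, int C, int k,
                       arma::mat &col) {
  const int Ho = H - k + 1, Wo = W - k + 1;
  int cidx = 0;
  for (int c = 0; c < C; ++c) {
    const double *xc = xp + (size_t)c * H * W;
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di, ++cidx) {
        double *cp = col.colptr(cidx);
        for (int j = 0; j < Wo; ++j) {
          const double *src = xc + (size_t)(j + dj) * H + di;
          double *dst = cp + (size_t)j * Ho;
          for (int i = 0; i < Ho; ++i) dst[i] = src[i];
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv_forward(NumericVector x, IntegerVector xd,
                           NumericVector w, IntegerVector wd,
                           NumericVector b) {
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int k = wd[0], F = wd[3];
  const int Ho = H - k + 1, Wo = W - k + 1, P = Ho * Wo, D = k * k * C;
  const arma::mat Wm(const_cast<double *>(w.begin()), D, F, false, true);
  NumericVector y((size_t)P * F * N);
  arma::mat col(P, D);
  for (int n = 0; n < N; ++n) {
    im2col_one(x.begin() + (size_t)n * H * W * C, H, W, C, k, col);
    arma::mat Y = col * Wm;  // P x F
    double *yp = y.begin() + (size_t)n * P * F;
    for (int f = 0; f < F; ++f) {
      const double bf = b[f];
      const double *src = Y.colptr(f);
      double *dst = yp + (size_t)f * P;
      for (int p = 0; p < P; ++p) dst[p] = src[p] + bf;
    }
  }
  y.attr("dim") = IntegerVector::create(Ho, Wo, F, N);
  return y;
}

// [[Rcpp::export]]
List conv_backward(NumericVector x, IntegerVector xd,
                   NumericVector w, IntegerVector wd,
                   NumericVector dy) {
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int k = wd[0], F = wd[3];
  const int Ho = H - k + 1, Wo = W - k + 1, P = Ho * Wo, D = k * k * C;
  const arma::mat Wm(const_cast<double *>(w.begin()), D, F, false, true);
  arma::mat dW(D, F, arma::fill::zeros);
  NumericVector db(F);
  NumericVector dx((size_t)H * W * C * N);
  arma::mat col(P, D);
  for (int n = 0; n < N; ++n) {
    const double *xp = x.begin() + (size_t)n * H * W * C;
    const arma::mat dY(const_cast<double *>(dy.begin()) + (size_t)n * P * F,
                       P, F, false, true);
    im2col_one(xp, H, W, C, k, col);
    dW += col.t() * dY;
    for (int f = 0; f < F; ++f) db[f] += arma::accu(dY.col(f));
    // col2im scatter-add of dCol = dY * Wm^T
    arma::mat dCol = dY * Wm.t();  // P x D
    double *dxp = dx.begin() + (size_t)n * H * W * C;
    int cidx = 0;
    for (int c = 0; c < C; ++c) {
      double *dxc = dxp + (size_t)c * H * W;
      for (int dj = 0; dj < k; ++dj) {
        for (int di = 0; di < k; ++di, ++cidx) {
          const double *cp = dCol.colptr(cidx);
          for (int j = 0; j < Wo; ++j) {
            double *dst = dxc + (size_t)(j + dj) * H + di;
            const double *src = cp + (size_t)j * Ho;
            for (int i = 0; i < Ho; ++i) dst[i] += src[i];
          }
        }
      }
    }
  }
  NumericVector dwOut(dW.begin(), dW.end());
  dwOut.attr("dim") = IntegerVector::create(k, k, C, F);
  dx.attr("dim") = xd;
  return List::create(_["dw"] = dwOut, _["db"] = db, _["dx"] = dx);
}

// 2x2 max pooling, stride 2, first-wins tie break; idx stores 0-based linear
// positions into the input tensor for the backward scatter.
// [[Rcpp::export]]
List pool_forward(NumericVector x, IntegerVector xd) {
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Hp = H / 2, Wp = W / 2;
  NumericVector y((size_t)Hp * Wp * C * N);
  IntegerVector idx(y.size());
  const double *xp = x.begin();
  size_t o = 0;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const size_t base = ((size_t)n * C + c) * H * W;
      for (int j = 0; j < Wp; ++j) {
        for (int i = 0; i < Hp; ++i, ++o) {
          const size_t i00 = base + (size_t)(2 * j) * H + 2 * i;
          size_t best = i00;
          double bv = xp[i00];
          const size_t cand[3] = {i00 + 1, i00 + (size_t)H, i00 + (size_t)H + 1};
          for (int q = 0; q < 3; ++q)
            if (xp[cand[q]] > bv) { bv = xp[cand[q]]; best = cand[q]; }
          y[o] = bv;
          idx[o] = (int)best;
        }
      }
    }
  }
  y.attr("dim") = IntegerVector::create(Hp, Wp, C, N);
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector pool_backward(NumericVector dy, IntegerVector idx, int xlen) {
  NumericVector dx(xlen);
  for (int o = 0; o < dy.size(); ++o) dx[idx[o]] += dy[o];
  return dx;
}

// [[Rcpp::export]]
NumericVector relu(NumericVector x) {
  NumericVector y(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) y[i] = x[i] > 0 ? x[i] : 0.0;
  y.attr("dim") = x.attr("dim");
  return y;
}

// Cross-channel (local response) normalisation over the 3rd dimension of an
// (H, W, C, N) tensor: den = K + alpha * winsum(x^2) / W_win,
// y = x * den^-beta.  Returns den and p = den^-beta for the backward pass.
// [[Rcpp::export]]
List lrn_forward(NumericVector x, IntegerVector xd, double alpha,
                 double beta, double k, int window) {
  const int HW = xd[0] * xd[1], C = xd[2], N = xd.size() > 3 ? xd[3] : 1;
  const int half = (window - 1) / 2;
  const R_xlen_t len = x.size();
  NumericVector den(len), p(len), y(len);
  const double *xp = x.begin();
  for (int n = 0; n < N; ++n) {
    const size_t base = (size_t)n * HW * C;
    for (int c = 0; c < C; ++c) {
      const int lo = std::max(0, c - half), hi = std::min(C - 1, c + half);
      double *dp = den.begin() + base + (size_t)c * HW;
      for (int i = 0; i < HW; ++i) {
        double s = 0.0;
        for (int c2 = lo; c2 <= hi; ++c2) {
          const double v = xp[base + (size_t)c2 * HW + i];
          s += v * v;
        }
        dp[i] = k + alpha * s / window;
      }
    }
  }
  for (R_xlen_t i = 0; i < len; ++i) {
    p[i] = std::pow(den[i], -beta);
    y[i] = xp[i] * p[i];
  }
  y.attr("dim") = xd;
  return List::create(_["y"] = y, _["den"] = den, _["p"] = p);
}

// [[Rcpp::export]]
NumericVector lrn_backward(NumericVector x, IntegerVector xd,
                           NumericVector dy, NumericVector den,
                           NumericVector p, double alpha, double beta,
                           int window) {
  const int HW = xd[0] * xd[1], C = xd[2], N = xd.size() > 3 ? xd[3] : 1;
  const int half = (window - 1) / 2;
  const R_xlen_t len = x.size();
  std::vector<double> u(len);
  for (R_xlen_t i = 0; i < len; ++i)
    u[i] = dy[i] * x[i] * p[i] / den[i];  // dy * x * den^(-beta-1)
  NumericVector dx(len);
  const double coef = 2.0 * alpha * beta / window;
  for (int n = 0; n < N; ++n) {
    const size_t base = (size_t)n * HW * C;
    for (int c = 0; c < C; ++c) {
      const int lo = std::max(0, c - half), hi = std::min(C - 1, c + half);
      double *dxp = dx.begin() + base + (size_t)c * HW;
      const size_t off = base + (size_t)c * HW;
      for (int i = 0; i < HW; ++i) {
        double U = 0.0;
        for (int c2 = lo; c2 <= hi; ++c2) U += u[base + (size_t)c2 * HW + i];
        dxp[i] = dy[off + i] * p[off + i] - coef * x[off + i] * U;
      }
    }
  }
  dx.attr("dim") = xd;
  return dx;
}
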