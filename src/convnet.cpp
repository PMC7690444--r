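// Minimal conv-net kernels for the siamese branch networks.
// Layout conventions match R arrays (column-major):
//   activations: dim (H, W, C, N)
//   conv weights: matrix (9*C_in) x C_out, patch element (di, dj, c) at row
//   (di+1) + 3*(dj+1) + 9*c, di/dj in {-1,0,1} (3x3 kernels, "same" padding,
//   stride 1, zero fill outside the image — consistent with skull-stripped
//   background).
// All images of a batch are gathered into one im2col matrix
// (H*W*N rows: i + H*j within image, image blocks stacked) so each layer is
// a single GEMM. ReLU is fused into the forward; the backward masks on the
// stored activations (act > 0).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// gather all images into P (H*W*N x 9C)
static void im2col_batch(const double* x, int H, int W, int C, int N,
                         arma::mat& P) {
  const std::size_t HW = (std::size_t)H * W;
  P.zeros((std::size_t)H * W * N, 9 * C);
  for (int c = 0; c < C; ++c) {
    for (int dj = -1; dj <= 1; ++dj) {
      for (int di = -1; di <= 1; ++di) {
        int col = (di + 1) + 3 * (dj + 1) + 9 * c;
        double* dst0 = P.colptr(col);
        int i_lo = std::max(0, -di), i_hi = std::min(H, H - di);  // valid i
        int j_lo = std::max(0, -dj), j_hi = std::min(W, W - dj);
        int len = i_hi - i_lo;
        if (len <= 0) continue;
        for (int n = 0; n < N; ++n) {
          const double* src0 = x + ((std::size_t)n * C + c) * HW;
          double* dimg = dst0 + (std::size_t)n * HW;
          for (int j = j_lo; j < j_hi; ++j) {
            const double* src = src0 + (i_lo + di) + (std::size_t)H * (j + dj);
            std::copy(src, src + len, dimg + i_lo + (std::size_t)H * j);
          }
        }
      }
    }
  }
}

// scatter-add dP (H*W*N x 9C) back onto input gradients (H, W, C, N)
static void col2im_batch(const arma::mat& dP, int H, int W, int C, int N,
                         double* dx) {
  const std::size_t HW = (std::size_t)H * W;
  for (int c = 0; c < C; ++c) {
    for (int dj = -1; dj <= 1; ++dj) {
      for (int di = -1; di <= 1; ++di) {
        int col = (di + 1) + 3 * (dj + 1) + 9 * c;
        const double* src0 = dP.colptr(col);
        int i_lo = std::max(0, -di), i_hi = std::min(H, H - di);
        int j_lo = std::max(0, -dj), j_hi = std::min(W, W - dj);
        int len = i_hi - i_lo;
        if (len <= 0) continue;
        for (int n = 0; n < N; ++n) {
          double* dst0 = dx + ((std::size_t)n * C + c) * HW;
          const double* simg = src0 + (std::size_t)n * HW;
          for (int j = j_lo; j < j_hi; ++j) {
            const double* src = simg + i_lo + (std::size_t)H * j;
            double* dst = dst0 + (i_lo + di) + (std::size_t)H * (j + dj);
            for (int k = 0; k < len; ++k) dst[k] += src[k];
          }
        }
      }
    }
  }
}

// Forward 3x3 same-padding convolution with fused ReLU. When keep_patches is
// true the batched im2col matrix is returned so the backward pass can form
// weight gradients without re-gathering.
// [[Rcpp::export]]
List cpp_conv2d_fwd(NumericVector x, IntegerVector dims, NumericMatrix wmat,
                    NumericVector bias, bool relu, bool keep_patches) {
  int H = dims[0], W = dims[1], C = dims[2], N = dims[3];
  int F = wmat.ncol();
  if (wmat.nrow() != 9 * C) stop("conv weight rows must equal 9*C_in");
  const std::size_t HW = (std::size_t)H * W;
  arma::mat Wm(wmat.begin(), wmat.nrow(), F, false);
  arma::mat P;
  im2col_batch(x.begin(), H, W, C, N, P);
  arma::mat Y = P * Wm;                       // (H*W*N) x F
  Y.each_row() += arma::rowvec(bias.begin(), F);
  if (relu) Y.transform([](double v) { return v > 0 ? v : 0.0; });
  NumericVector out(HW * F * N);
  out.attr("dim") = IntegerVector::create(H, W, F, N);
  for (int f = 0; f < F; ++f) {
    const double* src = Y.colptr(f);
    for (int n = 0; n < N; ++n)
      std::copy(src + n * HW, src + (n + 1) * HW,
                out.begin() + ((std::size_t)n * F + f) * HW);
  }
  if (keep_patches) {
    NumericMatrix Pr(P.n_rows, P.n_cols);
    std::copy(P.begin(), P.end(), Pr.begin());
    return List::create(_["out"] = out, _["patches"] = Pr);
  }
  return List::create(_["out"] = out);
}

// Backward through (ReLU o conv). `act` is the forward output (post-ReLU);
// dy is masked on act > 0 internally. `patches` may be a 0x0 matrix, in
// which case im2col is recomputed from x when dW is needed.
// [[Rcpp::export]]
List cpp_conv2d_bwd(NumericVector x, IntegerVector dims, NumericMatrix wmat,
                    NumericVector act, NumericVector dy,
                    NumericMatrix patches, bool need_dx, bool need_dw) {
  int H = dims[0], W = dims[1], C = dims[2], N = dims[3];
  int F = wmat.ncol();
  const std::size_t HW = (std::size_t)H * W;
  arma::mat Wm(wmat.begin(), wmat.nrow(), F, false);
  // masked dY in batch-row layout (H*W*N x F)
  arma::mat dY(HW * N, F);
  for (int f = 0; f < F; ++f) {
    double* dst = dY.colptr(f);
    for (int n = 0; n < N; ++n) {
      const double* pdy = dy.begin() + ((std::size_t)n * F + f) * HW;
      const double* pact = act.begin() + ((std::size_t)n * F + f) * HW;
      double* d = dst + n * HW;
      for (std::size_t k = 0; k < HW; ++k) d[k] = pact[k] > 0 ? pdy[k] : 0.0;
    }
  }
  NumericMatrix dWr(9 * C, F);
  if (need_dw) {
    if (patches.nrow() > 0) {
      arma::mat P(patches.begin(), patches.nrow(), patches.ncol(), false);
      arma::mat dW = P.t() * dY;
      std::copy(dW.begin(), dW.end(), dWr.begin());
    } else {
      arma::mat P;
      im2col_batch(x.begin(), H, W, C, N, P);
      arma::mat dW = P.t() * dY;
      std::copy(dW.begin(), dW.end(), dWr.begin());
    }
  }
  NumericVector dbr(F);
  arma::rowvec db = arma::sum(dY, 0);
  std::copy(db.begin(), db.end(), dbr.begin());
  NumericVector dx;
  if (need_dx) {
    dx = NumericVector(HW * C * N);
    dx.attr("dim") = IntegerVector::create(H, W, C, N);
    arma::mat dP = dY * Wm.t();               // (H*W*N) x (9C)
    col2im_batch(dP, H, W, C, N, dx.begin());
  }
  return List::create(_["dx"] = dx, _["dw"] = dWr, _["db"] = dbr);
}

// 2x2 max pooling, stride 2, floor division of odd dims (trailing row/col
// dropped, as in the standard VGG16 pooling ladder 150->75->37->18->9->4).
// [[Rcpp::export]]
List cpp_maxpool2_fwd(NumericVector x, IntegerVector dims) {
  int H = dims[0], W = dims[1], C = dims[2], N = dims[3];
  int Ho = H / 2, Wo = W / 2;
  std::size_t no = (std::size_t)Ho * Wo * C * N;
  NumericVector out(no);
  IntegerVector amax(no);  // 1-based linear index into x
  out.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  const double* px = x.begin();
  std::size_t o = 0;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      std::size_t base = ((std::size_t)n * C + c) * H * W;
      for (int j = 0; j < Wo; ++j) {
        for (int i = 0; i < Ho; ++i) {
          std::size_t best = base + (2 * i) + (std::size_t)H * (2 * j);
          double bv = px[best];
          std::size_t cand;
          cand = base + (2 * i + 1) + (std::size_t)H * (2 * j);
          if (px[cand] > bv) { bv = px[cand]; best = cand; }
          cand = base + (2 * i) + (std::size_t)H * (2 * j + 1);
          if (px[cand] > bv) { bv = px[cand]; best = cand; }
          cand = base + (2 * i + 1) + (std::size_t)H * (2 * j + 1);
          if (px[cand] > bv) { bv = px[cand]; best = cand; }
          out[o] = bv;
          amax[o] = (int)(best + 1);
          ++o;
        }
      }
    }
  }
  return List::create(_["out"] = out, _["argmax"] = amax);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool2_bwd(NumericVector dy, IntegerVector argmax,
                               IntegerVector dims) {
  int H = dims[0], W = dims[1], C = dims[2], N = dims[3];
  NumericVector dx((std::size_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  for (R_xlen_t k = 0; k < dy.size(); ++k) dx[argmax[k] - 1] += dy[k];
  return dx;
}
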