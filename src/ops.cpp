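#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Patch-matrix extraction for valid/padded convolution.
// x: [H, W, C, N] column-major. Output: [(oh*ow*N) x (k*k*C)], image-major
// row blocks; within a block, position p = i + j*oh (0-based, output row i,
// output col j); column t = di + dj*k + c*k*k.
// [[Rcpp::export]]
NumericMatrix im2col_batch(NumericVector x, int H, int W, int C, int N,
                           int k, int stride, int pad) {
  const int oh = (H + 2 * pad - k) / stride + 1;
  const int ow = (W + 2 * pad - k) / stride + 1;
  const int npos = oh * ow;
  NumericMatrix out(npos * N, k * k * C);
  const double* xp = x.begin();
  double* op = out.begin();
  const R_xlen_t ncolrows = (R_xlen_t)npos * N;
  for (int c = 0; c < C; ++c) {
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di) {
        const int t = di + dj * k + c * k * k;
        double* col = op + (R_xlen_t)t * ncolrows;
        for (int n = 0; n < N; ++n) {
          const double* img = xp + ((R_xlen_t)n * C + c) * H * W;
          double* blk = col + (R_xlen_t)n * npos;
          for (int j = 0; j < ow; ++j) {
            const int rj = j * stride + dj - pad;
            if (rj < 0 || rj >= W) continue;  // stays zero
            const double* src = img + (R_xlen_t)rj * H;
            double* dst = blk + (R_xlen_t)j * oh;
            for (int i = 0; i < oh; ++i) {
              const int ri = i * stride + di - pad;
              if (ri >= 0 && ri < H) dst[i] = src[ri];
            }
          }
        }
      }
    }
  }
  return out;
}

// Adjoint of im2col_batch: scatter-accumulate column gradients back to the
// input layout [H, W, C, N].
// [[Rcpp::export]]
NumericVector col2im_batch(NumericMatrix dcol, int H, int W, int C, int N,
                           int k, int stride, int pad) {
  const int oh = (H + 2 * pad - k) / stride + 1;
  const int ow = (W + 2 * pad - k) / stride + 1;
  const int npos = oh * ow;
  NumericVector dx((R_xlen_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  const double* dp = dcol.begin();
  double* xp = dx.begin();
  const R_xlen_t ncolrows = (R_xlen_t)npos * N;
  for (int c = 0; c < C; ++c) {
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di) {
        const int t = di + dj * k + c * k * k;
        const double* col = dp + (R_xlen_t)t * ncolrows;
        for (int n = 0; n < N; ++n) {
          double* img = xp + ((R_xlen_t)n * C + c) * H * W;
          const double* blk = col + (R_xlen_t)n * npos;
          for (int j = 0; j < ow; ++j) {
            const int rj = j * stride + dj - pad;
            if (rj < 0 || rj >= W) continue;
            double* dst = img + (R_xlen_t)rj * H;
            const double* src = blk + (R_xlen_t)j * oh;
            for (int i = 0; i < oh; ++i) {
              const int ri = i * stride + di - pad;
              if (ri >= 0 && ri < H) dst[ri] += src[i];
            }
          }
        }
      }
    }
  }
  return dx;
}

// In-place bias add + optional ReLU on a GEMM output [n x cout].
// Returns nothing; Y is modified directly (it is always a fresh allocation
// from the caller's matrix product).
// [[Rcpp::export]]
void bias_relu_inplace(NumericMatrix Y, NumericVector b, bool relu) {
  const int n = Y.nrow(), m = Y.ncol();
  for (int j = 0; j < m; ++j) {
    double* col = Y.begin() + (R_xlen_t)j * n;
    const double bj = b[j];
    if (relu) {
      for (int i = 0; i < n; ++i) {
        const double v = col[i] + bj;
        col[i] = v > 0 ? v : 0;
      }
    } else {
      for (int i = 0; i < n; ++i) col[i] += bj;
    }
  }
}

// 2x2 stride-2 max pooling on [H, W, C, N] (H, W even).
// [[Rcpp::export]]
NumericVector maxpool2(NumericVector x, int H, int W, int C, int N) {
  const int oh = H / 2, ow = W / 2;
  NumericVector out((R_xlen_t)oh * ow * C * N);
  out.attr("dim") = IntegerVector::create(oh, ow, C, N);
  const double* xp = x.begin();
  double* op = out.begin();
  const R_xlen_t planes = (R_xlen_t)C * N;
  for (R_xlen_t p = 0; p < planes; ++p) {
    const double* src = xp + p * H * W;
    double* dst = op + p * oh * ow;
    for (int j = 0; j < ow; ++j) {
      const double* c0 = src + (R_xlen_t)(2 * j) * H;
      const double* c1 = c0 + H;
      double* d = dst + (R_xlen_t)j * oh;
      for (int i = 0; i < oh; ++i) {
        const double a = c0[2 * i] > c0[2 * i + 1] ? c0[2 * i] : c0[2 * i + 1];
        const double b2 = c1[2 * i] > c1[2 * i + 1] ? c1[2 * i] : c1[2 * i + 1];
        d[i] = a > b2 ? a : b2;
      }
    }
  }
  return out;
}

// Batch-normalization forward on a GEMM output [n x C] (columns are
// channels): Y <- gamma * (Y - mu) * istd + beta, optional ReLU, in place.
// [[Rcpp::export]]
void bn_fwd_inplace(NumericMatrix Y, NumericVector mu, NumericVector istd,
                    NumericVector gamma, NumericVector beta, bool relu) {
  const int n = Y.nrow(), C = Y.ncol();
  for (int j = 0; j < C; ++j) {
    double* col = Y.begin() + (R_xlen_t)j * n;
    const double a = gamma[j] * istd[j];
    const double b = beta[j] - gamma[j] * istd[j] * mu[j];
    if (relu) {
      for (int i = 0; i < n; ++i) {
        const double v = a * col[i] + b;
        col[i] = v > 0 ? v : 0;
      }
    } else {
      for (int i = 0; i < n; ++i) col[i] = a * col[i] + b;
    }
  }
}

// Column means and (biased) variances of an [n x C] matrix.
// [[Rcpp::export]]
NumericMatrix col_stats(NumericMatrix Y) {
  const int n = Y.nrow(), C = Y.ncol();
  NumericMatrix out(2, C);
  for (int j = 0; j < C; ++j) {
    const double* col = Y.begin() + (R_xlen_t)j * n;
    double s = 0, s2 = 0;
    for (int i = 0; i < n; ++i) { s += col[i]; s2 += col[i] * col[i]; }
    const double m = s / n;
    out(0, j) = m;
    out(1, j) = s2 / n - m * m;
  }
  return out;
}

// Batch-normalization backward. dY (already ReLU-masked) is overwritten
// with the gradient w.r.t. the pre-normalization activations; returns the
// per-channel gradients for gamma and beta. With frozen = true the
// normalization statistics are treated as constants (frozen-stats
// fine-tuning), dropping the batch-coupling correction terms.
// [[Rcpp::export]]
List bn_bwd_inplace(NumericMatrix dY, NumericMatrix Ypre, NumericVector mu,
                    NumericVector istd, NumericVector gamma,
                    bool frozen = false) {
  const int n = dY.nrow(), C = dY.ncol();
  NumericVector dgamma(C), dbeta(C);
  for (int j = 0; j < C; ++j) {
    double* d = dY.begin() + (R_xlen_t)j * n;
    const double* yp = Ypre.begin() + (R_xlen_t)j * n;
    const double m = mu[j], is = istd[j], g = gamma[j];
    double sd = 0, sdx = 0;
    for (int i = 0; i < n; ++i) {
      const double xhat = (yp[i] - m) * is;
      sd += d[i];
      sdx += d[i] * xhat;
    }
    dbeta[j] = sd;
    dgamma[j] = sdx;
    const double c1 = frozen ? 0 : sd / n;
    const double c2 = frozen ? 0 : sdx / n;
    for (int i = 0; i < n; ++i) {
      const double xhat = (yp[i] - m) * is;
      d[i] = g * is * (d[i] - c1 - xhat * c2);
    }
  }
  return List::create(Named("dgamma") = dgamma, Named("dbeta") = dbeta);
}

// 4-connected component labelling of a logical matrix. Labels are assigned
// in row-major scan order of each component's first pixel, so label 1 is the
// component whose top-left pixel comes first in row-major order.
// [[Rcpp::export]]
IntegerMatrix conncomp4(LogicalMatrix m) {
  const int H = m.nrow(), W = m.ncol();
  IntegerMatrix lab(H, W);
  std::vector<int> stack;
  int next = 0;
  // row-major scan so the labelling order gives a deterministic tie-break
  for (int i = 0; i < H; ++i) {
    for (int j = 0; j < W; ++j) {
      if (!m(i, j) || lab(i, j) != 0) continue;
      ++next;
      stack.clear();
      stack.push_back(i + j * H);
      lab(i, j) = next;
      while (!stack.empty()) {
        const int p = stack.back();
        stack.pop_back();
        const int pi = p % H, pj = p / H;
        const int ni[4] = {pi - 1, pi + 1, pi, pi};
        const int nj[4] = {pj, pj, pj - 1, pj + 1};
        for (int q = 0; q < 4; ++q) {
          const int qi = ni[q], qj = nj[q];
          if (qi < 0 || qi >= H || qj < 0 || qj >= W) continue;
          if (m(qi, qj) && lab(qi, qj) == 0) {
            lab(qi, qj) = next;
            stack.push_back(qi + qj * H);
          }
        }
      }
    }
  }
  return lab;
}
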