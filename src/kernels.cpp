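#include <Rcpp.h>
using namespace Rcpp;

// MAG channel renderer: per frame, a background noise field plus the
// flow-region profile with multiplicative turbulence texture, clamped to
// [0, 1]. Uses R's RNG stream (draw order: background pixels, then region
// texture, per frame) so results are reproducible under set.seed().
// [[Rcpp::export]]
NumericMatrix render_mag_cpp(NumericVector svec, IntegerVector inside,
                             NumericVector prof, double amp,
                             double noise_sd, double bg) {
  const int npix = svec.size();
  const int nt = prof.size();
  const int nin = inside.size();
  NumericMatrix out(npix, nt);
  for (int t = 0; t < nt; ++t) {
    NumericVector noise = rnorm(npix, bg, noise_sd);
    double *col = &out(0, t);
    for (int p = 0; p < npix; ++p) {
      col[p] = noise[p] + 0.10 * svec[p];
    }
    if (prof[t] > 0 && amp > 0) {
      NumericVector tex = rnorm(nin, 0.0, 1.0);
      const double f = amp * prof[t];
      for (int j = 0; j < nin; ++j) {
        const int p = inside[j] - 1;
        col[p] += f * svec[p] * (1.0 + 0.08 * tex[j]);
      }
    }
    for (int p = 0; p < npix; ++p) {
      if (col[p] < 0) col[p] = 0;
      else if (col[p] > 1) col[p] = 1;
    }
  }
  return out;
}

// im2col patch gather: X is [npix_in x N] (one image per column), idx is
// the [ne x npos] 1-based receptive-field index; returns [npos*N x ne].
// [[Rcpp::export]]
NumericMatrix im2col_cpp(NumericMatrix X, IntegerMatrix idx) {
  const int N = X.ncol();
  const int ne = idx.nrow();
  const int npos = idx.ncol();
  NumericMatrix PM(npos * N, ne);
  std::vector<int> idxT((R_xlen_t)ne * npos);
  for (int e = 0; e < ne; ++e) {
    for (int p = 0; p < npos; ++p) idxT[(R_xlen_t)e * npos + p] = idx(e, p) - 1;
  }
  for (int e = 0; e < ne; ++e) {
    double *dst = &PM(0, e);
    const int *ix = &idxT[(R_xlen_t)e * npos];
    for (int n = 0; n < N; ++n) {
      const double *src = &X(0, n);
      double *d = dst + (R_xlen_t)n * npos;
      for (int p = 0; p < npos; ++p) {
        d[p] = src[ix[p]];
      }
    }
  }
  return PM;
}

// Accumulating scatter (transpose of im2col) for conv input gradients:
// dPM is [npos*N x ne]; returns [npix_in x N].
// [[Rcpp::export]]
NumericMatrix col2im_cpp(NumericMatrix dPM, IntegerMatrix idx, int npix_in) {
  const int ne = idx.nrow();
  const int npos = idx.ncol();
  const int N = dPM.nrow() / npos;
  NumericMatrix dX(npix_in, N);
  for (int e = 0; e < ne; ++e) {
    const double *src = &dPM(0, e);
    for (int n = 0; n < N; ++n) {
      double *dst = &dX(0, n);
      const double *s = src + (R_xlen_t)n * npos;
      for (int p = 0; p < npos; ++p) {
        dst[idx(e, p) - 1] += s[p];
      }
    }
  }
  return dX;
}

// Add bias, apply ReLU in place into A, and emit the channel-major output
// layout [npos*K x N] the next layer consumes.
// [[Rcpp::export]]
List bias_relu_split_cpp(NumericMatrix Z, NumericVector b, int npos, int N) {
  const int K = Z.ncol();
  NumericMatrix A(Z.nrow(), K);
  NumericMatrix out(npos * K, N);
  for (int k = 0; k < K; ++k) {
    const double bk = b[k];
    const double *z = &Z(0, k);
    double *a = &A(0, k);
    for (int n = 0; n < N; ++n) {
      double *o = &out(k * npos, n);
      const double *zz = z + (R_xlen_t)n * npos;
      double *aa = a + (R_xlen_t)n * npos;
      for (int p = 0; p < npos; ++p) {
        double v = zz[p] + bk;
        v = v > 0 ? v : 0;
        aa[p] = v;
        o[p] = v;
      }
    }
  }
  return List::create(_["A"] = A, _["out"] = out);
}

// Inverse of the split: gather channel-major gradients back to [npos*N x K]
// and mask by the ReLU activation pattern (A > 0).
// [[Rcpp::export]]
NumericMatrix join_mask_cpp(NumericMatrix dOut, NumericMatrix A, int npos,
                            int N) {
  const int K = dOut.nrow() / npos;
  NumericMatrix dZ(npos * N, K);
  for (int k = 0; k < K; ++k) {
    double *d = &dZ(0, k);
    const double *a = &A(0, k);
    for (int n = 0; n < N; ++n) {
      const double *src = &dOut(k * npos, n);
      double *dd = d + (R_xlen_t)n * npos;
      const double *aa = a + (R_xlen_t)n * npos;
      for (int p = 0; p < npos; ++p) {
        dd[p] = aa[p] > 0 ? src[p] : 0.0;
      }
    }
  }
  return dZ;
}

// Spread pooled-feature gradients uniformly over spatial positions:
// dF is [N x K]; result is [npos*K x N] with value dF(n,k)/npos.
// [[Rcpp::export]]
NumericMatrix gap_backward_cpp(NumericMatrix dF, int npos) {
  const int N = dF.nrow();
  const int K = dF.ncol();
  NumericMatrix out(npos * K, N);
  for (int n = 0; n < N; ++n) {
    double *col = &out(0, n);
    for (int k = 0; k < K; ++k) {
      const double v = dF(n, k) / npos;
      double *o = col + (R_xlen_t)k * npos;
      for (int p = 0; p < npos; ++p) o[p] = v;
    }
  }
  return out;
}
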