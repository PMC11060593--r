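#include <Rcpp.h>
using namespace Rcpp;

// Image batches are R arrays of dim (H, W, C, N), column-major, so element
// (h, w, c, n) sits at h + H*(w + W*(c + C*n)).  im2col lays every receptive
// field out as one column so convolution becomes a single GEMM; the column
// order is (oh fastest, then ow, then n) to match R's array order, and the
// row order is (kh fastest, then kw, then c).

// [[Rcpp::export]]
NumericMatrix im2col_cpp(NumericVector x, int H, int W, int C, int N,
                         int k, int stride, int pad) {
  const int OH = (H + 2 * pad - k) / stride + 1;
  const int OW = (W + 2 * pad - k) / stride + 1;
  const int R = C * k * k;
  NumericMatrix out(R, OH * OW * N);
  const double* xp = x.begin();
  double* op = out.begin();
  for (int n = 0; n < N; ++n) {
    const double* img = xp + (size_t)n * H * W * C;
    for (int ow = 0; ow < OW; ++ow) {
      for (int oh = 0; oh < OH; ++oh) {
        const size_t col = ((size_t)n * OW + ow) * OH + oh;
        double* dst = op + col * R;
        const int h0 = oh * stride - pad;
        const int w0 = ow * stride - pad;
        for (int c = 0; c < C; ++c) {
          const double* ch = img + (size_t)c * H * W;
          for (int kw = 0; kw < k; ++kw) {
            const int w_ = w0 + kw;
            const bool win = (w_ >= 0 && w_ < W);
            for (int kh = 0; kh < k; ++kh) {
              const int h_ = h0 + kh;
              dst[((size_t)c * k + kw) * k + kh] =
                (win && h_ >= 0 && h_ < H) ? ch[(size_t)w_ * H + h_] : 0.0;
            }
          }
        }
      }
    }
  }
  return out;
}

// Adjoint of im2col: scatter-adds column gradients back onto the input grid.

// [[Rcpp::export]]
NumericVector col2im_cpp(NumericMatrix cols, int H, int W, int C, int N,
                         int k, int stride, int pad) {
  const int OH = (H + 2 * pad - k) / stride + 1;
  const int OW = (W + 2 * pad - k) / stride + 1;
  const int R = C * k * k;
  NumericVector x((size_t)H * W * C * N);
  double* xp = x.begin();
  const double* cp = cols.begin();
  for (int n = 0; n < N; ++n) {
    double* img = xp + (size_t)n * H * W * C;
    for (int ow = 0; ow < OW; ++ow) {
      for (int oh = 0; oh < OH; ++oh) {
        const size_t col = ((size_t)n * OW + ow) * OH + oh;
        const double* src = cp + col * R;
        const int h0 = oh * stride - pad;
        const int w0 = ow * stride - pad;
        for (int c = 0; c < C; ++c) {
          double* ch = img + (size_t)c * H * W;
          for (int kw = 0; kw < k; ++kw) {
            const int w_ = w0 + kw;
            if (w_ < 0 || w_ >= W) continue;
            for (int kh = 0; kh < k; ++kh) {
              const int h_ = h0 + kh;
              if (h_ < 0 || h_ >= H) continue;
              ch[(size_t)w_ * H + h_] += src[((size_t)c * k + kw) * k + kh];
            }
          }
        }
      }
    }
  }
  x.attr("dim") = IntegerVector::create(H, W, C, N);
  return x;
}
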