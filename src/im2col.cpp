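#include <Rcpp.h>
using namespace Rcpp;

// Gather the im2col matrix of a [H, W, C, N] feature array for a stride-1,
// same-padded k x k convolution. Row order: i fastest, then j, then n
// (matching R's column-major linearization of [H, W, N]); column order:
// di fastest, then dj, then c (matching a [k, k, C, Cout] kernel layout).
// [[Rcpp::export(name = ".nn_im2col_cpp")]]
NumericMatrix nn_im2col_cpp(NumericVector x, int H, int W, int C, int N,
                            int k) {
  const int p = (k - 1) / 2;
  const R_xlen_t HW = (R_xlen_t)H * W;
  const R_xlen_t rows = HW * N;
  const int cols = k * k * C;
  NumericMatrix out(rows, cols);
  const double* xp = x.begin();
  double* op = out.begin();
  for (int c = 0; c < C; ++c) {
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di) {
        const int col = di + k * dj + k * k * c;
        double* pc = op + (R_xlen_t)col * rows;
        for (int n = 0; n < N; ++n) {
          const double* px = xp + ((R_xlen_t)n * C + c) * HW;
          double* pn = pc + (R_xlen_t)n * HW;
          for (int j = 0; j < W; ++j) {
            const int sj = j + dj - p;
            if (sj < 0 || sj >= W) continue;
            const double* src = px + (R_xlen_t)sj * H + (di - p);
            double* dst = pn + (R_xlen_t)j * H;
            const int i0 = std::max(0, p - di);
            const int i1 = std::min(H, H + p - di);
            for (int i = i0; i < i1; ++i) dst[i] = src[i];
          }
        }
      }
    }
  }
  return out;
}
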