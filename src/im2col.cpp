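#include <Rcpp.h>
using namespace Rcpp;

// Feature maps are R arrays with dim (H, W, C), column-major.
// im2col lowers a (H, W, C) map to a (k*k*C) x (Ho*Wo) matrix so that a
// convolution with kernel k, stride s and zero padding p becomes a single
// matrix product. Row index within a column: r = ((c*k + kw)*k + kh);
// column index: j = ho + Ho*wo (matching R's column-major (Ho, Wo) layout).

// [[Rcpp::export]]
NumericMatrix nn_im2col(NumericVector x, int H, int W, int C,
                        int k, int stride, int pad) {
  int Ho = (H + 2 * pad - k) / stride + 1;
  int Wo = (W + 2 * pad - k) / stride + 1;
  NumericMatrix out(k * k * C, Ho * Wo);
  const double* px = x.begin();
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      int col = ho + Ho * wo;
      double* pc = &out(0, col);
      int y0 = ho * stride - pad;
      int x0 = wo * stride - pad;
      for (int c = 0; c < C; ++c) {
        const double* plane = px + (size_t)c * H * W;
        for (int kw = 0; kw < k; ++kw) {
          int xx = x0 + kw;
          for (int kh = 0; kh < k; ++kh) {
            int yy = y0 + kh;
            double v = 0.0;
            if (yy >= 0 && yy < H && xx >= 0 && xx < W)
              v = plane[yy + (size_t)xx * H];
            pc[(c * k + kw) * k + kh] = v;
          }
        }
      }
    }
  }
  return out;
}

// Adjoint of nn_im2col: scatter-add columns back into a (H, W, C) array.
// [[Rcpp::export]]
NumericVector nn_col2im(NumericMatrix cols, int H, int W, int C,
                        int k, int stride, int pad) {
  int Ho = (H + 2 * pad - k) / stride + 1;
  int Wo = (W + 2 * pad - k) / stride + 1;
  NumericVector out((size_t)H * W * C);
  double* po = out.begin();
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      int col = ho + Ho * wo;
      const double* pc = &cols(0, col);
      int y0 = ho * stride - pad;
      int x0 = wo * stride - pad;
      for (int c = 0; c < C; ++c) {
        double* plane = po + (size_t)c * H * W;
        for (int kw = 0; kw < k; ++kw) {
          int xx = x0 + kw;
          if (xx < 0 || xx >= W) continue;
          for (int kh = 0; kh < k; ++kh) {
            int yy = y0 + kh;
            if (yy < 0 || yy >= H) continue;
            plane[yy + (size_t)xx * H] += pc[(c * k + kw) * k + kh];
          }
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(H, W, C);
  return out;
}
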