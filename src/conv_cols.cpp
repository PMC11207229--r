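#include <Rcpp.h>
using namespace Rcpp;

// Patch-matrix construction for 3x3 'same' convolutions (zero padding) and
// its adjoint scatter-add. Layout matches the pure-R reference: patch offset
// blocks ordered dc-major/dr-minor, each block holding all input channels.

// [[Rcpp::export]]
NumericMatrix im2col3_cpp(NumericVector x, int H, int W, int C) {
  NumericMatrix out(H * W, 9 * C);
  const double *px = x.begin();
  double *po = out.begin();
  int k = 0;
  for (int dc = 0; dc < 3; ++dc) {
    for (int dr = 0; dr < 3; ++dr, ++k) {
      for (int ch = 0; ch < C; ++ch) {
        double *col = po + (size_t)(k * C + ch) * H * W;
        const double *plane = px + (size_t)ch * H * W;
        for (int c = 0; c < W; ++c) {
          int ci = c + dc - 1;
          double *dst = col + (size_t)c * H;
          if (ci < 0 || ci >= W) {
            for (int r = 0; r < H; ++r) dst[r] = 0.0;
            continue;
          }
          const double *srccol = plane + (size_t)ci * H;
          for (int r = 0; r < H; ++r) {
            int ri = r + dr - 1;
            dst[r] = (ri < 0 || ri >= H) ? 0.0 : srccol[ri];
          }
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector col2im3_cpp(NumericMatrix dcols, int H, int W, int C) {
  NumericVector out((size_t)H * W * C);
  const double *pd = dcols.begin();
  double *po = out.begin();
  int k = 0;
  for (int dc = 0; dc < 3; ++dc) {
    for (int dr = 0; dr < 3; ++dr, ++k) {
      for (int ch = 0; ch < C; ++ch) {
        const double *col = pd + (size_t)(k * C + ch) * H * W;
        double *plane = po + (size_t)ch * H * W;
        for (int c = 0; c < W; ++c) {
          int ci = c + dc - 1;
          if (ci < 0 || ci >= W) continue;
          double *dstcol = plane + (size_t)ci * H;
          const double *srccol = col + (size_t)c * H;
          for (int r = 0; r < H; ++r) {
            int ri = r + dr - 1;
            if (ri >= 0 && ri < H) dstcol[ri] += srccol[r];
          }
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(H, W, C);
  return out;
}
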