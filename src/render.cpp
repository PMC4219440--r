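#include <Rcpp.h>
using namespace Rcpp;

// Pixel centers are at integer coordinates (1-based, matching R matrix
// indexing): column j is x = j, row i is y = i.  All kernels are truncated
// at trunc_mult * sigma and treated as zero beyond.

// Gaussian-weighted local average of `img` about (cx, cy).  Weights are
// renormalized over in-bounds pixels; returns 0 when no pixel is in range.
// [[Rcpp::export]]
double cpp_gauss_sample(const NumericMatrix& img, double cx, double cy,
                        double sigma, double trunc_mult) {
  if (sigma <= 0) stop("sigma must be positive");
  const int nr = img.nrow(), nc = img.ncol();
  const double rad = trunc_mult * sigma;
  const int x0 = std::max(1, (int)std::ceil(cx - rad));
  const int x1 = std::min(nc, (int)std::floor(cx + rad));
  const int y0 = std::max(1, (int)std::ceil(cy - rad));
  const int y1 = std::min(nr, (int)std::floor(cy + rad));
  if (x0 > x1 || y0 > y1) return 0.0;
  const double inv2s2 = 1.0 / (2.0 * sigma * sigma);
  const double r2max = rad * rad;
  double wsum = 0.0, vsum = 0.0;
  for (int x = x0; x <= x1; ++x) {
    const double dx2 = (x - cx) * (x - cx);
    for (int y = y0; y <= y1; ++y) {
      const double r2 = dx2 + (y - cy) * (y - cy);
      if (r2 > r2max) continue;
      const double w = std::exp(-r2 * inv2s2);
      wsum += w;
      vsum += w * img(y - 1, x - 1);
    }
  }
  return wsum > 0.0 ? vsum / wsum : 0.0;
}

// Add a peak-normalized Gaussian of the given amplitude to `frame`
// (modified in place; caller owns the copy semantics).
void splat_inplace(NumericMatrix& frame, double cx, double cy,
                   double sigma, double amp, double trunc_mult) {
  if (amp == 0.0) return;
  const int nr = frame.nrow(), nc = frame.ncol();
  const double rad = trunc_mult * sigma;
  const int x0 = std::max(1, (int)std::ceil(cx - rad));
  const int x1 = std::min(nc, (int)std::floor(cx + rad));
  const int y0 = std::max(1, (int)std::ceil(cy - rad));
  const int y1 = std::min(nr, (int)std::floor(cy + rad));
  if (x0 > x1 || y0 > y1) return;
  const double inv2s2 = 1.0 / (2.0 * sigma * sigma);
  const double r2max = rad * rad;
  for (int x = x0; x <= x1; ++x) {
    const double dx2 = (x - cx) * (x - cx);
    for (int y = y0; y <= y1; ++y) {
      const double r2 = dx2 + (y - cy) * (y - cy);
      if (r2 > r2max) continue;
      frame(y - 1, x - 1) += amp * std::exp(-r2 * inv2s2);
    }
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_splat_add(const NumericMatrix& frame, double cx, double cy,
                            double sigma, double amp, double trunc_mult) {
  if (sigma <= 0) stop("sigma must be positive");
  NumericMatrix out = clone(frame);
  splat_inplace(out, cx, cy, sigma, amp, trunc_mult);
  return out;
}

// Full sample-and-splat pass: for each phosphene, sample the stimulus with
// a Gaussian filter of its sigma, then splat a matching Gaussian of that
// brightness into a fresh frame.  Splats accumulate additively; the frame
// is clipped to [0, 1] once at the end (display saturation).
// [[Rcpp::export]]
NumericMatrix cpp_render_frame(const NumericMatrix& stimulus,
                               const NumericVector& xs, const NumericVector& ys,
                               const NumericVector& sigmas, double trunc_mult) {
  const int n = xs.size();
  if (ys.size() != n || sigmas.size() != n)
    stop("phosphene coordinate vectors must have equal length");
  NumericMatrix out(stimulus.nrow(), stimulus.ncol());
  for (int i = 0; i < n; ++i) {
    const double b = cpp_gauss_sample(stimulus, xs[i], ys[i], sigmas[i], trunc_mult);
    splat_inplace(out, xs[i], ys[i], sigmas[i], b, trunc_mult);
  }
  for (R_xlen_t j = 0; j < out.size(); ++j) {
    if (out[j] > 1.0) out[j] = 1.0;
    else if (out[j] < 0.0) out[j] = 0.0;
  }
  return out;
}
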