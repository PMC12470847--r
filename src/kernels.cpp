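#include <Rcpp.h>
using namespace Rcpp;

// Unnormalised 2D Gaussian field over flattened pixel coordinates.
// [[Rcpp::export]]
NumericVector cpp_gauss_field(NumericVector x, NumericVector y,
                              double x0, double y0, double sigma) {
  int n = x.size();
  NumericVector g(n);
  double inv2s2 = 1.0 / (2.0 * sigma * sigma);
  for (int i = 0; i < n; ++i) {
    double dx = x[i] - x0, dy = y[i] - y0;
    g[i] = std::exp(-(dx * dx + dy * dy) * inv2s2);
  }
  return g;
}

// Pearson correlation between an observed (pre-centred) mapping-volume
// series and the BOLD prediction of a Gaussian pRF. CF is the
// (mapping volumes x pixels) operator combining the aperture frames with
// the causal HRF convolution, so the prediction is CF * g up to a positive
// scale factor that correlation ignores. Returns -2 for degenerate input
// (sigma too small or a constant prediction) so callers can treat it as
// "worse than any correlation".
// [[Rcpp::export]]
double cpp_prf_cor(NumericMatrix CF, NumericVector x, NumericVector y,
                   NumericVector obs_centred, double obs_norm,
                   double x0, double y0, double sigma) {
  int m = CF.nrow(), n = CF.ncol();
  if (sigma < 1e-4) return -2.0;
  std::vector<double> g(n);
  double inv2s2 = 1.0 / (2.0 * sigma * sigma);
  for (int j = 0; j < n; ++j) {
    double dx = x[j] - x0, dy = y[j] - y0;
    g[j] = std::exp(-(dx * dx + dy * dy) * inv2s2);
  }
  std::vector<double> p(m, 0.0);
  for (int j = 0; j < n; ++j) {
    double gj = g[j];
    if (gj < 1e-12) continue;
    const double* col = &CF(0, j);
    for (int i = 0; i < m; ++i) p[i] += col[i] * gj;
  }
  double mean = 0.0;
  for (int i = 0; i < m; ++i) mean += p[i];
  mean /= m;
  double dot = 0.0, ss = 0.0;
  for (int i = 0; i < m; ++i) {
    double pc = p[i] - mean;
    dot += pc * obs_centred[i];
    ss += pc * pc;
  }
  if (ss < 1e-20) return -2.0;
  return dot / (std::sqrt(ss) * obs_norm);
}

// Residual sum of squares of the best scaled Gaussian fit to an image on
// the pixel grid, with the amplitude profiled out in closed form:
// amp* = <img, g> / <g, g>, RSS = <img, img> - amp*^2 <g, g>.
// [[Rcpp::export]]
double cpp_gauss_image_rss(NumericVector img, NumericVector x,
                           NumericVector y, double x0, double y0,
                           double sigma) {
  int n = img.size();
  if (sigma < 1e-4) return R_PosInf;
  double inv2s2 = 1.0 / (2.0 * sigma * sigma);
  double gg = 0.0, ig = 0.0, ii = 0.0;
  for (int i = 0; i < n; ++i) {
    double dx = x[i] - x0, dy = y[i] - y0;
    double g = std::exp(-(dx * dx + dy * dy) * inv2s2);
    gg += g * g;
    ig += img[i] * g;
    ii += img[i] * img[i];
  }
  if (gg < 1e-20) return R_PosInf;
  return ii - (ig * ig) / gg;
}
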