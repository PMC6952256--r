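#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Exact windowed median (R median semantics: mean of the two central order
// statistics when the neighbourhood has even size). Neighbourhoods are
// truncated at the frame border, so a constant image maps to itself exactly.
// [[Rcpp::export]]
NumericMatrix cpp_median_window(NumericMatrix x, int radius) {
  const int nr = x.nrow(), nc = x.ncol();
  NumericMatrix out(nr, nc);
  std::vector<double> buf;
  buf.reserve((2 * radius + 1) * (2 * radius + 1));
  for (int j = 0; j < nc; ++j) {
    const int j0 = std::max(0, j - radius), j1 = std::min(nc - 1, j + radius);
    for (int i = 0; i < nr; ++i) {
      const int i0 = std::max(0, i - radius), i1 = std::min(nr - 1, i + radius);
      buf.clear();
      for (int jj = j0; jj <= j1; ++jj)
        for (int ii = i0; ii <= i1; ++ii)
          buf.push_back(x(ii, jj));
      const int n = (int)buf.size();
      const int k = n / 2;
      std::nth_element(buf.begin(), buf.begin() + k, buf.end());
      double m = buf[k];
      if (n % 2 == 0) {
        // lower central order statistic is the max of the first half
        double lo = *std::max_element(buf.begin(), buf.begin() + k);
        m = 0.5 * (m + lo);
      }
      out(i, j) = m;
    }
  }
  return out;
}

// Joint (cross) bilateral filter. The range kernel is driven by the guide
// image's luminance, shared by the three colour channels; the weight field
// therefore needs to be evaluated once per pixel. Windows are truncated at
// the border and the normaliser K_p makes each output a convex combination
// of neighbourhood values.
// [[Rcpp::export]]
NumericVector cpp_joint_bilateral(NumericVector img, NumericMatrix guide,
                                  double sigma_s, double sigma_c, int radius) {
  IntegerVector d = img.attr("dim");
  const int nr = d[0], nc = d[1], nch = d[2];
  NumericVector out(img.size());
  out.attr("dim") = d;
  if (radius == 0) {  // N_p = {p}: identity
    std::copy(img.begin(), img.end(), out.begin());
    return out;
  }
  const double inv2ss = 1.0 / (2.0 * sigma_s * sigma_s);
  const double inv2sc = 1.0 / (2.0 * sigma_c * sigma_c);
  const int w = 2 * radius + 1;
  std::vector<double> spatial(w * w);
  for (int dj = -radius; dj <= radius; ++dj)
    for (int di = -radius; di <= radius; ++di)
      spatial[(dj + radius) * w + (di + radius)] =
          std::exp(-(double)(di * di + dj * dj) * inv2ss);
  const double *px = img.begin();
  double *po = out.begin();
  const int plane = nr * nc;
  for (int j = 0; j < nc; ++j) {
    const int j0 = std::max(0, j - radius), j1 = std::min(nc - 1, j + radius);
    for (int i = 0; i < nr; ++i) {
      const int i0 = std::max(0, i - radius), i1 = std::min(nr - 1, i + radius);
      const double gp = guide(i, j);
      double K = 0.0, acc0 = 0.0, acc1 = 0.0, acc2 = 0.0;
      for (int jj = j0; jj <= j1; ++jj) {
        const int soff = (jj - j + radius) * w + radius - i;
        const int coff = jj * nr;
        for (int ii = i0; ii <= i1; ++ii) {
          const double dg = guide(ii, jj) - gp;
          const double wgt = spatial[soff + ii] * std::exp(-dg * dg * inv2sc);
          K += wgt;
          const int q = coff + ii;
          acc0 += wgt * px[q];
          if (nch > 1) acc1 += wgt * px[q + plane];
          if (nch > 2) acc2 += wgt * px[q + 2 * plane];
        }
      }
      const int p = j * nr + i;
      po[p] = acc0 / K;
      if (nch > 1) po[p + plane] = acc1 / K;
      if (nch > 2) po[p + 2 * plane] = acc2 / K;
    }
  }
  return out;
}

// Domain-transform recursive filter (RF variant): edge-aware smoothing by
// causal/anticausal first-order passes over rows then columns, with the
// per-iteration sigma schedule sigma_i = sigma_s * sqrt(3) * 2^(N-i) /
// sqrt(4^N - 1) so the cascade's overall variance equals sigma_s^2. The
// feedback coefficient a^d adapts to guide-image gradients: d = 1 +
// (sigma_s/sigma_r)*|dI| blocks diffusion across strong edges.
// [[Rcpp::export]]
NumericMatrix cpp_domain_transform_rf(NumericMatrix x, NumericMatrix guide,
                                      double sigma_s, double sigma_r,
                                      int iterations) {
  const int nr = x.nrow(), nc = x.ncol();
  NumericMatrix J = clone(x);
  // domain-transform derivatives (distances between neighbours)
  NumericMatrix dx(nr, nc), dy(nr, nc);
  const double ratio = sigma_s / sigma_r;
  for (int j = 1; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      dx(i, j) = 1.0 + ratio * std::fabs(guide(i, j) - guide(i, j - 1));
  for (int j = 0; j < nc; ++j)
    for (int i = 1; i < nr; ++i)
      dy(i, j) = 1.0 + ratio * std::fabs(guide(i, j) - guide(i - 1, j));
  for (int it = 0; it < iterations; ++it) {
    const double sigma_i = sigma_s * std::sqrt(3.0) *
                           std::pow(2.0, iterations - (it + 1)) /
                           std::sqrt(std::pow(4.0, iterations) - 1.0);
    const double a = std::exp(-std::sqrt(2.0) / sigma_i);
    // horizontal: left->right then right->left
    for (int i = 0; i < nr; ++i) {
      for (int j = 1; j < nc; ++j) {
        const double v = std::pow(a, dx(i, j));
        J(i, j) += v * (J(i, j - 1) - J(i, j));
      }
      for (int j = nc - 2; j >= 0; --j) {
        const double v = std::pow(a, dx(i, j + 1));
        J(i, j) += v * (J(i, j + 1) - J(i, j));
      }
    }
    // vertical: top->bottom then bottom->top
    for (int j = 0; j < nc; ++j) {
      for (int i = 1; i < nr; ++i) {
        const double v = std::pow(a, dy(i, j));
        J(i, j) += v * (J(i - 1, j) - J(i, j));
      }
      for (int i = nr - 2; i >= 0; --i) {
        const double v = std::pow(a, dy(i + 1, j));
        J(i, j) += v * (J(i + 1, j) - J(i, j));
      }
    }
  }
  return J;
}
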