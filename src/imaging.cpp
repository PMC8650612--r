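#include <Rcpp.h>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Rasterise agents as radially symmetric Gaussian intensity bumps on a dark
// background, add Gaussian noise (R RNG, so renders are reproducible under
// set.seed) and clip to 8-bit. Matrix rows are y, columns x; world
// coordinates are um with the origin at the frame centre.
// [[Rcpp::export]]
NumericMatrix render_frame_cpp(NumericVector x, NumericVector y, int size,
                               double pixel_size, double bump_radius,
                               double amplitude, double background,
                               double noise_sd) {
  NumericMatrix img(size, size);
  std::fill(img.begin(), img.end(), background);

  const double sig_px = (bump_radius / 2.0) / pixel_size;
  const double rad_px = bump_radius / pixel_size;  // 2 sigma support
  const double inv2s2 = 1.0 / (2.0 * sig_px * sig_px);
  const int n = x.size();

  for (int k = 0; k < n; ++k) {
    double cx = x[k] / pixel_size + size / 2.0 + 0.5;  // 1-based px coords
    double cy = y[k] / pixel_size + size / 2.0 + 0.5;
    int j0 = std::max(1, (int)std::ceil(cx - rad_px));
    int j1 = std::min(size, (int)std::floor(cx + rad_px));
    int i0 = std::max(1, (int)std::ceil(cy - rad_px));
    int i1 = std::min(size, (int)std::floor(cy + rad_px));
    for (int j = j0; j <= j1; ++j) {
      double dx = j - cx;
      for (int i = i0; i <= i1; ++i) {
        double dy = i - cy;
        double d2 = dx * dx + dy * dy;
        if (d2 <= rad_px * rad_px)
          img(i - 1, j - 1) += amplitude * std::exp(-d2 * inv2s2);
      }
    }
  }

  if (noise_sd > 0) {
    RNGScope scope;
    for (int idx = 0; idx < size * size; ++idx)
      img[idx] += norm_rand() * noise_sd;
  }

  for (int idx = 0; idx < size * size; ++idx) {
    double v = std::round(img[idx]);
    img[idx] = v < 0 ? 0 : (v > 255 ? 255 : v);
  }
  return img;
}

// Local arithmetic mean over a block x block window clamped to the frame,
// via a summed-area table: O(N) in the number of pixels for any block size.
// [[Rcpp::export]]
NumericMatrix local_mean_cpp(NumericMatrix img, int block) {
  const int nr = img.nrow(), nc = img.ncol();
  const int h = block / 2;
  std::vector<double> sat((nr + 1) * (nc + 1), 0.0);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      sat[(i + 1) + (j + 1) * (nr + 1)] =
        img(i, j) + sat[i + (j + 1) * (nr + 1)] + sat[(i + 1) + j * (nr + 1)] -
        sat[i + j * (nr + 1)];

  NumericMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j) {
    int jl = std::max(0, j - h), jh = std::min(nc - 1, j + h);
    for (int i = 0; i < nr; ++i) {
      int il = std::max(0, i - h), ih = std::min(nr - 1, i + h);
      double s = sat[(ih + 1) + (jh + 1) * (nr + 1)] -
                 sat[il + (jh + 1) * (nr + 1)] -
                 sat[(ih + 1) + jl * (nr + 1)] + sat[il + jl * (nr + 1)];
      out(i, j) = s / ((ih - il + 1) * (jh - jl + 1));
    }
  }
  return out;
}

// Local maxima of a (background-subtracted) image: pixels >= every value in
// a square window of half-width w and strictly above `thresh`. Plateau ties
// are broken later by the merge step in R.
// [[Rcpp::export]]
IntegerMatrix local_maxima_cpp(NumericMatrix img, int w, double thresh) {
  const int nr = img.nrow(), nc = img.ncol();
  std::vector<int> ri, ci;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double v = img(i, j);
      if (v <= thresh) continue;
      bool ismax = true;
      int jl = std::max(0, j - w), jh = std::min(nc - 1, j + w);
      int il = std::max(0, i - w), ih = std::min(nr - 1, i + w);
      for (int jj = jl; jj <= jh && ismax; ++jj)
        for (int ii = il; ii <= ih; ++ii) {
          if (ii == i && jj == j) continue;
          double u = img(ii, jj);
          if (u > v || (u == v && (jj < j || (jj == j && ii < i)))) {
            ismax = false; break;
          }
        }
      if (ismax) { ri.push_back(i + 1); ci.push_back(j + 1); }
    }
  }
  IntegerMatrix out(ri.size(), 2);
  for (size_t k = 0; k < ri.size(); ++k) { out(k, 0) = ri[k]; out(k, 1) = ci[k]; }
  return out;
}

// Sub-pixel centroid and integrated mass of each candidate peak over a
// circular window of radius w px on the background-subtracted image
// (negative values ignored). Returns columns: row, col (sub-pixel, 1-based),
// mass.
// [[Rcpp::export]]
NumericMatrix refine_peaks_cpp(NumericMatrix img, IntegerMatrix peaks, int w) {
  const int nr = img.nrow(), nc = img.ncol(), np = peaks.nrow();
  NumericMatrix out(np, 3);
  for (int k = 0; k < np; ++k) {
    int pi = peaks(k, 0) - 1, pj = peaks(k, 1) - 1;
    double m = 0, sr = 0, sc = 0;
    int il = std::max(0, pi - w), ih = std::min(nr - 1, pi + w);
    int jl = std::max(0, pj - w), jh = std::min(nc - 1, pj + w);
    for (int j = jl; j <= jh; ++j)
      for (int i = il; i <= ih; ++i) {
        double di = i - pi, dj = j - pj;
        if (di * di + dj * dj > (double)w * w + 1e-9) continue;
        double v = img(i, j);
        if (v <= 0) continue;
        m += v; sr += v * i; sc += v * j;
      }
    if (m > 0) { out(k, 0) = sr / m + 1; out(k, 1) = sc / m + 1; out(k, 2) = m; }
    else { out(k, 0) = pi + 1; out(k, 1) = pj + 1; out(k, 2) = 0; }
  }
  return out;
}

// Greedy nearest-neighbour frame-to-frame assignment: candidate pairs within
// `maxdist` are sorted globally by distance and accepted when both endpoints
// are still free. Returns, for each point in frame 2, the 1-based index of
// its match in frame 1 (0 = unmatched, starts a new track).
// [[Rcpp::export]]
IntegerVector link_frames_cpp(NumericVector x1, NumericVector y1,
                              NumericVector x2, NumericVector y2,
                              double maxdist) {
  const int n1 = x1.size(), n2 = x2.size();
  IntegerVector match(n2, 0);
  if (n1 == 0 || n2 == 0 || maxdist <= 0) return match;

  // hash frame-1 points on a grid of cell size maxdist
  double xmin = *std::min_element(x1.begin(), x1.end());
  double ymin = *std::min_element(y1.begin(), y1.end());
  double xmax = *std::max_element(x1.begin(), x1.end());
  double ymax = *std::max_element(y1.begin(), y1.end());
  int gx = std::max(1, (int)((xmax - xmin) / maxdist) + 1);
  int gy = std::max(1, (int)((ymax - ymin) / maxdist) + 1);
  std::vector<std::vector<int>> cells((size_t)gx * gy);
  for (int i = 0; i < n1; ++i) {
    int cx = std::min(gx - 1, std::max(0, (int)((x1[i] - xmin) / maxdist)));
    int cy = std::min(gy - 1, std::max(0, (int)((y1[i] - ymin) / maxdist)));
    cells[cx + (size_t)gx * cy].push_back(i);
  }

  struct Pair { double d2; int i1, i2; };
  std::vector<Pair> pairs;
  const double md2 = maxdist * maxdist;
  for (int j = 0; j < n2; ++j) {
    int cx = (int)((x2[j] - xmin) / maxdist);
    int cy = (int)((y2[j] - ymin) / maxdist);
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int ux = cx + dx, uy = cy + dy;
        if (ux < 0 || uy < 0 || ux >= gx || uy >= gy) continue;
        for (int i : cells[ux + (size_t)gx * uy]) {
          double ddx = x2[j] - x1[i], ddy = y2[j] - y1[i];
          double d2 = ddx * ddx + ddy * ddy;
          if (d2 <= md2) pairs.push_back({d2, i, j});
        }
      }
  }
  std::sort(pairs.begin(), pairs.end(), [](const Pair& a, const Pair& b) {
    if (a.d2 != b.d2) return a.d2 < b.d2;
    if (a.i1 != b.i1) return a.i1 < b.i1;
    return a.i2 < b.i2;
  });
  std::vector<char> used1(n1, 0);
  for (const Pair& p : pairs) {
    if (used1[p.i1] || match[p.i2] != 0) continue;
    used1[p.i1] = 1;
    match[p.i2] = p.i1 + 1;
  }
  return match;
}
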