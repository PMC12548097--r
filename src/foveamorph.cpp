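#include <Rcpp.h>
#include <queue>
#include <cmath>
using namespace Rcpp;

// Connected-component labelling of a logical matrix by BFS flood fill.
// connectivity: 4 or 8. Returns integer matrix, 0 = background, labels 1..k
// in scan order of each component's first pixel (column-major, as stored).
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(LogicalMatrix mask, int connectivity) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  const int dr4[] = {-1, 1, 0, 0}, dc4[] = {0, 0, -1, 1};
  const int dr8[] = {-1, 1, 0, 0, -1, -1, 1, 1}, dc8[] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int *dr = connectivity == 8 ? dr8 : dr4;
  const int *dc = connectivity == 8 ? dc8 : dc4;
  const int nnb = connectivity == 8 ? 8 : 4;
  int next = 0;
  std::queue<std::pair<int, int> > q;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c) || lab(r, c) != 0) continue;
      ++next;
      lab(r, c) = next;
      q.push(std::make_pair(r, c));
      while (!q.empty()) {
        std::pair<int, int> p = q.front();
        q.pop();
        for (int i = 0; i < nnb; ++i) {
          int rr = p.first + dr[i], cc = p.second + dc[i];
          if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
          if (mask(rr, cc) && lab(rr, cc) == 0) {
            lab(rr, cc) = next;
            q.push(std::make_pair(rr, cc));
          }
        }
      }
    }
  }
  return lab;
}

// Variable-radius dart throwing on a rectangular ROI.
// Density surface (cones/um^2): d(x,y) = base + (peak - base) *
//   exp(-((x-cx)^2 + (y-cy)^2) / (2 sigma^2)).
// A candidate at (x,y) is accepted when no accepted point lies within
// inhibition * s(x,y), where s = sqrt(2 / (sqrt(3) * d)) is the hexagonal
// lattice pitch at the local target density. Proposals continue until
// max_rejections cumulative rejections. Uses R's RNG (seed-deterministic).
// [[Rcpp::export]]
NumericMatrix cpp_dart_throw(double width_um, double height_um,
                             double peak_density, double base_density,
                             double sigma_um, double cx, double cy,
                             double inhibition, double max_rejections) {
  const double amp = peak_density - base_density;
  // minimal spacing governs the hash-grid cell size
  const double s_min = std::sqrt(2.0 / (std::sqrt(3.0) * peak_density));
  const double cell = std::max(inhibition * s_min, 1e-6);
  const int gx = std::max(1, (int)std::ceil(width_um / cell));
  const int gy = std::max(1, (int)std::ceil(height_um / cell));
  std::vector<std::vector<int> > grid((size_t)gx * gy);
  std::vector<double> px, py;
  px.reserve(20000);
  py.reserve(20000);
  double rejections = 0.0;
  while (rejections < max_rejections) {
    double x = unif_rand() * width_um;
    double y = unif_rand() * height_um;
    double dxp = x - cx, dyp = y - cy;
    double dens = base_density + amp * std::exp(-(dxp * dxp + dyp * dyp) / (2.0 * sigma_um * sigma_um));
    double rad = inhibition * std::sqrt(2.0 / (std::sqrt(3.0) * dens));
    int span = (int)std::ceil(rad / cell);
    int ix = (int)(x / cell), iy = (int)(y / cell);
    if (ix >= gx) ix = gx - 1;
    if (iy >= gy) iy = gy - 1;
    bool ok = true;
    double r2 = rad * rad;
    for (int jx = std::max(0, ix - span); ok && jx <= std::min(gx - 1, ix + span); ++jx) {
      for (int jy = std::max(0, iy - span); ok && jy <= std::min(gy - 1, iy + span); ++jy) {
        const std::vector<int> &bucket = grid[(size_t)jx * gy + jy];
        for (size_t k = 0; k < bucket.size(); ++k) {
          double dx = px[bucket[k]] - x, dy = py[bucket[k]] - y;
          if (dx * dx + dy * dy < r2) { ok = false; break; }
        }
      }
    }
    if (ok) {
      px.push_back(x);
      py.push_back(y);
      grid[(size_t)ix * gy + iy].push_back((int)px.size() - 1);
    } else {
      rejections += 1.0;
    }
  }
  NumericMatrix out((int)px.size(), 2);
  for (int i = 0; i < (int)px.size(); ++i) {
    out(i, 0) = px[i];
    out(i, 1) = py[i];
  }
  return out;
}
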