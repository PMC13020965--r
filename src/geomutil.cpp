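#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <unordered_map>
#include <cstdint>

// Small geometric utilities: greedy minimum-spacing downsampling and
// nearest-neighbour queries, both on a uniform grid hash so desk-scale
// clouds stay fast.

namespace {

struct GridHash {
  double cell;
  std::unordered_map<uint64_t, std::vector<int> > cells;
  static uint64_t key(int ix, int iy, int iz) {
    return (uint64_t)(uint32_t)(ix + (1 << 20)) * 2097169ULL * 2097169ULL
         + (uint64_t)(uint32_t)(iy + (1 << 20)) * 2097169ULL
         + (uint64_t)(uint32_t)(iz + (1 << 20));
  }
  explicit GridHash(double cell_) : cell(cell_) {}
  void insert(int id, const double* p) {
    cells[key((int)std::floor(p[0] / cell), (int)std::floor(p[1] / cell),
              (int)std::floor(p[2] / cell))].push_back(id);
  }
  template <class F>
  void neighbours(const double* p, F fn) const {
    int ix = (int)std::floor(p[0] / cell);
    int iy = (int)std::floor(p[1] / cell);
    int iz = (int)std::floor(p[2] / cell);
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dz = -1; dz <= 1; ++dz) {
          std::unordered_map<uint64_t, std::vector<int> >::const_iterator it =
              cells.find(key(ix + dx, iy + dy, iz + dz));
          if (it == cells.end()) continue;
          for (size_t q = 0; q < it->second.size(); ++q) fn(it->second[q]);
        }
  }
};

} // namespace

// Keep points in input order whenever they are at least min_spacing away
// from every already-kept point.  Returns 1-based indices of kept points.
// [[Rcpp::export(name = ".greedy_downsample")]]
Rcpp::IntegerVector greedy_downsample(Rcpp::NumericMatrix pts, double min_spacing) {
  const int n = pts.nrow();
  if (min_spacing <= 0) Rcpp::stop("min_spacing must be positive");
  GridHash grid(min_spacing);
  std::vector<double> kept_pts;
  std::vector<int> kept;
  const double r2 = min_spacing * min_spacing;
  for (int i = 0; i < n; ++i) {
    double p[3] = {pts(i, 0), pts(i, 1), pts(i, 2)};
    bool ok = true;
    grid.neighbours(p, [&](int id) {
      if (!ok) return;
      const double* q = &kept_pts[3 * id];
      double d2 = (p[0] - q[0]) * (p[0] - q[0]) + (p[1] - q[1]) * (p[1] - q[1])
                + (p[2] - q[2]) * (p[2] - q[2]);
      if (d2 < r2) ok = false;
    });
    if (ok) {
      int id = (int)kept.size();
      kept_pts.push_back(p[0]); kept_pts.push_back(p[1]); kept_pts.push_back(p[2]);
      grid.insert(id, p);
      kept.push_back(i + 1);
    }
  }
  return Rcpp::IntegerVector(kept.begin(), kept.end());
}

// For each query row, the 1-based index of its nearest reference row.
// Grid-accelerated with progressive ring expansion; exact.
// [[Rcpp::export(name = ".nearest_index")]]
Rcpp::IntegerVector nearest_index(Rcpp::NumericMatrix query, Rcpp::NumericMatrix ref) {
  const int nq = query.nrow(), nr = ref.nrow();
  if (nr == 0) Rcpp::stop("empty reference set");
  Rcpp::IntegerVector out(nq);
  // estimate a grid cell from the reference bounding box
  double lo[3], hi[3];
  for (int k = 0; k < 3; ++k) { lo[k] = ref(0, k); hi[k] = ref(0, k); }
  for (int i = 1; i < nr; ++i)
    for (int k = 0; k < 3; ++k) {
      if (ref(i, k) < lo[k]) lo[k] = ref(i, k);
      if (ref(i, k) > hi[k]) hi[k] = ref(i, k);
    }
  // cell from the largest extent only: degenerate (planar/linear) clouds
  // must not shrink the cell, or ring expansion from distant queries crawls
  double ext = std::max(hi[0] - lo[0], std::max(hi[1] - lo[1], hi[2] - lo[2]));
  double cell = std::max(ext / (std::cbrt((double)nr) + 1.0), 1e-6);

  std::unordered_map<uint64_t, std::vector<int> > grid;
  struct K {
    static uint64_t key(int ix, int iy, int iz) {
      return (uint64_t)(uint32_t)(ix + (1 << 20)) * 2097169ULL * 2097169ULL
           + (uint64_t)(uint32_t)(iy + (1 << 20)) * 2097169ULL
           + (uint64_t)(uint32_t)(iz + (1 << 20));
    }
  };
  for (int i = 0; i < nr; ++i)
    grid[K::key((int)std::floor(ref(i, 0) / cell), (int)std::floor(ref(i, 1) / cell),
                (int)std::floor(ref(i, 2) / cell))].push_back(i);

  for (int q = 0; q < nq; ++q) {
    double p[3] = {query(q, 0), query(q, 1), query(q, 2)};
    int ix = (int)std::floor(p[0] / cell);
    int iy = (int)std::floor(p[1] / cell);
    int iz = (int)std::floor(p[2] / cell);
    int best = -1; double bestd = R_PosInf;
    for (int ring = 0; ring < (1 << 20); ++ring) {
      // scan shell at Chebyshev radius `ring`
      for (int dx = -ring; dx <= ring; ++dx)
        for (int dy = -ring; dy <= ring; ++dy)
          for (int dz = -ring; dz <= ring; ++dz) {
            if (std::max(std::abs(dx), std::max(std::abs(dy), std::abs(dz))) != ring)
              continue;
            std::unordered_map<uint64_t, std::vector<int> >::const_iterator it =
                grid.find(K::key(ix + dx, iy + dy, iz + dz));
            if (it == grid.end()) continue;
            for (size_t t = 0; t < it->second.size(); ++t) {
              int i = it->second[t];
              double d2 = (p[0] - ref(i, 0)) * (p[0] - ref(i, 0))
                        + (p[1] - ref(i, 1)) * (p[1] - ref(i, 1))
                        + (p[2] - ref(i, 2)) * (p[2] - ref(i, 2));
              if (d2 < bestd || (d2 == bestd && i < best)) { bestd = d2; best = i; }
            }
          }
      // every unscanned point lies at Euclidean distance >= ring * cell
      if (best >= 0 && (double)ring * cell >= std::sqrt(bestd)) break;
    }
    out[q] = best + 1;
  }
  return out;
}
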