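#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Sequential saturation binding of crosslinker molecules onto a lever field.
//
// Each lever starts with two free binding sites. Molecules are introduced
// one by one: each binds a random lever with a free site (uniform over
// eligible levers in ascending index order, or uniform over free sites if
// weight_by_sites), then binds the closest OTHER lever with a free site
// within `reach` (ties broken by lowest lever index); if none is reachable
// it stays singly bound. The loop ends when no free site remains.
//
// Uses R's RNG (unif_rand) so results are reproducible via set.seed() and
// exactly replayable by an R-level reference implementation drawing
// runif(1) with the same selection rule.
//
// Neighbour queries use a uniform grid of bucket size `reach`: the closest
// eligible lever within reach is always inside the 3x3 bucket
// neighbourhood of the query lever.

// [[Rcpp::export]]
List cpp_saturate(NumericVector x, NumericVector y, double reach,
                  bool weight_by_sites) {
  const int n = x.size();
  if (n == 0) stop("empty lever field");
  if (reach <= 0) stop("reach must be positive");

  std::vector<int> free_sites(n, 2);
  int total_free = 2 * n;

  // bucket grid
  double xmin = x[0], ymin = y[0], xmax = x[0], ymax = y[0];
  for (int i = 1; i < n; ++i) {
    if (x[i] < xmin) xmin = x[i];
    if (x[i] > xmax) xmax = x[i];
    if (y[i] < ymin) ymin = y[i];
    if (y[i] > ymax) ymax = y[i];
  }
  const double cell = reach;
  const int nx = std::max(1, (int)std::floor((xmax - xmin) / cell) + 1);
  const int ny = std::max(1, (int)std::floor((ymax - ymin) / cell) + 1);
  std::vector<std::vector<int>> buckets((size_t)nx * ny);
  std::vector<int> bx(n), by(n);
  for (int i = 0; i < n; ++i) {
    int cx = std::min(nx - 1, (int)std::floor((x[i] - xmin) / cell));
    int cy = std::min(ny - 1, (int)std::floor((y[i] - ymin) / cell));
    bx[i] = cx; by[i] = cy;
    buckets[(size_t)cy * nx + cx].push_back(i);
  }

  const double reach2 = reach * reach;
  std::vector<int> mol_a, mol_b;
  mol_a.reserve(2 * n);
  mol_b.reserve(2 * n);

  while (total_free > 0) {
    // pick initial lever: k-th eligible unit in ascending lever order
    int a = -1;
    if (weight_by_sites) {
      int k = (int)(unif_rand() * total_free);
      if (k >= total_free) k = total_free - 1;
      int acc = 0;
      for (int i = 0; i < n; ++i) {
        acc += free_sites[i];
        if (k < acc) { a = i; break; }
      }
    } else {
      int n_elig = 0;
      for (int i = 0; i < n; ++i) if (free_sites[i] > 0) ++n_elig;
      int k = (int)(unif_rand() * n_elig);
      if (k >= n_elig) k = n_elig - 1;
      int seen = 0;
      for (int i = 0; i < n; ++i) {
        if (free_sites[i] > 0) {
          if (seen == k) { a = i; break; }
          ++seen;
        }
      }
    }
    free_sites[a] -= 1;
    total_free -= 1;

    // closest other eligible lever within reach; tie -> lowest index
    int best = -1;
    double best_d2 = reach2;
    for (int dy = -1; dy <= 1; ++dy) {
      int cy = by[a] + dy;
      if (cy < 0 || cy >= ny) continue;
      for (int dx = -1; dx <= 1; ++dx) {
        int cx = bx[a] + dx;
        if (cx < 0 || cx >= nx) continue;
        const std::vector<int> &bk = buckets[(size_t)cy * nx + cx];
        for (size_t m = 0; m < bk.size(); ++m) {
          int j = bk[m];
          if (j == a || free_sites[j] <= 0) continue;
          double ddx = x[j] - x[a], ddy = y[j] - y[a];
          double d2 = ddx * ddx + ddy * ddy;
          if (d2 <= reach2 &&
              (best < 0 || d2 < best_d2 || (d2 == best_d2 && j < best))) {
            best = j;
            best_d2 = d2;
          }
        }
      }
    }
    if (best >= 0) {
      free_sites[best] -= 1;
      total_free -= 1;
      mol_a.push_back(a + 1);
      mol_b.push_back(best + 1);
    } else {
      mol_a.push_back(a + 1);
      mol_b.push_back(NA_INTEGER);
    }
  }

  return List::create(_["lever_a"] = wrap(mol_a),
                      _["lever_b"] = wrap(mol_b));
}
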