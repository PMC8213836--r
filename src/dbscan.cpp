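#include <Rcpp.h>
#include <vector>
#include <deque>
#include <cmath>
using namespace Rcpp;

// Fixed-radius density clustering (DBSCAN) over 2-D points.
// A point is a core point if at least min_pts points (itself included) lie
// within eps; clusters are grown from core points by breadth-first
// expansion; border points join the first cluster that reaches them;
// remaining points are noise (label 0). Neighbour search uses a uniform
// grid of bucket size eps, so each query scans a 3x3 neighbourhood.

// [[Rcpp::export]]
IntegerVector cpp_dbscan(NumericVector x, NumericVector y, double eps,
                         int min_pts) {
  const int n = x.size();
  if (n == 0) stop("empty point set");
  if (eps <= 0 || min_pts < 1) stop("eps must be positive, min_pts >= 1");

  double xmin = x[0], ymin = y[0], xmax = x[0], ymax = y[0];
  for (int i = 1; i < n; ++i) {
    if (x[i] < xmin) xmin = x[i];
    if (x[i] > xmax) xmax = x[i];
    if (y[i] < ymin) ymin = y[i];
    if (y[i] > ymax) ymax = y[i];
  }
  const double cell = eps;
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

  const double eps2 = eps * eps;
  std::vector<int> nbr; // reused scratch
  auto neighbours = [&](int i) {
    nbr.clear();
    for (int dy = -1; dy <= 1; ++dy) {
      int cy = by[i] + dy;
      if (cy < 0 || cy >= ny) continue;
      for (int dx = -1; dx <= 1; ++dx) {
        int cx = bx[i] + dx;
        if (cx < 0 || cx >= nx) continue;
        const std::vector<int> &bk = buckets[(size_t)cy * nx + cx];
        for (size_t m = 0; m < bk.size(); ++m) {
          int j = bk[m];
          double ddx = x[j] - x[i], ddy = y[j] - y[i];
          if (ddx * ddx + ddy * ddy <= eps2) nbr.push_back(j);
        }
      }
    }
  };

  IntegerVector labels(n, 0);
  std::vector<char> visited(n, 0);
  int cluster = 0;
  std::deque<int> queue;

  for (int i = 0; i < n; ++i) {
    if (visited[i]) continue;
    visited[i] = 1;
    neighbours(i);
    if ((int)nbr.size() < min_pts) continue; // noise unless claimed later
    ++cluster;
    labels[i] = cluster;
    queue.assign(nbr.begin(), nbr.end());
    while (!queue.empty()) {
      int j = queue.front();
      queue.pop_front();
      if (labels[j] == 0) labels[j] = cluster; // border or new core
      if (visited[j]) continue;
      visited[j] = 1;
      neighbours(j);
      if ((int)nbr.size() >= min_pts) {
        for (size_t m = 0; m < nbr.size(); ++m) queue.push_back(nbr[m]);
      }
    }
  }
  return labels;
}
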