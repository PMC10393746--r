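#include <Rcpp.h>
using namespace Rcpp;

// Point sets may overlap (a cell can carry several hierarchy marks, e.g.
// Tcell and CD8+ Tcell). Each point carries an integer cell id; pairs with
// equal ids are excluded so "nearest cell of type j" never means the cell
// itself. Pass all-distinct ids for genuinely disjoint sets.

// Nearest-neighbour distance from each point of set i to set j.
// [[Rcpp::export]]
NumericVector cpp_nn_dist(NumericVector xi, NumericVector yi, IntegerVector idi,
                          NumericVector xj, NumericVector yj, IntegerVector idj) {
  const int ni = xi.size(), nj = xj.size();
  NumericVector out(ni);
  for (int a = 0; a < ni; ++a) {
    double best = R_PosInf;
    for (int b = 0; b < nj; ++b) {
      if (idi[a] == idj[b]) continue;
      const double dx = xi[a] - xj[b], dy = yi[a] - yj[b];
      const double d2 = dx * dx + dy * dy;
      if (d2 < best) best = d2;
    }
    out[a] = std::sqrt(best);
  }
  return out;
}

// For each radius r (ascending), total number of (i, j) point pairs at
// distance strictly less than r; the K-function numerator.
// [[Rcpp::export]]
NumericVector cpp_count_within(NumericVector xi, NumericVector yi, IntegerVector idi,
                               NumericVector xj, NumericVector yj, IntegerVector idj,
                               NumericVector radii) {
  const int ni = xi.size(), nj = xj.size(), nr = radii.size();
  NumericVector counts(nr);
  std::vector<double> r2(nr);
  for (int k = 0; k < nr; ++k) r2[k] = radii[k] * radii[k];
  for (int a = 0; a < ni; ++a) {
    for (int b = 0; b < nj; ++b) {
      if (idi[a] == idj[b]) continue;
      const double dx = xi[a] - xj[b], dy = yi[a] - yj[b];
      const double d2 = dx * dx + dy * dy;
      for (int k = nr - 1; k >= 0 && d2 < r2[k]; --k) counts[k] += 1.0;
    }
  }
  return counts;
}

// All pairwise i-j distances (same-id pairs dropped: the i == j diagonal
// of the MD/MADD distance matrix).
// [[Rcpp::export]]
NumericVector cpp_pairwise_dists(NumericVector xi, NumericVector yi, IntegerVector idi,
                                 NumericVector xj, NumericVector yj, IntegerVector idj) {
  const int ni = xi.size(), nj = xj.size();
  std::vector<double> buf;
  buf.reserve((size_t)ni * nj);
  for (int a = 0; a < ni; ++a)
    for (int b = 0; b < nj; ++b) {
      if (idi[a] == idj[b]) continue;
      const double dx = xi[a] - xj[b], dy = yi[a] - yj[b];
      buf.push_back(std::sqrt(dx * dx + dy * dy));
    }
  return wrap(buf);
}

// Nearest-neighbour distance from every point of an evenly spaced lattice
// (cell centres of an nx x ny partition of the window) to the point set.
// [[Rcpp::export]]
NumericVector cpp_grid_nn_dist(double xmin, double xmax,
                               double ymin, double ymax,
                               int nx, int ny,
                               NumericVector xp, NumericVector yp) {
  const int np = xp.size();
  const double wx = (xmax - xmin) / nx, wy = (ymax - ymin) / ny;
  NumericVector out((R_xlen_t)nx * ny);
  R_xlen_t k = 0;
  for (int iy = 0; iy < ny; ++iy) {
    const double gy = ymin + (iy + 0.5) * wy;
    for (int ix = 0; ix < nx; ++ix) {
      const double gx = xmin + (ix + 0.5) * wx;
      double best = R_PosInf;
      for (int b = 0; b < np; ++b) {
        const double dx = gx - xp[b], dy = gy - yp[b];
        const double d2 = dx * dx + dy * dy;
        if (d2 < best) best = d2;
      }
      out[k++] = std::sqrt(best);
    }
  }
  return out;
}
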