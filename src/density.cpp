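#include <Rcpp.h>
using namespace Rcpp;

// Accumulate normalized 3D Gaussians (one per center) onto a regular grid.
// values: length nx*ny*nz, x fastest. Each Gaussian integrates to 1 over
// continuous space; contributions are truncated at `cutoff` standard
// deviations.
// [[Rcpp::export]]
NumericVector cpp_accumulate_gaussian(IntegerVector dims, NumericVector origin,
                                      double spacing, NumericMatrix centers,
                                      double sigma, double cutoff = 4.0) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector values(static_cast<R_xlen_t>(nx) * ny * nz);
  const double norm = 1.0 / std::pow(2.0 * M_PI * sigma * sigma, 1.5);
  const double r = cutoff * sigma;
  const int w = static_cast<int>(std::ceil(r / spacing));
  const double r2 = r * r;
  const double inv2s2 = 1.0 / (2.0 * sigma * sigma);
  for (int c = 0; c < centers.nrow(); ++c) {
    const double cx = centers(c, 0), cy = centers(c, 1), cz = centers(c, 2);
    const int ix = static_cast<int>(std::floor((cx - origin[0]) / spacing));
    const int iy = static_cast<int>(std::floor((cy - origin[1]) / spacing));
    const int iz = static_cast<int>(std::floor((cz - origin[2]) / spacing));
    const int x0 = std::max(0, ix - w), x1 = std::min(nx - 1, ix + w + 1);
    const int y0 = std::max(0, iy - w), y1 = std::min(ny - 1, iy + w + 1);
    const int z0 = std::max(0, iz - w), z1 = std::min(nz - 1, iz + w + 1);
    for (int k = z0; k <= z1; ++k) {
      const double dz = origin[2] + k * spacing - cz;
      for (int j = y0; j <= y1; ++j) {
        const double dy = origin[1] + j * spacing - cy;
        const double dyz2 = dy * dy + dz * dz;
        if (dyz2 > r2) continue;
        const R_xlen_t base = (static_cast<R_xlen_t>(k) * ny + j) * nx;
        for (int i = x0; i <= x1; ++i) {
          const double dx = origin[0] + i * spacing - cx;
          const double d2 = dx * dx + dyz2;
          if (d2 <= r2) values[base + i] += norm * std::exp(-d2 * inv2s2);
        }
      }
    }
  }
  return values;
}

// Logical mask of voxels within `radius` of any atom.
// [[Rcpp::export]]
LogicalVector cpp_shell_mask(IntegerVector dims, NumericVector origin,
                             double spacing, NumericMatrix atoms,
                             double radius) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  LogicalVector mask(static_cast<R_xlen_t>(nx) * ny * nz, false);
  const int w = static_cast<int>(std::ceil(radius / spacing));
  const double r2 = radius * radius;
  for (int a = 0; a < atoms.nrow(); ++a) {
    const double ax = atoms(a, 0), ay = atoms(a, 1), az = atoms(a, 2);
    const int ix = static_cast<int>(std::floor((ax - origin[0]) / spacing));
    const int iy = static_cast<int>(std::floor((ay - origin[1]) / spacing));
    const int iz = static_cast<int>(std::floor((az - origin[2]) / spacing));
    const int x0 = std::max(0, ix - w), x1 = std::min(nx - 1, ix + w + 1);
    const int y0 = std::max(0, iy - w), y1 = std::min(ny - 1, iy + w + 1);
    const int z0 = std::max(0, iz - w), z1 = std::min(nz - 1, iz + w + 1);
    for (int k = z0; k <= z1; ++k) {
      const double dz = origin[2] + k * spacing - az;
      for (int j = y0; j <= y1; ++j) {
        const double dy = origin[1] + j * spacing - ay;
        const double dyz2 = dy * dy + dz * dz;
        if (dyz2 > r2) continue;
        const R_xlen_t base = (static_cast<R_xlen_t>(k) * ny + j) * nx;
        for (int i = x0; i <= x1; ++i) {
          if (mask[base + i]) continue;
          const double dx = origin[0] + i * spacing - ax;
          if (dx * dx + dyz2 <= r2) mask[base + i] = true;
        }
      }
    }
  }
  return mask;
}

// Minimum distance from each query point to any reference point.
// [[Rcpp::export]]
NumericVector cpp_min_dist(NumericMatrix query, NumericMatrix ref) {
  NumericVector out(query.nrow());
  for (int i = 0; i < query.nrow(); ++i) {
    double best = R_PosInf;
    const double qx = query(i, 0), qy = query(i, 1), qz = query(i, 2);
    for (int j = 0; j < ref.nrow(); ++j) {
      const double dx = qx - ref(j, 0), dy = qy - ref(j, 1),
                   dz = qz - ref(j, 2);
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

// For each site, count distinct frames with at least one water within
// `radius`. waters: n x 3; frame: frame index (1-based) per water row.
// [[Rcpp::export]]
IntegerVector cpp_site_support(NumericMatrix sites, NumericMatrix waters,
                               IntegerVector frame, int n_frames,
                               double radius) {
  const double r2 = radius * radius;
  IntegerVector out(sites.nrow());
  std::vector<char> seen(n_frames);
  for (int s = 0; s < sites.nrow(); ++s) {
    std::fill(seen.begin(), seen.end(), 0);
    const double sx = sites(s, 0), sy = sites(s, 1), sz = sites(s, 2);
    int count = 0;
    for (int w = 0; w < waters.nrow(); ++w) {
      const int f = frame[w] - 1;
      if (seen[f]) continue;
      const double dx = sx - waters(w, 0), dy = sy - waters(w, 1),
                   dz = sz - waters(w, 2);
      if (dx * dx + dy * dy + dz * dz <= r2) {
        seen[f] = 1;
        ++count;
      }
    }
    out[s] = count;
  }
  return out;
}
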