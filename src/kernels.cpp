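#include <Rcpp.h>
#include <cmath>
#include <algorithm>
#include <vector>
#include <limits>

using namespace Rcpp;

// Linear index for a 0-based voxel (i,j,k) in an nx*ny*nz array (column-major,
// matching R's array layout).
static inline R_xlen_t vidx(int i, int j, int k, int nx, int ny) {
  return (R_xlen_t)i + (R_xlen_t)nx * ((R_xlen_t)j + (R_xlen_t)ny * (R_xlen_t)k);
}

// Mark all voxels whose center lies within `radius` of any sphere center.
// Centers are 0-based voxel coordinates (rows of `centers`), radius in px.
// [[Rcpp::export]]
LogicalVector cpp_raster_spheres(IntegerVector dims, NumericMatrix centers,
                                 double radius) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  LogicalVector out((R_xlen_t)nx * ny * nz, false);
  const double r2 = radius * radius;
  for (int c = 0; c < centers.nrow(); ++c) {
    const double cx = centers(c, 0), cy = centers(c, 1), cz = centers(c, 2);
    const int i0 = std::max(0, (int)std::ceil(cx - radius));
    const int i1 = std::min(nx - 1, (int)std::floor(cx + radius));
    const int j0 = std::max(0, (int)std::ceil(cy - radius));
    const int j1 = std::min(ny - 1, (int)std::floor(cy + radius));
    const int k0 = std::max(0, (int)std::ceil(cz - radius));
    const int k1 = std::min(nz - 1, (int)std::floor(cz + radius));
    for (int k = k0; k <= k1; ++k) {
      const double dz2 = (k - cz) * (k - cz);
      for (int j = j0; j <= j1; ++j) {
        const double dyz2 = dz2 + (j - cy) * (j - cy);
        if (dyz2 > r2) continue;
        for (int i = i0; i <= i1; ++i) {
          if (dyz2 + (i - cx) * (i - cx) <= r2)
            out[vidx(i, j, k, nx, ny)] = true;
        }
      }
    }
  }
  return out;
}

// Per-shell tally around a spherical membrane. Shell s (1..nshells) holds
// voxels with surface distance d in ((s-1)*thickness, s*thickness], exterior
// side only (d > 0). Returns shell voxel counts, occupied (ribosome) voxel
// counts and the per-shell sum of surface distances (px).
// [[Rcpp::export]]
List cpp_shell_tally(IntegerVector dims, NumericVector center, double radius,
                     double thickness, int nshells, LogicalVector ribo) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  if ((R_xlen_t)nx * ny * nz != ribo.size())
    stop("ribosome mask does not match dims");
  std::vector<double> vol(nshells, 0.0), occ(nshells, 0.0), dsum(nshells, 0.0);
  const double cx = center[0], cy = center[1], cz = center[2];
  for (int k = 0; k < nz; ++k) {
    const double dz2 = (k - cz) * (k - cz);
    for (int j = 0; j < ny; ++j) {
      const double dyz2 = dz2 + (j - cy) * (j - cy);
      const R_xlen_t base = (R_xlen_t)nx * ((R_xlen_t)j + (R_xlen_t)ny * k);
      for (int i = 0; i < nx; ++i) {
        const double d = std::sqrt(dyz2 + (i - cx) * (i - cx)) - radius;
        if (d <= 0) continue;
        const int s = (int)std::ceil(d / thickness);
        if (s < 1 || s > nshells) continue;
        vol[s - 1] += 1.0;
        dsum[s - 1] += d;
        if (ribo[base + i]) occ[s - 1] += 1.0;
      }
    }
  }
  return List::create(_["volume"] = wrap(vol), _["occupied"] = wrap(occ),
                      _["dist_sum"] = wrap(dsum));
}

// Shell index per voxel (0 = interior/outside all shells). Used by the
// mask-based cross-check path and the partition tests.
// [[Rcpp::export]]
IntegerVector cpp_shell_index(IntegerVector dims, NumericVector center,
                              double radius, double thickness, int nshells) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  IntegerVector out((R_xlen_t)nx * ny * nz);
  const double cx = center[0], cy = center[1], cz = center[2];
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        const double d = std::sqrt((i - cx) * (i - cx) + (j - cy) * (j - cy) +
                                   (k - cz) * (k - cz)) - radius;
        int s = 0;
        if (d > 0) {
          s = (int)std::ceil(d / thickness);
          if (s > nshells) s = 0;
        }
        out[vidx(i, j, k, nx, ny)] = s;
      }
  return out;
}

// 1-voxel-thick spherical membrane surface mask (|dist to center - R| < 0.5).
// [[Rcpp::export]]
LogicalVector cpp_surface_mask(IntegerVector dims, NumericVector center,
                               double radius) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  LogicalVector out((R_xlen_t)nx * ny * nz, false);
  const double cx = center[0], cy = center[1], cz = center[2];
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        const double d = std::sqrt((i - cx) * (i - cx) + (j - cy) * (j - cy) +
                                   (k - cz) * (k - cz));
        if (std::fabs(d - radius) < 0.5)
          out[vidx(i, j, k, nx, ny)] = true;
      }
  return out;
}

// ---- exact Euclidean distance transform (Felzenszwalb & Huttenlocher) ----

static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n,
                 std::vector<int>& v, std::vector<double>& z) {
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s = ((f[q] + q * q) - (f[v[k]] + v[k] * v[k])) / (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      --k;
      s = ((f[q] + q * q) - (f[v[k]] + v[k] * v[k])) / (2.0 * q - 2.0 * v[k]);
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    d[q] = (q - v[k]) * (q - v[k]) + f[v[k]];
  }
}

// Squared Euclidean distance from each foreground voxel to the nearest
// background voxel. Background voxels get 0. Volume boundary is not treated
// as background.
// [[Rcpp::export]]
NumericVector cpp_edt3d(LogicalVector fg, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (n != fg.size()) stop("mask does not match dims");
  const double INF = 1e18;
  NumericVector d(n);
  for (R_xlen_t t = 0; t < n; ++t) d[t] = fg[t] ? INF : 0.0;
  const int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), g(nmax), z(nmax + 1);
  std::vector<int> v(nmax);
  // x pass
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i) f[i] = d[vidx(i, j, k, nx, ny)];
      dt1d(f, g, nx, v, z);
      for (int i = 0; i < nx; ++i) d[vidx(i, j, k, nx, ny)] = g[i];
    }
  // y pass
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      for (int j = 0; j < ny; ++j) f[j] = d[vidx(i, j, k, nx, ny)];
      dt1d(f, g, ny, v, z);
      for (int j = 0; j < ny; ++j) d[vidx(i, j, k, nx, ny)] = g[j];
    }
  // z pass
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      for (int k = 0; k < nz; ++k) f[k] = d[vidx(i, j, k, nx, ny)];
      dt1d(f, g, nz, v, z);
      for (int k = 0; k < nz; ++k) d[vidx(i, j, k, nx, ny)] = g[k];
    }
  return d;
}

// Separable Gaussian smoothing with reflective boundaries.
// [[Rcpp::export]]
NumericVector cpp_gauss3d(NumericVector volume, IntegerVector dims,
                          double sigma) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (n != volume.size()) stop("volume does not match dims");
  if (sigma <= 0) return clone(volume);
  const int r = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> kern(2 * r + 1);
  double ksum = 0;
  for (int t = -r; t <= r; ++t) {
    kern[t + r] = std::exp(-0.5 * t * t / (sigma * sigma));
    ksum += kern[t + r];
  }
  for (double& w : kern) w /= ksum;
  NumericVector a = clone(volume), b(n);
  auto reflect = [](int p, int len) {
    while (p < 0 || p >= len) {
      if (p < 0) p = -p - 1;
      if (p >= len) p = 2 * len - p - 1;
    }
    return p;
  };
  // x
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        double s = 0;
        for (int t = -r; t <= r; ++t)
          s += kern[t + r] * a[vidx(reflect(i + t, nx), j, k, nx, ny)];
        b[vidx(i, j, k, nx, ny)] = s;
      }
  // y
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        double s = 0;
        for (int t = -r; t <= r; ++t)
          s += kern[t + r] * b[vidx(i, reflect(j + t, ny), k, nx, ny)];
        a[vidx(i, j, k, nx, ny)] = s;
      }
  // z
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        double s = 0;
        for (int t = -r; t <= r; ++t)
          s += kern[t + r] * a[vidx(i, j, reflect(k + t, nz), nx, ny)];
        b[vidx(i, j, k, nx, ny)] = s;
      }
  return b;
}

// Local maxima of `volume` restricted to `mask` (26-connectivity, >= all
// neighbours), with greedy suppression: candidates are visited in decreasing
// value (ties broken by linear voxel order) and kept if farther than min_sep
// from every already kept seed. Returns a matrix of 0-based (x,y,z) coords.
// [[Rcpp::export]]
NumericMatrix cpp_local_maxima(NumericVector volume, IntegerVector dims,
                               LogicalVector mask, double min_sep) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  std::vector<R_xlen_t> cand;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        const R_xlen_t id = vidx(i, j, k, nx, ny);
        if (!mask[id]) continue;
        const double v = volume[id];
        bool ismax = true;
        for (int dk = -1; dk <= 1 && ismax; ++dk)
          for (int dj = -1; dj <= 1 && ismax; ++dj)
            for (int di = -1; di <= 1 && ismax; ++di) {
              if (!di && !dj && !dk) continue;
              const int ii = i + di, jj = j + dj, kk = k + dk;
              if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
                continue;
              if (volume[vidx(ii, jj, kk, nx, ny)] > v) ismax = false;
            }
        if (ismax) cand.push_back(id);
      }
  std::stable_sort(cand.begin(), cand.end(), [&](R_xlen_t a, R_xlen_t b) {
    if (volume[a] != volume[b]) return volume[a] > volume[b];
    return a < b;
  });
  const double sep2 = min_sep * min_sep;
  std::vector<double> sx, sy, sz;
  for (R_xlen_t id : cand) {
    const int i = (int)(id % nx);
    const int j = (int)((id / nx) % ny);
    const int k = (int)(id / ((R_xlen_t)nx * ny));
    bool keep = true;
    for (size_t s = 0; s < sx.size(); ++s) {
      const double dd = (i - sx[s]) * (i - sx[s]) + (j - sy[s]) * (j - sy[s]) +
                        (k - sz[s]) * (k - sz[s]);
      if (dd <= sep2) { keep = false; break; }
    }
    if (keep) { sx.push_back(i); sy.push_back(j); sz.push_back(k); }
  }
  NumericMatrix out(sx.size(), 3);
  for (size_t s = 0; s < sx.size(); ++s) {
    out(s, 0) = sx[s]; out(s, 1) = sy[s]; out(s, 2) = sz[s];
  }
  return out;
}

// Assign each masked voxel the label of its nearest seed (1..nseeds).
// [[Rcpp::export]]
IntegerVector cpp_nearest_seed_label(LogicalVector mask, IntegerVector dims,
                                     NumericMatrix seeds) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  IntegerVector out((R_xlen_t)nx * ny * nz);
  const int ns = seeds.nrow();
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        const R_xlen_t id = vidx(i, j, k, nx, ny);
        if (!mask[id] || ns == 0) { out[id] = 0; continue; }
        int best = 1;
        double bestd = std::numeric_limits<double>::infinity();
        for (int s = 0; s < ns; ++s) {
          const double dd = (i - seeds(s, 0)) * (i - seeds(s, 0)) +
                            (j - seeds(s, 1)) * (j - seeds(s, 1)) +
                            (k - seeds(s, 2)) * (k - seeds(s, 2));
          if (dd < bestd) { bestd = dd; best = s + 1; }
        }
        out[id] = best;
      }
  return out;
}
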