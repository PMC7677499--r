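// Voxel kernels for the solvent-probe rain algorithm.
//
// Grids are flat vectors in column-major (i fastest) order:
//   idx = i + nx * (j + ny * k),  0-based in C++, 1-based when returned to R.
// Grid point (i,j,k) sits at origin + a * (i,j,k) in Angstrom.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline R_xlen_t idx3(int i, int j, int k, int nx, int ny) {
  return (R_xlen_t)i + (R_xlen_t)nx * ((R_xlen_t)j + (R_xlen_t)ny * (R_xlen_t)k);
}

// Mark grid points lying within (vdw[t] + extra) of any sphere center.
// strict = true uses d < R (overlap), strict = false uses d <= R (contact).
// [[Rcpp::export]]
LogicalVector cpp_overlap_mask(NumericMatrix coords, NumericVector vdw, double extra,
                               NumericVector origin, double a, IntegerVector dims,
                               bool strict) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  LogicalVector mask((R_xlen_t)nx * ny * nz);
  const double ox = origin[0], oy = origin[1], oz = origin[2];
  for (int t = 0; t < coords.nrow(); ++t) {
    const double R = vdw[t] + extra;
    if (R <= 0) continue;
    const double R2 = R * R;
    const double cx = coords(t, 0), cy = coords(t, 1), cz = coords(t, 2);
    int i0 = (int)std::floor((cx - R - ox) / a) - 1, i1 = (int)std::ceil((cx + R - ox) / a) + 1;
    int j0 = (int)std::floor((cy - R - oy) / a) - 1, j1 = (int)std::ceil((cy + R - oy) / a) + 1;
    int k0 = (int)std::floor((cz - R - oz) / a) - 1, k1 = (int)std::ceil((cz + R - oz) / a) + 1;
    if (i0 < 0) i0 = 0; if (i1 > nx - 1) i1 = nx - 1;
    if (j0 < 0) j0 = 0; if (j1 > ny - 1) j1 = ny - 1;
    if (k0 < 0) k0 = 0; if (k1 > nz - 1) k1 = nz - 1;
    for (int k = k0; k <= k1; ++k) {
      const double dz = oz + a * k - cz;
      for (int j = j0; j <= j1; ++j) {
        const double dy = oy + a * j - cy;
        const double dyz2 = dy * dy + dz * dz;
        if (dyz2 > R2) continue;
        for (int i = i0; i <= i1; ++i) {
          const double dx = ox + a * i - cx;
          const double d2 = dx * dx + dyz2;
          if (strict ? (d2 < R2) : (d2 <= R2)) mask[idx3(i, j, k, nx, ny)] = true;
        }
      }
    }
  }
  return mask;
}

// Six-wall rain: for every perpendicular grid line, march inward from the wall
// marking points visited until the first probe-blocked point (exclusive).
// [[Rcpp::export]]
LogicalVector cpp_rain(LogicalVector blocked, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  LogicalVector visited((R_xlen_t)nx * ny * nz);
  for (int k = 0; k < nz; ++k) {
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i) {            // +x wall, marching in +i
        R_xlen_t p = idx3(i, j, k, nx, ny);
        if (blocked[p]) break;
        visited[p] = true;
      }
      for (int i = nx - 1; i >= 0; --i) {       // -x wall
        R_xlen_t p = idx3(i, j, k, nx, ny);
        if (blocked[p]) break;
        visited[p] = true;
      }
    }
    for (int i = 0; i < nx; ++i) {
      for (int j = 0; j < ny; ++j) {            // +y wall
        R_xlen_t p = idx3(i, j, k, nx, ny);
        if (blocked[p]) break;
        visited[p] = true;
      }
      for (int j = ny - 1; j >= 0; --j) {       // -y wall
        R_xlen_t p = idx3(i, j, k, nx, ny);
        if (blocked[p]) break;
        visited[p] = true;
      }
    }
  }
  for (int j = 0; j < ny; ++j) {
    for (int i = 0; i < nx; ++i) {
      for (int k = 0; k < nz; ++k) {            // +z wall
        R_xlen_t p = idx3(i, j, k, nx, ny);
        if (blocked[p]) break;
        visited[p] = true;
      }
      for (int k = nz - 1; k >= 0; --k) {       // -z wall
        R_xlen_t p = idx3(i, j, k, nx, ny);
        if (blocked[p]) break;
        visited[p] = true;
      }
    }
  }
  return visited;
}

// Binary dilation by an explicit offset set (stamping from set points).
// offsets: m x 3 integer matrix of (di, dj, dk), excluding or including (0,0,0)
// as the caller chooses.
// [[Rcpp::export]]
LogicalVector cpp_dilate(LogicalVector mask, IntegerVector dims, IntegerMatrix offsets) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  LogicalVector out((R_xlen_t)nx * ny * nz);
  const int m = offsets.nrow();
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        if (!mask[idx3(i, j, k, nx, ny)]) continue;
        for (int t = 0; t < m; ++t) {
          const int ii = i + offsets(t, 0), jj = j + offsets(t, 1), kk = k + offsets(t, 2);
          if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) continue;
          out[idx3(ii, jj, kk, nx, ny)] = true;
        }
      }
  return out;
}

// Connected components of a mask under 6-connectivity (face adjacency).
// Returns labels 1..L in scan-discovery order, 0 outside the mask.
// [[Rcpp::export]]
IntegerVector cpp_label6(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector labels(n);
  int next = 0;
  std::vector<R_xlen_t> stack;
  const int di[6] = {1, -1, 0, 0, 0, 0};
  const int dj[6] = {0, 0, 1, -1, 0, 0};
  const int dk[6] = {0, 0, 0, 0, 1, -1};
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        const R_xlen_t p0 = idx3(i, j, k, nx, ny);
        if (!mask[p0] || labels[p0] != 0) continue;
        ++next;
        labels[p0] = next;
        stack.clear();
        stack.push_back(p0);
        while (!stack.empty()) {
          const R_xlen_t p = stack.back();
          stack.pop_back();
          const int pi = (int)(p % nx), pj = (int)((p / nx) % ny), pk = (int)(p / ((R_xlen_t)nx * ny));
          for (int t = 0; t < 6; ++t) {
            const int ii = pi + di[t], jj = pj + dj[t], kk = pk + dk[t];
            if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) continue;
            const R_xlen_t q = idx3(ii, jj, kk, nx, ny);
            if (mask[q] && labels[q] == 0) {
              labels[q] = next;
              stack.push_back(q);
            }
          }
        }
      }
  return labels;
}

// Assign halo (probe-covered) cavity points to chambers: each halo point takes
// the label, among chamber centers within the offset ball, of the chamber with
// the most center points; ties go to the lower label.
// [[Rcpp::export]]
IntegerVector cpp_halo_assign(LogicalVector halo, IntegerVector labels,
                              IntegerVector sizes, IntegerVector dims,
                              IntegerMatrix offsets) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector out(n);
  const int m = offsets.nrow();
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        const R_xlen_t p = idx3(i, j, k, nx, ny);
        if (!halo[p]) continue;
        int best = 0, best_size = -1;
        for (int t = 0; t < m; ++t) {
          const int ii = i + offsets(t, 0), jj = j + offsets(t, 1), kk = k + offsets(t, 2);
          if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) continue;
          const int lab = labels[idx3(ii, jj, kk, nx, ny)];
          if (lab == 0) continue;
          const int sz = sizes[lab - 1];
          if (sz > best_size || (sz == best_size && lab < best)) {
            best = lab;
            best_size = sz;
          }
        }
        out[p] = best;
      }
  return out;
}

// For every grid point: is at least one of the 6 axis-aligned rays to the box
// wall (the point itself included) free of obstructed points?
// [[Rcpp::export]]
LogicalVector cpp_clear_any_axis(LogicalVector obstructed, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  LogicalVector out(n);
  std::vector<char> run;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      char clear = 1;                            // towards +x wall
      for (int i = nx - 1; i >= 0; --i) {
        const R_xlen_t p = idx3(i, j, k, nx, ny);
        clear = clear && !obstructed[p];
        if (clear) out[p] = true;
      }
      clear = 1;                                 // towards -x wall
      for (int i = 0; i < nx; ++i) {
        const R_xlen_t p = idx3(i, j, k, nx, ny);
        clear = clear && !obstructed[p];
        if (clear) out[p] = true;
      }
    }
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      char clear = 1;                            // towards +y wall
      for (int j = ny - 1; j >= 0; --j) {
        const R_xlen_t p = idx3(i, j, k, nx, ny);
        clear = clear && !obstructed[p];
        if (clear) out[p] = true;
      }
      clear = 1;                                 // towards -y wall
      for (int j = 0; j < ny; ++j) {
        const R_xlen_t p = idx3(i, j, k, nx, ny);
        clear = clear && !obstructed[p];
        if (clear) out[p] = true;
      }
    }
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      char clear = 1;                            // towards +z wall
      for (int k = nz - 1; k >= 0; --k) {
        const R_xlen_t p = idx3(i, j, k, nx, ny);
        clear = clear && !obstructed[p];
        if (clear) out[p] = true;
      }
      clear = 1;                                 // towards -z wall
      for (int k = 0; k < nz; ++k) {
        const R_xlen_t p = idx3(i, j, k, nx, ny);
        clear = clear && !obstructed[p];
        if (clear) out[p] = true;
      }
    }
  return out;
}

// Per-point count of exposed faces: 6-neighbors q of p with !pset[q] && ext[q].
// [[Rcpp::export]]
IntegerVector cpp_boundary_faces(LogicalVector pset, LogicalVector ext, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector faces(n);
  const int di[6] = {1, -1, 0, 0, 0, 0};
  const int dj[6] = {0, 0, 1, -1, 0, 0};
  const int dk[6] = {0, 0, 0, 0, 1, -1};
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        const R_xlen_t p = idx3(i, j, k, nx, ny);
        if (!pset[p]) continue;
        int f = 0;
        for (int t = 0; t < 6; ++t) {
          const int ii = i + di[t], jj = j + dj[t], kk = k + dk[t];
          if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) continue;
          const R_xlen_t q = idx3(ii, jj, kk, nx, ny);
          if (!pset[q] && ext[q]) ++f;
        }
        faces[p] = f;
      }
  return faces;
}

// For each query point, 1-based index of the atom minimizing
// (euclidean distance - vdw radius); ties resolved to the first atom.
// [[Rcpp::export]]
IntegerVector cpp_nearest_atom(NumericMatrix pts, NumericMatrix atoms, NumericVector vdw) {
  const int np = pts.nrow(), na = atoms.nrow();
  IntegerVector out(np);
  for (int p = 0; p < np; ++p) {
    const double px = pts(p, 0), py = pts(p, 1), pz = pts(p, 2);
    double best = R_PosInf;
    int best_t = 0;
    for (int t = 0; t < na; ++t) {
      const double dx = atoms(t, 0) - px, dy = atoms(t, 1) - py, dz = atoms(t, 2) - pz;
      const double d = std::sqrt(dx * dx + dy * dy + dz * dz) - vdw[t];
      if (d < best) {
        best = d;
        best_t = t + 1;
      }
    }
    out[p] = best_t;
  }
  return out;
}
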