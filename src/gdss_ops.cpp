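#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Lattice kernels for 3D statistical maps: separable Gaussian smoothing,
// connected-component labeling, the TFCE transform, and ICM refinement of a
// binary MRF labeling.  All arrays are column-major with dims (nx, ny, nz);
// a 4D stack appends the subject dimension last.

static inline int idx3(int x, int y, int z, int nx, int ny) {
  return x + nx * (y + ny * z);
}

// Build the neighbor offset table for 6/18/26-connectivity.
static void neighbor_offsets(int conn, std::vector<int>& dx,
                             std::vector<int>& dy, std::vector<int>& dz) {
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b)
      for (int c = -1; c <= 1; ++c) {
        int nz = std::abs(a) + std::abs(b) + std::abs(c);
        if (nz == 0) continue;
        if (conn == 6 && nz > 1) continue;
        if (conn == 18 && nz > 2) continue;
        dx.push_back(a); dy.push_back(b); dz.push_back(c);
      }
}

// ---------------------------------------------------------------------------
// Separable Gaussian convolution, zero padding outside the grid, kernel
// truncated at 4*sigma and renormalized to unit sum.  Smooths `nvol`
// consecutive 3D volumes of `vol` IN PLACE (callers must own the array).
// [[Rcpp::export(name = ".smooth_stack_inplace")]]
NumericVector smooth_stack_inplace(NumericVector vol, IntegerVector dims,
                                   int nvol, double fwhm) {
  if (fwhm <= 0) stop("fwhm must be positive");
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t vsize = (R_xlen_t)nx * ny * nz;
  const double sigma = fwhm / std::sqrt(8.0 * std::log(2.0));
  const int radius = (int)std::ceil(4.0 * sigma);
  std::vector<double> w(2 * radius + 1);
  double s = 0.0;
  for (int i = -radius; i <= radius; ++i) {
    w[i + radius] = std::exp(-0.5 * (double)i * i / (sigma * sigma));
    s += w[i + radius];
  }
  for (double& wi : w) wi /= s;

  const int maxdim = std::max(nx, std::max(ny, nz));
  std::vector<double> line(maxdim);
  double* v = REAL(vol);

  for (int sub = 0; sub < nvol; ++sub) {
    double* base = v + (R_xlen_t)sub * vsize;
    // axis 0 (x): stride 1
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y) {
        double* p = base + idx3(0, y, z, nx, ny);
        for (int x = 0; x < nx; ++x) {
          double acc = 0.0;
          int lo = std::max(0, x - radius), hi = std::min(nx - 1, x + radius);
          for (int k = lo; k <= hi; ++k) acc += p[k] * w[k - x + radius];
          line[x] = acc;
        }
        for (int x = 0; x < nx; ++x) p[x] = line[x];
      }
    // axis 1 (y): stride nx
    for (int z = 0; z < nz; ++z)
      for (int x = 0; x < nx; ++x) {
        double* p = base + idx3(x, 0, z, nx, ny);
        for (int y = 0; y < ny; ++y) {
          double acc = 0.0;
          int lo = std::max(0, y - radius), hi = std::min(ny - 1, y + radius);
          for (int k = lo; k <= hi; ++k) acc += p[(R_xlen_t)k * nx] * w[k - y + radius];
          line[y] = acc;
        }
        for (int y = 0; y < ny; ++y) p[(R_xlen_t)y * nx] = line[y];
      }
    // axis 2 (z): stride nx*ny
    const R_xlen_t sz = (R_xlen_t)nx * ny;
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        double* p = base + idx3(x, y, 0, nx, ny);
        for (int z = 0; z < nz; ++z) {
          double acc = 0.0;
          int lo = std::max(0, z - radius), hi = std::min(nz - 1, z + radius);
          for (int k = lo; k <= hi; ++k) acc += p[(R_xlen_t)k * sz] * w[k - z + radius];
          line[z] = acc;
        }
        for (int z = 0; z < nz; ++z) p[(R_xlen_t)z * sz] = line[z];
      }
  }
  return vol;
}

// ---------------------------------------------------------------------------
// Connected components of the excursion set {v > threshold}.  Voxels outside
// the excursion set get label 0; components are labeled 1..K in scan order.
// [[Rcpp::export(name = ".cc_label")]]
IntegerVector cc_label(NumericVector vol, IntegerVector dims,
                       double threshold, int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (vol.size() != n) stop("volume size does not match dims");
  std::vector<int> dx, dy, dz;
  neighbor_offsets(connectivity, dx, dy, dz);
  const int nb = (int)dx.size();

  IntegerVector labels(n, 0);
  const double* v = REAL(vol);
  int* lab = INTEGER(labels);
  std::vector<int> stack;
  int next = 0;

  for (int z0 = 0; z0 < nz; ++z0)
    for (int y0 = 0; y0 < ny; ++y0)
      for (int x0 = 0; x0 < nx; ++x0) {
        int i0 = idx3(x0, y0, z0, nx, ny);
        if (lab[i0] != 0 || !(v[i0] > threshold)) continue;
        lab[i0] = ++next;
        stack.clear();
        stack.push_back(i0);
        while (!stack.empty()) {
          int i = stack.back(); stack.pop_back();
          int x = i % nx, rem = i / nx, y = rem % ny, zz = rem / ny;
          for (int k = 0; k < nb; ++k) {
            int xn = x + dx[k], yn = y + dy[k], zn = zz + dz[k];
            if (xn < 0 || xn >= nx || yn < 0 || yn >= ny || zn < 0 || zn >= nz)
              continue;
            int j = idx3(xn, yn, zn, nx, ny);
            if (lab[j] == 0 && v[j] > threshold) {
              lab[j] = next;
              stack.push_back(j);
            }
          }
        }
      }
  labels.attr("n_clusters") = next;
  return labels;
}

// ---------------------------------------------------------------------------
// TFCE transform: per voxel, sum over thresholds h = dh, 2dh, ... <= value of
// extent(cluster at h)^E * h^H * dh.  Negative values contribute nothing.
// Implemented by descending through the threshold ladder with an incremental
// union-find, accumulating the extent term for every active voxel per rung.

struct UnionFind {
  std::vector<int> parent, size;
  void init(int n) {
    parent.assign(n, -1);
    size.assign(n, 0);
  }
  int find(int i) {
    int r = i;
    while (parent[r] != r) r = parent[r];
    while (parent[i] != r) { int nxt = parent[i]; parent[i] = r; i = nxt; }
    return r;
  }
  void link(int a, int b) {
    a = find(a); b = find(b);
    if (a == b) return;
    if (size[a] < size[b]) std::swap(a, b);
    parent[b] = a;
    size[a] += size[b];
  }
};

// [[Rcpp::export(name = ".tfce_transform")]]
NumericVector tfce_transform_cpp(NumericVector vol, IntegerVector dims,
                                 double E, double H, double dh,
                                 int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (vol.size() != n) stop("volume size does not match dims");
  if (dh <= 0) stop("dh must be positive");
  std::vector<int> dx, dy, dz;
  neighbor_offsets(connectivity, dx, dy, dz);
  const int nb = (int)dx.size();

  NumericVector out(n, 0.0);
  const double* v = REAL(vol);
  double* o = REAL(out);

  double vmax = 0.0;
  std::vector<int> pos;
  pos.reserve(1024);
  for (R_xlen_t i = 0; i < n; ++i)
    if (v[i] > 0) { pos.push_back((int)i); if (v[i] > vmax) vmax = v[i]; }
  if (pos.empty() || vmax < dh) return out;

  // sort positive voxels by value, descending
  std::sort(pos.begin(), pos.end(),
            [&](int a, int b) { return v[a] > v[b]; });

  UnionFind uf;
  uf.init((int)n);
  std::vector<char> active(n, 0);
  std::vector<int> act;          // activation order (for per-rung accumulation)
  act.reserve(pos.size());
  // per-root extent^E cache, invalidated per rung via an epoch stamp
  std::vector<double> pow_cache(n, 0.0);
  std::vector<int> pow_epoch(n, -1);

  const int nsteps = (int)std::floor(vmax / dh);
  size_t next_add = 0;
  for (int stp = nsteps; stp >= 1; --stp) {
    const double h = stp * dh;
    while (next_add < pos.size() && v[pos[next_add]] >= h) {
      int i = pos[next_add++];
      uf.parent[i] = i;
      uf.size[i] = 1;
      active[i] = 1;
      act.push_back(i);
      int x = i % nx, rem = i / nx, y = rem % ny, zz = rem / ny;
      for (int k = 0; k < nb; ++k) {
        int xn = x + dx[k], yn = y + dy[k], zn = zz + dz[k];
        if (xn < 0 || xn >= nx || yn < 0 || yn >= ny || zn < 0 || zn >= nz)
          continue;
        int j = idx3(xn, yn, zn, nx, ny);
        if (active[j]) uf.link(i, j);
      }
    }
    const double hterm = std::pow(h, H) * dh;
    // accumulate extent^E * h^H * dh for every active voxel
    for (int i : act) {
      int r = uf.find(i);
      if (pow_epoch[r] != stp) {
        pow_cache[r] = std::pow((double)uf.size[r], E) * hterm;
        pow_epoch[r] = stp;
      }
      o[i] += pow_cache[r];
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// ICM refinement of a binary labeling under a Gaussian bin likelihood and a
// Potts prior over the 10-voxel neighborhood (8 in-slice neighbors plus the
// co-located voxel in each adjacent slice).  labels: 0 = null, 1 = rejected.
// mu, sd: nbins x 2 matrices (column 1 = null group, column 2 = rejected).
// bin: 1-based histogram bin per voxel (0 outside mask).

static inline double lik_energy(double y, double mu, double sd) {
  double zr = (y - mu) / sd;
  return 0.5 * zr * zr + 0.5 * std::log(2.0 * M_PI * sd * sd);
}

// [[Rcpp::export(name = ".icm_refine")]]
List icm_refine(IntegerVector labels, NumericVector y, IntegerVector bin,
                LogicalVector mask, IntegerVector dims,
                NumericMatrix mu, NumericMatrix sd, IntegerMatrix empty,
                double gamma, int max_sweeps) {
  // labels may never move into a group that was empty at initialization:
  // an empty group has no observed p-values to support its likelihood
  const double EMPTY_PENALTY = 1e12;
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (labels.size() != n) stop("labels size does not match dims");
  IntegerVector lab = clone(labels);
  int* L = INTEGER(lab);
  const double* Y = REAL(y);
  const int* B = INTEGER(bin);
  const int* M = LOGICAL(mask);

  // 10-neighborhood offsets: 8 in-slice + co-located voxel in adjacent slices
  std::vector<int> dx, dy, dz;
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b) {
      if (a == 0 && b == 0) continue;
      dx.push_back(a); dy.push_back(b); dz.push_back(0);
    }
  dx.push_back(0); dy.push_back(0); dz.push_back(-1);
  dx.push_back(0); dy.push_back(0); dz.push_back(1);
  const int nb = (int)dx.size();

  std::vector<double> energy_trace;
  int sweeps = 0;

  // total posterior energy: sum of voxel likelihood terms + gamma per
  // disagreeing neighbor pair (each pair counted once)
  auto total_energy = [&]() {
    double e = 0.0;
    for (int z = 0; z < nz; ++z)
      for (int yy = 0; yy < ny; ++yy)
        for (int x = 0; x < nx; ++x) {
          int i = idx3(x, yy, z, nx, ny);
          if (!M[i]) continue;
          int b0 = B[i] - 1, l0 = L[i];
          e += lik_energy(Y[i], mu(b0, l0), sd(b0, l0));
          if (empty(b0, l0)) e += EMPTY_PENALTY;
          for (int k = 0; k < nb; ++k) {
            // count each clique once: only "forward" offsets
            if (dz[k] < 0) continue;
            if (dz[k] == 0 && (dy[k] < 0 || (dy[k] == 0 && dx[k] < 0))) continue;
            int xn = x + dx[k], yn = yy + dy[k], zn = z + dz[k];
            if (xn < 0 || xn >= nx || yn < 0 || yn >= ny || zn < 0 || zn >= nz)
              continue;
            int j = idx3(xn, yn, zn, nx, ny);
            if (M[j] && L[j] != l0) e += gamma;
          }
        }
    return e;
  };

  energy_trace.push_back(total_energy());
  for (int sweep = 0; sweep < max_sweeps; ++sweep) {
    R_xlen_t flips = 0;
    for (int z = 0; z < nz; ++z)
      for (int yy = 0; yy < ny; ++yy)
        for (int x = 0; x < nx; ++x) {
          int i = idx3(x, yy, z, nx, ny);
          if (!M[i]) continue;
          int b0 = B[i] - 1;
          int nrej = 0, ntot = 0;
          for (int k = 0; k < nb; ++k) {
            int xn = x + dx[k], yn = yy + dy[k], zn = z + dz[k];
            if (xn < 0 || xn >= nx || yn < 0 || yn >= ny || zn < 0 || zn >= nz)
              continue;
            int j = idx3(xn, yn, zn, nx, ny);
            if (M[j]) { ++ntot; nrej += (L[j] == 1); }
          }
          double e0 = lik_energy(Y[i], mu(b0, 0), sd(b0, 0)) + gamma * nrej +
                      (empty(b0, 0) ? EMPTY_PENALTY : 0.0);
          double e1 = lik_energy(Y[i], mu(b0, 1), sd(b0, 1)) +
                      gamma * (ntot - nrej) +
                      (empty(b0, 1) ? EMPTY_PENALTY : 0.0);
          int newl = (e1 < e0) ? 1 : (e0 < e1 ? 0 : L[i]);  // keep on tie
          if (newl != L[i]) { L[i] = newl; ++flips; }
        }
    ++sweeps;
    energy_trace.push_back(total_energy());
    if (flips == 0) break;
  }

  return List::create(_["labels"] = lab, _["sweeps"] = sweeps,
                      _["energy"] = NumericVector(energy_trace.begin(),
                                                  energy_trace.end()));
}
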