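// Compute kernels for the phase-contrast CT pipeline: parallel-beam
// projection / backprojection, 3D Euclidean distance transform,
// 26-connected labeling, morphology, separable convolution and
// marching-tetrahedra surface area. All arrays are column-major with
// dim = c(nx, ny, nz); voxel (i,j,k) sits at i + nx*(j + ny*k).
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
#include <limits>
using namespace Rcpp;

static inline double bilin(const double* s, int nx, int ny, double x, double y) {
  if (x <= -1.0 || y <= -1.0 || x >= (double)nx || y >= (double)ny) return 0.0;
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y);
  double fx = x - x0, fy = y - y0;
  double v00 = 0, v10 = 0, v01 = 0, v11 = 0;
  bool x0in = x0 >= 0 && x0 < nx, x1in = x0 + 1 >= 0 && x0 + 1 < nx;
  bool y0in = y0 >= 0 && y0 < ny, y1in = y0 + 1 >= 0 && y0 + 1 < ny;
  if (x0in && y0in) v00 = s[x0 + nx * y0];
  if (x1in && y0in) v10 = s[x0 + 1 + nx * y0];
  if (x0in && y1in) v01 = s[x0 + nx * (y0 + 1)];
  if (x1in && y1in) v11 = s[x0 + 1 + nx * (y0 + 1)];
  return v00 * (1 - fx) * (1 - fy) + v10 * fx * (1 - fy) +
         v01 * (1 - fx) * fy + v11 * fx * fy;
}

// Parallel-beam line integrals of a volume, rotation about the z axis,
// rotation centre ((nx-1)/2, (ny-1)/2). Detector columns map to the
// rotated x' axis (one column per x voxel), detector rows to z slices.
// Returns [nx x nz x nAngles] in voxel-length units (multiply by the
// voxel size upstream for physical path lengths).
// [[Rcpp::export]]
NumericVector cpp_forward_project(NumericVector vol, IntegerVector dims,
                                  NumericVector angles_rad) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int na = angles_rad.size();
  NumericVector out(Dimension(nx, nz, na));
  const double cx = (nx - 1) / 2.0, cy = (ny - 1) / 2.0;
  const double* v = REAL(vol);
  double* o = REAL(out);
  for (int a = 0; a < na; ++a) {
    const double c = std::cos(angles_rad[a]), s = std::sin(angles_rad[a]);
    for (int k = 0; k < nz; ++k) {
      const double* slice = v + (R_xlen_t)nx * ny * k;
      double* orow = o + (R_xlen_t)nx * (k + (R_xlen_t)nz * a);
      for (int t = 0; t < nx; ++t) {
        const double tp = t - cx;
        double acc = 0.0;
        for (int sy = 0; sy < ny; ++sy) {
          const double sp = sy - cy;
          acc += bilin(slice, nx, ny, cx + tp * c - sp * s, cy + tp * s + sp * c);
        }
        orow[t] += acc;
      }
    }
  }
  return out;
}

// Backprojection of filtered projections for one slice.
// filt: [ncol x nAngles]; output N x N with rotation centre (N-1)/2
// aligned to detector column (ncol-1)/2. Caller applies pi/nAngles.
// [[Rcpp::export]]
NumericMatrix cpp_back_project(NumericMatrix filt, NumericVector angles_rad, int N) {
  const int ncol = filt.nrow(), na = filt.ncol();
  NumericMatrix out(N, N);
  const double c0 = (N - 1) / 2.0, d0 = (ncol - 1) / 2.0;
  for (int a = 0; a < na; ++a) {
    const double c = std::cos(angles_rad[a]), s = std::sin(angles_rad[a]);
    const double* p = &filt(0, a);
    for (int y = 0; y < N; ++y) {
      const double ys = (y - c0) * s + d0;
      for (int x = 0; x < N; ++x) {
        const double t = (x - c0) * c + ys;
        if (t < 0 || t > ncol - 1) continue;
        int t0 = (int)std::floor(t);
        if (t0 == ncol - 1) t0--;
        const double f = t - t0;
        out(x, y) += p[t0] * (1 - f) + p[t0 + 1] * f;
      }
    }
  }
  return out;
}

// ---- 3D squared Euclidean distance transform (Felzenszwalb-Huttenlocher) ----
static void dt1d(std::vector<double>& f, std::vector<double>& d, int n) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0; z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double sq;
    while (true) {
      sq = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
           (2.0 * q - 2.0 * v[k]);
      if (sq <= z[k]) { --k; } else break;
    }
    ++k; v[k] = q; z[k] = sq; z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = q - (double)v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// Distance (in voxels) from each foreground voxel to the nearest
// background voxel centre; 0 on background.
// [[Rcpp::export]]
NumericVector cpp_edt3d(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  const double INF = 1e20;
  const int* m = LOGICAL(mask);
  double* g = REAL(out);
  for (R_xlen_t i = 0; i < n; ++i) g[i] = m[i] ? INF : 0.0;
  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax);
  // along x
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      double* row = g + (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
      for (int i = 0; i < nx; ++i) f[i] = row[i];
      dt1d(f, d, nx);
      for (int i = 0; i < nx; ++i) row[i] = d[i];
    }
  // along y
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      double* base = g + i + (R_xlen_t)nx * ny * k;
      for (int j = 0; j < ny; ++j) f[j] = base[(R_xlen_t)nx * j];
      dt1d(f, d, ny);
      for (int j = 0; j < ny; ++j) base[(R_xlen_t)nx * j] = d[j];
    }
  // along z
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      double* base = g + i + (R_xlen_t)nx * j;
      for (int k = 0; k < nz; ++k) f[k] = base[(R_xlen_t)nx * ny * k];
      dt1d(f, d, nz);
      for (int k = 0; k < nz; ++k) base[(R_xlen_t)nx * ny * k] = d[k];
    }
  for (R_xlen_t i = 0; i < n; ++i) g[i] = std::sqrt(g[i]);
  return out;
}

// 26-connected component labeling, labels 1..K in scan order.
// [[Rcpp::export]]
IntegerVector cpp_label26(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n);
  const int* m = LOGICAL(mask);
  int* L = INTEGER(lab);
  for (R_xlen_t i = 0; i < n; ++i) L[i] = 0;
  std::vector<R_xlen_t> stack;
  int cur = 0;
  for (R_xlen_t seed = 0; seed < n; ++seed) {
    if (!m[seed] || L[seed]) continue;
    ++cur;
    L[seed] = cur;
    stack.push_back(seed);
    while (!stack.empty()) {
      R_xlen_t p = stack.back(); stack.pop_back();
      int k = p / ((R_xlen_t)nx * ny);
      int r = p - (R_xlen_t)nx * ny * k;
      int j = r / nx, i = r - nx * j;
      for (int dk = -1; dk <= 1; ++dk) {
        int kk = k + dk; if (kk < 0 || kk >= nz) continue;
        for (int dj = -1; dj <= 1; ++dj) {
          int jj = j + dj; if (jj < 0 || jj >= ny) continue;
          for (int di = -1; di <= 1; ++di) {
            int ii = i + di; if (ii < 0 || ii >= nx) continue;
            R_xlen_t q = ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk);
            if (m[q] && !L[q]) { L[q] = cur; stack.push_back(q); }
          }
        }
      }
    }
  }
  return lab;
}

// Fill background cavities not 6-connected to the volume faces.
// [[Rcpp::export]]
LogicalVector cpp_fill_holes(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const int* m = LOGICAL(mask);
  std::vector<char> vis(n, 0);
  std::vector<R_xlen_t> stack;
  auto idx = [&](int i, int j, int k) { return i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k); };
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        if (i && j && k && i < nx - 1 && j < ny - 1 && k < nz - 1) continue;
        R_xlen_t p = idx(i, j, k);
        if (!m[p] && !vis[p]) { vis[p] = 1; stack.push_back(p); }
      }
  const int di[6] = {1, -1, 0, 0, 0, 0};
  const int dj[6] = {0, 0, 1, -1, 0, 0};
  const int dk[6] = {0, 0, 0, 0, 1, -1};
  while (!stack.empty()) {
    R_xlen_t p = stack.back(); stack.pop_back();
    int k = p / ((R_xlen_t)nx * ny);
    int r = p - (R_xlen_t)nx * ny * k;
    int j = r / nx, i = r - nx * j;
    for (int d = 0; d < 6; ++d) {
      int ii = i + di[d], jj = j + dj[d], kk = k + dk[d];
      if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) continue;
      R_xlen_t q = idx(ii, jj, kk);
      if (!m[q] && !vis[q]) { vis[q] = 1; stack.push_back(q); }
    }
  }
  LogicalVector out(n);
  int* o = LOGICAL(out);
  for (R_xlen_t p = 0; p < n; ++p) o[p] = m[p] || !vis[p];
  return out;
}

// Box 3^3 dilation (op=1) or erosion (op=0); separable min/max.
static void minmax_axis(std::vector<char>& a, int nx, int ny, int nz,
                        int axis, bool takeMax) {
  std::vector<char> b(a.size());
  auto idx = [&](int i, int j, int k) { return i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k); };
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        char v = a[idx(i, j, k)];
        int im = axis == 0 ? i - 1 : i, ip = axis == 0 ? i + 1 : i;
        int jm = axis == 1 ? j - 1 : j, jp = axis == 1 ? j + 1 : j;
        int km = axis == 2 ? k - 1 : k, kp = axis == 2 ? k + 1 : k;
        char vm = (im >= 0 && jm >= 0 && km >= 0) ? a[idx(im, jm, km)] : (takeMax ? 0 : 1);
        char vp = (ip < nx && jp < ny && kp < nz) ? a[idx(ip, jp, kp)] : (takeMax ? 0 : 1);
        b[idx(i, j, k)] = takeMax ? std::max(v, std::max(vm, vp))
                                  : std::min(v, std::min(vm, vp));
      }
  a.swap(b);
}

// [[Rcpp::export]]
LogicalVector cpp_morph_box3(LogicalVector mask, IntegerVector dims, bool dilate) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<char> a(n);
  const int* m = LOGICAL(mask);
  for (R_xlen_t i = 0; i < n; ++i) a[i] = (char)(m[i] != 0);
  for (int ax = 0; ax < 3; ++ax) minmax_axis(a, nx, ny, nz, ax, dilate);
  LogicalVector out(n);
  int* o = LOGICAL(out);
  for (R_xlen_t i = 0; i < n; ++i) o[i] = a[i];
  return out;
}

// 3^3 median filter with replicated borders.
// [[Rcpp::export]]
NumericVector cpp_median3(NumericVector vol, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector out(Dimension(nx, ny, nz));
  const double* v = REAL(vol);
  double* o = REAL(out);
  double buf[27];
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        int c = 0;
        for (int dk = -1; dk <= 1; ++dk) {
          int kk = std::min(std::max(k + dk, 0), nz - 1);
          for (int dj = -1; dj <= 1; ++dj) {
            int jj = std::min(std::max(j + dj, 0), ny - 1);
            for (int di = -1; di <= 1; ++di) {
              int ii = std::min(std::max(i + di, 0), nx - 1);
              buf[c++] = v[ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk)];
            }
          }
        }
        std::nth_element(buf, buf + 13, buf + 27);
        o[i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)] = buf[13];
      }
  return out;
}

// 1D convolution along one axis with reflected borders (kernel odd length).
// [[Rcpp::export]]
NumericVector cpp_convolve_axis(NumericVector vol, IntegerVector dims,
                                NumericVector kernel, int axis) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int kl = kernel.size(), h = kl / 2;
  NumericVector out(Dimension(nx, ny, nz));
  const double* v = REAL(vol);
  const double* K = REAL(kernel);
  double* o = REAL(out);
  const int len = axis == 0 ? nx : (axis == 1 ? ny : nz);
  auto refl = [&](int p) {
    while (p < 0 || p >= len) { if (p < 0) p = -p - 1; if (p >= len) p = 2 * len - p - 1; }
    return p;
  };
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        double acc = 0;
        for (int t = 0; t < kl; ++t) {
          int off = t - h;
          int ii = i, jj = j, kk = k;
          if (axis == 0) ii = refl(i + off);
          else if (axis == 1) jj = refl(j + off);
          else kk = refl(k + off);
          acc += K[t] * v[ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk)];
        }
        o[i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)] = acc;
      }
  return out;
}

// ---- marching tetrahedra surface area ----
static const int TETS[6][4] = {
  {0, 5, 1, 6}, {0, 1, 2, 6}, {0, 2, 3, 6},
  {0, 3, 7, 6}, {0, 7, 4, 6}, {0, 4, 5, 6}};
// cube corner offsets (x,y,z) for corners 0..7
static const int CO[8][3] = {
  {0, 0, 0}, {1, 0, 0}, {1, 1, 0}, {0, 1, 0},
  {0, 0, 1}, {1, 0, 1}, {1, 1, 1}, {0, 1, 1}};

static inline void interp(const double* P, const double* Q, double vp, double vq,
                          double level, double* out) {
  double t = (level - vp) / (vq - vp);
  for (int d = 0; d < 3; ++d) out[d] = P[d] + t * (Q[d] - P[d]);
}
static inline double triArea(const double* a, const double* b, const double* c) {
  double u[3], v[3], w[3];
  for (int d = 0; d < 3; ++d) { u[d] = b[d] - a[d]; v[d] = c[d] - a[d]; }
  w[0] = u[1] * v[2] - u[2] * v[1];
  w[1] = u[2] * v[0] - u[0] * v[2];
  w[2] = u[0] * v[1] - u[1] * v[0];
  return 0.5 * std::sqrt(w[0] * w[0] + w[1] * w[1] + w[2] * w[2]);
}

// Total area of the `level` isosurface of a scalar field, in units of
// spacing^2 (spacing = voxel edge length applied isotropically).
// [[Rcpp::export]]
double cpp_surface_area(NumericVector vol, IntegerVector dims,
                        double level, double spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double* v = REAL(vol);
  double total = 0.0;
  double cp[8][3], cv[8];
  for (int k = 0; k < nz - 1; ++k)
    for (int j = 0; j < ny - 1; ++j)
      for (int i = 0; i < nx - 1; ++i) {
        bool anyAbove = false, anyBelow = false;
        for (int c = 0; c < 8; ++c) {
          int ii = i + CO[c][0], jj = j + CO[c][1], kk = k + CO[c][2];
          cv[c] = v[ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk)];
          cp[c][0] = ii; cp[c][1] = jj; cp[c][2] = kk;
          if (cv[c] > level) anyAbove = true; else anyBelow = true;
        }
        if (!anyAbove || !anyBelow) continue;
        for (int t = 0; t < 6; ++t) {
          const int* T = TETS[t];
          int above[4], nab = 0, below[4], nbe = 0;
          for (int c = 0; c < 4; ++c) {
            if (cv[T[c]] > level) above[nab++] = T[c]; else below[nbe++] = T[c];
          }
          if (nab == 0 || nab == 4) continue;
          double p[4][3];
          if (nab == 1 || nab == 3) {
            int apex = (nab == 1) ? above[0] : below[0];
            int* base = (nab == 1) ? below : above;
            for (int c = 0; c < 3; ++c)
              interp(cp[apex], cp[base[c]], cv[apex], cv[base[c]], level, p[c]);
            total += triArea(p[0], p[1], p[2]);
          } else { // 2-2: quad = two triangles
            interp(cp[above[0]], cp[below[0]], cv[above[0]], cv[below[0]], level, p[0]);
            interp(cp[above[0]], cp[below[1]], cv[above[0]], cv[below[1]], level, p[1]);
            interp(cp[above[1]], cp[below[1]], cv[above[1]], cv[below[1]], level, p[2]);
            interp(cp[above[1]], cp[below[0]], cv[above[1]], cv[below[0]], level, p[3]);
            total += triArea(p[0], p[1], p[2]) + triArea(p[0], p[2], p[3]);
          }
        }
      }
  return total * spacing * spacing;
}

// Maximum pairwise Euclidean distance between rows of an N x 3 matrix.
// [[Rcpp::export]]
double cpp_max_pairwise_dist(NumericMatrix pts) {
  const int n = pts.nrow();
  double best = 0.0;
  for (int i = 0; i < n; ++i) {
    const double xi = pts(i, 0), yi = pts(i, 1), zi = pts(i, 2);
    for (int j = i + 1; j < n; ++j) {
      const double dx = pts(j, 0) - xi, dy = pts(j, 1) - yi, dz = pts(j, 2) - zi;
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 > best) best = d2;
    }
  }
  return std::sqrt(best);
}

// Synchronous competitive multi-label growth: each round, every
// unclaimed allowed voxel adjacent (26-conn) to a claimed voxel is
// assigned the smallest neighbouring label; ties are therefore
// deterministic and regions compete instead of engulfing each other.
// [[Rcpp::export]]
IntegerVector cpp_multilabel_grow(IntegerVector labels, LogicalVector allow,
                                  IntegerVector dims, int iterations) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector out = clone(labels);
  int* L = INTEGER(out);
  const int* A = LOGICAL(allow);
  std::vector<R_xlen_t> frontier;
  for (R_xlen_t p = 0; p < n; ++p) if (L[p] > 0) frontier.push_back(p);
  std::vector<R_xlen_t> cand;
  std::vector<int> candLab;
  for (int it = 0; it < iterations && !frontier.empty(); ++it) {
    cand.clear(); candLab.clear();
    for (size_t f = 0; f < frontier.size(); ++f) {
      R_xlen_t p = frontier[f];
      int lab = L[p];
      int k = p / ((R_xlen_t)nx * ny);
      int r = p - (R_xlen_t)nx * ny * k;
      int j = r / nx, i = r - nx * j;
      for (int dk = -1; dk <= 1; ++dk) {
        int kk = k + dk; if (kk < 0 || kk >= nz) continue;
        for (int dj = -1; dj <= 1; ++dj) {
          int jj = j + dj; if (jj < 0 || jj >= ny) continue;
          for (int di = -1; di <= 1; ++di) {
            int ii = i + di; if (ii < 0 || ii >= nx) continue;
            R_xlen_t q = ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk);
            if (L[q] == 0 && A[q]) { cand.push_back(q); candLab.push_back(lab); }
          }
        }
      }
    }
    frontier.clear();
    // assign smallest label per candidate voxel, synchronously
    for (size_t c = 0; c < cand.size(); ++c) {
      R_xlen_t q = cand[c];
      if (L[q] == 0 || L[q] > candLab[c]) {
        if (L[q] == 0) frontier.push_back(q);
        L[q] = candLab[c];
      }
    }
  }
  return out;
}

// Joint projection of two fields (absorption and refraction volumes)
// sharing the interpolation weights; halves the cost of an
// acquisition sweep. Layout as cpp_forward_project.
// [[Rcpp::export]]
List cpp_forward_project2(NumericVector volA, NumericVector volB,
                          IntegerVector dims, NumericVector angles_rad) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int na = angles_rad.size();
  NumericVector outA(Dimension(nx, nz, na)), outB(Dimension(nx, nz, na));
  const double cx = (nx - 1) / 2.0, cy = (ny - 1) / 2.0;
  const double* A = REAL(volA);
  const double* B = REAL(volB);
  double* oA = REAL(outA);
  double* oB = REAL(outB);
  for (int a = 0; a < na; ++a) {
    const double c = std::cos(angles_rad[a]), s = std::sin(angles_rad[a]);
    for (int k = 0; k < nz; ++k) {
      const R_xlen_t off = (R_xlen_t)nx * ny * k;
      double* rA = oA + (R_xlen_t)nx * (k + (R_xlen_t)nz * a);
      double* rB = oB + (R_xlen_t)nx * (k + (R_xlen_t)nz * a);
      for (int t = 0; t < nx; ++t) {
        const double tp = t - cx;
        double accA = 0.0, accB = 0.0;
        for (int sy = 0; sy < ny; ++sy) {
          const double sp = sy - cy;
          const double x = cx + tp * c - sp * s, y = cy + tp * s + sp * c;
          if (x <= -1.0 || y <= -1.0 || x >= (double)nx || y >= (double)ny)
            continue;
          int x0 = (int)std::floor(x), y0 = (int)std::floor(y);
          double fx = x - x0, fy = y - y0;
          bool x0in = x0 >= 0, x1in = x0 + 1 < nx;
          bool y0in = y0 >= 0, y1in = y0 + 1 < ny;
          double w00 = (1 - fx) * (1 - fy), w10 = fx * (1 - fy);
          double w01 = (1 - fx) * fy, w11 = fx * fy;
          R_xlen_t b00 = off + x0 + (R_xlen_t)nx * y0;
          if (x0in && y0in && x0 < nx && y0 < ny) {
            accA += w00 * A[b00]; accB += w00 * B[b00];
          }
          if (x1in && y0in && y0 < ny) {
            accA += w10 * A[b00 + 1]; accB += w10 * B[b00 + 1];
          }
          if (x0in && y1in && x0 < nx) {
            accA += w01 * A[b00 + nx]; accB += w01 * B[b00 + nx];
          }
          if (x1in && y1in) {
            accA += w11 * A[b00 + nx + 1]; accB += w11 * B[b00 + nx + 1];
          }
        }
        rA[t] = accA; rB[t] = accB;
      }
    }
  }
  return List::create(Named("a") = outA, Named("b") = outB);
}
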