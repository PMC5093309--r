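// Low-level 3D voxel kernels: separable Gaussian filtering, connected
// component labelling, anisotropic Euclidean distance transform, and a
// seeded watershed.  Arrays are R numeric/integer/logical 3D arrays in
// column-major order with dims (nx, ny, nz).

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

static inline int reflect_index(int i, int n) {
  // whole-sample symmetric reflection: ... 2 1 0 | 0 1 2 ... n-1 | n-1 n-2 ...
  if (n == 1) return 0;
  int period = 2 * n;
  i = ((i % period) + period) % period;
  return (i < n) ? i : (period - 1 - i);
}

// Convolve along one axis with a symmetric normalized kernel, reflected
// boundary.  axis: 0=x, 1=y, 2=z.  Each line is copied into a
// contiguous buffer with reflected padding so the inner loop is
// cache-friendly regardless of the axis stride.
static void conv_axis(std::vector<double>& src, std::vector<double>& dst,
                      int nx, int ny, int nz,
                      const std::vector<double>& kern, int axis) {
  int half = ((int)kern.size() - 1) / 2;
  int n[3] = {nx, ny, nz};
  int stride[3] = {1, nx, nx * ny};
  int len = n[axis], st = stride[axis];
  int a1 = (axis + 1) % 3, a2 = (axis + 2) % 3;
  std::vector<double> line(len + 2 * half);
  for (int j2 = 0; j2 < n[a2]; ++j2) {
    for (int j1 = 0; j1 < n[a1]; ++j1) {
      size_t base = (size_t)j1 * stride[a1] + (size_t)j2 * stride[a2];
      for (int i = 0; i < len; ++i)
        line[half + i] = src[base + (size_t)i * st];
      for (int k = 0; k < half; ++k) {
        line[half - 1 - k] = line[half + reflect_index(-1 - k, len)];
        line[half + len + k] = line[half + reflect_index(len + k, len)];
      }
      for (int i = 0; i < len; ++i) {
        double acc = 0.0;
        const double* p = &line[i];
        for (int k = 0; k < 2 * half + 1; ++k) acc += kern[k] * p[k];
        dst[base + (size_t)i * st] = acc;
      }
    }
  }
}

static std::vector<double> gauss_kernel(double sigma) {
  if (sigma <= 0) return std::vector<double>(1, 1.0);
  int half = (int)std::ceil(3.5 * sigma);
  if (half < 1) half = 1;
  std::vector<double> k(2 * half + 1);
  double s = 0.0;
  for (int i = -half; i <= half; ++i) {
    k[i + half] = std::exp(-0.5 * (double)i * i / (sigma * sigma));
    s += k[i + half];
  }
  for (auto& v : k) v /= s;
  return k;
}

// [[Rcpp::export(name = ".cpp_gaussian_blur3")]]
NumericVector cpp_gaussian_blur3(NumericVector img, IntegerVector dims,
                                 NumericVector sigma_vox) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  size_t nvox = (size_t)nx * ny * nz;
  std::vector<double> a(img.begin(), img.end()), b(nvox);
  for (int axis = 0; axis < 3; ++axis) {
    double s = sigma_vox[axis];
    if (s <= 0) continue;
    std::vector<double> k = gauss_kernel(s);
    conv_axis(a, b, nx, ny, nz, k, axis);
    std::swap(a, b);
  }
  NumericVector out(a.begin(), a.end());
  out.attr("dim") = dims;
  return out;
}

// 26- or 6-connected component labelling of a logical mask.
// [[Rcpp::export(name = ".cpp_label3")]]
IntegerVector cpp_label3(LogicalVector mask, IntegerVector dims,
                         int connectivity) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  size_t nvox = (size_t)nx * ny * nz;
  IntegerVector lab(nvox, 0);
  lab.attr("dim") = dims;
  std::vector<int> dx, dy, dz;
  for (int c = -1; c <= 1; ++c)
    for (int b = -1; b <= 1; ++b)
      for (int a = -1; a <= 1; ++a) {
        if (a == 0 && b == 0 && c == 0) continue;
        if (connectivity == 6 && (std::abs(a) + std::abs(b) + std::abs(c)) != 1)
          continue;
        dx.push_back(a); dy.push_back(b); dz.push_back(c);
      }
  int nextlab = 0;
  std::vector<size_t> stack;
  for (size_t s = 0; s < nvox; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++nextlab;
    stack.clear();
    stack.push_back(s);
    lab[s] = nextlab;
    while (!stack.empty()) {
      size_t v = stack.back(); stack.pop_back();
      int k = (int)(v / ((size_t)nx * ny));
      int rem = (int)(v % ((size_t)nx * ny));
      int j = rem / nx, i = rem % nx;
      for (size_t q = 0; q < dx.size(); ++q) {
        int ii = i + dx[q], jj = j + dy[q], kk = k + dz[q];
        if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
          continue;
        size_t w = (size_t)ii + (size_t)jj * nx + (size_t)kk * nx * ny;
        if (mask[w] && lab[w] == 0) {
          lab[w] = nextlab;
          stack.push_back(w);
        }
      }
    }
  }
  return lab;
}

// Felzenszwalb-Huttenlocher 1D squared distance transform with sample
// spacing `h` (parabolas at positions i*h).
static void dt1d(std::vector<double>& f, std::vector<double>& d, int n,
                 double h) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  double h2 = h * h;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + h2 * q * q) - (f[v[k]] + h2 * v[k] * v[k])) /
          (2.0 * h2 * (q - v[k]));
      if (s > z[k]) break;
      --k;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = (double)(q - v[k]) * h;
    d[q] = dq * dq + f[v[k]];
  }
}

// Euclidean distance (in physical units) from each true voxel of `mask`
// to the nearest false voxel; 0 outside the mask.  Voxels on a fully
// foreground grid get distance to the grid border + spacing/2.
// [[Rcpp::export(name = ".cpp_edt3")]]
NumericVector cpp_edt3(LogicalVector mask, IntegerVector dims,
                       NumericVector spacing) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  size_t nvox = (size_t)nx * ny * nz;
  const double INF = 1e30;
  std::vector<double> f(nvox);
  for (size_t s = 0; s < nvox; ++s) f[s] = mask[s] ? INF : 0.0;
  int n[3] = {nx, ny, nz};
  int stride[3] = {1, nx, nx * ny};
  for (int axis = 0; axis < 3; ++axis) {
    int len = n[axis], st = stride[axis];
    int a1 = (axis + 1) % 3, a2 = (axis + 2) % 3;
    std::vector<double> line(len), out(len);
    for (int j2 = 0; j2 < n[a2]; ++j2)
      for (int j1 = 0; j1 < n[a1]; ++j1) {
        size_t base = (size_t)j1 * stride[a1] + (size_t)j2 * stride[a2];
        for (int i = 0; i < len; ++i) line[i] = f[base + (size_t)i * st];
        dt1d(line, out, len, spacing[axis]);
        for (int i = 0; i < len; ++i) f[base + (size_t)i * st] = out[i];
      }
  }
  NumericVector res(nvox);
  for (size_t s = 0; s < nvox; ++s)
    res[s] = (f[s] >= INF) ? std::sqrt(1e30) : std::sqrt(f[s]);
  res.attr("dim") = dims;
  return res;
}

struct WsNode {
  double prio;   // lower = flooded earlier (use -distance)
  size_t order;  // FIFO tie-break for determinism
  size_t idx;
};
struct WsCmp {
  bool operator()(const WsNode& a, const WsNode& b) const {
    if (a.prio != b.prio) return a.prio > b.prio;
    return a.order > b.order;
  }
};

// Seeded watershed by priority flooding of `prio` (typically the negated
// distance transform), restricted to `mask`.  `seeds` carries positive
// labels at seed voxels.  Every mask voxel connected (at the given
// connectivity) to a seed receives that basin's label.
// [[Rcpp::export(name = ".cpp_watershed3")]]
IntegerVector cpp_watershed3(NumericVector prio, IntegerVector seeds,
                             LogicalVector mask, IntegerVector dims,
                             int connectivity) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  size_t nvox = (size_t)nx * ny * nz;
  IntegerVector lab(nvox, 0);
  lab.attr("dim") = dims;
  std::priority_queue<WsNode, std::vector<WsNode>, WsCmp> pq;
  size_t order = 0;
  for (size_t s = 0; s < nvox; ++s)
    if (seeds[s] > 0 && mask[s]) {
      lab[s] = seeds[s];
      pq.push({prio[s], order++, s});
    }
  std::vector<int> dx, dy, dz;
  for (int c = -1; c <= 1; ++c)
    for (int b = -1; b <= 1; ++b)
      for (int a = -1; a <= 1; ++a) {
        if (a == 0 && b == 0 && c == 0) continue;
        if (connectivity == 6 && (std::abs(a) + std::abs(b) + std::abs(c)) != 1)
          continue;
        dx.push_back(a); dy.push_back(b); dz.push_back(c);
      }
  int nnb = (int)dx.size();
  while (!pq.empty()) {
    WsNode nd = pq.top(); pq.pop();
    size_t v = nd.idx;
    int k = (int)(v / ((size_t)nx * ny));
    int rem = (int)(v % ((size_t)nx * ny));
    int j = rem / nx, i = rem % nx;
    for (int q = 0; q < nnb; ++q) {
      int ii = i + dx[q], jj = j + dy[q], kk = k + dz[q];
      if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
        continue;
      size_t w = (size_t)ii + (size_t)jj * nx + (size_t)kk * nx * ny;
      if (!mask[w] || lab[w] != 0) continue;
      lab[w] = lab[v];
      pq.push({prio[w], order++, w});
    }
  }
  return lab;
}
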