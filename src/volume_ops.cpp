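#include <Rcpp.h>
#include <vector>
#include <array>
#include <cmath>

using namespace Rcpp;

// half-sample symmetric reflection: -1 -> 0, n -> n-1
static inline int reflect_index(int i, int n) {
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - 1 - i;
  }
  return i;
}

static std::vector<double> gauss_kernel(double sigma) {
  if (sigma <= 0.0) return std::vector<double>(1, 1.0);
  int r = std::max(1, (int)std::ceil(4.0 * sigma));
  std::vector<double> k(2 * r + 1);
  double s = 0.0;
  for (int i = -r; i <= r; ++i) {
    k[i + r] = std::exp(-0.5 * (double)(i * i) / (sigma * sigma));
    s += k[i + r];
  }
  for (size_t i = 0; i < k.size(); ++i) k[i] /= s;
  return k;
}

// convolve along one spatial axis of an nx*ny*nz*nt lattice, reflective boundary
static void smooth_axis(std::vector<double>& x, int nx, int ny, int nz, int nt,
                        int axis, const std::vector<double>& kern) {
  if (kern.size() == 1) return;
  int r = ((int)kern.size() - 1) / 2;
  int n = (axis == 0) ? nx : (axis == 1) ? ny : nz;
  std::vector<double> line(n);
  const long sx = 1, sy = nx, sz = (long)nx * ny, st = (long)nx * ny * nz;
  long stride = (axis == 0) ? sx : (axis == 1) ? sy : sz;

  for (int t = 0; t < nt; ++t) {
    // iterate over all lines orthogonal to axis
    int n1 = (axis == 0) ? ny : nx;
    int n2 = (axis == 2) ? ny : nz;
    for (int b = 0; b < n2; ++b) {
      for (int a = 0; a < n1; ++a) {
        long base;
        if (axis == 0)      base = (long)a * sy + (long)b * sz + (long)t * st;
        else if (axis == 1) base = (long)a * sx + (long)b * sz + (long)t * st;
        else                base = (long)a * sx + (long)b * sy + (long)t * st;
        for (int i = 0; i < n; ++i) line[i] = x[base + (long)i * stride];
        int lo = std::min(r, n);
        int hi = std::max(lo, n - r);
        for (int i = 0; i < lo; ++i) {
          double acc = 0.0;
          for (int j = -r; j <= r; ++j)
            acc += kern[j + r] * line[reflect_index(i + j, n)];
          x[base + (long)i * stride] = acc;
        }
        for (int i = lo; i < hi; ++i) {   // interior: no boundary handling
          double acc = 0.0;
          const double* lp = &line[i - r];
          for (int j = 0; j <= 2 * r; ++j) acc += kern[j] * lp[j];
          x[base + (long)i * stride] = acc;
        }
        for (int i = hi; i < n; ++i) {
          double acc = 0.0;
          for (int j = -r; j <= r; ++j)
            acc += kern[j + r] * line[reflect_index(i + j, n)];
          x[base + (long)i * stride] = acc;
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector gauss_smooth_cpp(NumericVector arr, IntegerVector dims,
                               NumericVector sigma_vox) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int nt = (dims.size() > 3) ? dims[3] : 1;
  std::vector<double> x(arr.begin(), arr.end());
  for (int axis = 0; axis < 3; ++axis) {
    std::vector<double> k = gauss_kernel(sigma_vox[axis]);
    smooth_axis(x, nx, ny, nz, nt, axis, k);
  }
  NumericVector out(x.begin(), x.end());
  out.attr("dim") = arr.attr("dim");
  return out;
}

// [[Rcpp::export]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector dims,
                                   int connectivity) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  long n = (long)nx * ny * nz;
  IntegerVector labels(n, 0);

  std::vector<std::array<int, 3> > offs;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int manh = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && manh > 1) continue;
        offs.push_back({{dx, dy, dz}});
      }

  int next_label = 0;
  std::vector<long> stack;
  for (long s = 0; s < n; ++s) {
    if (!mask[s] || labels[s] != 0) continue;
    ++next_label;
    stack.push_back(s);
    labels[s] = next_label;
    while (!stack.empty()) {
      long v = stack.back();
      stack.pop_back();
      int vx = (int)(v % nx);
      int vy = (int)((v / nx) % ny);
      int vz = (int)(v / ((long)nx * ny));
      for (size_t o = 0; o < offs.size(); ++o) {
        int ux = vx + offs[o][0], uy = vy + offs[o][1], uz = vz + offs[o][2];
        if (ux < 0 || ux >= nx || uy < 0 || uy >= ny || uz < 0 || uz >= nz)
          continue;
        long u = (long)ux + (long)nx * (uy + (long)ny * uz);
        if (mask[u] && labels[u] == 0) {
          labels[u] = next_label;
          stack.push_back(u);
        }
      }
    }
  }
  labels.attr("dim") = dims;
  return labels;
}
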