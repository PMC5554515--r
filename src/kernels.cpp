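#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

// 26-connected component labeling of a 3D logical array by breadth-first
// flood fill. Labels are assigned in increasing order of the first linear
// (column-major) index of each component, so labeling is deterministic.
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = nx * ny * nz;
  IntegerVector labels(n, 0);
  int next_label = 0;
  std::queue<int> q;
  for (int start = 0; start < n; ++start) {
    if (!mask[start] || labels[start]) continue;
    ++next_label;
    labels[start] = next_label;
    q.push(start);
    while (!q.empty()) {
      const int v = q.front(); q.pop();
      const int i = v % nx;
      const int j = (v / nx) % ny;
      const int k = v / (nx * ny);
      for (int dk = -1; dk <= 1; ++dk) {
        const int kk = k + dk;
        if (kk < 0 || kk >= nz) continue;
        for (int dj = -1; dj <= 1; ++dj) {
          const int jj = j + dj;
          if (jj < 0 || jj >= ny) continue;
          for (int di = -1; di <= 1; ++di) {
            if (!di && !dj && !dk) continue;
            const int ii = i + di;
            if (ii < 0 || ii >= nx) continue;
            const int w = ii + nx * (jj + ny * kk);
            if (mask[w] && !labels[w]) { labels[w] = next_label; q.push(w); }
          }
        }
      }
    }
  }
  labels.attr("dim") = dims;
  return labels;
}

// One-dimensional squared-distance transform (lower envelope of parabolas)
// with grid spacing w. BIG stands in for infinity; squared distances on any
// realistic grid are far below it, so BIG - BIG never occurs.
static const double BIG = 1e20;

static void dt1d(const std::vector<double> &f, std::vector<double> &d,
                 std::vector<int> &v, std::vector<double> &z,
                 const int n, const double w) {
  const double w2 = w * w;
  int k = 0;
  v[0] = 0;
  z[0] = -BIG;
  z[1] = BIG;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      const int p = v[k];
      s = ((f[q] + w2 * q * q) - (f[p] + w2 * p * p)) / (2.0 * w2 * (q - p));
      if (k > 0 && s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = BIG;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    const double dq = w * (q - v[k]);
    d[q] = dq * dq + f[v[k]];
  }
}

// Exact anisotropic Euclidean distance transform: for each voxel inside the
// mask, the distance (mm) to the nearest voxel center outside the mask.
// Outside voxels get 0. Three separable passes of dt1d.
// [[Rcpp::export]]
NumericVector cpp_edt(LogicalVector mask, IntegerVector dims,
                      NumericVector spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = nx * ny * nz;
  std::vector<double> g(n);
  for (int i = 0; i < n; ++i) g[i] = mask[i] ? BIG : 0.0;

  const int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // pass along x
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      const int base = nx * (j + ny * k);
      for (int i = 0; i < nx; ++i) f[i] = g[base + i];
      dt1d(f, d, v, z, nx, spacing[0]);
      for (int i = 0; i < nx; ++i) g[base + i] = d[i];
    }
  // pass along y
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      for (int j = 0; j < ny; ++j) f[j] = g[i + nx * (j + ny * k)];
      dt1d(f, d, v, z, ny, spacing[1]);
      for (int j = 0; j < ny; ++j) g[i + nx * (j + ny * k)] = d[j];
    }
  // pass along z
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      for (int k = 0; k < nz; ++k) f[k] = g[i + nx * (j + ny * k)];
      dt1d(f, d, v, z, nz, spacing[2]);
      for (int k = 0; k < nz; ++k) g[i + nx * (j + ny * k)] = d[k];
    }

  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = std::sqrt(g[i]);
  out.attr("dim") = dims;
  return out;
}

// Separable 3D Gaussian smoothing with per-axis sigma in voxel units,
// kernel truncated at 4 sigma, zero padding beyond the array edge
// (appropriate for difference maps that vanish at the boundary).
// [[Rcpp::export]]
NumericVector cpp_gaussian_smooth(NumericVector x, IntegerVector dims,
                                  NumericVector sigma_vox) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = nx * ny * nz;
  std::vector<double> cur(x.begin(), x.end()), nxt(n);
  const int strides[3] = {1, nx, nx * ny};
  const int counts[3] = {nx, ny, nz};

  for (int axis = 0; axis < 3; ++axis) {
    const double s = sigma_vox[axis];
    if (s < 1e-8) continue;
    const int r = (int)std::ceil(4.0 * s);
    std::vector<double> kern(2 * r + 1);
    double ksum = 0.0;
    for (int t = -r; t <= r; ++t) {
      kern[t + r] = std::exp(-0.5 * t * t / (s * s));
      ksum += kern[t + r];
    }
    for (size_t t = 0; t < kern.size(); ++t) kern[t] /= ksum;

    const int stride = strides[axis];
    const int len = counts[axis];
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          const int idx[3] = {i, j, k};
          const int pos = idx[axis];
          const int v = i + nx * (j + ny * k);
          double acc = 0.0;
          const int lo = std::max(-r, -pos);
          const int hi = std::min(r, len - 1 - pos);
          for (int t = lo; t <= hi; ++t)
            acc += kern[t + r] * cur[v + t * stride];
          nxt[v] = acc;
        }
    cur.swap(nxt);
  }
  NumericVector out(cur.begin(), cur.end());
  out.attr("dim") = dims;
  return out;
}
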