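#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
#include <limits>

using namespace Rcpp;

// 1-D squared distance transform (Felzenszwalb & Huttenlocher), sample
// spacing `step`. f holds squared distances on input and output.
static void dt1d(std::vector<double> &f, std::vector<double> &d, int n,
                 double step) {
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = -1;
  const double s2 = step * step;
  for (int q = 0; q < n; ++q) {
    if (f[q] == INF) continue;  // only finite parabolas enter the envelope
    if (k < 0) {
      k = 0;
      v[0] = q;
      z[0] = -INF;
      z[1] = INF;
      continue;
    }
    double s;
    while (true) {
      int p = v[k];
      s = ((f[q] + s2 * q * q) - (f[p] + s2 * p * p)) / (2.0 * s2 * (q - p));
      if (s <= z[k] && k > 0) {
        --k;
      } else if (s <= z[k]) {  // k == 0: new parabola dominates everywhere
        v[0] = q;
        break;
      } else {
        break;
      }
    }
    if (v[k] != q) {
      ++k;
      v[k] = q;
      z[k] = s;
    }
    z[k + 1] = INF;
  }
  if (k < 0) {
    for (int q = 0; q < n; ++q) d[q] = INF;
    return;
  }
  int j = 0;
  for (int q = 0; q < n; ++q) {
    while (z[j + 1] < q) ++j;
    double dq = (q - v[j]) * step;
    d[q] = dq * dq + f[v[j]];
  }
}

//' @noRd
// [[Rcpp::export(name = ".edt_sq_cpp")]]
NumericVector edt_sq_cpp(LogicalVector mask, IntegerVector dims,
                         NumericVector spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  const double INF = std::numeric_limits<double>::infinity();
  for (R_xlen_t i = 0; i < n; ++i) out[i] = mask[i] ? 0.0 : INF;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax);

  // pass along x
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      R_xlen_t base = (R_xlen_t)nx * (y + (R_xlen_t)ny * z);
      for (int x = 0; x < nx; ++x) f[x] = out[base + x];
      dt1d(f, d, nx, spacing[0]);
      for (int x = 0; x < nx; ++x) out[base + x] = d[x];
    }
  // pass along y
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      R_xlen_t base = x + (R_xlen_t)nx * ny * z;
      for (int y = 0; y < ny; ++y) f[y] = out[base + (R_xlen_t)nx * y];
      dt1d(f, d, ny, spacing[1]);
      for (int y = 0; y < ny; ++y) out[base + (R_xlen_t)nx * y] = d[y];
    }
  // pass along z
  const R_xlen_t nxy = (R_xlen_t)nx * ny;
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      R_xlen_t base = x + (R_xlen_t)nx * y;
      for (int z = 0; z < nz; ++z) f[z] = out[base + nxy * z];
      dt1d(f, d, nz, spacing[2]);
      for (int z = 0; z < nz; ++z) out[base + nxy * z] = d[z];
    }
  return out;
}

//' @noRd
// [[Rcpp::export(name = ".label_components_cpp")]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n);  // zero-initialised
  const R_xlen_t nxy = (R_xlen_t)nx * ny;
  int cur = 0;
  std::queue<R_xlen_t> q;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++cur;
    lab[s] = cur;
    q.push(s);
    while (!q.empty()) {
      R_xlen_t p = q.front();
      q.pop();
      int x = (int)(p % nx);
      int y = (int)((p / nx) % ny);
      int z = (int)(p / nxy);
      const int dx[6] = {-1, 1, 0, 0, 0, 0};
      const int dy[6] = {0, 0, -1, 1, 0, 0};
      const int dz[6] = {0, 0, 0, 0, -1, 1};
      for (int k = 0; k < 6; ++k) {
        int xx = x + dx[k], yy = y + dy[k], zz = z + dz[k];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          continue;
        R_xlen_t pp = xx + (R_xlen_t)nx * yy + nxy * zz;
        if (mask[pp] && lab[pp] == 0) {
          lab[pp] = cur;
          q.push(pp);
        }
      }
    }
  }
  lab.attr("n_components") = cur;
  return lab;
}
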