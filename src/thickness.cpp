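#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

static const double DT_INF = 1e15;

// 1D lower-envelope squared distance transform (Felzenszwalb-Huttenlocher).
static void dt1d(const std::vector<double>& f, int n, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& z) {
  int k = 0;
  v[0] = 0;
  z[0] = -DT_INF;
  z[1] = DT_INF;
  for (int q = 1; q < n; ++q) {
    double s = 0.0;
    while (true) {
      int p = v[k];
      s = ((f[q] + (double)q * q) - (f[p] + (double)p * p)) / (2.0 * q - 2.0 * p);
      if (s <= z[k] && k > 0) {
        --k;
      } else {
        break;
      }
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = DT_INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = (double)(q - v[k]);
    d[q] = dq * dq + f[v[k]];
  }
}

// Exact squared Euclidean distance from each foreground voxel to the nearest
// background voxel *center*.  Space outside the volume is treated as
// foreground (no artificial boundary background), matching the convention of
// sphere-fitting thickness tools.
// [[Rcpp::export]]
NumericVector edt_sq_cpp(LogicalVector mask, IntegerVector dim) {
  const int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  const size_t n = (size_t)d1 * d2 * d3;
  std::vector<double> g(n);
  for (size_t i = 0; i < n; ++i) g[i] = mask[i] ? DT_INF : 0.0;

  int dmax = std::max(d1, std::max(d2, d3));
  std::vector<double> f(dmax), d(dmax), z(dmax + 1);
  std::vector<int> v(dmax);

  // pass along axis 1
  for (int i3 = 0; i3 < d3; ++i3)
    for (int i2 = 0; i2 < d2; ++i2) {
      size_t base = (size_t)d1 * (i2 + (size_t)d2 * i3);
      for (int i1 = 0; i1 < d1; ++i1) f[i1] = g[base + i1];
      dt1d(f, d1, d, v, z);
      for (int i1 = 0; i1 < d1; ++i1) g[base + i1] = d[i1];
    }
  // pass along axis 2
  for (int i3 = 0; i3 < d3; ++i3)
    for (int i1 = 0; i1 < d1; ++i1) {
      size_t base = i1 + (size_t)d1 * d2 * (size_t)i3;
      for (int i2 = 0; i2 < d2; ++i2) f[i2] = g[base + (size_t)d1 * i2];
      dt1d(f, d2, d, v, z);
      for (int i2 = 0; i2 < d2; ++i2) g[base + (size_t)d1 * i2] = d[i2];
    }
  // pass along axis 3
  for (int i2 = 0; i2 < d2; ++i2)
    for (int i1 = 0; i1 < d1; ++i1) {
      size_t base = i1 + (size_t)d1 * i2;
      for (int i3 = 0; i3 < d3; ++i3)
        f[i3] = g[base + (size_t)d1 * d2 * (size_t)i3];
      dt1d(f, d3, d, v, z);
      for (int i3 = 0; i3 < d3; ++i3)
        g[base + (size_t)d1 * d2 * (size_t)i3] = d[i3];
    }

  NumericVector out(n);
  std::copy(g.begin(), g.end(), out.begin());
  return out;
}

// Sphere-fitting local thickness (Hildebrand-Ruegsegger definition as used
// by bone morphometry tools): the thickness at a voxel is the diameter of
// the largest inscribed sphere containing it.  Pipeline: exact EDT ->
// distance ridge (spheres not contained in a neighbor's sphere) -> sphere
// painting taking the maximum.  Diameters use 2*r - 1 because distances are
// measured to the nearest background voxel center, half a voxel beyond the
// physical interface.
// [[Rcpp::export]]
NumericVector local_thickness_cpp(LogicalVector mask, IntegerVector dim) {
  const int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  const size_t n = (size_t)d1 * d2 * d3;
  NumericVector d2v = edt_sq_cpp(mask, dim);
  std::vector<double> dist(n);
  for (size_t i = 0; i < n; ++i) dist[i] = std::sqrt(d2v[i]);

  // 26-neighborhood offsets and their lengths
  std::vector<int> off1, off2, off3;
  std::vector<double> olen;
  for (int o3 = -1; o3 <= 1; ++o3)
    for (int o2 = -1; o2 <= 1; ++o2)
      for (int o1 = -1; o1 <= 1; ++o1) {
        if (o1 == 0 && o2 == 0 && o3 == 0) continue;
        off1.push_back(o1);
        off2.push_back(o2);
        off3.push_back(o3);
        olen.push_back(std::sqrt((double)(o1 * o1 + o2 * o2 + o3 * o3)));
      }

  // distance ridge: drop p when a neighbor's sphere contains p's sphere
  std::vector<char> ridge(n, 0);
  for (int i3 = 0; i3 < d3; ++i3)
    for (int i2 = 0; i2 < d2; ++i2)
      for (int i1 = 0; i1 < d1; ++i1) {
        size_t id = i1 + (size_t)d1 * (i2 + (size_t)d2 * i3);
        if (!mask[id]) continue;
        bool keep = true;
        for (size_t o = 0; o < off1.size() && keep; ++o) {
          int j1 = i1 + off1[o], j2 = i2 + off2[o], j3 = i3 + off3[o];
          if (j1 < 0 || j1 >= d1 || j2 < 0 || j2 >= d2 || j3 < 0 || j3 >= d3)
            continue;
          size_t jd = j1 + (size_t)d1 * (j2 + (size_t)d2 * j3);
          if (!mask[jd]) continue;
          if (dist[jd] >= dist[id] + olen[o] - 1e-9) keep = false;
        }
        if (keep) ridge[id] = 1;
      }

  // sphere painting: every voxel strictly inside a ridge sphere receives at
  // least that sphere's diameter; take the maximum over covering spheres
  NumericVector th(n);
  for (int i3 = 0; i3 < d3; ++i3)
    for (int i2 = 0; i2 < d2; ++i2)
      for (int i1 = 0; i1 < d1; ++i1) {
        size_t id = i1 + (size_t)d1 * (i2 + (size_t)d2 * i3);
        if (!ridge[id]) continue;
        double r2 = d2v[id];
        double r = dist[id];
        double t = 2.0 * r - 1.0;
        int ri = (int)std::ceil(r);
        for (int o3 = -ri; o3 <= ri; ++o3) {
          int j3 = i3 + o3;
          if (j3 < 0 || j3 >= d3) continue;
          for (int o2 = -ri; o2 <= ri; ++o2) {
            int j2 = i2 + o2;
            if (j2 < 0 || j2 >= d2) continue;
            double s23 = (double)(o2 * o2 + o3 * o3);
            if (s23 >= r2) continue;
            size_t base = (size_t)d1 * (j2 + (size_t)d2 * j3);
            for (int o1 = -ri; o1 <= ri; ++o1) {
              int j1 = i1 + o1;
              if (j1 < 0 || j1 >= d1) continue;
              if (s23 + o1 * o1 >= r2) continue;
              size_t jd = base + j1;
              if (mask[jd] && th[jd] < t) th[jd] = t;
            }
          }
        }
      }
  return th;
}
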