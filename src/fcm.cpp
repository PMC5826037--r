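#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

// One membership row of 1D fuzzy c-means:
//   u_c = [ sum_j (|x - v_c| / |x - v_j|)^(2/(m-1)) ]^-1
// computed in the numerically stable form (dmin/d_c)^p / sum_j (dmin/d_j)^p.
// If x coincides exactly with one or more centers, membership 1 is split
// equally among the coinciding centers and is 0 elsewhere.
static inline void memb_row(double x, const double* v, int C, double p,
                            double* out) {
  int nzero = 0;
  for (int c = 0; c < C; ++c)
    if (x == v[c]) ++nzero;
  if (nzero > 0) {
    for (int c = 0; c < C; ++c) out[c] = (x == v[c]) ? 1.0 / nzero : 0.0;
    return;
  }
  double dmin = R_PosInf;
  for (int c = 0; c < C; ++c) dmin = std::min(dmin, std::fabs(x - v[c]));
  double s = 0.0;
  for (int c = 0; c < C; ++c) {
    double r = std::pow(dmin / std::fabs(x - v[c]), p);
    out[c] = r;
    s += r;
  }
  for (int c = 0; c < C; ++c) out[c] /= s;
}

// Weighted center update v_c = sum_k w_k u_ck^m x_k / sum_k w_k u_ck^m.
// A class with no membership mass keeps its previous center.
static void center_step(const std::vector<double>& x,
                        const std::vector<double>& w,
                        const std::vector<double>& u, int n, int C, double m,
                        std::vector<double>& v) {
  for (int c = 0; c < C; ++c) {
    double num = 0.0, den = 0.0;
    const double* uc = u.data() + (size_t)c * n;
    for (int k = 0; k < n; ++k) {
      double um = std::pow(uc[k], m) * w[k];
      num += um * x[k];
      den += um;
    }
    if (den > 0.0) v[c] = num / den;
  }
}

static double objective(const std::vector<double>& x,
                        const std::vector<double>& w,
                        const std::vector<double>& u, int n, int C, double m,
                        const std::vector<double>& v) {
  double J = 0.0;
  for (int c = 0; c < C; ++c) {
    const double* uc = u.data() + (size_t)c * n;
    for (int k = 0; k < n; ++k) {
      double d = x[k] - v[c];
      J += w[k] * std::pow(uc[k], m) * d * d;
    }
  }
  return J;
}

// Returns indices (i, j) of the first collapsed center pair, or (-1, -1).
static void collapse_pair(const std::vector<double>& v, int C, double spread,
                          int* ci, int* cj) {
  *ci = -1;
  *cj = -1;
  for (int i = 0; i < C; ++i)
    for (int j = i + 1; j < C; ++j)
      if (std::fabs(v[i] - v[j]) < 1e-9 * spread) {
        *ci = i;
        *cj = j;
        return;
      }
}

struct FcmOut {
  std::vector<double> u;  // n x C, column-major
  std::vector<double> v;
  std::vector<double> obj;
  int iterations;
  bool collapsed;
  int collapse_i, collapse_j;
};

// Core loop shared by the exported fit and the per-cube refinement.
// u0 (if non-empty) seeds the first center update; otherwise v0 is used.
static FcmOut fcm_core(const std::vector<double>& x,
                       const std::vector<double>& w,
                       const std::vector<double>& v0,
                       const std::vector<double>& u0, double m, double tol,
                       int maxit) {
  int n = (int)x.size(), C = (int)v0.size();
  double p = 2.0 / (m - 1.0);
  FcmOut out;
  out.collapsed = false;
  out.collapse_i = out.collapse_j = -1;
  out.iterations = 0;
  double xmin = *std::min_element(x.begin(), x.end());
  double xmax = *std::max_element(x.begin(), x.end());
  double spread = xmax - xmin;
  if (spread <= 0.0) spread = std::max(std::fabs(xmax), 1.0);

  std::vector<double> v(v0), vn(C);
  out.u.assign((size_t)n * C, 0.0);
  std::vector<double> row(C);

  if (!u0.empty()) center_step(x, w, u0, n, C, m, v);

  for (int it = 1; it <= maxit; ++it) {
    out.iterations = it;
    for (int k = 0; k < n; ++k) {
      memb_row(x[k], v.data(), C, p, row.data());
      for (int c = 0; c < C; ++c) out.u[(size_t)c * n + k] = row[c];
    }
    out.obj.push_back(objective(x, w, out.u, n, C, m, v));
    vn = v;
    center_step(x, w, out.u, n, C, m, vn);
    int ci, cj;
    collapse_pair(vn, C, spread, &ci, &cj);
    if (ci >= 0) {
      out.collapsed = true;
      out.collapse_i = ci;
      out.collapse_j = cj;
      out.v = vn;
      return out;
    }
    double delta = 0.0;
    for (int c = 0; c < C; ++c)
      delta = std::max(delta, std::fabs(vn[c] - v[c]));
    delta /= spread;
    v = vn;
    if (delta < tol) break;
  }
  // final memberships consistent with the returned centers
  for (int k = 0; k < n; ++k) {
    memb_row(x[k], v.data(), C, p, row.data());
    for (int c = 0; c < C; ++c) out.u[(size_t)c * n + k] = row[c];
  }
  out.v = v;
  return out;
}

// [[Rcpp::export]]
NumericMatrix fcm_memberships_cpp(NumericVector x, NumericVector centers,
                                  double m) {
  int n = x.size(), C = centers.size();
  double p = 2.0 / (m - 1.0);
  NumericMatrix u(n, C);
  std::vector<double> row(C);
  for (int k = 0; k < n; ++k) {
    memb_row(x[k], REAL(centers), C, p, row.data());
    for (int c = 0; c < C; ++c) u(k, c) = row[c];
  }
  return u;
}

// [[Rcpp::export]]
List fcm_fit_cpp(NumericVector x, NumericVector w, NumericVector v0, double m,
                 double tol, int maxit, Nullable<NumericMatrix> u0_) {
  int n = x.size(), C = v0.size();
  std::vector<double> xs(x.begin(), x.end()), ws(w.begin(), w.end());
  std::vector<double> vs(v0.begin(), v0.end()), u0;
  if (u0_.isNotNull()) {
    NumericMatrix u0m(u0_);
    u0.assign(u0m.begin(), u0m.end());
  }
  FcmOut res = fcm_core(xs, ws, vs, u0, m, tol, maxit);
  if (res.collapsed)
    stop("fcm center collapse: classes %d and %d converged to the same value",
         res.collapse_i + 1, res.collapse_j + 1);
  // re-sort centers ascending, permuting membership columns accordingly
  std::vector<int> ord(C);
  for (int c = 0; c < C; ++c) ord[c] = c;
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return res.v[a] < res.v[b]; });
  NumericMatrix u(n, C);
  NumericVector v(C);
  for (int c = 0; c < C; ++c) {
    v[c] = res.v[ord[c]];
    std::copy(res.u.begin() + (size_t)ord[c] * n,
              res.u.begin() + (size_t)(ord[c] + 1) * n, u.begin() + (size_t)c * n);
  }
  return List::create(_["memberships"] = u, _["centers"] = v,
                      _["objective"] = NumericVector(res.obj.begin(), res.obj.end()),
                      _["iterations"] = res.iterations);
}

// Local refinement in overlapping cubes (the locally adaptive stage).
// For each cube: class-presence test against the global memberships, drop
// weak classes, re-run fuzzy c-means on the cube's in-mask intensities
// seeded from the surviving global memberships (renormalized), and
// accumulate the per-cube membership vectors.  The merged field is the
// unweighted mean over all cubes covering a voxel, renormalized to sum 1.
// [[Rcpp::export]]
List local_refine_cpp(NumericVector vol, IntegerVector dim, LogicalVector mask,
                      NumericMatrix ug, NumericVector centers,
                      IntegerMatrix origins0, IntegerVector edge,
                      double presence, double m, double tol, int maxit) {
  const int d1 = dim[0], d2 = dim[1];
  const R_xlen_t n = vol.size();
  const int C = centers.size();
  const int ncube = origins0.nrow();
  const int e1 = edge[0], e2 = edge[1], e3 = edge[2];

  std::vector<double> acc((size_t)n * C, 0.0);
  std::vector<int> cnt(n, 0);
  std::vector<int> idx;
  std::vector<double> xs;
  idx.reserve((size_t)e1 * e2 * e3);
  xs.reserve((size_t)e1 * e2 * e3);
  std::vector<double> S(C);
  long long total_iter = 0;
  int cubes_used = 0, cubes_dropping = 0, cubes_single = 0, cubes_degenerate = 0;

  for (int q = 0; q < ncube; ++q) {
    const int o1 = origins0(q, 0), o2 = origins0(q, 1), o3 = origins0(q, 2);
    idx.clear();
    xs.clear();
    for (int k3 = o3; k3 < o3 + e3; ++k3)
      for (int k2 = o2; k2 < o2 + e2; ++k2) {
        size_t base = (size_t)d1 * (k2 + (size_t)d2 * k3);
        for (int k1 = o1; k1 < o1 + e1; ++k1) {
          size_t id = base + k1;
          if (mask[id]) {
            idx.push_back((int)id);
            xs.push_back(vol[id]);
          }
        }
      }
    const int nin = (int)idx.size();
    if (nin == 0) continue;  // cube holds no in-mask voxels
    ++cubes_used;

    std::fill(S.begin(), S.end(), 0.0);
    for (int i = 0; i < nin; ++i)
      for (int c = 0; c < C; ++c) S[c] += ug(idx[i], c);
    std::vector<int> surv;
    for (int c = 0; c < C; ++c)
      if (S[c] >= presence * nin) surv.push_back(c);
    if (surv.empty())  // degenerate config (presence * C > 1): keep dominant
      surv.push_back((int)(std::max_element(S.begin(), S.end()) - S.begin()));
    const int Cs = (int)surv.size();
    if (Cs < C) ++cubes_dropping;

    if (Cs == 1) {
      ++cubes_single;
      const size_t coff = (size_t)surv[0] * n;
      for (int i = 0; i < nin; ++i) {
        acc[coff + idx[i]] += 1.0;
        ++cnt[idx[i]];
      }
      continue;
    }

    double xmn = *std::min_element(xs.begin(), xs.end());
    double xmx = *std::max_element(xs.begin(), xs.end());
    bool fallback = !(xmx > xmn);  // constant cube: nothing to refine

    if (!fallback) {
      // seed from global memberships restricted to survivors
      std::vector<double> u0((size_t)nin * Cs), v0(Cs);
      for (int c = 0; c < Cs; ++c) v0[c] = centers[surv[c]];
      for (int i = 0; i < nin; ++i) {
        double s = 0.0;
        for (int c = 0; c < Cs; ++c) s += ug(idx[i], surv[c]);
        for (int c = 0; c < Cs; ++c)
          u0[(size_t)c * nin + i] =
              (s > 0.0) ? ug(idx[i], surv[c]) / s : 1.0 / Cs;
      }
      std::vector<double> w(nin, 1.0);
      FcmOut res = fcm_core(xs, w, v0, u0, m, tol, maxit);
      if (res.collapsed) {
        // locally indistinguishable classes: keep the global field here
        fallback = true;
      } else {
        total_iter += res.iterations;
        for (int c = 0; c < Cs; ++c) {
          const size_t coff = (size_t)surv[c] * n;
          const double* uc = res.u.data() + (size_t)c * nin;
          for (int i = 0; i < nin; ++i) acc[coff + idx[i]] += uc[i];
        }
        for (int i = 0; i < nin; ++i) ++cnt[idx[i]];
      }
    }
    if (fallback) {
      ++cubes_degenerate;
      for (int i = 0; i < nin; ++i) {
        for (int c = 0; c < C; ++c) acc[(size_t)c * n + idx[i]] += ug(idx[i], c);
        ++cnt[idx[i]];
      }
    }
  }

  NumericMatrix merged(n, C);
  for (R_xlen_t k = 0; k < n; ++k) {
    if (!mask[k]) continue;
    if (cnt[k] == 0) {  // uncovered in-mask voxel: keep global (grid bug guard)
      for (int c = 0; c < C; ++c) merged(k, c) = ug(k, c);
      continue;
    }
    double s = 0.0;
    for (int c = 0; c < C; ++c) s += acc[(size_t)c * n + k];
    if (s <= 0.0) continue;
    for (int c = 0; c < C; ++c) merged(k, c) = acc[(size_t)c * n + k] / s;
  }
  return List::create(
      _["memberships"] = merged, _["cubes_used"] = cubes_used,
      _["cubes_dropping"] = cubes_dropping, _["cubes_single"] = cubes_single,
      _["cubes_degenerate"] = cubes_degenerate,
      _["iterations"] = (double)total_iter);
}
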