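#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>
#include <limits>

using namespace Rcpp;

// Closest-point squared distance from p to triangle (a,b,c).
// Ericson, Real-Time Collision Detection, 5.1.5.
static inline double pt_tri_dist2(const double* p, const double* a,
                                  const double* b, const double* c) {
  double ab[3], ac[3], ap[3];
  for (int i = 0; i < 3; ++i) {
    ab[i] = b[i] - a[i];
    ac[i] = c[i] - a[i];
    ap[i] = p[i] - a[i];
  }
  double d1 = ab[0]*ap[0] + ab[1]*ap[1] + ab[2]*ap[2];
  double d2 = ac[0]*ap[0] + ac[1]*ap[1] + ac[2]*ap[2];
  double q[3];
  if (d1 <= 0.0 && d2 <= 0.0) {
    q[0] = a[0]; q[1] = a[1]; q[2] = a[2];
  } else {
    double bp[3] = {p[0]-b[0], p[1]-b[1], p[2]-b[2]};
    double d3 = ab[0]*bp[0] + ab[1]*bp[1] + ab[2]*bp[2];
    double d4 = ac[0]*bp[0] + ac[1]*bp[1] + ac[2]*bp[2];
    if (d3 >= 0.0 && d4 <= d3) {
      q[0] = b[0]; q[1] = b[1]; q[2] = b[2];
    } else {
      double vc = d1*d4 - d3*d2;
      if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
        double v = d1 / (d1 - d3);
        for (int i = 0; i < 3; ++i) q[i] = a[i] + v * ab[i];
      } else {
        double cp[3] = {p[0]-c[0], p[1]-c[1], p[2]-c[2]};
        double d5 = ab[0]*cp[0] + ab[1]*cp[1] + ab[2]*cp[2];
        double d6 = ac[0]*cp[0] + ac[1]*cp[1] + ac[2]*cp[2];
        if (d6 >= 0.0 && d5 <= d6) {
          q[0] = c[0]; q[1] = c[1]; q[2] = c[2];
        } else {
          double vb = d5*d2 - d1*d6;
          if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
            double w = d2 / (d2 - d6);
            for (int i = 0; i < 3; ++i) q[i] = a[i] + w * ac[i];
          } else {
            double va = d3*d6 - d5*d4;
            if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
              double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
              for (int i = 0; i < 3; ++i) q[i] = b[i] + w * (c[i] - b[i]);
            } else {
              double denom = 1.0 / (va + vb + vc);
              double v = vb * denom, w = vc * denom;
              for (int i = 0; i < 3; ++i) q[i] = a[i] + ab[i]*v + ac[i]*w;
            }
          }
        }
      }
    }
  }
  double dx = p[0]-q[0], dy = p[1]-q[1], dz = p[2]-q[2];
  return dx*dx + dy*dy + dz*dz;
}

// Squared distance from point to axis-aligned box [lo, hi].
static inline double pt_box_dist2(const double* p, const double* lo, const double* hi) {
  double d2 = 0.0;
  for (int i = 0; i < 3; ++i) {
    double d = 0.0;
    if (p[i] < lo[i]) d = lo[i] - p[i];
    else if (p[i] > hi[i]) d = p[i] - hi[i];
    d2 += d * d;
  }
  return d2;
}

struct MeshRef {
  const double* V;   // n x 3, column major (R matrix)
  const int* F;      // m x 3, column major, 0-based
  int n, m;
  std::vector<double> tlo, thi;  // per-triangle AABB, 3*m each
  double lo[3], hi[3];           // mesh AABB

  MeshRef(const NumericMatrix& Vm, const IntegerMatrix& Fm)
      : V(Vm.begin()), F(Fm.begin()), n(Vm.nrow()), m(Fm.nrow()),
        tlo(3 * Fm.nrow()), thi(3 * Fm.nrow()) {
    for (int i = 0; i < 3; ++i) {
      lo[i] = std::numeric_limits<double>::infinity();
      hi[i] = -std::numeric_limits<double>::infinity();
    }
    for (int t = 0; t < m; ++t) {
      for (int i = 0; i < 3; ++i) {
        double a = V[F[t] + i * n];
        double b = V[F[t + m] + i * n];
        double c = V[F[t + 2 * m] + i * n];
        double mn = std::min(a, std::min(b, c));
        double mx = std::max(a, std::max(b, c));
        tlo[3 * t + i] = mn;
        thi[3 * t + i] = mx;
        if (mn < lo[i]) lo[i] = mn;
        if (mx > hi[i]) hi[i] = mx;
      }
    }
  }
  inline void tri(int t, double* a, double* b, double* c) const {
    for (int i = 0; i < 3; ++i) {
      a[i] = V[F[t] + i * n];
      b[i] = V[F[t + m] + i * n];
      c[i] = V[F[t + 2 * m] + i * n];
    }
  }
};

static inline double min_dist2_to_mesh(const MeshRef& M, const double* p,
                                       double best2 = std::numeric_limits<double>::infinity()) {
  double a[3], b[3], c[3];
  for (int t = 0; t < M.m; ++t) {
    if (pt_box_dist2(p, &M.tlo[3 * t], &M.thi[3 * t]) >= best2) continue;
    double d2 = pt_tri_dist2(p, (M.tri(t, a, b, c), a), b, c);
    if (d2 < best2) best2 = d2;
  }
  return best2;
}

// Ray-triangle intersection test (Moller-Trumbore). Returns 1 on clean hit
// with t > 0, 0 on clean miss, -1 on a numerically marginal configuration
// (near-parallel ray or hit near an edge) that requires a retry.
static inline int ray_tri(const double* o, const double* d,
                          const double* a, const double* b, const double* c) {
  const double eps = 1e-10, beps = 1e-9;
  double e1[3], e2[3], pv[3], tv[3], qv[3];
  for (int i = 0; i < 3; ++i) { e1[i] = b[i]-a[i]; e2[i] = c[i]-a[i]; }
  pv[0] = d[1]*e2[2] - d[2]*e2[1];
  pv[1] = d[2]*e2[0] - d[0]*e2[2];
  pv[2] = d[0]*e2[1] - d[1]*e2[0];
  double det = e1[0]*pv[0] + e1[1]*pv[1] + e1[2]*pv[2];
  double scale = std::sqrt((e1[0]*e1[0]+e1[1]*e1[1]+e1[2]*e1[2]) *
                           (e2[0]*e2[0]+e2[1]*e2[1]+e2[2]*e2[2]));
  if (std::fabs(det) < eps * std::max(scale, 1.0)) return -1;
  double inv = 1.0 / det;
  for (int i = 0; i < 3; ++i) tv[i] = o[i] - a[i];
  double u = (tv[0]*pv[0] + tv[1]*pv[1] + tv[2]*pv[2]) * inv;
  if (u < -beps || u > 1.0 + beps) return 0;
  qv[0] = tv[1]*e1[2] - tv[2]*e1[1];
  qv[1] = tv[2]*e1[0] - tv[0]*e1[2];
  qv[2] = tv[0]*e1[1] - tv[1]*e1[0];
  double v = (d[0]*qv[0] + d[1]*qv[1] + d[2]*qv[2]) * inv;
  if (v < -beps || (u + v) > 1.0 + beps) return 0;
  double t = (e2[0]*qv[0] + e2[1]*qv[1] + e2[2]*qv[2]) * inv;
  if (std::fabs(t) < beps) return -1;  // origin on surface
  if (t < 0.0) return 0;
  if (u < beps || v < beps || (u + v) > 1.0 - beps) return -1;  // near edge
  return 1;
}

// Parity inside test with deterministic retry directions.
static bool inside_mesh(const MeshRef& M, const double* p) {
  if (pt_box_dist2(p, M.lo, M.hi) > 0.0) return false;
  static const double dirs[8][3] = {
    {0.5377, 0.8323, 0.1332}, {-0.2718, 0.9213, 0.2786},
    {0.3141, -0.2718, 0.9097}, {0.7071, 0.1234, -0.6963},
    {-0.5774, -0.5774, 0.5774}, {0.9511, 0.2939, 0.0954},
    {0.1123, 0.4567, 0.8825}, {-0.8018, 0.2673, 0.5345}};
  double a[3], b[3], c[3];
  for (int k = 0; k < 8; ++k) {
    const double* d = dirs[k];
    int crossings = 0;
    bool marginal = false;
    for (int t = 0; t < M.m && !marginal; ++t) {
      // skip triangles entirely behind or beside the ray via AABB slab test
      int r = ray_tri(p, d, (M.tri(t, a, b, c), a), b, c);
      if (r < 0) marginal = true;
      else crossings += r;
    }
    if (!marginal) return (crossings % 2) == 1;
  }
  Rcpp::stop("inside test failed: degenerate ray configuration for all retry directions");
  return false;  // unreachable
}

// [[Rcpp::export]]
NumericVector cpp_min_dist(const NumericMatrix& V, const IntegerMatrix& F,
                           const NumericMatrix& P) {
  MeshRef M(V, F);
  int np = P.nrow();
  NumericVector out(np);
  for (int i = 0; i < np; ++i) {
    double p[3] = {P(i, 0), P(i, 1), P(i, 2)};
    out[i] = std::sqrt(min_dist2_to_mesh(M, p));
  }
  return out;
}

// [[Rcpp::export]]
LogicalVector cpp_inside(const NumericMatrix& V, const IntegerMatrix& F,
                         const NumericMatrix& P) {
  MeshRef M(V, F);
  int np = P.nrow();
  LogicalVector out(np);
  for (int i = 0; i < np; ++i) {
    double p[3] = {P(i, 0), P(i, 1), P(i, 2)};
    out[i] = inside_mesh(M, p);
  }
  return out;
}

// Min distance with cutoff: entries > cap are returned as +Inf (cheap reject).
// [[Rcpp::export]]
NumericVector cpp_min_dist_capped(const NumericMatrix& V, const IntegerMatrix& F,
                                  const NumericMatrix& P, double cap) {
  MeshRef M(V, F);
  int np = P.nrow();
  double cap2 = cap * cap;
  const double inf = std::numeric_limits<double>::infinity();
  NumericVector out(np);
  for (int i = 0; i < np; ++i) {
    double p[3] = {P(i, 0), P(i, 1), P(i, 2)};
    if (pt_box_dist2(p, M.lo, M.hi) > cap2) { out[i] = inf; continue; }
    double d2 = min_dist2_to_mesh(M, p, cap2 * (1.0 + 1e-12));
    out[i] = (d2 <= cap2) ? std::sqrt(d2) : inf;
  }
  return out;
}

// Shell membership |d| <= t with early exit per point.
// [[Rcpp::export]]
LogicalVector cpp_in_shell(const NumericMatrix& V, const IntegerMatrix& F,
                           const NumericMatrix& P, double t) {
  MeshRef M(V, F);
  int np = P.nrow();
  double t2 = t * t;
  LogicalVector out(np);
  double a[3], b[3], c[3];
  for (int i = 0; i < np; ++i) {
    double p[3] = {P(i, 0), P(i, 1), P(i, 2)};
    bool hit = false;
    if (pt_box_dist2(p, M.lo, M.hi) <= t2) {
      for (int tr = 0; tr < M.m; ++tr) {
        if (pt_box_dist2(p, &M.tlo[3 * tr], &M.thi[3 * tr]) > t2) continue;
        if (pt_tri_dist2(p, (M.tri(tr, a, b, c), a), b, c) <= t2) { hit = true; break; }
      }
    }
    out[i] = hit;
  }
  return out;
}

// Shell volume by voxel-centre counting. Voxels are laid on a grid covering the
// mesh AABB padded by t + pitch; a voxel counts if its centre lies within
// distance t of the surface (equivalently |signed distance| <= t for a
// watertight mesh). Optional clipping to a bounding box.
// [[Rcpp::export]]
double cpp_shell_volume(const NumericMatrix& V, const IntegerMatrix& F,
                        double t, double pitch, bool clip,
                        const NumericVector& clip_lo, const NumericVector& clip_hi) {
  MeshRef M(V, F);
  double glo[3], ghi[3];
  for (int i = 0; i < 3; ++i) {
    glo[i] = M.lo[i] - t - pitch;
    ghi[i] = M.hi[i] + t + pitch;
  }
  long long nx = (long long)std::ceil((ghi[0] - glo[0]) / pitch);
  long long ny = (long long)std::ceil((ghi[1] - glo[1]) / pitch);
  long long nz = (long long)std::ceil((ghi[2] - glo[2]) / pitch);
  long long ntot = nx * ny * nz;
  if (ntot <= 0 || ntot > 400000000LL)
    Rcpp::stop("shell volume grid too large (%lld voxels); increase voxel_pitch", ntot);
  std::vector<uint8_t> mark((size_t)ntot, 0);
  double t2 = t * t;
  double a[3], b[3], c[3];
  for (int tr = 0; tr < M.m; ++tr) {
    M.tri(tr, a, b, c);
    long long i0[3], i1[3];
    for (int i = 0; i < 3; ++i) {
      double lo = M.tlo[3 * tr + i] - t, hi = M.thi[3 * tr + i] + t;
      i0[i] = std::max(0LL, (long long)std::floor((lo - glo[i]) / pitch - 0.5));
      long long nmax = (i == 0 ? nx : (i == 1 ? ny : nz)) - 1;
      i1[i] = std::min(nmax, (long long)std::ceil((hi - glo[i]) / pitch - 0.5));
    }
    for (long long iz = i0[2]; iz <= i1[2]; ++iz) {
      double pz = glo[2] + (iz + 0.5) * pitch;
      for (long long iy = i0[1]; iy <= i1[1]; ++iy) {
        double py = glo[1] + (iy + 0.5) * pitch;
        size_t base = (size_t)((iz * ny + iy) * nx);
        for (long long ix = i0[0]; ix <= i1[0]; ++ix) {
          size_t idx = base + (size_t)ix;
          if (mark[idx]) continue;
          double p[3] = {glo[0] + (ix + 0.5) * pitch, py, pz};
          if (clip) {
            if (p[0] < clip_lo[0] || p[0] > clip_hi[0] ||
                p[1] < clip_lo[1] || p[1] > clip_hi[1] ||
                p[2] < clip_lo[2] || p[2] > clip_hi[2]) continue;
          }
          if (pt_tri_dist2(p, a, b, c) <= t2) mark[idx] = 1;
        }
      }
    }
  }
  long long count = 0;
  for (size_t i = 0; i < mark.size(); ++i) count += mark[i];
  return (double)count * pitch * pitch * pitch;
}

// Uniform rejection sampling of points inside the shell, using the R RNG so
// that set.seed() governs reproducibility.
// [[Rcpp::export]]
NumericMatrix cpp_sample_in_shell(const NumericMatrix& V, const IntegerMatrix& F,
                                  double t, int n, int max_tries_per_point) {
  MeshRef M(V, F);
  double lo[3], hi[3];
  for (int i = 0; i < 3; ++i) { lo[i] = M.lo[i] - t; hi[i] = M.hi[i] + t; }
  NumericMatrix out(n, 3);
  RNGScope scope;
  double t2 = t * t;
  double a[3], b[3], c[3];
  for (int k = 0; k < n; ++k) {
    bool ok = false;
    for (int tries = 0; tries < max_tries_per_point; ++tries) {
      double p[3];
      for (int i = 0; i < 3; ++i) p[i] = lo[i] + unif_rand() * (hi[i] - lo[i]);
      bool hit = false;
      for (int tr = 0; tr < M.m; ++tr) {
        if (pt_box_dist2(p, &M.tlo[3 * tr], &M.thi[3 * tr]) > t2) continue;
        if (pt_tri_dist2(p, (M.tri(tr, a, b, c), a), b, c) <= t2) { hit = true; break; }
      }
      if (hit) {
        out(k, 0) = p[0]; out(k, 1) = p[1]; out(k, 2) = p[2];
        ok = true;
        break;
      }
    }
    if (!ok) Rcpp::stop("shell rejection sampling failed after %d tries", max_tries_per_point);
  }
  return out;
}
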