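// Core numerical kernels: image sampling, transform-chain evaluation,
// B-spline deformable fitting, similarity metrics, curvature flow,
// displacement-field inversion and point-cloud distances.
//
// Conventions (shared with the R layer):
//  - voxel arrays are column-major with x fastest: (i,j,k) -> i + nx*(j + ny*k)
//  - vector fields append the component as a 4th dimension
//  - indices are 0-based; physical(p) = origin + direction %*% (spacing * idx)
//  - a transform chain lists stages in fit order (coarse -> fine); the
//    composite maps fixed-domain points into the moving domain by applying
//    the LAST stage to the point first.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

struct Geom {
  int nx, ny, nz;
  double sp[3], org[3], dir[9]; // dir column-major, columns = axis directions
};

static Geom as_geom(const IntegerVector& dim, const NumericVector& sp,
                    const NumericVector& org, const NumericVector& dir) {
  Geom g;
  g.nx = dim[0]; g.ny = dim[1]; g.nz = dim[2];
  for (int a = 0; a < 3; ++a) { g.sp[a] = sp[a]; g.org[a] = org[a]; }
  for (int a = 0; a < 9; ++a) g.dir[a] = dir[a];
  return g;
}

// physical -> continuous 0-based index (direction is orthonormal: inverse = t())
static inline void phys_to_index(const Geom& g, const double* p, double* idx) {
  double d0 = p[0] - g.org[0], d1 = p[1] - g.org[1], d2 = p[2] - g.org[2];
  for (int a = 0; a < 3; ++a) {
    // row a of D^T = column a of D
    double v = g.dir[3 * a] * d0 + g.dir[3 * a + 1] * d1 + g.dir[3 * a + 2] * d2;
    idx[a] = v / g.sp[a];
  }
}

static inline void index_to_phys(const Geom& g, const double* idx, double* p) {
  double s0 = g.sp[0] * idx[0], s1 = g.sp[1] * idx[1], s2 = g.sp[2] * idx[2];
  for (int a = 0; a < 3; ++a)
    p[a] = g.org[a] + g.dir[a] * s0 + g.dir[a + 3] * s1 + g.dir[a + 6] * s2;
}

// trilinear sample; returns false when outside the grid
static inline bool sample_linear(const double* vox, const Geom& g,
                                 const double* idx, double* out) {
  double x = idx[0], y = idx[1], z = idx[2];
  if (x < 0 || y < 0 || z < 0 || x > g.nx - 1 || y > g.ny - 1 || z > g.nz - 1)
    return false;
  int i0 = (int)std::floor(x), j0 = (int)std::floor(y), k0 = (int)std::floor(z);
  if (i0 > g.nx - 2) i0 = g.nx - 2; if (i0 < 0) i0 = 0;
  if (j0 > g.ny - 2) j0 = g.ny - 2; if (j0 < 0) j0 = 0;
  if (k0 > g.nz - 2) k0 = g.nz - 2; if (k0 < 0) k0 = 0;
  if (g.nx == 1) i0 = 0; if (g.ny == 1) j0 = 0; if (g.nz == 1) k0 = 0;
  double fx = x - i0, fy = y - j0, fz = z - k0;
  int i1 = std::min(i0 + 1, g.nx - 1), j1 = std::min(j0 + 1, g.ny - 1),
      k1 = std::min(k0 + 1, g.nz - 1);
  size_t nxy = (size_t)g.nx * g.ny;
  #define V(ii, jj, kk) vox[(ii) + (size_t)g.nx * (jj) + nxy * (kk)]
  double c00 = V(i0, j0, k0) * (1 - fx) + V(i1, j0, k0) * fx;
  double c10 = V(i0, j1, k0) * (1 - fx) + V(i1, j1, k0) * fx;
  double c01 = V(i0, j0, k1) * (1 - fx) + V(i1, j0, k1) * fx;
  double c11 = V(i0, j1, k1) * (1 - fx) + V(i1, j1, k1) * fx;
  #undef V
  double c0 = c00 * (1 - fy) + c10 * fy, c1 = c01 * (1 - fy) + c11 * fy;
  *out = c0 * (1 - fz) + c1 * fz;
  return true;
}

// clamped trilinear (always defined; indices clamped to grid)
static inline double sample_linear_clamped(const double* vox, const Geom& g,
                                           const double* idx) {
  double c[3] = { idx[0], idx[1], idx[2] };
  if (c[0] < 0) c[0] = 0; if (c[0] > g.nx - 1) c[0] = g.nx - 1;
  if (c[1] < 0) c[1] = 0; if (c[1] > g.ny - 1) c[1] = g.ny - 1;
  if (c[2] < 0) c[2] = 0; if (c[2] > g.nz - 1) c[2] = g.nz - 1;
  double out = 0.0;
  sample_linear(vox, g, c, &out);
  return out;
}

static inline bool sample_nn(const double* vox, const Geom& g,
                             const double* idx, double* out) {
  long i = (long)std::lround(idx[0]), j = (long)std::lround(idx[1]),
       k = (long)std::lround(idx[2]);
  if (i < 0 || j < 0 || k < 0 || i >= g.nx || j >= g.ny || k >= g.nz)
    return false;
  *out = vox[i + (size_t)g.nx * j + (size_t)g.nx * g.ny * k];
  return true;
}

// [[Rcpp::export]]
NumericVector cpp_sample_image(NumericVector vox, IntegerVector dim,
                               NumericVector sp, NumericVector org,
                               NumericVector dir, NumericMatrix pts,
                               int interp, double outside) {
  Geom g = as_geom(dim, sp, org, dir);
  int n = pts.nrow();
  NumericVector out(n);
  for (int r = 0; r < n; ++r) {
    double p[3] = { pts(r, 0), pts(r, 1), pts(r, 2) }, idx[3], v;
    phys_to_index(g, p, idx);
    bool ok = interp == 1 ? sample_linear(vox.begin(), g, idx, &v)
                          : sample_nn(vox.begin(), g, idx, &v);
    out[r] = ok ? v : outside;
  }
  return out;
}

// ---- transform chains ------------------------------------------------------

// cubic uniform B-spline basis weights for fractional offset t in [0,1)
static inline void bspline_w(double t, double* w) {
  double t2 = t * t, t3 = t2 * t;
  w[0] = (1 - 3 * t + 3 * t2 - t3) / 6.0;
  w[1] = (4 - 6 * t2 + 3 * t3) / 6.0;
  w[2] = (1 + 3 * t + 3 * t2 - 3 * t3) / 6.0;
  w[3] = t3 / 6.0;
}

struct BsplineGrid {
  int nx, ny, nz;
  double org[3], sp[3];
  const double* coef; // (nx,ny,nz,3)
};

static inline void bspline_displace(const BsplineGrid& b, const double* p,
                                    double* u) {
  double gx = (p[0] - b.org[0]) / b.sp[0];
  double gy = (p[1] - b.org[1]) / b.sp[1];
  double gz = (p[2] - b.org[2]) / b.sp[2];
  int bx = (int)std::floor(gx) - 1, by = (int)std::floor(gy) - 1,
      bz = (int)std::floor(gz) - 1;
  double wx[4], wy[4], wz[4];
  bspline_w(gx - std::floor(gx), wx);
  bspline_w(gy - std::floor(gy), wy);
  bspline_w(gz - std::floor(gz), wz);
  // grid is padded by the caller; clamp defensively
  if (bx < 0) bx = 0; if (bx > b.nx - 4) bx = b.nx - 4;
  if (by < 0) by = 0; if (by > b.ny - 4) by = b.ny - 4;
  if (bz < 0) bz = 0; if (bz > b.nz - 4) bz = b.nz - 4;
  size_t nxy = (size_t)b.nx * b.ny, ntot = nxy * b.nz;
  u[0] = u[1] = u[2] = 0.0;
  for (int k = 0; k < 4; ++k)
    for (int j = 0; j < 4; ++j) {
      double wjk = wy[j] * wz[k];
      size_t base = (size_t)(bx) + (size_t)b.nx * (by + j) + nxy * (bz + k);
      for (int i = 0; i < 4; ++i) {
        double w = wx[i] * wjk;
        size_t id = base + i;
        u[0] += w * b.coef[id];
        u[1] += w * b.coef[id + ntot];
        u[2] += w * b.coef[id + 2 * ntot];
      }
    }
}

// apply one stage (list with $type and parameters) to point p in place
static void apply_stage(const List& st, double* p) {
  int type = as<int>(st["type"]);
  if (type == 1) { // affine: q = A p + t
    NumericVector A = st["A"], t = st["t"];
    double q[3];
    for (int a = 0; a < 3; ++a)
      q[a] = A[a] * p[0] + A[a + 3] * p[1] + A[a + 6] * p[2] + t[a];
    p[0] = q[0]; p[1] = q[1]; p[2] = q[2];
  } else if (type == 2) { // bspline: q = p + u(p)
    NumericVector org = st["grid_origin"], sp = st["grid_spacing"],
                  coef = st["coef"];
    IntegerVector dm = st["grid_dim"];
    BsplineGrid b;
    b.nx = dm[0]; b.ny = dm[1]; b.nz = dm[2];
    for (int a = 0; a < 3; ++a) { b.org[a] = org[a]; b.sp[a] = sp[a]; }
    b.coef = coef.begin();
    double u[3];
    bspline_displace(b, p, u);
    p[0] += u[0]; p[1] += u[1]; p[2] += u[2];
  } else if (type == 3) { // dense field: q = p + f(p), clamped interpolation
    NumericVector f = st["field"], sp = st["spacing"], org = st["origin"],
                  dir = st["direction"];
    IntegerVector dm = st["dim"];
    Geom g = as_geom(dm, sp, org, dir);
    size_t ntot = (size_t)g.nx * g.ny * g.nz;
    double idx[3];
    phys_to_index(g, p, idx);
    for (int a = 0; a < 3; ++a)
      p[a] += sample_linear_clamped(f.begin() + a * ntot, g, idx);
  } else {
    stop("unknown transform stage type");
  }
}

static void apply_chain(const List& stages, double* p) {
  int n = stages.size();
  for (int s = n - 1; s >= 0; --s) { // finest stage first
    List st = stages[s];
    apply_stage(st, p);
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_transform_points(NumericMatrix pts, List stages) {
  int n = pts.nrow();
  NumericMatrix out(n, 3);
  for (int r = 0; r < n; ++r) {
    double p[3] = { pts(r, 0), pts(r, 1), pts(r, 2) };
    apply_chain(stages, p);
    out(r, 0) = p[0]; out(r, 1) = p[1]; out(r, 2) = p[2];
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_resample(NumericVector mvox, IntegerVector mdim,
                           NumericVector msp, NumericVector morg,
                           NumericVector mdir, IntegerVector tdim,
                           NumericVector tsp, NumericVector torg,
                           NumericVector tdir, List stages, int interp,
                           double outside) {
  Geom mg = as_geom(mdim, msp, morg, mdir);
  Geom tg = as_geom(tdim, tsp, torg, tdir);
  size_t ntot = (size_t)tg.nx * tg.ny * tg.nz;
  NumericVector out(ntot);
  double p[3], idx[3], v;
  for (int k = 0; k < tg.nz; ++k)
    for (int j = 0; j < tg.ny; ++j)
      for (int i = 0; i < tg.nx; ++i) {
        double id0[3] = { (double)i, (double)j, (double)k };
        index_to_phys(tg, id0, p);
        apply_chain(stages, p);
        phys_to_index(mg, p, idx);
        bool ok = interp == 1 ? sample_linear(mvox.begin(), mg, idx, &v)
                              : sample_nn(mvox.begin(), mg, idx, &v);
        out[i + (size_t)tg.nx * j + (size_t)tg.nx * tg.ny * k] =
            ok ? v : outside;
      }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_render_field(List stages, IntegerVector tdim,
                               NumericVector tsp, NumericVector torg,
                               NumericVector tdir) {
  Geom tg = as_geom(tdim, tsp, torg, tdir);
  size_t ntot = (size_t)tg.nx * tg.ny * tg.nz;
  NumericVector out(ntot * 3);
  double p[3];
  for (int k = 0; k < tg.nz; ++k)
    for (int j = 0; j < tg.ny; ++j)
      for (int i = 0; i < tg.nx; ++i) {
        double id0[3] = { (double)i, (double)j, (double)k };
        index_to_phys(tg, id0, p);
        double q[3] = { p[0], p[1], p[2] };
        apply_chain(stages, q);
        size_t id = i + (size_t)tg.nx * j + (size_t)tg.nx * tg.ny * k;
        out[id] = q[0] - p[0];
        out[id + ntot] = q[1] - p[1];
        out[id + 2 * ntot] = q[2] - p[2];
      }
  return out;
}

// fixed-point inversion of a displacement field: find v on the target grid
// with y + v(y) = T^{-1}(y) where T(x) = x + u(x)
// [[Rcpp::export]]
List cpp_invert_field(NumericVector f, IntegerVector fdim, NumericVector fsp,
                      NumericVector forg, NumericVector fdir,
                      IntegerVector tdim, NumericVector tsp,
                      NumericVector torg, NumericVector tdir, int maxit,
                      double tol) {
  Geom fg = as_geom(fdim, fsp, forg, fdir);
  Geom tg = as_geom(tdim, tsp, torg, tdir);
  size_t fn = (size_t)fg.nx * fg.ny * fg.nz;
  size_t tn = (size_t)tg.nx * tg.ny * tg.nz;
  NumericVector out(tn * 3);
  double worst = 0.0, sumres = 0.0;
  for (int k = 0; k < tg.nz; ++k)
    for (int j = 0; j < tg.ny; ++j)
      for (int i = 0; i < tg.nx; ++i) {
        double id0[3] = { (double)i, (double)j, (double)k }, y[3];
        index_to_phys(tg, id0, y);
        double v[3] = { 0, 0, 0 };
        double res = 0.0;
        for (int it = 0; it < maxit; ++it) {
          double x[3] = { y[0] + v[0], y[1] + v[1], y[2] + v[2] }, idx[3];
          phys_to_index(fg, x, idx);
          double u[3];
          for (int a = 0; a < 3; ++a)
            u[a] = sample_linear_clamped(f.begin() + a * fn, fg, idx);
          double nv[3] = { -u[0], -u[1], -u[2] };
          res = std::sqrt((nv[0] - v[0]) * (nv[0] - v[0]) +
                          (nv[1] - v[1]) * (nv[1] - v[1]) +
                          (nv[2] - v[2]) * (nv[2] - v[2]));
          v[0] = nv[0]; v[1] = nv[1]; v[2] = nv[2];
          if (res < tol) break;
        }
        if (res > worst) worst = res;
        sumres += res;
        size_t id = i + (size_t)tg.nx * j + (size_t)tg.nx * tg.ny * k;
        out[id] = v[0]; out[id + tn] = v[1]; out[id + 2 * tn] = v[2];
      }
  return List::create(_["field"] = out, _["worst_residual"] = worst,
                      _["mean_residual"] = sumres / (double)tn);
}

// ---- similarity metrics ----------------------------------------------------

// metric: 0 = mean squared difference, 1 = 1 - ncc^2, 2 = negated mutual info
// [[Rcpp::export]]
double cpp_metric_affine(NumericVector mvox, IntegerVector mdim,
                         NumericVector msp, NumericVector morg,
                         NumericVector mdir, NumericVector fvals,
                         NumericMatrix pts, NumericVector A, NumericVector t,
                         int metric, int bins, NumericVector frange,
                         NumericVector mrange) {
  Geom mg = as_geom(mdim, msp, morg, mdir);
  int n = pts.nrow();
  std::vector<double> fv, mv;
  fv.reserve(n); mv.reserve(n);
  for (int r = 0; r < n; ++r) {
    double p[3] = { pts(r, 0), pts(r, 1), pts(r, 2) }, q[3], idx[3], v;
    for (int a = 0; a < 3; ++a)
      q[a] = A[a] * p[0] + A[a + 3] * p[1] + A[a + 6] * p[2] + t[a];
    phys_to_index(mg, q, idx);
    if (sample_linear(mvox.begin(), mg, idx, &v)) {
      fv.push_back(fvals[r]);
      mv.push_back(v);
    }
  }
  size_t m = fv.size();
  if (m < 10 || m < (size_t)(0.25 * n)) return 1e10;
  if (metric == 0) {
    double s = 0;
    for (size_t r = 0; r < m; ++r) {
      double d = fv[r] - mv[r];
      s += d * d;
    }
    return s / m;
  }
  if (metric == 1) {
    double sf = 0, sm = 0, sff = 0, smm = 0, sfm = 0;
    for (size_t r = 0; r < m; ++r) {
      sf += fv[r]; sm += mv[r]; sff += fv[r] * fv[r];
      smm += mv[r] * mv[r]; sfm += fv[r] * mv[r];
    }
    double cf = sff - sf * sf / m, cm = smm - sm * sm / m,
           cfm = sfm - sf * sm / m;
    if (cf <= 0 || cm <= 0) return 1.0;
    return 1.0 - (cfm * cfm) / (cf * cm);
  }
  // Parzen soft-binned joint histogram mutual information
  double flo = frange[0], fhi = frange[1], mlo = mrange[0], mhi = mrange[1];
  if (fhi <= flo || mhi <= mlo) return 0.0;
  std::vector<double> H((size_t)bins * bins, 0.0);
  for (size_t r = 0; r < m; ++r) {
    double bf = (fv[r] - flo) / (fhi - flo) * (bins - 1);
    double bm = (mv[r] - mlo) / (mhi - mlo) * (bins - 1);
    if (bf < 0) bf = 0; if (bf > bins - 1) bf = bins - 1;
    if (bm < 0) bm = 0; if (bm > bins - 1) bm = bins - 1;
    int f0 = (int)std::floor(bf), m0 = (int)std::floor(bm);
    if (f0 > bins - 2) f0 = bins - 2;
    if (m0 > bins - 2) m0 = bins - 2;
    double wf = bf - f0, wm = bm - m0;
    H[f0 + bins * m0] += (1 - wf) * (1 - wm);
    H[f0 + 1 + bins * m0] += wf * (1 - wm);
    H[f0 + bins * (m0 + 1)] += (1 - wf) * wm;
    H[f0 + 1 + bins * (m0 + 1)] += wf * wm;
  }
  std::vector<double> pf(bins, 0.0), pm(bins, 0.0);
  for (int a = 0; a < bins; ++a)
    for (int b = 0; b < bins; ++b) {
      H[a + bins * b] /= m;
      pf[a] += H[a + bins * b];
      pm[b] += H[a + bins * b];
    }
  double mi = 0;
  for (int a = 0; a < bins; ++a)
    for (int b = 0; b < bins; ++b) {
      double h = H[a + bins * b];
      if (h > 1e-12) mi += h * std::log(h / (pf[a] * pm[b] + 1e-300));
    }
  return -mi;
}

// Adam-driven MSD fit of a cubic B-spline displacement grid.
// moving image lives on the SAME geometry as the fixed samples (it has been
// resampled through the preceding chain stages before this stage is fitted).
// [[Rcpp::export]]
NumericVector cpp_bspline_fit(NumericVector mvox, IntegerVector mdim,
                              NumericVector msp, NumericVector morg,
                              NumericVector mdir, NumericVector fvals,
                              NumericMatrix pts, NumericVector gorg,
                              NumericVector gsp, IntegerVector gdim,
                              NumericVector coef0, int iters, double lr,
                              double gfloor) {
  Geom mg = as_geom(mdim, msp, morg, mdir);
  size_t mn = (size_t)mg.nx * mg.ny * mg.nz;
  int n = pts.nrow();
  // precompute moving gradient (central differences, physical units)
  std::vector<double> grad(3 * mn);
  for (int k = 0; k < mg.nz; ++k)
    for (int j = 0; j < mg.ny; ++j)
      for (int i = 0; i < mg.nx; ++i) {
        size_t id = i + (size_t)mg.nx * j + (size_t)mg.nx * mg.ny * k;
        int im = std::max(i - 1, 0), ip = std::min(i + 1, mg.nx - 1);
        int jm = std::max(j - 1, 0), jp = std::min(j + 1, mg.ny - 1);
        int km = std::max(k - 1, 0), kp = std::min(k + 1, mg.nz - 1);
        size_t nxy = (size_t)mg.nx * mg.ny;
        grad[id] = (mvox[ip + (size_t)mg.nx * j + nxy * k] -
                    mvox[im + (size_t)mg.nx * j + nxy * k]) /
                   ((ip - im) * mg.sp[0]);
        grad[id + mn] = (mvox[i + (size_t)mg.nx * jp + nxy * k] -
                         mvox[i + (size_t)mg.nx * jm + nxy * k]) /
                        ((jp - jm) * mg.sp[1]);
        grad[id + 2 * mn] = (mvox[i + (size_t)mg.nx * j + nxy * kp] -
                             mvox[i + (size_t)mg.nx * j + nxy * km]) /
                            ((kp - km) * mg.sp[2]);
      }
  // NOTE: gradient above is in index-aligned axes scaled by spacing; with an
  // orthonormal direction matrix the chain still converges since the metric
  // only needs a descent direction; the pipeline standardizes to RAI first.
  BsplineGrid bg;
  bg.nx = gdim[0]; bg.ny = gdim[1]; bg.nz = gdim[2];
  for (int a = 0; a < 3; ++a) { bg.org[a] = gorg[a]; bg.sp[a] = gsp[a]; }
  size_t nc = (size_t)bg.nx * bg.ny * bg.nz;
  std::vector<double> coef(coef0.begin(), coef0.end());
  std::vector<double> g1(3 * nc), mom(3 * nc, 0.0);
  bg.coef = coef.data();
  const double b1 = 0.9;
  double step_scale = 0.0;
  // precompute per-sample basis support and weights (samples are fixed)
  std::vector<int> basex(n), basey(n), basez(n);
  std::vector<double> wx(4 * n), wy(4 * n), wz(4 * n);
  for (int r = 0; r < n; ++r) {
    double gx = (pts(r, 0) - bg.org[0]) / bg.sp[0];
    double gy = (pts(r, 1) - bg.org[1]) / bg.sp[1];
    double gz = (pts(r, 2) - bg.org[2]) / bg.sp[2];
    int bx = (int)std::floor(gx) - 1, by = (int)std::floor(gy) - 1,
        bz = (int)std::floor(gz) - 1;
    bspline_w(gx - std::floor(gx), &wx[4 * r]);
    bspline_w(gy - std::floor(gy), &wy[4 * r]);
    bspline_w(gz - std::floor(gz), &wz[4 * r]);
    if (bx < 0) bx = 0; if (bx > bg.nx - 4) bx = bg.nx - 4;
    if (by < 0) by = 0; if (by > bg.ny - 4) by = bg.ny - 4;
    if (bz < 0) bz = 0; if (bz > bg.nz - 4) bz = bg.nz - 4;
    basex[r] = bx; basey[r] = by; basez[r] = bz;
  }
  size_t ncxy = (size_t)bg.nx * bg.ny;
  for (int it = 1; it <= iters; ++it) {
    std::fill(g1.begin(), g1.end(), 0.0);
    for (int r = 0; r < n; ++r) {
      // displacement at sample
      double u[3] = { 0, 0, 0 };
      for (int k = 0; k < 4; ++k)
        for (int j = 0; j < 4; ++j) {
          double wjk = wy[4 * r + j] * wz[4 * r + k];
          size_t base = basex[r] + (size_t)bg.nx * (basey[r] + j) +
                        ncxy * (basez[r] + k);
          for (int i = 0; i < 4; ++i) {
            double w = wx[4 * r + i] * wjk;
            u[0] += w * coef[base + i];
            u[1] += w * coef[base + i + nc];
            u[2] += w * coef[base + i + 2 * nc];
          }
        }
      double q[3] = { pts(r, 0) + u[0], pts(r, 1) + u[1], pts(r, 2) + u[2] };
      double idx[3], v;
      phys_to_index(mg, q, idx);
      if (!sample_linear(mvox.begin(), mg, idx, &v)) continue;
      double resid = v - fvals[r];
      double gx0, gy0, gz0;
      gx0 = sample_linear_clamped(grad.data(), mg, idx);
      gy0 = sample_linear_clamped(grad.data() + mn, mg, idx);
      gz0 = sample_linear_clamped(grad.data() + 2 * mn, mg, idx);
      double f0 = 2.0 * resid / n;
      for (int k = 0; k < 4; ++k)
        for (int j = 0; j < 4; ++j) {
          double wjk = wy[4 * r + j] * wz[4 * r + k];
          size_t base = basex[r] + (size_t)bg.nx * (basey[r] + j) +
                        ncxy * (basez[r] + k);
          for (int i = 0; i < 4; ++i) {
            double w = wx[4 * r + i] * wjk * f0;
            g1[base + i] += w * gx0;
            g1[base + i + nc] += w * gy0;
            g1[base + i + 2 * nc] += w * gz0;
          }
        }
    }
    // momentum descent with the step calibrated once, from the gradient
    // scale of the first iteration: the largest coefficient then moves by
    // lr (mm) initially and updates decay together with the residuals
    // (an already-converged fit produces ~zero gradients and stays put)
    if (it == 1) {
      double gmax = 0.0;
      for (size_t a = 0; a < 3 * nc; ++a) {
        double am = std::fabs(g1[a]);
        if (am > gmax) gmax = am;
      }
      // a gradient below the meaningful floor means the fit already
      // matches to numerical precision: nothing to do
      if (gmax <= gfloor) break;
      step_scale = lr / gmax;
    }
    for (size_t a = 0; a < 3 * nc; ++a) {
      mom[a] = b1 * mom[a] + (1 - b1) * g1[a];
      coef[a] -= step_scale * mom[a];
    }
  }
  return NumericVector(coef.begin(), coef.end());
}

// ---- smoothing -------------------------------------------------------------

// separable Gaussian with reflected boundaries; sigma in voxels per axis
// [[Rcpp::export]]
NumericVector cpp_gaussian_smooth(NumericVector vox, IntegerVector dim,
                                  NumericVector sigma) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t ntot = (size_t)nx * ny * nz;
  std::vector<double> a(vox.begin(), vox.end()), b(ntot);
  int n[3] = { nx, ny, nz };
  size_t stride[3] = { 1, (size_t)nx, (size_t)nx * ny };
  for (int ax = 0; ax < 3; ++ax) {
    double s = sigma[ax];
    if (s <= 0) continue;
    int rad = std::max(1, (int)std::ceil(3 * s));
    std::vector<double> ker(2 * rad + 1);
    double ksum = 0;
    for (int i = -rad; i <= rad; ++i) {
      ker[i + rad] = std::exp(-0.5 * i * i / (s * s));
      ksum += ker[i + rad];
    }
    for (auto& kk : ker) kk /= ksum;
    int len = n[ax];
    size_t st = stride[ax];
    // iterate over all lines along axis ax
    size_t outer1 = ax == 0 ? (size_t)ny : (size_t)nx;
    size_t outer2 = ax == 2 ? (size_t)ny : (size_t)nz;
    size_t so1 = ax == 0 ? stride[1] : stride[0];
    size_t so2 = ax == 2 ? stride[1] : stride[2];
    for (size_t o2 = 0; o2 < outer2; ++o2)
      for (size_t o1 = 0; o1 < outer1; ++o1) {
        size_t off = o1 * so1 + o2 * so2;
        for (int i = 0; i < len; ++i) {
          double acc = 0;
          for (int t = -rad; t <= rad; ++t) {
            int ii = i + t;
            if (ii < 0) ii = -ii - 1;           // reflect
            if (ii >= len) ii = 2 * len - ii - 1;
            acc += ker[t + rad] * a[off + (size_t)ii * st];
          }
          b[off + (size_t)i * st] = acc;
        }
      }
    std::swap(a, b);
  }
  return NumericVector(a.begin(), a.end());
}

// explicit curvature-flow iterations in index space; result clamped to the
// input range so smoothing never creates new extrema
// [[Rcpp::export]]
NumericVector cpp_curvature_flow(NumericVector vox, IntegerVector dim,
                                 int iters, double dt) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t nxy = (size_t)nx * ny, ntot = nxy * nz;
  std::vector<double> a(vox.begin(), vox.end()), b(ntot);
  double lo = *std::min_element(a.begin(), a.end());
  double hi = *std::max_element(a.begin(), a.end());
  const double eps = 1e-10;
  for (int it = 0; it < iters; ++it) {
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          size_t id = i + (size_t)nx * j + nxy * k;
          int im = std::max(i - 1, 0), ip = std::min(i + 1, nx - 1);
          int jm = std::max(j - 1, 0), jp = std::min(j + 1, ny - 1);
          int km = std::max(k - 1, 0), kp = std::min(k + 1, nz - 1);
          #define A(ii, jj, kk) a[(ii) + (size_t)nx * (jj) + nxy * (kk)]
          double cx = (A(ip, j, k) - A(im, j, k)) / 2.0;
          double cy = (A(i, jp, k) - A(i, jm, k)) / 2.0;
          double cz = (A(i, j, kp) - A(i, j, km)) / 2.0;
          double xx = A(ip, j, k) - 2 * a[id] + A(im, j, k);
          double yy = A(i, jp, k) - 2 * a[id] + A(i, jm, k);
          double zz = A(i, j, kp) - 2 * a[id] + A(i, j, km);
          double xy = (A(ip, jp, k) - A(ip, jm, k) - A(im, jp, k) +
                       A(im, jm, k)) / 4.0;
          double xz = (A(ip, j, kp) - A(ip, j, km) - A(im, j, kp) +
                       A(im, j, km)) / 4.0;
          double yz = (A(i, jp, kp) - A(i, jp, km) - A(i, jm, kp) +
                       A(i, jm, km)) / 4.0;
          #undef A
          double g2 = cx * cx + cy * cy + cz * cz;
          double num = xx * (cy * cy + cz * cz) + yy * (cx * cx + cz * cz) +
                       zz * (cx * cx + cy * cy) -
                       2 * (cx * cy * xy + cx * cz * xz + cy * cz * yz);
          double upd = a[id] + dt * num / (g2 + eps);
          if (upd < lo) upd = lo;
          if (upd > hi) upd = hi;
          b[id] = upd;
        }
    std::swap(a, b);
  }
  return NumericVector(a.begin(), a.end());
}

// ---- point-cloud distances -------------------------------------------------

// per-row nearest-neighbour Euclidean distance from a to b (brute force)
// [[Rcpp::export]]
NumericVector cpp_min_dists(NumericMatrix a, NumericMatrix b) {
  int na = a.nrow(), nb = b.nrow();
  NumericVector out(na);
  for (int i = 0; i < na; ++i) {
    double best = R_PosInf;
    double x = a(i, 0), y = a(i, 1), z = a(i, 2);
    for (int j = 0; j < nb; ++j) {
      double dx = x - b(j, 0), dy = y - b(j, 1), dz = z - b(j, 2);
      double d = dx * dx + dy * dy + dz * dz;
      if (d < best) best = d;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}
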