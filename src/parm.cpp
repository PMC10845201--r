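// Compute kernels for the spatio-temporal trail analysis:
//  - separable Gaussian / Gaussian-derivative filtering of (t, z, x) stacks
//  - per-voxel 3x3 structure-tensor orientation (principal trail axis)
//  - SRRF-style radiality transform on a magnified grid
//  - Gaussian PSF blob rendering for the synthetic simulator
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// ---- separable convolution along one axis, replicate boundary -------------

static std::vector<double> gauss_kernel(double sigma) {
  if (sigma <= 0) return std::vector<double>(1, 1.0);
  int r = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> k(2 * r + 1);
  double s2 = sigma * sigma, sum = 0.0;
  for (int i = -r; i <= r; ++i) { k[i + r] = std::exp(-0.5 * i * i / s2); sum += k[i + r]; }
  for (double& v : k) v /= sum;
  return k;
}

// correlation kernel normalised so a unit ramp f(n) = n has response 1
static std::vector<double> gauss_deriv_kernel(double sigma) {
  if (sigma <= 0) { // central difference
    std::vector<double> k(3); k[0] = -0.5; k[1] = 0.0; k[2] = 0.5; return k;
  }
  int r = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> k(2 * r + 1);
  double s2 = sigma * sigma, norm = 0.0;
  for (int i = -r; i <= r; ++i) { k[i + r] = i * std::exp(-0.5 * i * i / s2); norm += i * k[i + r]; }
  for (double& v : k) v /= norm;
  return k;
}

// dims d0 (fastest-varying), d1, d2; out[n] = sum_i k[i] in[n + i] along axis
static void conv_axis(const double* in, double* out, int d0, int d1, int d2,
                      int axis, const std::vector<double>& k) {
  int d[3] = {d0, d1, d2};
  long s[3] = {1L, (long)d0, (long)d0 * d1};
  int r = ((int)k.size() - 1) / 2;
  int na = d[axis];
  long sa = s[axis];
  int o1 = (axis == 0) ? 1 : 0;
  int o2 = (axis == 2) ? 1 : 2;
  for (int j2 = 0; j2 < d[o2]; ++j2) {
    for (int j1 = 0; j1 < d[o1]; ++j1) {
      long base = j1 * s[o1] + j2 * s[o2];
      for (int i = 0; i < na; ++i) {
        double acc = 0.0;
        for (int t = -r; t <= r; ++t) {
          int ii = i + t;
          if (ii < 0) ii = 0; else if (ii >= na) ii = na - 1;
          acc += k[t + r] * in[base + (long)ii * sa];
        }
        out[base + (long)i * sa] = acc;
      }
    }
  }
}

// [[Rcpp::export(name = ".gauss_smooth3_cpp")]]
NumericVector gauss_smooth3_cpp(NumericVector stack, IntegerVector dims,
                                double sigma_t, double sigma_z, double sigma_x) {
  int nt = dims[0], nz = dims[1], nx = dims[2];
  long N = (long)nt * nz * nx;
  NumericVector out(N);
  std::vector<double> tmp(N);
  conv_axis(REAL(stack), tmp.data(), nt, nz, nx, 0, gauss_kernel(sigma_t));
  std::vector<double> tmp2(N);
  conv_axis(tmp.data(), tmp2.data(), nt, nz, nx, 1, gauss_kernel(sigma_z));
  conv_axis(tmp2.data(), REAL(out), nt, nz, nx, 2, gauss_kernel(sigma_x));
  return out;
}

// ---- 3x3 symmetric eigen-decomposition (analytic) --------------------------

static void eig3_sym(const double A[6], double lam[3]) {
  // A = (a11, a12, a13, a22, a23, a33)
  double a11 = A[0], a12 = A[1], a13 = A[2], a22 = A[3], a23 = A[4], a33 = A[5];
  double p1 = a12 * a12 + a13 * a13 + a23 * a23;
  double q = (a11 + a22 + a33) / 3.0;
  double p2 = (a11 - q) * (a11 - q) + (a22 - q) * (a22 - q) + (a33 - q) * (a33 - q) + 2.0 * p1;
  double p = std::sqrt(std::max(p2 / 6.0, 0.0));
  if (p < 1e-300) { lam[0] = lam[1] = lam[2] = q; return; }
  double b11 = (a11 - q) / p, b12 = a12 / p, b13 = a13 / p;
  double b22 = (a22 - q) / p, b23 = a23 / p, b33 = (a33 - q) / p;
  double detB = b11 * (b22 * b33 - b23 * b23) - b12 * (b12 * b33 - b23 * b13)
              + b13 * (b12 * b23 - b22 * b13);
  double r = detB / 2.0;
  if (r < -1.0) r = -1.0; else if (r > 1.0) r = 1.0;
  double phi = std::acos(r) / 3.0;
  lam[0] = q + 2.0 * p * std::cos(phi);                       // largest
  lam[2] = q + 2.0 * p * std::cos(phi + 2.0 * M_PI / 3.0);    // smallest
  lam[1] = 3.0 * q - lam[0] - lam[2];
}

static void cross3(const double a[3], const double b[3], double c[3]) {
  c[0] = a[1] * b[2] - a[2] * b[1];
  c[1] = a[2] * b[0] - a[0] * b[2];
  c[2] = a[0] * b[1] - a[1] * b[0];
}

// eigenvector of the smallest eigenvalue lam3 of symmetric A
static bool smallest_evec(const double A[6], double lam3, double v[3]) {
  double r1[3] = {A[0] - lam3, A[1], A[2]};
  double r2[3] = {A[1], A[3] - lam3, A[4]};
  double r3[3] = {A[2], A[4], A[5] - lam3};
  double c[3][3];
  cross3(r1, r2, c[0]); cross3(r1, r3, c[1]); cross3(r2, r3, c[2]);
  int best = 0; double bn = -1.0;
  for (int i = 0; i < 3; ++i) {
    double n = c[i][0] * c[i][0] + c[i][1] * c[i][1] + c[i][2] * c[i][2];
    if (n > bn) { bn = n; best = i; }
  }
  if (bn <= 0.0 || !std::isfinite(bn)) return false;
  double inv = 1.0 / std::sqrt(bn);
  v[0] = c[best][0] * inv; v[1] = c[best][1] * inv; v[2] = c[best][2] * inv;
  return true;
}

// ---- structure-tensor orientation at masked voxels -------------------------
//
// stack: (t, z, x) array, t fastest; mask_idx: 1-based linear indices.
// tscale: voxels per frame used to put the time axis on the spatial metric.
// Returns nmask x 4 matrix: u_t, u_z, u_x (unit trail axis, u_t >= 0), coherence.
// [[Rcpp::export(name = ".st_orient_cpp")]]
NumericMatrix st_orient_cpp(NumericVector stack, IntegerVector dims,
                            double grad_sigma, double window_sigma,
                            double tscale, IntegerVector mask_idx) {
  int nt = dims[0], nz = dims[1], nx = dims[2];
  long N = (long)nt * nz * nx;
  int nm = mask_idx.size();
  const double* in = REAL(stack);

  double sig_t_g = grad_sigma / tscale, sig_t_w = window_sigma / tscale;
  std::vector<double> kg_sp = gauss_kernel(grad_sigma), kg_t = gauss_kernel(sig_t_g);
  std::vector<double> kd_sp = gauss_deriv_kernel(grad_sigma), kd_t = gauss_deriv_kernel(sig_t_g);
  std::vector<double> kw_sp = gauss_kernel(window_sigma), kw_t = gauss_kernel(sig_t_w);

  std::vector<double> gt(N), gz(N), gx(N), t1(N), t2(N);

  // g_t = smooth_x(smooth_z(deriv_t(f))) / tscale
  conv_axis(in, t1.data(), nt, nz, nx, 0, kd_t);
  conv_axis(t1.data(), t2.data(), nt, nz, nx, 1, kg_sp);
  conv_axis(t2.data(), gt.data(), nt, nz, nx, 2, kg_sp);
  for (long i = 0; i < N; ++i) gt[i] /= tscale;
  // A = smooth_t(f); g_z = smooth_x(deriv_z(A)); g_x = smooth_z(deriv_x(A))
  conv_axis(in, t1.data(), nt, nz, nx, 0, kg_t);
  conv_axis(t1.data(), t2.data(), nt, nz, nx, 1, kd_sp);
  conv_axis(t2.data(), gz.data(), nt, nz, nx, 2, kg_sp);
  conv_axis(t1.data(), t2.data(), nt, nz, nx, 2, kd_sp);
  conv_axis(t2.data(), gx.data(), nt, nz, nx, 1, kg_sp);

  // smoothed tensor components gathered at the mask
  NumericMatrix J(nm, 6);
  const double* G[3] = {gt.data(), gz.data(), gx.data()};
  int pairs[6][2] = {{0, 0}, {0, 1}, {0, 2}, {1, 1}, {1, 2}, {2, 2}};
  for (int c = 0; c < 6; ++c) {
    const double* ga = G[pairs[c][0]];
    const double* gb = G[pairs[c][1]];
    for (long i = 0; i < N; ++i) t1[i] = ga[i] * gb[i];
    conv_axis(t1.data(), t2.data(), nt, nz, nx, 0, kw_t);
    conv_axis(t2.data(), t1.data(), nt, nz, nx, 1, kw_sp);
    conv_axis(t1.data(), t2.data(), nt, nz, nx, 2, kw_sp);
    for (int m = 0; m < nm; ++m) J(m, c) = t2[(long)mask_idx[m] - 1];
  }

  NumericMatrix out(nm, 4);
  for (int m = 0; m < nm; ++m) {
    double A[6] = {J(m, 0), J(m, 1), J(m, 2), J(m, 3), J(m, 4), J(m, 5)};
    double lam[3];
    eig3_sym(A, lam);
    double l1 = lam[0], l2 = lam[1], l3 = std::max(lam[2], 0.0);
    double v[3];
    if (!(l1 > 0) || !smallest_evec(A, lam[2], v)) {
      // zero-gradient or degenerate voxel: axis undefined
      out(m, 0) = NA_REAL; out(m, 1) = NA_REAL;
      out(m, 2) = NA_REAL; out(m, 3) = NA_REAL;
      continue;
    }
    double coh = 0.0;
    if ((l2 + l3) > 1e-12 * l1) coh = (l2 - l3) / (l2 + l3);
    if (coh < 0) coh = 0; else if (coh > 1) coh = 1;
    if (v[0] < 0) { v[0] = -v[0]; v[1] = -v[1]; v[2] = -v[2]; }
    out(m, 0) = v[0]; out(m, 1) = v[1]; out(m, 2) = v[2]; out(m, 3) = coh;
  }
  return out;
}

// ---- radiality (SRRF-style) -------------------------------------------------

// gradient of a frame (nz x nx, z fastest) by central differences
static void frame_grad(const double* f, int nz, int nx,
                       std::vector<double>& gz, std::vector<double>& gx) {
  for (int j = 0; j < nx; ++j) {
    for (int i = 0; i < nz; ++i) {
      int im = i > 0 ? i - 1 : 0, ip = i < nz - 1 ? i + 1 : nz - 1;
      int jm = j > 0 ? j - 1 : 0, jp = j < nx - 1 ? j + 1 : nx - 1;
      gz[i + (long)nz * j] = 0.5 * (f[ip + (long)nz * j] - f[im + (long)nz * j]);
      gx[i + (long)nz * j] = 0.5 * (f[i + (long)nz * jp] - f[i + (long)nz * jm]);
    }
  }
}

static inline double bilin(const std::vector<double>& a, int nz, int nx,
                           double pz, double px) {
  if (pz < 0) pz = 0; if (pz > nz - 1) pz = nz - 1;
  if (px < 0) px = 0; if (px > nx - 1) px = nx - 1;
  int i0 = (int)std::floor(pz), j0 = (int)std::floor(px);
  if (i0 > nz - 2) i0 = nz - 2; if (j0 > nx - 2) j0 = nx - 2;
  if (i0 < 0) i0 = 0; if (j0 < 0) j0 = 0;
  double fz = pz - i0, fx = px - j0;
  double v00 = a[i0 + (long)nz * j0],     v10 = a[i0 + 1 + (long)nz * j0];
  double v01 = a[i0 + (long)nz * (j0 + 1)], v11 = a[i0 + 1 + (long)nz * (j0 + 1)];
  return v00 * (1 - fz) * (1 - fx) + v10 * fz * (1 - fx)
       + v01 * (1 - fz) * fx + v11 * fz * fx;
}

// radiality of one frame onto the magnified grid
static void radiality_one(const double* f, int nz, int nx,
                          double ring_radius, int mag, int axes,
                          std::vector<double>& gz, std::vector<double>& gx,
                          double* out /* (nz*mag) x (nx*mag), z fastest */) {
  frame_grad(f, nz, nx, gz, gx);
  // gradients far below the frame's gradient scale carry no orientation
  // information (their direction is floating-point noise); skip them
  double gmax = 0.0;
  for (long i = 0; i < (long)nz * nx; ++i) {
    double g2 = gz[i] * gz[i] + gx[i] * gx[i];
    if (g2 > gmax) gmax = g2;
  }
  double gmin = 1e-6 * std::sqrt(gmax);
  int mz = nz * mag, mx = nx * mag;
  for (int j = 0; j < mx; ++j) {
    double cx = (j + 0.5) / mag - 0.5;
    for (int i = 0; i < mz; ++i) {
      double cz = (i + 0.5) / mag - 0.5;
      double acc = 0.0; int cnt = 0;
      for (int k = 0; k < axes; ++k) {
        double th = 2.0 * M_PI * (k + 0.5) / axes;
        double pz = cz + ring_radius * std::cos(th);
        double px = cx + ring_radius * std::sin(th);
        if (pz < 0 || pz > nz - 1 || px < 0 || px > nx - 1) continue;
        double gzz = bilin(gz, nz, nx, pz, px);
        double gxx = bilin(gx, nz, nx, pz, px);
        double gn = std::sqrt(gzz * gzz + gxx * gxx);
        ++cnt;
        if (gn <= gmin) continue;
        double vz = cz - pz, vx = cx - px;
        double d = std::fabs(gzz * vx - gxx * vz) / gn;
        double s = (gzz * vz + gxx * vx) > 0 ? 1.0 : -1.0;
        double w = 1.0 - d / ring_radius;
        if (w < 0) w = 0;
        acc += s * w * w;   // squared weight sharpens the convergence peak
      }
      double r = cnt > 0 ? acc / cnt : 0.0;
      out[i + (long)mz * j] = r > 0 ? r : 0.0;
    }
  }
}

// [[Rcpp::export(name = ".radiality_frame_cpp")]]
NumericMatrix radiality_frame_cpp(NumericMatrix frame, double ring_radius,
                                  int mag, int axes) {
  int nz = frame.nrow(), nx = frame.ncol();
  std::vector<double> gz((long)nz * nx), gx((long)nz * nx);
  NumericMatrix out(nz * mag, nx * mag);
  radiality_one(REAL(frame), nz, nx, ring_radius, mag, axes, gz, gx, REAL(out));
  return out;
}

// temporal aggregation of per-frame radiality: mode 0 = mean, 1 = variance
// [[Rcpp::export(name = ".srrf_stack_cpp")]]
NumericMatrix srrf_stack_cpp(NumericVector stack, IntegerVector dims,
                             double ring_radius, int mag, int axes, int mode) {
  int nt = dims[0], nz = dims[1], nx = dims[2];
  long M = (long)nz * mag * nx * mag;
  std::vector<double> fr((long)nz * nx), gz((long)nz * nx), gx((long)nz * nx);
  std::vector<double> rad(M), sum(M, 0.0), sumsq(M, 0.0);
  const double* in = REAL(stack);
  for (int t = 0; t < nt; ++t) {
    for (int j = 0; j < nx; ++j)
      for (int i = 0; i < nz; ++i)
        fr[i + (long)nz * j] = in[t + (long)nt * (i + (long)nz * j)];
    radiality_one(fr.data(), nz, nx, ring_radius, mag, axes, gz, gx, rad.data());
    for (long m = 0; m < M; ++m) { sum[m] += rad[m]; sumsq[m] += rad[m] * rad[m]; }
  }
  NumericMatrix out(nz * mag, nx * mag);
  double* o = REAL(out);
  for (long m = 0; m < M; ++m) {
    double mu = sum[m] / nt;
    o[m] = (mode == 0) ? mu : std::max(sumsq[m] / nt - mu * mu, 0.0);
  }
  return out;
}

// ---- Gaussian blob rendering ------------------------------------------------

// t_idx 1-based frame; pz/px 0-based continuous pixel-centre coordinates
// [[Rcpp::export(name = ".stamp_gaussians_cpp")]]
NumericVector stamp_gaussians_cpp(IntegerVector dims, IntegerVector t_idx,
                                  NumericVector pz, NumericVector px,
                                  NumericVector amp, double sigma_px) {
  int nt = dims[0], nz = dims[1], nx = dims[2];
  NumericVector out((long)nt * nz * nx);
  double* o = REAL(out);
  int r = std::max(1, (int)std::ceil(4.0 * sigma_px));
  double inv2s2 = 1.0 / (2.0 * sigma_px * sigma_px);
  int n = t_idx.size();
  for (int e = 0; e < n; ++e) {
    int t = t_idx[e] - 1;
    if (t < 0 || t >= nt) continue;
    int zc = (int)std::round(pz[e]), xc = (int)std::round(px[e]);
    for (int j = std::max(0, xc - r); j <= std::min(nx - 1, xc + r); ++j) {
      double dx = j - px[e];
      for (int i = std::max(0, zc - r); i <= std::min(nz - 1, zc + r); ++i) {
        double dz = i - pz[e];
        o[t + (long)nt * (i + (long)nz * j)] += amp[e] * std::exp(-(dz * dz + dx * dx) * inv2s2);
      }
    }
  }
  return out;
}
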