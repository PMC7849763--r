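// Core numerical kernels: Siddon ray tracing (forward/back projection with an
// exactly matched adjoint), trilinear warping with exact positional Jacobian,
// separable Gaussian smoothing, the bilateral DVF regularizer and its analytic
// gradient, and a small connected-component labeller.
//
// Conventions (shared with the R layer):
//   * volumes are column-major arrays [nx, ny, nz]; linear index i + nx*(j + ny*k)
//   * world frame: volume centered on the rotation axis (isocenter at 0,0,0);
//     voxel (0,0,0) center sits at -extent/2 + spacing/2; units mm
//   * gantry rotates about +z; at angle a the source is at
//     (SAD cos a, SAD sin a, 0), detector center at (-(SDD-SAD) cos a, ...),
//     detector u axis = (-sin a, cos a, 0), v axis = +z
//   * DVFs are pull-back displacements in mm: out(x) = in(x + v(x))

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <queue>
using namespace Rcpp;

struct Grid {
  int n[3];
  double sp[3];
  double low[3];   // low edge of voxel (0,0,0)
};

static Grid make_grid(const IntegerVector& dim, const NumericVector& spacing) {
  Grid g;
  for (int a = 0; a < 3; ++a) {
    g.n[a] = dim[a];
    g.sp[a] = spacing[a];
    g.low[a] = -0.5 * g.n[a] * g.sp[a];
  }
  return g;
}

// Walk the segment S->P through the grid, calling f(i, j, k, length_mm) for
// every voxel the segment intersects. Exact Siddon/Amanatides-Woo traversal;
// ties at voxel faces are resolved by the half-open [low, high) convention of
// the incremental walk.
template <typename F>
static inline void walk_ray(const double S[3], const double P[3], const Grid& g, F&& f) {
  double d[3];
  double L2 = 0.0;
  for (int a = 0; a < 3; ++a) { d[a] = P[a] - S[a]; L2 += d[a] * d[a]; }
  const double L = std::sqrt(L2);
  if (L <= 0.0) return;

  double tmin = -1e300, tmax = 1e300;
  for (int a = 0; a < 3; ++a) {
    const double hi = g.low[a] + g.n[a] * g.sp[a];
    if (std::fabs(d[a]) < 1e-12) {
      if (S[a] < g.low[a] || S[a] >= hi) return;
    } else {
      double t1 = (g.low[a] - S[a]) / d[a];
      double t2 = (hi - S[a]) / d[a];
      if (t1 > t2) std::swap(t1, t2);
      if (t1 > tmin) tmin = t1;
      if (t2 < tmax) tmax = t2;
    }
  }
  if (tmax <= tmin) return;

  int idx[3], step[3];
  double tnext[3], dt[3];
  const double eps = 1e-10 * (tmax - tmin);
  for (int a = 0; a < 3; ++a) {
    const double pos = S[a] + (tmin + eps) * d[a];
    int i = (int)std::floor((pos - g.low[a]) / g.sp[a]);
    if (i < 0) i = 0;
    if (i > g.n[a] - 1) i = g.n[a] - 1;
    idx[a] = i;
    if (std::fabs(d[a]) < 1e-12) {
      step[a] = 0; tnext[a] = 1e300; dt[a] = 1e300;
    } else if (d[a] > 0) {
      step[a] = 1;
      tnext[a] = (g.low[a] + (i + 1) * g.sp[a] - S[a]) / d[a];
      dt[a] = g.sp[a] / d[a];
    } else {
      step[a] = -1;
      tnext[a] = (g.low[a] + i * g.sp[a] - S[a]) / d[a];
      dt[a] = -g.sp[a] / d[a];
    }
  }

  double t = tmin;
  while (t < tmax - 1e-12) {
    int a = 0;
    if (tnext[1] < tnext[a]) a = 1;
    if (tnext[2] < tnext[a]) a = 2;
    const double te = tnext[a] < tmax ? tnext[a] : tmax;
    const double len = (te - t) * L;
    if (len > 0.0) f(idx[0], idx[1], idx[2], len);
    if (tnext[a] >= tmax) break;
    t = tnext[a];
    idx[a] += step[a];
    if (idx[a] < 0 || idx[a] >= g.n[a]) break;
    tnext[a] += dt[a];
  }
}

static inline void source_and_pixel(double angle, double sad, double sdd,
                                    int iu, int iv, int nu, int nv,
                                    double du, double dv,
                                    double S[3], double P[3]) {
  const double c = std::cos(angle), s = std::sin(angle);
  S[0] = sad * c; S[1] = sad * s; S[2] = 0.0;
  const double odd = sdd - sad;
  const double u = (iu - 0.5 * (nu - 1)) * du;
  const double v = (iv - 0.5 * (nv - 1)) * dv;
  P[0] = -odd * c - u * s;
  P[1] = -odd * s + u * c;
  P[2] = v;
}

// [[Rcpp::export]]
List cpp_trace_ray(IntegerVector dim, NumericVector spacing,
                   double sad, double sdd, int nu, int nv,
                   double du, double dv, int iu, int iv, double angle) {
  Grid g = make_grid(dim, spacing);
  double S[3], P[3];
  source_and_pixel(angle, sad, sdd, iu, iv, nu, nv, du, dv, S, P);
  std::vector<int> ii, jj, kk;
  std::vector<double> len;
  walk_ray(S, P, g, [&](int i, int j, int k, double l) {
    ii.push_back(i + 1); jj.push_back(j + 1); kk.push_back(k + 1);
    len.push_back(l);
  });
  return List::create(_["i"] = wrap(ii), _["j"] = wrap(jj), _["k"] = wrap(kk),
                      _["length"] = wrap(len));
}

// [[Rcpp::export]]
NumericVector cpp_forward_project(NumericVector vol, IntegerVector dim,
                                  NumericVector spacing,
                                  double sad, double sdd, int nu, int nv,
                                  double du, double dv, NumericVector angles) {
  Grid g = make_grid(dim, spacing);
  const int nview = angles.size();
  NumericVector out(static_cast<R_xlen_t>(nu) * nv * nview);
  const double* mu = vol.begin();
  double* o = out.begin();
  const int nx = g.n[0], ny = g.n[1];
  for (int w = 0; w < nview; ++w) {
    const double a = angles[w];
    for (int iv2 = 0; iv2 < nv; ++iv2) {
      for (int iu2 = 0; iu2 < nu; ++iu2) {
        double S[3], P[3];
        source_and_pixel(a, sad, sdd, iu2, iv2, nu, nv, du, dv, S, P);
        double acc = 0.0;
        walk_ray(S, P, g, [&](int i, int j, int k, double l) {
          acc += l * mu[i + nx * (j + static_cast<R_xlen_t>(ny) * k)];
        });
        o[iu2 + nu * (iv2 + static_cast<R_xlen_t>(nv) * w)] = acc;
      }
    }
  }
  return out;
}

// Adjoint of cpp_forward_project: accumulates a_in * p_i into voxels using the
// identical traversal, so <Ax, y> == <x, A^T y> to rounding error.
// [[Rcpp::export]]
NumericVector cpp_back_project(NumericVector proj, IntegerVector dim,
                               NumericVector spacing,
                               double sad, double sdd, int nu, int nv,
                               double du, double dv, NumericVector angles) {
  Grid g = make_grid(dim, spacing);
  const int nview = angles.size();
  NumericVector out(static_cast<R_xlen_t>(g.n[0]) * g.n[1] * g.n[2]);
  double* o = out.begin();
  const double* p = proj.begin();
  const int nx = g.n[0], ny = g.n[1];
  for (int w = 0; w < nview; ++w) {
    const double a = angles[w];
    for (int iv2 = 0; iv2 < nv; ++iv2) {
      for (int iu2 = 0; iu2 < nu; ++iu2) {
        const double pv = p[iu2 + nu * (iv2 + static_cast<R_xlen_t>(nv) * w)];
        if (pv == 0.0) continue;
        double S[3], P[3];
        source_and_pixel(a, sad, sdd, iu2, iv2, nu, nv, du, dv, S, P);
        walk_ray(S, P, g, [&](int i, int j, int k, double l) {
          o[i + nx * (j + static_cast<R_xlen_t>(ny) * k)] += l * pv;
        });
      }
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Trilinear pull-back warp: out(x) = in(x + v(x)), sample positions clamped to
// the grid (boundary value extension).

static inline double sample_trilinear(const double* f, const int n[3],
                                      double qx, double qy, double qz) {
  if (qx < 0) qx = 0; if (qx > n[0] - 1) qx = n[0] - 1;
  if (qy < 0) qy = 0; if (qy > n[1] - 1) qy = n[1] - 1;
  if (qz < 0) qz = 0; if (qz > n[2] - 1) qz = n[2] - 1;
  int i0 = (int)std::floor(qx); if (i0 > n[0] - 2) i0 = n[0] - 2; if (i0 < 0) i0 = 0;
  int j0 = (int)std::floor(qy); if (j0 > n[1] - 2) j0 = n[1] - 2; if (j0 < 0) j0 = 0;
  int k0 = (int)std::floor(qz); if (k0 > n[2] - 2) k0 = n[2] - 2; if (k0 < 0) k0 = 0;
  const double fx = qx - i0, fy = qy - j0, fz = qz - k0;
  const R_xlen_t nx = n[0], nxy = static_cast<R_xlen_t>(n[0]) * n[1];
  const double* b = f + i0 + nx * j0 + nxy * k0;
  const double c00 = b[0] * (1 - fx) + b[1] * fx;
  const double c10 = b[nx] * (1 - fx) + b[nx + 1] * fx;
  const double c01 = b[nxy] * (1 - fx) + b[nxy + 1] * fx;
  const double c11 = b[nxy + nx] * (1 - fx) + b[nxy + nx + 1] * fx;
  return (c00 * (1 - fy) + c10 * fy) * (1 - fz) + (c01 * (1 - fy) + c11 * fy) * fz;
}

// [[Rcpp::export]]
NumericVector cpp_warp(NumericVector vol, IntegerVector dim,
                       NumericVector dvf, NumericVector spacing) {
  const int n[3] = {dim[0], dim[1], dim[2]};
  const R_xlen_t N = static_cast<R_xlen_t>(n[0]) * n[1] * n[2];
  NumericVector out(N);
  const double* f = vol.begin();
  const double* vx = dvf.begin();
  const double* vy = vx + N;
  const double* vz = vy + N;
  double* o = out.begin();
  R_xlen_t id = 0;
  for (int k = 0; k < n[2]; ++k)
    for (int j = 0; j < n[1]; ++j)
      for (int i = 0; i < n[0]; ++i, ++id) {
        const double qx = i + vx[id] / spacing[0];
        const double qy = j + vy[id] / spacing[1];
        const double qz = k + vz[id] / spacing[2];
        o[id] = sample_trilinear(f, n, qx, qy, qz);
      }
  return out;
}

// Warp plus the exact derivative of the warped value with respect to each
// displacement component (derivative of the trilinear interpolant, 1/mm).
// Zero where the sample position is clamped outside the grid.
// [[Rcpp::export]]
List cpp_warp_jac(NumericVector vol, IntegerVector dim,
                  NumericVector dvf, NumericVector spacing) {
  const int n[3] = {dim[0], dim[1], dim[2]};
  const R_xlen_t N = static_cast<R_xlen_t>(n[0]) * n[1] * n[2];
  NumericVector out(N), gx(N), gy(N), gz(N);
  const double* f = vol.begin();
  const double* vx = dvf.begin();
  const double* vy = vx + N;
  const double* vz = vy + N;
  const R_xlen_t nx = n[0], nxy = static_cast<R_xlen_t>(n[0]) * n[1];
  R_xlen_t id = 0;
  for (int k = 0; k < n[2]; ++k)
    for (int j = 0; j < n[1]; ++j)
      for (int i = 0; i < n[0]; ++i, ++id) {
        double qx = i + vx[id] / spacing[0];
        double qy = j + vy[id] / spacing[1];
        double qz = k + vz[id] / spacing[2];
        const bool cx = qx <= 0 || qx >= n[0] - 1;
        const bool cy = qy <= 0 || qy >= n[1] - 1;
        const bool cz = qz <= 0 || qz >= n[2] - 1;
        if (qx < 0) qx = 0; if (qx > n[0] - 1) qx = n[0] - 1;
        if (qy < 0) qy = 0; if (qy > n[1] - 1) qy = n[1] - 1;
        if (qz < 0) qz = 0; if (qz > n[2] - 1) qz = n[2] - 1;
        int i0 = (int)std::floor(qx); if (i0 > n[0] - 2) i0 = n[0] - 2; if (i0 < 0) i0 = 0;
        int j0 = (int)std::floor(qy); if (j0 > n[1] - 2) j0 = n[1] - 2; if (j0 < 0) j0 = 0;
        int k0 = (int)std::floor(qz); if (k0 > n[2] - 2) k0 = n[2] - 2; if (k0 < 0) k0 = 0;
        const double fx = qx - i0, fy = qy - j0, fz = qz - k0;
        const double* b = f + i0 + nx * j0 + nxy * k0;
        const double f000 = b[0],        f100 = b[1];
        const double f010 = b[nx],       f110 = b[nx + 1];
        const double f001 = b[nxy],      f101 = b[nxy + 1];
        const double f011 = b[nxy + nx], f111 = b[nxy + nx + 1];
        const double c00 = f000 * (1 - fx) + f100 * fx;
        const double c10 = f010 * (1 - fx) + f110 * fx;
        const double c01 = f001 * (1 - fx) + f101 * fx;
        const double c11 = f011 * (1 - fx) + f111 * fx;
        out[id] = (c00 * (1 - fy) + c10 * fy) * (1 - fz) +
                  (c01 * (1 - fy) + c11 * fy) * fz;
        const double dx = ((f100 - f000) * (1 - fy) + (f110 - f010) * fy) * (1 - fz) +
                          ((f101 - f001) * (1 - fy) + (f111 - f011) * fy) * fz;
        const double dy = ((c10 - c00) * (1 - fz) + (c11 - c01) * fz);
        const double dz = ((c01 * (1 - fy) + c11 * fy) - (c00 * (1 - fy) + c10 * fy));
        gx[id] = cx ? 0.0 : dx / spacing[0];
        gy[id] = cy ? 0.0 : dy / spacing[1];
        gz[id] = cz ? 0.0 : dz / spacing[2];
      }
  return List::create(_["value"] = out, _["gx"] = gx, _["gy"] = gy, _["gz"] = gz);
}

// Trilinear resampling to a new grid covering the same physical extent
// (cell-centered alignment).
// [[Rcpp::export]]
NumericVector cpp_resample(NumericVector vol, IntegerVector dim, IntegerVector newdim) {
  const int n[3] = {dim[0], dim[1], dim[2]};
  const int m[3] = {newdim[0], newdim[1], newdim[2]};
  NumericVector out(static_cast<R_xlen_t>(m[0]) * m[1] * m[2]);
  const double* f = vol.begin();
  double* o = out.begin();
  const double sc[3] = {(double)n[0] / m[0], (double)n[1] / m[1], (double)n[2] / m[2]};
  R_xlen_t id = 0;
  for (int k = 0; k < m[2]; ++k) {
    const double qz = (k + 0.5) * sc[2] - 0.5;
    for (int j = 0; j < m[1]; ++j) {
      const double qy = (j + 0.5) * sc[1] - 0.5;
      for (int i = 0; i < m[0]; ++i, ++id) {
        const double qx = (i + 0.5) * sc[0] - 0.5;
        o[id] = sample_trilinear(f, n, qx, qy, qz);
      }
    }
  }
  return out;
}

// Separable Gaussian smoothing, sigma in voxel units per axis, truncated at
// 3 sigma, kernel normalized, replicate boundary.
// [[Rcpp::export]]
NumericVector cpp_gauss3(NumericVector vol, IntegerVector dim, NumericVector sigma_vox) {
  const int n[3] = {dim[0], dim[1], dim[2]};
  const R_xlen_t N = static_cast<R_xlen_t>(n[0]) * n[1] * n[2];
  std::vector<double> cur(vol.begin(), vol.end()), tmp(N);
  const R_xlen_t stride[3] = {1, n[0], static_cast<R_xlen_t>(n[0]) * n[1]};
  for (int a = 0; a < 3; ++a) {
    const double s = sigma_vox[a];
    if (s <= 0) continue;
    const int r = std::max(1, (int)std::ceil(3.0 * s));
    std::vector<double> ker(2 * r + 1);
    double sum = 0;
    for (int t = -r; t <= r; ++t) { ker[t + r] = std::exp(-0.5 * t * t / (s * s)); sum += ker[t + r]; }
    for (double& kv : ker) kv /= sum;
    const int na = n[a];
    const R_xlen_t st = stride[a];
    // iterate over all lines along axis a
    for (R_xlen_t base = 0; base < N; ++base) {
      // base must be the first element of its line along axis a
      R_xlen_t rem = base;
      const R_xlen_t k2 = rem / stride[2]; rem -= k2 * stride[2];
      const R_xlen_t j2 = rem / stride[1]; rem -= j2 * stride[1];
      const R_xlen_t i2 = rem;
      const R_xlen_t coord = (a == 0) ? i2 : (a == 1) ? j2 : k2;
      if (coord != 0) continue;
      for (int p = 0; p < na; ++p) {
        double acc = 0;
        for (int t = -r; t <= r; ++t) {
          int q = p + t;
          if (q < 0) q = 0;
          if (q > na - 1) q = na - 1;
          acc += ker[t + r] * cur[base + st * q];
        }
        tmp[base + st * p] = acc;
      }
    }
    cur.swap(tmp);
  }
  return NumericVector(cur.begin(), cur.end());
}

// ---------------------------------------------------------------------------
// Bilateral DVF regularizer (3x3x3 neighborhood by default).
//
// phi(v) = sum_x sum_{o in nbhd} sum_{i=1..3}
//            Gx(|dx|) * Gmu(mu(x), mu(x+o)) * Gv(v_i(x), v_i(x+o))
//            * ((v_i(x) - v_i(x+o)) / |dx|)^2
// with unnormalized Gaussians G(d) = exp(-d^2 / (2 sigma^2)); center excluded;
// ordered neighbor pairs (both orders counted, as the sum over every center and
// its full neighborhood implies). All sigmas > 0; |dx| in mm.

struct Nbhd {
  std::vector<int> off[3];
  std::vector<double> r2;   // squared distance, mm^2
  std::vector<double> gx;   // spatial kernel value
};

static Nbhd make_nbhd(int hw, const double sp[3], double sigma_x) {
  Nbhd nb;
  for (int oz = -hw; oz <= hw; ++oz)
    for (int oy = -hw; oy <= hw; ++oy)
      for (int ox = -hw; ox <= hw; ++ox) {
        if (ox == 0 && oy == 0 && oz == 0) continue;
        const double r2 = ox * sp[0] * ox * sp[0] + oy * sp[1] * oy * sp[1] +
                          oz * sp[2] * oz * sp[2];
        nb.off[0].push_back(ox); nb.off[1].push_back(oy); nb.off[2].push_back(oz);
        nb.r2.push_back(r2);
        nb.gx.push_back(std::exp(-0.5 * r2 / (sigma_x * sigma_x)));
      }
  return nb;
}

// Precomputed spatial*intensity weights for every (voxel, neighbor) pair:
// N x K matrix (K = (2hw+1)^3 - 1), zero where the neighbor falls outside
// the grid. The weights do not depend on the displacement field, so one
// cache serves every phi/grad evaluation against the same intensity image.
// [[Rcpp::export]]
NumericVector cpp_bilateral_wcache(NumericVector intensity, IntegerVector dim,
                                   NumericVector spacing, double sigma_x,
                                   double sigma_mu, int hw) {
  const int n[3] = {dim[0], dim[1], dim[2]};
  const R_xlen_t N = static_cast<R_xlen_t>(n[0]) * n[1] * n[2];
  const double sp[3] = {spacing[0], spacing[1], spacing[2]};
  Nbhd nb = make_nbhd(hw, sp, sigma_x);
  const int K = (int)nb.r2.size();
  const double* mu = intensity.begin();
  NumericVector out(N * K);
  double* o = out.begin();
  const double inv2smu = 0.5 / (sigma_mu * sigma_mu);
  R_xlen_t id = 0;
  for (int k = 0; k < n[2]; ++k)
    for (int j = 0; j < n[1]; ++j)
      for (int i = 0; i < n[0]; ++i, ++id) {
        for (int t = 0; t < K; ++t) {
          const int i2 = i + nb.off[0][t], j2 = j + nb.off[1][t], k2 = k + nb.off[2][t];
          double w = 0.0;
          if (i2 >= 0 && i2 < n[0] && j2 >= 0 && j2 < n[1] && k2 >= 0 && k2 < n[2]) {
            const R_xlen_t id2 = i2 + static_cast<R_xlen_t>(n[0]) * (j2 + static_cast<R_xlen_t>(n[1]) * k2);
            const double dmu = mu[id] - mu[id2];
            w = nb.gx[t] * std::exp(-dmu * dmu * inv2smu);
          }
          o[id * K + t] = w;
        }
      }
  return out;
}

// [[Rcpp::export]]
double cpp_bilateral_phi_cached(NumericVector dvf, NumericVector wcache,
                                IntegerVector dim, NumericVector spacing,
                                double sigma_x, double sigma_v, int hw) {
  const int n[3] = {dim[0], dim[1], dim[2]};
  const R_xlen_t N = static_cast<R_xlen_t>(n[0]) * n[1] * n[2];
  const double sp[3] = {spacing[0], spacing[1], spacing[2]};
  Nbhd nb = make_nbhd(hw, sp, sigma_x);
  const int K = (int)nb.r2.size();
  const double* v[3] = {dvf.begin(), dvf.begin() + N, dvf.begin() + 2 * N};
  const double* wc = wcache.begin();
  const double inv2sv = 0.5 / (sigma_v * sigma_v);
  double phi = 0.0;
  R_xlen_t id = 0;
  for (int k = 0; k < n[2]; ++k)
    for (int j = 0; j < n[1]; ++j)
      for (int i = 0; i < n[0]; ++i, ++id) {
        for (int t = 0; t < K; ++t) {
          const double wxm = wc[id * K + t];
          if (wxm == 0.0) continue;
          const R_xlen_t id2 = id + nb.off[0][t] +
            static_cast<R_xlen_t>(n[0]) * (nb.off[1][t] + static_cast<R_xlen_t>(n[1]) * nb.off[2][t]);
          for (int c = 0; c < 3; ++c) {
            const double d = v[c][id] - v[c][id2];
            phi += wxm * std::exp(-d * d * inv2sv) * d * d / nb.r2[t];
          }
        }
      }
  return phi;
}

// [[Rcpp::export]]
NumericVector cpp_bilateral_grad_cached(NumericVector dvf, NumericVector wcache,
                                        IntegerVector dim, NumericVector spacing,
                                        double sigma_x, double sigma_v, int hw) {
  const int n[3] = {dim[0], dim[1], dim[2]};
  const R_xlen_t N = static_cast<R_xlen_t>(n[0]) * n[1] * n[2];
  const double sp[3] = {spacing[0], spacing[1], spacing[2]};
  Nbhd nb = make_nbhd(hw, sp, sigma_x);
  const int K = (int)nb.r2.size();
  const double* v[3] = {dvf.begin(), dvf.begin() + N, dvf.begin() + 2 * N};
  const double* wc = wcache.begin();
  NumericVector out(3 * N);
  double* g[3] = {out.begin(), out.begin() + N, out.begin() + 2 * N};
  const double inv2sv = 0.5 / (sigma_v * sigma_v);
  const double invsv2 = 1.0 / (sigma_v * sigma_v);
  R_xlen_t id = 0;
  for (int k = 0; k < n[2]; ++k)
    for (int j = 0; j < n[1]; ++j)
      for (int i = 0; i < n[0]; ++i, ++id) {
        for (int t = 0; t < K; ++t) {
          const double wxm = wc[id * K + t];
          if (wxm == 0.0) continue;
          const R_xlen_t id2 = id + nb.off[0][t] +
            static_cast<R_xlen_t>(n[0]) * (nb.off[1][t] + static_cast<R_xlen_t>(n[1]) * nb.off[2][t]);
          for (int c = 0; c < 3; ++c) {
            const double d = v[c][id] - v[c][id2];
            const double gv = std::exp(-d * d * inv2sv);
            g[c][id] += 2.0 * wxm * gv * (2.0 * d - d * d * d * invsv2) / nb.r2[t];
          }
        }
      }
  return out;
}

// [[Rcpp::export]]
double cpp_bilateral_phi(NumericVector dvf, NumericVector intensity,
                         IntegerVector dim, NumericVector spacing,
                         double sigma_x, double sigma_mu, double sigma_v, int hw) {
  const int n[3] = {dim[0], dim[1], dim[2]};
  const R_xlen_t N = static_cast<R_xlen_t>(n[0]) * n[1] * n[2];
  const double sp[3] = {spacing[0], spacing[1], spacing[2]};
  Nbhd nb = make_nbhd(hw, sp, sigma_x);
  const int K = (int)nb.r2.size();
  const double* mu = intensity.begin();
  const double* v[3] = {dvf.begin(), dvf.begin() + N, dvf.begin() + 2 * N};
  const double inv2smu = 0.5 / (sigma_mu * sigma_mu);
  const double inv2sv = 0.5 / (sigma_v * sigma_v);
  double phi = 0.0;
  R_xlen_t id = 0;
  for (int k = 0; k < n[2]; ++k)
    for (int j = 0; j < n[1]; ++j)
      for (int i = 0; i < n[0]; ++i, ++id) {
        for (int t = 0; t < K; ++t) {
          const int i2 = i + nb.off[0][t], j2 = j + nb.off[1][t], k2 = k + nb.off[2][t];
          if (i2 < 0 || i2 >= n[0] || j2 < 0 || j2 >= n[1] || k2 < 0 || k2 >= n[2])
            continue;
          const R_xlen_t id2 = i2 + static_cast<R_xlen_t>(n[0]) * (j2 + static_cast<R_xlen_t>(n[1]) * k2);
          const double dmu = mu[id] - mu[id2];
          const double wxm = nb.gx[t] * std::exp(-dmu * dmu * inv2smu);
          for (int c = 0; c < 3; ++c) {
            const double d = v[c][id] - v[c][id2];
            phi += wxm * std::exp(-d * d * inv2sv) * d * d / nb.r2[t];
          }
        }
      }
  return phi;
}

// Analytic gradient of cpp_bilateral_phi with respect to every v_i(x).
// For an ordered pair term T = W * gv(d) * d^2 / r^2 with d = v(x) - v(y):
//   dT/dv(x) =  W * gv(d) * (2 d - d^3 / sigma_v^2) / r^2
//   dT/dv(y) = -W * gv(d) * (2 d - d^3 / sigma_v^2) / r^2
// Both orders of each pair appear in the sum, and the mirrored term has the
// same magnitude, so grad(x) accumulates 2 * W * gv(d) * (2d - d^3/sv^2)/r^2
// over in-grid neighbors.
// [[Rcpp::export]]
NumericVector cpp_bilateral_grad(NumericVector dvf, NumericVector intensity,
                                 IntegerVector dim, NumericVector spacing,
                                 double sigma_x, double sigma_mu, double sigma_v,
                                 int hw) {
  const int n[3] = {dim[0], dim[1], dim[2]};
  const R_xlen_t N = static_cast<R_xlen_t>(n[0]) * n[1] * n[2];
  const double sp[3] = {spacing[0], spacing[1], spacing[2]};
  Nbhd nb = make_nbhd(hw, sp, sigma_x);
  const int K = (int)nb.r2.size();
  const double* mu = intensity.begin();
  const double* v[3] = {dvf.begin(), dvf.begin() + N, dvf.begin() + 2 * N};
  NumericVector out(3 * N);
  double* g[3] = {out.begin(), out.begin() + N, out.begin() + 2 * N};
  const double inv2smu = 0.5 / (sigma_mu * sigma_mu);
  const double inv2sv = 0.5 / (sigma_v * sigma_v);
  const double invsv2 = 1.0 / (sigma_v * sigma_v);
  R_xlen_t id = 0;
  for (int k = 0; k < n[2]; ++k)
    for (int j = 0; j < n[1]; ++j)
      for (int i = 0; i < n[0]; ++i, ++id) {
        for (int t = 0; t < K; ++t) {
          const int i2 = i + nb.off[0][t], j2 = j + nb.off[1][t], k2 = k + nb.off[2][t];
          if (i2 < 0 || i2 >= n[0] || j2 < 0 || j2 >= n[1] || k2 < 0 || k2 >= n[2])
            continue;
          const R_xlen_t id2 = i2 + static_cast<R_xlen_t>(n[0]) * (j2 + static_cast<R_xlen_t>(n[1]) * k2);
          const double dmu = mu[id] - mu[id2];
          const double wxm = nb.gx[t] * std::exp(-dmu * dmu * inv2smu);
          for (int c = 0; c < 3; ++c) {
            const double d = v[c][id] - v[c][id2];
            const double gv = std::exp(-d * d * inv2sv);
            g[c][id] += 2.0 * wxm * gv * (2.0 * d - d * d * d * invsv2) / nb.r2[t];
          }
        }
      }
  return out;
}

// Isotropic smoothness penalty (forward differences over the 6-neighbor
// stencil, scaled by spacing) and its exact gradient.
// [[Rcpp::export]]
double cpp_iso_phi(NumericVector dvf, IntegerVector dim, NumericVector spacing) {
  const int n[3] = {dim[0], dim[1], dim[2]};
  const R_xlen_t N = static_cast<R_xlen_t>(n[0]) * n[1] * n[2];
  const R_xlen_t stride[3] = {1, n[0], static_cast<R_xlen_t>(n[0]) * n[1]};
  double phi = 0.0;
  for (int c = 0; c < 3; ++c) {
    const double* v = dvf.begin() + c * N;
    for (int a = 0; a < 3; ++a) {
      const double inv_h = 1.0 / spacing[a];
      const R_xlen_t st = stride[a];
      R_xlen_t id = 0;
      for (int k = 0; k < n[2]; ++k)
        for (int j = 0; j < n[1]; ++j)
          for (int i = 0; i < n[0]; ++i, ++id) {
            const int coord = (a == 0) ? i : (a == 1) ? j : k;
            if (coord >= n[a] - 1) continue;
            const double d = (v[id + st] - v[id]) * inv_h;
            phi += d * d;
          }
    }
  }
  return phi;
}

// [[Rcpp::export]]
NumericVector cpp_iso_grad(NumericVector dvf, IntegerVector dim,
                           NumericVector spacing) {
  const int n[3] = {dim[0], dim[1], dim[2]};
  const R_xlen_t N = static_cast<R_xlen_t>(n[0]) * n[1] * n[2];
  const R_xlen_t stride[3] = {1, n[0], static_cast<R_xlen_t>(n[0]) * n[1]};
  NumericVector out(3 * N);
  for (int c = 0; c < 3; ++c) {
    const double* v = dvf.begin() + c * N;
    double* g = out.begin() + c * N;
    for (int a = 0; a < 3; ++a) {
      const double inv_h2 = 1.0 / (spacing[a] * spacing[a]);
      const R_xlen_t st = stride[a];
      R_xlen_t id = 0;
      for (int k = 0; k < n[2]; ++k)
        for (int j = 0; j < n[1]; ++j)
          for (int i = 0; i < n[0]; ++i, ++id) {
            const int coord = (a == 0) ? i : (a == 1) ? j : k;
            if (coord >= n[a] - 1) continue;
            const double d2 = 2.0 * (v[id + st] - v[id]) * inv_h2;
            g[id] -= d2;
            g[id + st] += d2;
          }
    }
  }
  return out;
}

// 6-connected component labelling of a binary mask; labels 1..L by BFS order.
// [[Rcpp::export]]
IntegerVector cpp_label(LogicalVector mask, IntegerVector dim) {
  const int n[3] = {dim[0], dim[1], dim[2]};
  const R_xlen_t N = static_cast<R_xlen_t>(n[0]) * n[1] * n[2];
  IntegerVector lab(N, 0);
  const R_xlen_t stride[3] = {1, n[0], static_cast<R_xlen_t>(n[0]) * n[1]};
  int next = 0;
  std::queue<R_xlen_t> q;
  for (R_xlen_t s = 0; s < N; ++s) {
    if (!mask[s] || lab[s]) continue;
    lab[s] = ++next;
    q.push(s);
    while (!q.empty()) {
      const R_xlen_t cur = q.front(); q.pop();
      R_xlen_t rem = cur;
      const int ck = (int)(rem / stride[2]); rem -= ck * stride[2];
      const int cj = (int)(rem / stride[1]); rem -= cj * stride[1];
      const int ci = (int)rem;
      const int co[3] = {ci, cj, ck};
      for (int a = 0; a < 3; ++a)
        for (int d = -1; d <= 1; d += 2) {
          const int nc = co[a] + d;
          if (nc < 0 || nc >= n[a]) continue;
          const R_xlen_t nb = cur + d * stride[a];
          if (mask[nb] && !lab[nb]) { lab[nb] = next; q.push(nb); }
        }
    }
  }
  return lab;
}
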