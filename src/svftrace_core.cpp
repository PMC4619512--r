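// Core numerics for the svftrace package.
//
// All coordinates are 0-based voxel coordinates (x, y, z) with voxel centers
// at integer positions; arrays are laid out R-style (x fastest), so the voxel
// (x, y, z) lives at linear index x + nx*(y + ny*z), i.e. R's [x+1, y+1, z+1].
// Samples taken outside the volume read as 0 (flat zero padding).

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
#include <limits>

using namespace Rcpp;

namespace {

struct Dims {
  int nx, ny, nz;
};

Dims get_dims(const NumericVector &vol) {
  IntegerVector d = vol.attr("dim");
  if (d.size() != 3) stop("expected a 3-D array");
  Dims out;
  out.nx = d[0]; out.ny = d[1]; out.nz = d[2];
  return out;
}

inline double at_or_zero(const double *v, const Dims &d, int x, int y, int z) {
  if (x < 0 || y < 0 || z < 0 || x >= d.nx || y >= d.ny || z >= d.nz) return 0.0;
  return v[x + (size_t)d.nx * (y + (size_t)d.ny * z)];
}

// Trilinear interpolation with zero padding outside the volume.
inline double trilinear(const double *v, const Dims &d,
                        double x, double y, double z) {
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
  double fx = x - x0, fy = y - y0, fz = z - z0;
  double c000 = at_or_zero(v, d, x0,     y0,     z0);
  double c100 = at_or_zero(v, d, x0 + 1, y0,     z0);
  double c010 = at_or_zero(v, d, x0,     y0 + 1, z0);
  double c110 = at_or_zero(v, d, x0 + 1, y0 + 1, z0);
  double c001 = at_or_zero(v, d, x0,     y0,     z0 + 1);
  double c101 = at_or_zero(v, d, x0 + 1, y0,     z0 + 1);
  double c011 = at_or_zero(v, d, x0,     y0 + 1, z0 + 1);
  double c111 = at_or_zero(v, d, x0 + 1, y0 + 1, z0 + 1);
  double c00 = c000 * (1 - fx) + c100 * fx;
  double c10 = c010 * (1 - fx) + c110 * fx;
  double c01 = c001 * (1 - fx) + c101 * fx;
  double c11 = c011 * (1 - fx) + c111 * fx;
  double c0 = c00 * (1 - fy) + c10 * fy;
  double c1 = c01 * (1 - fy) + c11 * fy;
  return c0 * (1 - fz) + c1 * fz;
}

const double EPS_GRAD = 1e-6;   // gradient magnitudes below this count as flat

inline double profile_intensity(double rho, double radius, double peak,
                                int profile) {
  if (rho > radius) return 0.0;
  if (profile == 1) return peak;                      // hard binary disk
  double c = std::cos(M_PI * rho / (2.0 * radius));   // cosine falloff
  return peak * c * c;
}

} // namespace

// ---------------------------------------------------------------------------
// Sampling helpers exposed to R
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_sample_trilinear(NumericVector vol, NumericMatrix pts) {
  Dims d = get_dims(vol);
  const double *v = REAL(vol);
  int n = pts.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = trilinear(v, d, pts(i, 0), pts(i, 1), pts(i, 2));
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_sample_vec3(NumericVector fx, NumericVector fy,
                              NumericVector fz, NumericMatrix pts) {
  Dims d = get_dims(fx);
  const double *vx = REAL(fx), *vy = REAL(fy), *vz = REAL(fz);
  int n = pts.nrow();
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i) {
    double x = pts(i, 0), y = pts(i, 1), z = pts(i, 2);
    out(i, 0) = trilinear(vx, d, x, y, z);
    out(i, 1) = trilinear(vy, d, x, y, z);
    out(i, 2) = trilinear(vz, d, x, y, z);
  }
  return out;
}

// ---------------------------------------------------------------------------
// Phantom rendering
// ---------------------------------------------------------------------------

// Render a union of capsule segments (max blend) on a supersampled grid,
// then box-average down to the voxel grid. segs columns: x1 y1 z1 x2 y2 z2 r1 r2
// (per-endpoint radii, linearly interpolated along the segment).
// [[Rcpp::export]]
NumericVector cpp_render_tubes(IntegerVector shape, NumericMatrix segs,
                               double peak, int profile, int ss) {
  int nx = shape[0], ny = shape[1], nz = shape[2];
  int sx = nx * ss, sy = ny * ss, sz = nz * ss;
  std::vector<float> grid((size_t)sx * sy * sz, 0.0f);

  // subsample center (0-based voxel coords) for supersample index i:
  // (i + 0.5)/ss - 0.5
  auto sub2world = [&](int i) { return (i + 0.5) / (double)ss - 0.5; };
  auto world2sub = [&](double w) { return (w + 0.5) * ss - 0.5; };

  int nseg = segs.nrow();
  for (int s = 0; s < nseg; ++s) {
    double x1 = segs(s, 0), y1 = segs(s, 1), z1 = segs(s, 2);
    double x2 = segs(s, 3), y2 = segs(s, 4), z2 = segs(s, 5);
    double r1 = segs(s, 6), r2 = segs(s, 7);
    double rmax = std::max(r1, r2);
    double margin = rmax + 1.0;
    double lox = std::min(x1, x2) - margin, hix = std::max(x1, x2) + margin;
    double loy = std::min(y1, y2) - margin, hiy = std::max(y1, y2) + margin;
    double loz = std::min(z1, z2) - margin, hiz = std::max(z1, z2) + margin;
    int ix0 = std::max(0, (int)std::floor(world2sub(lox)));
    int ix1 = std::min(sx - 1, (int)std::ceil(world2sub(hix)));
    int iy0 = std::max(0, (int)std::floor(world2sub(loy)));
    int iy1 = std::min(sy - 1, (int)std::ceil(world2sub(hiy)));
    int iz0 = std::max(0, (int)std::floor(world2sub(loz)));
    int iz1 = std::min(sz - 1, (int)std::ceil(world2sub(hiz)));
    double ax = x2 - x1, ay = y2 - y1, az = z2 - z1;
    double len2 = ax * ax + ay * ay + az * az;
    for (int iz = iz0; iz <= iz1; ++iz) {
      double wz = sub2world(iz);
      for (int iy = iy0; iy <= iy1; ++iy) {
        double wy = sub2world(iy);
        for (int ix = ix0; ix <= ix1; ++ix) {
          double wx = sub2world(ix);
          double px = wx - x1, py = wy - y1, pz = wz - z1;
          double t = len2 > 0 ? (px * ax + py * ay + pz * az) / len2 : 0.0;
          if (t < 0) t = 0; else if (t > 1) t = 1;
          double dx = px - t * ax, dy = py - t * ay, dz = pz - t * az;
          double rho = std::sqrt(dx * dx + dy * dy + dz * dz);
          double rad = r1 + t * (r2 - r1);
          double val = profile_intensity(rho, rad, peak, profile);
          if (val > 0) {
            size_t idx = ix + (size_t)sx * (iy + (size_t)sy * iz);
            if (val > grid[idx]) grid[idx] = (float)val;
          }
        }
      }
    }
  }

  NumericVector out((size_t)nx * ny * nz);
  out.attr("dim") = shape;
  double norm = 1.0 / (ss * ss * ss);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        double acc = 0.0;
        for (int cz = 0; cz < ss; ++cz)
          for (int cy = 0; cy < ss; ++cy)
            for (int cx = 0; cx < ss; ++cx)
              acc += grid[(size_t)(x * ss + cx) +
                          (size_t)sx * ((y * ss + cy) +
                                        (size_t)sy * (z * ss + cz))];
        out[x + (size_t)nx * (y + (size_t)ny * z)] = acc * norm;
      }
  return out;
}

// Straight tube with an elliptical cross-section (semi-axes a along n1 and b
// along n2), rounded caps; same supersampling scheme as cpp_render_tubes.
// [[Rcpp::export]]
NumericVector cpp_render_elliptic_tube(IntegerVector shape,
                                       NumericVector p1, NumericVector p2,
                                       NumericVector n1, NumericVector n2,
                                       double a, double b, double peak,
                                       int profile, int ss) {
  int nx = shape[0], ny = shape[1], nz = shape[2];
  int sx = nx * ss, sy = ny * ss, sz = nz * ss;
  double ax = p2[0] - p1[0], ay = p2[1] - p1[1], az = p2[2] - p1[2];
  double len2 = ax * ax + ay * ay + az * az;
  double rcap = std::min(a, b);
  NumericVector out((size_t)nx * ny * nz);
  out.attr("dim") = shape;
  double norm = 1.0 / (ss * ss * ss);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        double acc = 0.0;
        for (int cz = 0; cz < ss; ++cz)
          for (int cy = 0; cy < ss; ++cy)
            for (int cx = 0; cx < ss; ++cx) {
              double wx = x + (cx + 0.5) / ss - 0.5;
              double wy = y + (cy + 0.5) / ss - 0.5;
              double wz = z + (cz + 0.5) / ss - 0.5;
              double px = wx - p1[0], py = wy - p1[1], pz = wz - p1[2];
              double t = len2 > 0 ? (px * ax + py * ay + pz * az) / len2 : 0.0;
              if (t < 0) t = 0; else if (t > 1) t = 1;
              double dx = px - t * ax, dy = py - t * ay, dz = pz - t * az;
              double d1 = dx * n1[0] + dy * n1[1] + dz * n1[2];
              double d2 = dx * n2[0] + dy * n2[1] + dz * n2[2];
              // residual along the axis beyond the endpoints (cap region)
              double du = std::sqrt(std::max(
                  0.0, dx * dx + dy * dy + dz * dz - d1 * d1 - d2 * d2));
              double rho = std::sqrt((d1 / a) * (d1 / a) +
                                     (d2 / b) * (d2 / b) +
                                     (du / rcap) * (du / rcap));
              acc += profile_intensity(rho, 1.0, peak, profile);
            }
        out[x + (size_t)nx * (y + (size_t)ny * z)] = acc * norm;
      }
  return out;
}

// ---------------------------------------------------------------------------
// Smoothing and gradients
// ---------------------------------------------------------------------------

// Separable Gaussian smoothing, replicate borders.
// [[Rcpp::export]]
NumericVector cpp_gaussian_smooth(NumericVector vol, double sigma) {
  Dims d = get_dims(vol);
  if (sigma <= 0) return clone(vol);
  int w = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> k(2 * w + 1);
  double s = 0;
  for (int i = -w; i <= w; ++i) {
    k[i + w] = std::exp(-0.5 * i * i / (sigma * sigma));
    s += k[i + w];
  }
  for (double &v : k) v /= s;

  size_t n = (size_t)d.nx * d.ny * d.nz;
  std::vector<double> a(REAL(vol), REAL(vol) + n), b(n);
  auto idx = [&](int x, int y, int z) {
    return (size_t)x + (size_t)d.nx * (y + (size_t)d.ny * z);
  };
  auto clampi = [](int v, int hi) { return v < 0 ? 0 : (v > hi ? hi : v); };
  // x pass
  for (int z = 0; z < d.nz; ++z)
    for (int y = 0; y < d.ny; ++y)
      for (int x = 0; x < d.nx; ++x) {
        double acc = 0;
        for (int i = -w; i <= w; ++i)
          acc += k[i + w] * a[idx(clampi(x + i, d.nx - 1), y, z)];
        b[idx(x, y, z)] = acc;
      }
  // y pass
  for (int z = 0; z < d.nz; ++z)
    for (int y = 0; y < d.ny; ++y)
      for (int x = 0; x < d.nx; ++x) {
        double acc = 0;
        for (int i = -w; i <= w; ++i)
          acc += k[i + w] * b[idx(x, clampi(y + i, d.ny - 1), z)];
        a[idx(x, y, z)] = acc;
      }
  // z pass
  for (int z = 0; z < d.nz; ++z)
    for (int y = 0; y < d.ny; ++y)
      for (int x = 0; x < d.nx; ++x) {
        double acc = 0;
        for (int i = -w; i <= w; ++i)
          acc += k[i + w] * a[idx(x, y, clampi(z + i, d.nz - 1))];
        b[idx(x, y, z)] = acc;
      }
  NumericVector out(b.begin(), b.end());
  out.attr("dim") = vol.attr("dim");
  return out;
}

// Central differences (one-sided at borders) on an already-smoothed volume.
// [[Rcpp::export]]
List cpp_central_gradient(NumericVector vol) {
  Dims d = get_dims(vol);
  const double *v = REAL(vol);
  size_t n = (size_t)d.nx * d.ny * d.nz;
  NumericVector gx(n), gy(n), gz(n);
  gx.attr("dim") = vol.attr("dim");
  gy.attr("dim") = vol.attr("dim");
  gz.attr("dim") = vol.attr("dim");
  auto idx = [&](int x, int y, int z) {
    return (size_t)x + (size_t)d.nx * (y + (size_t)d.ny * z);
  };
  for (int z = 0; z < d.nz; ++z)
    for (int y = 0; y < d.ny; ++y)
      for (int x = 0; x < d.nx; ++x) {
        size_t i = idx(x, y, z);
        int xm = std::max(0, x - 1), xp = std::min(d.nx - 1, x + 1);
        int ym = std::max(0, y - 1), yp = std::min(d.ny - 1, y + 1);
        int zm = std::max(0, z - 1), zp = std::min(d.nz - 1, z + 1);
        gx[i] = (v[idx(xp, y, z)] - v[idx(xm, y, z)]) / (double)(xp - xm);
        gy[i] = (v[idx(x, yp, z)] - v[idx(x, ym, z)]) / (double)(yp - ym);
        gz[i] = (v[idx(x, y, zp)] - v[idx(x, y, zm)]) / (double)(zp - zm);
      }
  return List::create(_["gx"] = gx, _["gy"] = gy, _["gz"] = gz);
}

// ---------------------------------------------------------------------------
// Sliding volume filter
// ---------------------------------------------------------------------------

// SVF response at one (possibly off-grid) point O. dirs is M x 3 (unit rows).
// Band center r runs over the *strict* integer range (rmin, rmax); band
// samples at integer radial offsets rho in [r - d/2, r + d/2].
// [[Rcpp::export]]
double cpp_svf_at(NumericVector gx, NumericVector gy, NumericVector gz,
                  NumericMatrix dirs, NumericVector O,
                  int rmin, int rmax, int dband) {
  Dims d = get_dims(gx);
  const double *vx = REAL(gx), *vy = REAL(gy), *vz = REAL(gz);
  int M = dirs.nrow();
  int h = dband / 2;
  int rlo = rmin + 1, rhi = rmax - 1;
  if (rhi < rlo) stop("empty band-center range");
  int plo = rlo - h, phi = rhi + h;
  int np = phi - plo + 1;
  std::vector<double> vci(np);
  double total = 0.0;
  for (int m = 0; m < M; ++m) {
    double ux = dirs(m, 0), uy = dirs(m, 1), uz = dirs(m, 2);
    for (int p = 0; p < np; ++p) {
      double rho = plo + p;
      double qx = O[0] + rho * ux, qy = O[1] + rho * uy, qz = O[2] + rho * uz;
      double g1 = trilinear(vx, d, qx, qy, qz);
      double g2 = trilinear(vy, d, qx, qy, qz);
      double g3 = trilinear(vz, d, qx, qy, qz);
      double nrm = std::sqrt(g1 * g1 + g2 * g2 + g3 * g3);
      // direction Q -> O is -u
      vci[p] = nrm < EPS_GRAD ? 0.0 : -(g1 * ux + g2 * uy + g3 * uz) / nrm;
    }
    double best = -2.0;
    double bw = 1.0 / (dband + 1);
    for (int r = rlo; r <= rhi; ++r) {
      double acc = 0.0;
      for (int p = r - h - plo; p <= r + h - plo; ++p) acc += vci[p];
      acc *= bw;
      if (acc > best) best = acc;
    }
    total += best;
  }
  return total / M;
}

// SVF response at every voxel whose mask entry is TRUE; others get -1.
// Exploits the fact that for integer voxel centers the fractional parts of
// every radial sample are fixed, so trilinear corner weights are precomputed.
// [[Rcpp::export]]
NumericVector cpp_svf_volume(NumericVector gx, NumericVector gy,
                             NumericVector gz, LogicalVector mask,
                             NumericMatrix dirs, int rmin, int rmax,
                             int dband) {
  Dims d = get_dims(gx);
  const double *vx = REAL(gx), *vy = REAL(gy), *vz = REAL(gz);
  int M = dirs.nrow();
  int h = dband / 2;
  int rlo = rmin + 1, rhi = rmax - 1;
  if (rhi < rlo) stop("empty band-center range");
  int plo = rlo - h, phi = rhi + h;
  int np = phi - plo + 1;

  // Precompute, per (direction, rho): integer corner offset, 8 weights and
  // the (negated) direction for the VCI dot product.
  struct Samp {
    int ox, oy, oz;
    double w[8];
    double ux, uy, uz;
  };
  std::vector<Samp> samp((size_t)M * np);
  for (int m = 0; m < M; ++m) {
    double ux = dirs(m, 0), uy = dirs(m, 1), uz = dirs(m, 2);
    for (int p = 0; p < np; ++p) {
      double rho = plo + p;
      double qx = rho * ux, qy = rho * uy, qz = rho * uz;
      Samp &s = samp[(size_t)m * np + p];
      s.ox = (int)std::floor(qx);
      s.oy = (int)std::floor(qy);
      s.oz = (int)std::floor(qz);
      double fx = qx - s.ox, fy = qy - s.oy, fz = qz - s.oz;
      s.w[0] = (1 - fx) * (1 - fy) * (1 - fz);
      s.w[1] = fx * (1 - fy) * (1 - fz);
      s.w[2] = (1 - fx) * fy * (1 - fz);
      s.w[3] = fx * fy * (1 - fz);
      s.w[4] = (1 - fx) * (1 - fy) * fz;
      s.w[5] = fx * (1 - fy) * fz;
      s.w[6] = (1 - fx) * fy * fz;
      s.w[7] = fx * fy * fz;
      s.ux = ux; s.uy = uy; s.uz = uz;
    }
  }

  size_t n = (size_t)d.nx * d.ny * d.nz;
  NumericVector out(n, -1.0);
  out.attr("dim") = gx.attr("dim");
  std::vector<double> vci(np);
  double bw = 1.0 / (dband + 1);

  for (int z = 0; z < d.nz; ++z)
    for (int y = 0; y < d.ny; ++y)
      for (int x = 0; x < d.nx; ++x) {
        size_t vi = (size_t)x + (size_t)d.nx * (y + (size_t)d.ny * z);
        if (!mask[vi]) continue;
        double total = 0.0;
        for (int m = 0; m < M; ++m) {
          const Samp *sm = &samp[(size_t)m * np];
          for (int p = 0; p < np; ++p) {
            const Samp &s = sm[p];
            int bx = x + s.ox, by = y + s.oy, bz = z + s.oz;
            double g1, g2, g3;
            if (bx >= 0 && by >= 0 && bz >= 0 &&
                bx + 1 < d.nx && by + 1 < d.ny && bz + 1 < d.nz) {
              size_t i0 = (size_t)bx + (size_t)d.nx * (by + (size_t)d.ny * bz);
              size_t dxs = 1, dys = d.nx, dzs = (size_t)d.nx * d.ny;
              g1 = s.w[0] * vx[i0] + s.w[1] * vx[i0 + dxs] +
                   s.w[2] * vx[i0 + dys] + s.w[3] * vx[i0 + dxs + dys] +
                   s.w[4] * vx[i0 + dzs] + s.w[5] * vx[i0 + dxs + dzs] +
                   s.w[6] * vx[i0 + dys + dzs] +
                   s.w[7] * vx[i0 + dxs + dys + dzs];
              g2 = s.w[0] * vy[i0] + s.w[1] * vy[i0 + dxs] +
                   s.w[2] * vy[i0 + dys] + s.w[3] * vy[i0 + dxs + dys] +
                   s.w[4] * vy[i0 + dzs] + s.w[5] * vy[i0 + dxs + dzs] +
                   s.w[6] * vy[i0 + dys + dzs] +
                   s.w[7] * vy[i0 + dxs + dys + dzs];
              g3 = s.w[0] * vz[i0] + s.w[1] * vz[i0 + dxs] +
                   s.w[2] * vz[i0 + dys] + s.w[3] * vz[i0 + dxs + dys] +
                   s.w[4] * vz[i0 + dzs] + s.w[5] * vz[i0 + dxs + dzs] +
                   s.w[6] * vz[i0 + dys + dzs] +
                   s.w[7] * vz[i0 + dxs + dys + dzs];
            } else {
              double qx = x + (plo + p) * s.ux;
              double qy = y + (plo + p) * s.uy;
              double qz = z + (plo + p) * s.uz;
              g1 = trilinear(vx, d, qx, qy, qz);
              g2 = trilinear(vy, d, qx, qy, qz);
              g3 = trilinear(vz, d, qx, qy, qz);
            }
            double nrm = std::sqrt(g1 * g1 + g2 * g2 + g3 * g3);
            vci[p] = nrm < EPS_GRAD
                         ? 0.0
                         : -(g1 * s.ux + g2 * s.uy + g3 * s.uz) / nrm;
          }
          double best = -2.0;
          double acc = 0.0;
          for (int p = 0; p <= 2 * h; ++p) acc += vci[p];
          if (acc * bw > best) best = acc * bw;
          for (int r = rlo + 1; r <= rhi; ++r) {
            acc += vci[r + h - plo] - vci[r - 1 - h - plo];
            if (acc * bw > best) best = acc * bw;
          }
          total += best;
        }
        out[vi] = total / M;
      }
  return out;
}

// ---------------------------------------------------------------------------
// Gradient vector flow
// ---------------------------------------------------------------------------

// Diffusion GVF on the unit-scaled edge map f; returns the field normalized
// to unit vectors (zero where the magnitude is negligible).
// [[Rcpp::export]]
List cpp_gvf(NumericVector f, double mu, int n_iters, double dt) {
  Dims d = get_dims(f);
  List g = cpp_central_gradient(f);
  NumericVector gx = g["gx"], gy = g["gy"], gz = g["gz"];
  size_t n = (size_t)d.nx * d.ny * d.nz;
  std::vector<double> ux(REAL(gx), REAL(gx) + n), uy(REAL(gy), REAL(gy) + n),
      uz(REAL(gz), REAL(gz) + n), b(n);
  for (size_t i = 0; i < n; ++i)
    b[i] = ux[i] * ux[i] + uy[i] * uy[i] + uz[i] * uz[i];
  const double *fx = REAL(gx), *fy = REAL(gy), *fz = REAL(gz);

  auto idx = [&](int x, int y, int z) {
    return (size_t)x + (size_t)d.nx * (y + (size_t)d.ny * z);
  };
  std::vector<double> nx_(n), ny_(n), nz_(n);
  for (int it = 0; it < n_iters; ++it) {
    for (int z = 0; z < d.nz; ++z)
      for (int y = 0; y < d.ny; ++y)
        for (int x = 0; x < d.nx; ++x) {
          size_t i = idx(x, y, z);
          int xm = std::max(0, x - 1), xp = std::min(d.nx - 1, x + 1);
          int ym = std::max(0, y - 1), yp = std::min(d.ny - 1, y + 1);
          int zm = std::max(0, z - 1), zp = std::min(d.nz - 1, z + 1);
          double lx = ux[idx(xm, y, z)] + ux[idx(xp, y, z)] +
                      ux[idx(x, ym, z)] + ux[idx(x, yp, z)] +
                      ux[idx(x, y, zm)] + ux[idx(x, y, zp)] - 6 * ux[i];
          double ly = uy[idx(xm, y, z)] + uy[idx(xp, y, z)] +
                      uy[idx(x, ym, z)] + uy[idx(x, yp, z)] +
                      uy[idx(x, y, zm)] + uy[idx(x, y, zp)] - 6 * uy[i];
          double lz = uz[idx(xm, y, z)] + uz[idx(xp, y, z)] +
                      uz[idx(x, ym, z)] + uz[idx(x, yp, z)] +
                      uz[idx(x, y, zm)] + uz[idx(x, y, zp)] - 6 * uz[i];
          nx_[i] = ux[i] + dt * (mu * lx - (ux[i] - fx[i]) * b[i]);
          ny_[i] = uy[i] + dt * (mu * ly - (uy[i] - fy[i]) * b[i]);
          nz_[i] = uz[i] + dt * (mu * lz - (uz[i] - fz[i]) * b[i]);
        }
    ux.swap(nx_); uy.swap(ny_); uz.swap(nz_);
  }
  NumericVector ox(n), oy(n), oz(n);
  bool bad = false;
  double mmax = 0.0;
  for (size_t i = 0; i < n; ++i) {
    double m2 = ux[i] * ux[i] + uy[i] * uy[i] + uz[i] * uz[i];
    if (!std::isfinite(m2)) { bad = true; break; }
    if (m2 > mmax) mmax = m2;
  }
  if (bad) stop("gradient vector flow diverged (non-finite values)");
  // normalization floor: 1% of the field maximum. Without it the residual
  // numerical noise exactly on a centerline (where opposing flows cancel)
  // would be blown up to unit vectors and bias the snake equilibrium.
  double floor_ = std::max(1e-8, 0.01 * std::sqrt(mmax));
  for (size_t i = 0; i < n; ++i) {
    double m = std::sqrt(ux[i] * ux[i] + uy[i] * uy[i] + uz[i] * uz[i]);
    if (m < floor_) {
      ox[i] = oy[i] = oz[i] = 0.0;
    } else {
      ox[i] = ux[i] / m; oy[i] = uy[i] / m; oz[i] = uz[i] / m;
    }
  }
  ox.attr("dim") = f.attr("dim");
  oy.attr("dim") = f.attr("dim");
  oz.attr("dim") = f.attr("dim");
  return List::create(_["gx"] = ox, _["gy"] = oy, _["gz"] = oz);
}

// ---------------------------------------------------------------------------
// Gaussian-derivative Hessian at a point
// ---------------------------------------------------------------------------

// Returns (Ixx, Iyy, Izz, Ixy, Ixz, Iyz) at an arbitrary (trilinear) point.
// Kernels are exact on quadratics: k0 sums to 1, k1 recovers unit slopes,
// k2 recovers unit second derivatives.
// [[Rcpp::export]]
NumericVector cpp_hessian_at(NumericVector vol, NumericVector p, double sigma) {
  Dims d = get_dims(vol);
  const double *v = REAL(vol);
  int w = std::max(2, (int)std::ceil(3.0 * sigma));
  int nk = 2 * w + 1;
  std::vector<double> k0(nk), k1(nk), k2(nk);
  double s0 = 0;
  for (int i = -w; i <= w; ++i) {
    k0[i + w] = std::exp(-0.5 * i * i / (sigma * sigma));
    s0 += k0[i + w];
  }
  for (int i = 0; i < nk; ++i) k0[i] /= s0;
  double s1 = 0;
  for (int i = -w; i <= w; ++i) {
    k1[i + w] = i * k0[i + w];
    s1 += i * k1[i + w];
  }
  for (int i = 0; i < nk; ++i) k1[i] /= s1;
  double m2 = 0;
  for (int i = -w; i <= w; ++i)
    k2[i + w] = (i * i / (sigma * sigma) - 1.0) * k0[i + w];
  for (int i = 0; i < nk; ++i) m2 += k2[i];
  for (int i = 0; i < nk; ++i) k2[i] -= m2 / nk;
  double s2 = 0;
  for (int i = -w; i <= w; ++i) s2 += k2[i + w] * i * i / 2.0;
  for (int i = 0; i < nk; ++i) k2[i] /= s2;

  double hxx = 0, hyy = 0, hzz = 0, hxy = 0, hxz = 0, hyz = 0;
  for (int kz = -w; kz <= w; ++kz)
    for (int ky = -w; ky <= w; ++ky)
      for (int kx = -w; kx <= w; ++kx) {
        double val = trilinear(v, d, p[0] + kx, p[1] + ky, p[2] + kz);
        if (val == 0.0) continue;
        int ix = kx + w, iy = ky + w, iz = kz + w;
        hxx += val * k2[ix] * k0[iy] * k0[iz];
        hyy += val * k0[ix] * k2[iy] * k0[iz];
        hzz += val * k0[ix] * k0[iy] * k2[iz];
        hxy += val * k1[ix] * k1[iy] * k0[iz];
        hxz += val * k1[ix] * k0[iy] * k1[iz];
        hyz += val * k0[ix] * k1[iy] * k1[iz];
      }
  return NumericVector::create(hxx, hyy, hzz, hxy, hxz, hyz);
}

// ---------------------------------------------------------------------------
// Sliding band filter rays (radius estimation)
// ---------------------------------------------------------------------------

// For each of n in-plane rays u_k = cos(theta_k) v2 + sin(theta_k) v3 with
// theta_k = 2*pi*k/n, return the band-center radius maximizing the mean VCI
// (measured toward the center) and that response. Ties break to smaller r.
// [[Rcpp::export]]
NumericMatrix cpp_sbf_rays(NumericVector gx, NumericVector gy,
                           NumericVector gz, NumericVector center,
                           NumericVector v2, NumericVector v3, int n,
                           int rmin, int rmax, int dband) {
  Dims d = get_dims(gx);
  const double *ax = REAL(gx), *ay = REAL(gy), *az = REAL(gz);
  int h = dband / 2;
  int rlo = rmin + 1, rhi = rmax - 1;
  if (rhi < rlo) stop("empty band-center range");
  int plo = rlo - h, phi = rhi + h;
  int np = phi - plo + 1;
  NumericMatrix out(n, 2);
  std::vector<double> vci(np);
  double bw = 1.0 / (dband + 1);
  for (int kdir = 0; kdir < n; ++kdir) {
    double th = 2.0 * M_PI * kdir / n;
    double ux = std::cos(th) * v2[0] + std::sin(th) * v3[0];
    double uy = std::cos(th) * v2[1] + std::sin(th) * v3[1];
    double uz = std::cos(th) * v2[2] + std::sin(th) * v3[2];
    for (int p = 0; p < np; ++p) {
      double rho = plo + p;
      double qx = center[0] + rho * ux;
      double qy = center[1] + rho * uy;
      double qz = center[2] + rho * uz;
      double g1 = trilinear(ax, d, qx, qy, qz);
      double g2 = trilinear(ay, d, qx, qy, qz);
      double g3 = trilinear(az, d, qx, qy, qz);
      double nrm = std::sqrt(g1 * g1 + g2 * g2 + g3 * g3);
      vci[p] = nrm < EPS_GRAD ? 0.0
                              : -(g1 * ux + g2 * uy + g3 * uz) / nrm;
    }
    double best = -2.0;
    int bestr = rlo;
    for (int r = rlo; r <= rhi; ++r) {
      double acc = 0.0;
      for (int p = r - h - plo; p <= r + h - plo; ++p) acc += vci[p];
      acc *= bw;
      if (acc > best + 1e-15) { best = acc; bestr = r; }
    }
    out(kdir, 0) = bestr;
    out(kdir, 1) = best;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Nearest-neighbour distances (uniform-grid spatial index)
// ---------------------------------------------------------------------------

// Exact nearest-neighbour Euclidean distance from each query row to the
// reference point set.
// [[Rcpp::export]]
NumericVector cpp_nn_dist(NumericMatrix query, NumericMatrix ref) {
  int nq = query.nrow(), nr = ref.nrow();
  if (nr == 0) stop("empty reference point set");
  NumericVector out(nq);
  if (nr <= 64) { // brute force for tiny sets
    for (int i = 0; i < nq; ++i) {
      double best = std::numeric_limits<double>::infinity();
      for (int j = 0; j < nr; ++j) {
        double dx = query(i, 0) - ref(j, 0);
        double dy = query(i, 1) - ref(j, 1);
        double dz = query(i, 2) - ref(j, 2);
        double dd = dx * dx + dy * dy + dz * dz;
        if (dd < best) best = dd;
      }
      out[i] = std::sqrt(best);
    }
    return out;
  }
  double lo[3], hi[3];
  for (int c = 0; c < 3; ++c) {
    lo[c] = hi[c] = ref(0, c);
    for (int j = 1; j < nr; ++j) {
      lo[c] = std::min(lo[c], ref(j, c));
      hi[c] = std::max(hi[c], ref(j, c));
    }
  }
  double ext = std::max({hi[0] - lo[0], hi[1] - lo[1], hi[2] - lo[2], 1e-9});
  double cell = std::max(ext / std::cbrt((double)nr), 1e-9);
  int gx = std::max(1, (int)std::floor((hi[0] - lo[0]) / cell) + 1);
  int gy = std::max(1, (int)std::floor((hi[1] - lo[1]) / cell) + 1);
  int gz = std::max(1, (int)std::floor((hi[2] - lo[2]) / cell) + 1);
  std::vector<std::vector<int>> buckets((size_t)gx * gy * gz);
  auto cellof = [&](double x, double y, double z, int &cx, int &cy, int &cz) {
    cx = std::min(gx - 1, std::max(0, (int)std::floor((x - lo[0]) / cell)));
    cy = std::min(gy - 1, std::max(0, (int)std::floor((y - lo[1]) / cell)));
    cz = std::min(gz - 1, std::max(0, (int)std::floor((z - lo[2]) / cell)));
  };
  for (int j = 0; j < nr; ++j) {
    int cx, cy, cz;
    cellof(ref(j, 0), ref(j, 1), ref(j, 2), cx, cy, cz);
    buckets[cx + (size_t)gx * (cy + (size_t)gy * cz)].push_back(j);
  }
  int kmax = gx + gy + gz + 2;
  for (int i = 0; i < nq; ++i) {
    double qx = query(i, 0), qy = query(i, 1), qz = query(i, 2);
    int cx, cy, cz;
    cellof(qx, qy, qz, cx, cy, cz);
    double best = std::numeric_limits<double>::infinity();
    for (int k = 0; k <= kmax; ++k) {
      if (k > 0 && (double)(k - 1) * cell > std::sqrt(best)) break;
      bool any = false;
      for (int dz2 = -k; dz2 <= k; ++dz2) {
        int zc = cz + dz2;
        if (zc < 0 || zc >= gz) continue;
        for (int dy2 = -k; dy2 <= k; ++dy2) {
          int yc = cy + dy2;
          if (yc < 0 || yc >= gy) continue;
          for (int dx2 = -k; dx2 <= k; ++dx2) {
            if (std::max({std::abs(dx2), std::abs(dy2), std::abs(dz2)}) != k)
              continue;
            int xc = cx + dx2;
            if (xc < 0 || xc >= gx) continue;
            any = true;
            for (int j : buckets[xc + (size_t)gx * (yc + (size_t)gy * zc)]) {
              double ddx = qx - ref(j, 0);
              double ddy = qy - ref(j, 1);
              double ddz = qz - ref(j, 2);
              double dd = ddx * ddx + ddy * ddy + ddz * ddz;
              if (dd < best) best = dd;
            }
          }
        }
      }
      if (!any && std::isfinite(best)) break;
      if (!any && k > kmax) break;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}
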