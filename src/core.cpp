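#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>
using namespace Rcpp;

// Conventions shared with the R layer:
//  - cubic volumes, side n (even); voxel (0-based) index i maps to the
//    physical coordinate i - n/2, so the rotation/projection centre sits at
//    voxel n/2 in every axis;
//  - images are n x n matrices with the same centring;
//  - rotation matrices are passive ZYZ frames: camera = A * object, the
//    projection integrates along the camera z axis;
//  - an in-plane shift (x, y) moves the projected object by (+x, +y) pixels,
//    i.e. the image is the unshifted projection sampled at (u - x, v - y);
//  - out-of-support samples are zero.

static inline double tri(const double *v, int n, double x, double y, double z) {
  if (x < 0.0 || y < 0.0 || z < 0.0 ||
      x > n - 1.0 || y > n - 1.0 || z > n - 1.0)
    return 0.0;
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
  if (x0 == n - 1) x0--;
  if (y0 == n - 1) y0--;
  if (z0 == n - 1) z0--;
  double fx = x - x0, fy = y - y0, fz = z - z0;
  const double *p = v + (size_t)z0 * n * n + (size_t)y0 * n + x0;
  size_t sy = n, sz = (size_t)n * n;
  double c00 = p[0] * (1 - fx) + p[1] * fx;
  double c10 = p[sy] * (1 - fx) + p[sy + 1] * fx;
  double c01 = p[sz] * (1 - fx) + p[sz + 1] * fx;
  double c11 = p[sz + sy] * (1 - fx) + p[sz + sy + 1] * fx;
  double c0 = c00 * (1 - fy) + c10 * fy;
  double c1 = c01 * (1 - fy) + c11 * fy;
  return c0 * (1 - fz) + c1 * fz;
}

static inline double bil(const double *m, int n, double x, double y) {
  if (x < 0.0 || y < 0.0 || x > n - 1.0 || y > n - 1.0)
    return 0.0;
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y);
  if (x0 == n - 1) x0--;
  if (y0 == n - 1) y0--;
  double fx = x - x0, fy = y - y0;
  const double *p = m + (size_t)y0 * n + x0;
  double c0 = p[0] * (1 - fx) + p[1] * fx;
  double c1 = p[n] * (1 - fx) + p[n + 1] * fx;
  return c0 * (1 - fy) + c1 * fy;
}

// Single-pass affine resample: out(r) = in(Rinv * (r - t - c) + c), with r in
// centred coordinates.  If out_r > 0, only output voxels within out_r of
// (c + t) are computed (support restriction for compact densities).
// [[Rcpp::export]]
NumericVector cpp_affine_sample(NumericVector vol, int n, NumericMatrix Rinv,
                                NumericVector t, NumericVector c,
                                double out_r) {
  NumericVector out((size_t)n * n * n);
  const double *v = REAL(vol);
  double *o = REAL(out);
  double n2 = n / 2.0;
  double R[9];
  for (int j = 0; j < 3; j++)
    for (int i = 0; i < 3; i++) R[3 * j + i] = Rinv(i, j); // column-major
  double cx = c[0], cy = c[1], cz = c[2];
  double tx = t[0], ty = t[1], tz = t[2];
  double ox = cx + tx, oy = cy + ty, oz = cz + tz;
  double r2 = out_r > 0 ? out_r * out_r : -1.0;
  for (int k = 0; k < n; k++) {
    double pz = k - n2;
    for (int j = 0; j < n; j++) {
      double py = j - n2;
      double *row = o + (size_t)k * n * n + (size_t)j * n;
      for (int i = 0; i < n; i++) {
        double px = i - n2;
        if (r2 > 0) {
          double dx = px - ox, dy = py - oy, dz = pz - oz;
          if (dx * dx + dy * dy + dz * dz > r2) continue;
        }
        double qx = px - tx - cx, qy = py - ty - cy, qz = pz - tz - cz;
        double sx = R[0] * qx + R[3] * qy + R[6] * qz + cx;
        double sy = R[1] * qx + R[4] * qy + R[7] * qz + cy;
        double sz = R[2] * qx + R[5] * qy + R[8] * qz + cz;
        row[i] = tri(v, n, sx + n2, sy + n2, sz + n2);
      }
    }
  }
  return out;
}

// Projection along the camera z axis: img(u,v) = sum_w vol(A^T (u-x, v-y, w)).
// support_r: radius of the bounding sphere of the nonzero density around the
// box centre (<= 0 disables the restriction; integration then covers the
// n axial steps).  The w range guaranteed inside the voxel box is computed
// per pixel so the inner loop needs no bounds checks.
// [[Rcpp::export]]
NumericMatrix cpp_project(NumericVector vol, int n, NumericMatrix A,
                          double x, double y, double support_r) {
  NumericMatrix img(n, n);
  const double *v = REAL(vol);
  double n2 = n / 2.0;
  // object = A^T * camera; rows of A^T are columns of A
  double a0x = A(0, 0), a0y = A(0, 1), a0z = A(0, 2); // first row of A
  double a1x = A(1, 0), a1y = A(1, 1), a1z = A(1, 2);
  double a2x = A(2, 0), a2y = A(2, 1), a2z = A(2, 2);
  double R = support_r > 0 ? support_r + 1.5 : -1.0;
  const size_t sy = n, sz = (size_t)n * n;
  for (int j = 0; j < n; j++) {
    double vv = j - n2 - y;
    for (int i = 0; i < n; i++) {
      double uu = i - n2 - x;
      double w0 = -n2, w1 = n2 - 1.0;
      if (R > 0) {
        double rho2 = uu * uu + vv * vv;
        if (rho2 > R * R) continue;
        double h = std::sqrt(R * R - rho2);
        if (-h > w0) w0 = -h;
        if (h < w1) w1 = h;
      }
      // object coords (voxel units, 0-based): base + w * step
      double bx = a0x * uu + a1x * vv + n2;
      double by = a0y * uu + a1y * vv + n2;
      double bz = a0z * uu + a1z * vv + n2;
      // clip w so every trilinear neighbourhood stays inside [0, n-1]
      double lo = w0, hi = w1;
      const double st[3] = {a2x, a2y, a2z};
      const double bs[3] = {bx, by, bz};
      bool empty = false;
      for (int a = 0; a < 3 && !empty; a++) {
        if (std::fabs(st[a]) < 1e-12) {
          if (bs[a] < 0.0 || bs[a] > n - 1.0) empty = true;
        } else {
          double t0 = (0.0 - bs[a]) / st[a];
          double t1 = (n - 1.0 - 1e-9 - bs[a]) / st[a];
          if (t0 > t1) std::swap(t0, t1);
          if (t0 > lo) lo = t0;
          if (t1 < hi) hi = t1;
        }
      }
      if (empty) { img(i, j) = 0.0; continue; }
      int wlo = (int)std::ceil(lo), whi = (int)std::floor(hi);
      double s = 0.0;
      double px = bx + a2x * wlo, py = by + a2y * wlo, pz = bz + a2z * wlo;
      for (int w = wlo; w <= whi; w++) {
        int x0 = (int)px, y0 = (int)py, z0 = (int)pz;
        double fx = px - x0, fy = py - y0, fz = pz - z0;
        const double *p = v + (size_t)z0 * sz + (size_t)y0 * sy + x0;
        double c00 = p[0] + (p[1] - p[0]) * fx;
        double c10 = p[sy] + (p[sy + 1] - p[sy]) * fx;
        double c01 = p[sz] + (p[sz + 1] - p[sz]) * fx;
        double c11 = p[sz + sy] + (p[sz + sy + 1] - p[sz + sy]) * fx;
        double c0 = c00 + (c10 - c00) * fy;
        double c1 = c01 + (c11 - c01) * fy;
        s += c0 + (c1 - c0) * fz;
        px += a2x; py += a2y; pz += a2z;
      }
      img(i, j) = s;
    }
  }
  return img;
}

// In-plane rotation by psi degrees about the image centre; exactly the
// resampling induced by A(psi) = Rz(psi) A(0):
// out(u,v) = in(u cos - v sin, u sin + v cos).
// [[Rcpp::export]]
NumericMatrix cpp_rotate_image(NumericMatrix img, double psi_deg) {
  int n = img.nrow();
  NumericMatrix out(n, n);
  const double *m = REAL(img);
  double n2 = n / 2.0;
  double a = psi_deg * M_PI / 180.0;
  double cs = std::cos(a), sn = std::sin(a);
  for (int j = 0; j < n; j++) {
    double v = j - n2;
    for (int i = 0; i < n; i++) {
      double u = i - n2;
      double u0 = u * cs - v * sn;
      double v0 = u * sn + v * cs;
      out(i, j) = bil(m, n, u0 + n2, v0 + n2);
    }
  }
  return out;
}

// out(u,v) = in(u - dx, v - dy): the object moves by (+dx, +dy).
// [[Rcpp::export]]
NumericMatrix cpp_shift_image(NumericMatrix img, double dx, double dy) {
  int n = img.nrow();
  NumericMatrix out(n, n);
  const double *m = REAL(img);
  for (int j = 0; j < n; j++)
    for (int i = 0; i < n; i++)
      out(i, j) = bil(m, n, i - dx, j - dy);
  return out;
}

// Accumulate one ramp-filtered image into the reconstruction:
// acc(p) += img((A p)_x, (A p)_y).  acc is modified in place.
// [[Rcpp::export]]
void cpp_backproject(NumericMatrix img, int n, NumericMatrix A,
                     NumericVector acc) {
  const double *m = REAL(img);
  double *o = REAL(acc);
  double n2 = n / 2.0;
  double a00 = A(0, 0), a01 = A(0, 1), a02 = A(0, 2);
  double a10 = A(1, 0), a11 = A(1, 1), a12 = A(1, 2);
  for (int k = 0; k < n; k++) {
    double pz = k - n2;
    for (int j = 0; j < n; j++) {
      double py = j - n2;
      double *row = o + (size_t)k * n * n + (size_t)j * n;
      for (int i = 0; i < n; i++) {
        double px = i - n2;
        double u = a00 * px + a01 * py + a02 * pz;
        double v = a10 * px + a11 * py + a12 * pz;
        row[i] += bil(m, n, u + n2, v + n2);
      }
    }
  }
}

// Weighted cross-correlation coefficient; NA if either weighted variance is
// not positive.
// [[Rcpp::export]]
double cpp_wccc(NumericVector a, NumericVector b, NumericVector w) {
  size_t m = a.size();
  double sw = 0, sa = 0, sb = 0, saa = 0, sbb = 0, sab = 0;
  for (size_t i = 0; i < m; i++) {
    double wi = w[i];
    if (wi <= 0) continue;
    double x = a[i], y = b[i];
    sw += wi; sa += wi * x; sb += wi * y;
    saa += wi * x * x; sbb += wi * y * y; sab += wi * x * y;
  }
  if (sw <= 0) return NA_REAL;
  double va = saa - sa * sa / sw, vb = sbb - sb * sb / sw;
  double eps = 1e-12 * (saa + sbb + 1e-300);
  if (va <= eps || vb <= eps) return NA_REAL;
  return (sab - sa * sb / sw) / std::sqrt(va * vb);
}

// Masked-CCC scores for one candidate direction of one particle, over the
// in-plane rotation grid x integer shift offsets.
//  exp, rem : experimental image and fixed non-target projection (n x n)
//  proj     : target projection at this direction, psi = 0, zero shift
//             (already CTF-modulated if applicable)
//  psis     : absolute in-plane angles to evaluate
//  basex/y  : fractional base shift applied to the target projection
//  offx/y   : integer shift offsets (pixels) added on top of the base
//  widx     : 0-based linear indices of mask pixels; wval their weights
// Returns scores indexed ((p * nsy + iy) * nsx + ix); degenerate masked
// variance yields NA.
// [[Rcpp::export]]
NumericVector cpp_score_psi_shift(NumericMatrix expimg, NumericMatrix rem,
                                  NumericMatrix proj, NumericVector psis,
                                  double basex, double basey,
                                  IntegerVector offx, IntegerVector offy,
                                  IntegerVector widx, NumericVector wval) {
  int n = expimg.nrow();
  int np = psis.size(), nsx = offx.size(), nsy = offy.size();
  int m = widx.size();
  NumericVector scores((size_t)np * nsy * nsx);
  std::vector<int> mi(m), mj(m);
  std::vector<double> w(m), ev(m), rv(m);
  const double *em = REAL(expimg), *rm = REAL(rem);
  double sw = 0, se = 0, see = 0, sr = 0, srr = 0, ser = 0;
  for (int t = 0; t < m; t++) {
    int id = widx[t];
    mi[t] = id % n; mj[t] = id / n;
    w[t] = wval[t];
    ev[t] = em[id]; rv[t] = rm[id];
    sw += w[t]; se += w[t] * ev[t]; see += w[t] * ev[t] * ev[t];
    sr += w[t] * rv[t]; srr += w[t] * rv[t] * rv[t];
    ser += w[t] * ev[t] * rv[t];
  }
  double ve = see - se * se / sw;
  size_t idx = 0;
  for (int p = 0; p < np; p++) {
    NumericMatrix sh = proj;
    if (psis[p] != 0.0) sh = cpp_rotate_image(sh, psis[p]);
    if (basex != 0.0 || basey != 0.0) sh = cpp_shift_image(sh, basex, basey);
    const double *sm = REAL(sh);
    for (int iy = 0; iy < nsy; iy++) {
      int oy = offy[iy];
      for (int ix = 0; ix < nsx; ix++, idx++) {
        int ox = offx[ix];
        double st = 0, stt = 0, srt = 0, set = 0;
        for (int t = 0; t < m; t++) {
          int i0 = mi[t] - ox, j0 = mj[t] - oy;
          double tv = (i0 >= 0 && i0 < n && j0 >= 0 && j0 < n)
                          ? sm[(size_t)j0 * n + i0]
                          : 0.0;
          double wt = w[t];
          st += wt * tv;
          stt += wt * tv * tv;
          srt += wt * rv[t] * tv;
          set += wt * ev[t] * tv;
        }
        double sc = st + sr;
        double scc = stt + 2.0 * srt + srr;
        double sec = set + ser;
        double vc = scc - sc * sc / sw;
        double eps = 1e-12 * (scc + see + 1e-300);
        if (ve <= eps || vc <= eps) {
          scores[idx] = NA_REAL;
        } else {
          scores[idx] = (sec - se * sc / sw) / std::sqrt(ve * vc);
        }
      }
    }
  }
  return scores;
}

// 1D squared Euclidean distance transform (Felzenszwalb & Huttenlocher),
// applied in place along one axis of a 3D field via strides.
static void edt1d(std::vector<double> &f, std::vector<double> &d,
                  std::vector<int> &v, std::vector<double> &z, int n) {
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; q++) {
    double s;
    while (true) {
      s = ((f[q] + q * q) - (f[v[k]] + v[k] * v[k])) / (2.0 * q - 2.0 * v[k]);
      if (s <= z[k]) k--; else break;
    }
    k++;
    v[k] = q;
    z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    while (z[k + 1] < q) k++;
    d[q] = (q - v[k]) * (double)(q - v[k]) + f[v[k]];
  }
}

// Squared Euclidean distance (in voxels) to the nearest voxel where
// mask > 0.5, over a cubic grid of side n.
// [[Rcpp::export]]
NumericVector cpp_edt3(NumericVector mask, int n) {
  size_t nn = (size_t)n * n * n;
  NumericVector out(nn);
  const double big = 1e12;
  for (size_t i = 0; i < nn; i++)
    out[i] = mask[i] > 0.5 ? 0.0 : big;
  std::vector<double> f(n), d(n), z(n + 1);
  std::vector<int> v(n);
  double *o = REAL(out);
  // x axis
  for (int k = 0; k < n; k++)
    for (int j = 0; j < n; j++) {
      double *line = o + (size_t)k * n * n + (size_t)j * n;
      for (int i = 0; i < n; i++) f[i] = line[i];
      edt1d(f, d, v, z, n);
      for (int i = 0; i < n; i++) line[i] = d[i];
    }
  // y axis
  for (int k = 0; k < n; k++)
    for (int i = 0; i < n; i++) {
      double *base = o + (size_t)k * n * n + i;
      for (int j = 0; j < n; j++) f[j] = base[(size_t)j * n];
      edt1d(f, d, v, z, n);
      for (int j = 0; j < n; j++) base[(size_t)j * n] = d[j];
    }
  // z axis
  for (int j = 0; j < n; j++)
    for (int i = 0; i < n; i++) {
      double *base = o + (size_t)j * n + i;
      for (int k = 0; k < n; k++) f[k] = base[(size_t)k * n * n];
      edt1d(f, d, v, z, n);
      for (int k = 0; k < n; k++) base[(size_t)k * n * n] = d[k];
    }
  return out;
}
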