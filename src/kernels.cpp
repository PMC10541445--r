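#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <cstring>
using namespace Rcpp;

// quaternion (w,x,y,z) -> rotation matrix, row-major 3x3
static inline void quat_to_mat(const double *q, double *M) {
  double w = q[0], x = q[1], y = q[2], z = q[3];
  M[0] = 1 - 2 * (y * y + z * z); M[1] = 2 * (x * y - w * z); M[2] = 2 * (x * z + w * y);
  M[3] = 2 * (x * y + w * z); M[4] = 1 - 2 * (x * x + z * z); M[5] = 2 * (y * z - w * x);
  M[6] = 2 * (x * z - w * y); M[7] = 2 * (y * z + w * x); M[8] = 1 - 2 * (x * x + y * y);
}

static inline void quat_mult(const double *a, const double *b, double *out) {
  out[0] = a[0] * b[0] - a[1] * b[1] - a[2] * b[2] - a[3] * b[3];
  out[1] = a[0] * b[1] + a[1] * b[0] + a[2] * b[3] - a[3] * b[2];
  out[2] = a[0] * b[2] - a[1] * b[3] + a[2] * b[0] + a[3] * b[1];
  out[3] = a[0] * b[3] + a[1] * b[2] - a[2] * b[1] + a[3] * b[0];
}

// trilinear gather from cubic volume (edge^3, column-major x fastest),
// coordinates in voxel units relative to the center voxel
static inline double trilin_get(const double *vol, int edge, double gx, double gy,
                                double gz) {
  double c = (edge - 1) / 2.0;
  double fx = gx + c, fy = gy + c, fz = gz + c;
  int x0 = (int)std::floor(fx), y0 = (int)std::floor(fy), z0 = (int)std::floor(fz);
  if (x0 < 0 || y0 < 0 || z0 < 0 || x0 > edge - 2 || y0 > edge - 2 || z0 > edge - 2)
    return NA_REAL;
  double dx = fx - x0, dy = fy - y0, dz = fz - z0;
  const double *v = vol;
  size_t e = edge, e2 = (size_t)edge * edge;
  size_t base = (size_t)x0 + e * y0 + e2 * z0;
  double c00 = v[base] * (1 - dx) + v[base + 1] * dx;
  double c10 = v[base + e] * (1 - dx) + v[base + e + 1] * dx;
  double c01 = v[base + e2] * (1 - dx) + v[base + e2 + 1] * dx;
  double c11 = v[base + e2 + e] * (1 - dx) + v[base + e2 + e + 1] * dx;
  double c0 = c00 * (1 - dy) + c10 * dy;
  double c1 = c01 * (1 - dy) + c11 * dy;
  return c0 * (1 - dz) + c1 * dz;
}

// [[Rcpp::export]]
NumericMatrix cpp_expand(NumericVector vol, int edge, NumericMatrix qcoords,
                         NumericMatrix quats) {
  int npix = qcoords.nrow(), nrot = quats.nrow();
  NumericMatrix out(npix, nrot);
  const double *v = REAL(vol);
  const double *qc = &qcoords(0, 0);
  for (int r = 0; r < nrot; ++r) {
    double M[9], q[4] = {quats(r, 0), quats(r, 1), quats(r, 2), quats(r, 3)};
    quat_to_mat(q, M);
    double *col = &out(0, r);
    for (int t = 0; t < npix; ++t) {
      double ux = qc[t], uy = qc[t + npix], uz = qc[t + 2 * npix];
      double gx = M[0] * ux + M[1] * uy + M[2] * uz;
      double gy = M[3] * ux + M[4] * uy + M[5] * uz;
      double gz = M[6] * ux + M[7] * uy + M[8] * uz;
      double val = trilin_get(v, edge, gx, gy, gz);
      if (ISNA(val)) stop("pixel q outside volume support");
      col[t] = val < 0 ? 0 : val;
    }
  }
  return out;
}

// adjoint of expand: deposit tomogram pixels into voxels with trilinear weights
// [[Rcpp::export]]
List cpp_compress(NumericMatrix tomo, int edge, NumericMatrix qcoords,
                  NumericMatrix quats) {
  int npix = qcoords.nrow(), nrot = quats.nrow();
  size_t nvox = (size_t)edge * edge * edge;
  NumericVector num(nvox), wt(nvox);
  double *pn = REAL(num), *pw = REAL(wt);
  double c = (edge - 1) / 2.0;
  size_t e = edge, e2 = (size_t)edge * edge;
  for (int r = 0; r < nrot; ++r) {
    double M[9], q[4] = {quats(r, 0), quats(r, 1), quats(r, 2), quats(r, 3)};
    quat_to_mat(q, M);
    const double *col = &tomo(0, r);
    for (int t = 0; t < npix; ++t) {
      double ux = qcoords(t, 0), uy = qcoords(t, 1), uz = qcoords(t, 2);
      double fx = M[0] * ux + M[1] * uy + M[2] * uz + c;
      double fy = M[3] * ux + M[4] * uy + M[5] * uz + c;
      double fz = M[6] * ux + M[7] * uy + M[8] * uz + c;
      int x0 = (int)std::floor(fx), y0 = (int)std::floor(fy), z0 = (int)std::floor(fz);
      if (x0 < 0 || y0 < 0 || z0 < 0 || x0 > edge - 2 || y0 > edge - 2 ||
          z0 > edge - 2)
        stop("pixel q outside volume support");
      double dx = fx - x0, dy = fy - y0, dz = fz - z0;
      double val = col[t];
      size_t base = (size_t)x0 + e * y0 + e2 * z0;
      double w000 = (1 - dx) * (1 - dy) * (1 - dz), w100 = dx * (1 - dy) * (1 - dz);
      double w010 = (1 - dx) * dy * (1 - dz), w110 = dx * dy * (1 - dz);
      double w001 = (1 - dx) * (1 - dy) * dz, w101 = dx * (1 - dy) * dz;
      double w011 = (1 - dx) * dy * dz, w111 = dx * dy * dz;
      pn[base] += w000 * val; pw[base] += w000;
      pn[base + 1] += w100 * val; pw[base + 1] += w100;
      pn[base + e] += w010 * val; pw[base + e] += w010;
      pn[base + e + 1] += w110 * val; pw[base + e + 1] += w110;
      pn[base + e2] += w001 * val; pw[base + e2] += w001;
      pn[base + e2 + 1] += w101 * val; pw[base + e2 + 1] += w101;
      pn[base + e2 + e] += w011 * val; pw[base + e2 + e] += w011;
      pn[base + e2 + e + 1] += w111 * val; pw[base + e2 + e + 1] += w111;
    }
  }
  return List::create(Named("num") = num, Named("wt") = wt);
}

// resample volume under active rotation of the object: out(x) = vol(R^T x)
// [[Rcpp::export]]
NumericVector cpp_rotate_volume(NumericVector vol, int edge, NumericVector quat) {
  double M[9], q[4] = {quat[0], quat[1], quat[2], quat[3]};
  quat_to_mat(q, M);
  size_t nvox = (size_t)edge * edge * edge;
  NumericVector out(nvox);
  const double *v = REAL(vol);
  double c = (edge - 1) / 2.0;
  size_t idx = 0;
  for (int z = 0; z < edge; ++z)
    for (int y = 0; y < edge; ++y)
      for (int x = 0; x < edge; ++x, ++idx) {
        double ux = x - c, uy = y - c, uz = z - c;
        // R^T x
        double gx = M[0] * ux + M[3] * uy + M[6] * uz;
        double gy = M[1] * ux + M[4] * uy + M[7] * uz;
        double gz = M[2] * ux + M[5] * uy + M[8] * uz;
        double val = trilin_get(v, edge, gx, gy, gz);
        out[idx] = ISNA(val) ? 0.0 : (val < 0 ? 0 : val);
      }
  return out;
}

// Pearson correlation of sqrt(vol resampled at R^T x) against precomputed
// sqrt reference values, over a fixed list of voxel-centre offsets
// [[Rcpp::export]]
NumericVector cpp_align_corr(NumericVector vol, int edge, NumericMatrix coords,
                             NumericVector sqrtRef, NumericMatrix quats) {
  int n = coords.nrow(), nrot = quats.nrow();
  NumericVector out(nrot);
  const double *v = REAL(vol);
  double refMean = 0, refSS = 0;
  for (int i = 0; i < n; ++i) refMean += sqrtRef[i];
  refMean /= n;
  for (int i = 0; i < n; ++i) {
    double d = sqrtRef[i] - refMean;
    refSS += d * d;
  }
  std::vector<double> buf(n);
  for (int r = 0; r < nrot; ++r) {
    double M[9], q[4] = {quats(r, 0), quats(r, 1), quats(r, 2), quats(r, 3)};
    quat_to_mat(q, M);
    double m = 0;
    for (int i = 0; i < n; ++i) {
      double ux = coords(i, 0), uy = coords(i, 1), uz = coords(i, 2);
      double gx = M[0] * ux + M[3] * uy + M[6] * uz;
      double gy = M[1] * ux + M[4] * uy + M[7] * uz;
      double gz = M[2] * ux + M[5] * uy + M[8] * uz;
      double val = trilin_get(v, edge, gx, gy, gz);
      if (ISNA(val) || val < 0) val = 0;
      buf[i] = std::sqrt(val);
      m += buf[i];
    }
    m /= n;
    double sxy = 0, sxx = 0;
    for (int i = 0; i < n; ++i) {
      double dx = buf[i] - m;
      sxx += dx * dx;
      sxy += dx * (sqrtRef[i] - refMean);
    }
    out[r] = (sxx > 0 && refSS > 0) ? sxy / std::sqrt(sxx * refSS) : 0.0;
  }
  return out;
}

// evaluate per-species scattering factors at given |q| (crystallographic
// s = q/2 convention); ff is a list of list(ab = k x 2 matrix, c = scalar)
static void eval_ff(const List &ff, const std::vector<double> &qmag,
                    std::vector<std::vector<double> > &fvals) {
  int nspec = ff.size(), m = qmag.size();
  fvals.assign(nspec, std::vector<double>(m));
  for (int e = 0; e < nspec; ++e) {
    List le = ff[e];
    NumericMatrix ab = le["ab"];
    double cc = as<double>(le["c"]);
    int k = ab.nrow();
    for (int i = 0; i < m; ++i) {
      double s2 = qmag[i] * 0.5;
      s2 *= s2;
      double f = cc;
      for (int g = 0; g < k; ++g) f += ab(g, 0) * std::exp(-ab(g, 1) * s2);
      fvals[e][i] = f;
    }
  }
}

// ideal intensity volume: I(q) = |sum_j s_j f_j(|q|) exp(2 pi i q.r_j)|^2
// on a cubic grid of odd edge, voxel size dq, center voxel = q = 0.
// Uses separable per-axis phase tables (cubic grid) per atom.
// [[Rcpp::export]]
NumericVector cpp_ideal_volume(NumericMatrix pos, NumericVector scale,
                               IntegerVector elemIdx, List ff, int edge,
                               double dq) {
  int natom = pos.nrow(), nspec = ff.size();
  size_t nvox = (size_t)edge * edge * edge;
  double c = (edge - 1) / 2.0;
  // per-voxel |q| (only need radial profile per species on unique radii: use
  // full per-voxel evaluation, cheap relative to the phase accumulation)
  std::vector<double> qmag(nvox);
  {
    size_t idx = 0;
    for (int z = 0; z < edge; ++z)
      for (int y = 0; y < edge; ++y)
        for (int x = 0; x < edge; ++x, ++idx) {
          double qx = (x - c) * dq, qy = (y - c) * dq, qz = (z - c) * dq;
          qmag[idx] = std::sqrt(qx * qx + qy * qy + qz * qz);
        }
  }
  std::vector<std::vector<double> > fvals;
  eval_ff(ff, qmag, fvals);
  std::vector<double> Are(nvox, 0.0), Aim(nvox, 0.0);
  std::vector<double> cx(edge), sx(edge), cy(edge), sy(edge), cz(edge), sz(edge);
  std::vector<double> Fre(nvox), Fim(nvox);
  for (int e = 0; e < nspec; ++e) {
    bool any = false;
    std::fill(Fre.begin(), Fre.end(), 0.0);
    std::fill(Fim.begin(), Fim.end(), 0.0);
    for (int j = 0; j < natom; ++j) {
      if (elemIdx[j] != e) continue;
      any = true;
      double sj = scale[j];
      for (int x = 0; x < edge; ++x) {
        double px = 2 * M_PI * (x - c) * dq * pos(j, 0);
        cx[x] = std::cos(px); sx[x] = std::sin(px);
        double py = 2 * M_PI * (x - c) * dq * pos(j, 1);
        cy[x] = std::cos(py); sy[x] = std::sin(py);
        double pz = 2 * M_PI * (x - c) * dq * pos(j, 2);
        cz[x] = std::cos(pz); sz[x] = std::sin(pz);
      }
      size_t idx = 0;
      for (int z = 0; z < edge; ++z) {
        double czz = cz[z], szz = sz[z];
        for (int y = 0; y < edge; ++y) {
          // exp(i(py+pz))
          double cyz = cy[y] * czz - sy[y] * szz;
          double syz = sy[y] * czz + cy[y] * szz;
          for (int x = 0; x < edge; ++x, ++idx) {
            double re = cx[x] * cyz - sx[x] * syz;
            double im = sx[x] * cyz + cx[x] * syz;
            Fre[idx] += sj * re;
            Fim[idx] += sj * im;
          }
        }
      }
    }
    if (!any) continue;
    const std::vector<double> &fv = fvals[e];
    for (size_t i = 0; i < nvox; ++i) {
      Are[i] += fv[i] * Fre[i];
      Aim[i] += fv[i] * Fim[i];
    }
  }
  NumericVector out(nvox);
  for (size_t i = 0; i < nvox; ++i) out[i] = Are[i] * Are[i] + Aim[i] * Aim[i];
  return out;
}

// exact atom-path slice: expected intensity per pixel at each orientation,
// pattern at orientation Omega samples the reference-frame transform at
// R(Omega) q_t
// [[Rcpp::export]]
NumericMatrix cpp_slice_atoms(NumericMatrix pos, NumericVector scale,
                              IntegerVector elemIdx, List ff, NumericMatrix qvec,
                              NumericMatrix quats) {
  int natom = pos.nrow(), npix = qvec.nrow(), nrot = quats.nrow();
  std::vector<double> qmag(npix);
  for (int t = 0; t < npix; ++t)
    qmag[t] = std::sqrt(qvec(t, 0) * qvec(t, 0) + qvec(t, 1) * qvec(t, 1) +
                        qvec(t, 2) * qvec(t, 2));
  std::vector<std::vector<double> > fvals;
  eval_ff(ff, qmag, fvals);
  NumericMatrix out(npix, nrot);
  for (int r = 0; r < nrot; ++r) {
    double M[9], q[4] = {quats(r, 0), quats(r, 1), quats(r, 2), quats(r, 3)};
    quat_to_mat(q, M);
    for (int t = 0; t < npix; ++t) {
      double ux = qvec(t, 0), uy = qvec(t, 1), uz = qvec(t, 2);
      double gx = M[0] * ux + M[1] * uy + M[2] * uz;
      double gy = M[3] * ux + M[4] * uy + M[5] * uz;
      double gz = M[6] * ux + M[7] * uy + M[8] * uz;
      double re = 0, im = 0;
      for (int j = 0; j < natom; ++j) {
        double ph = 2 * M_PI * (gx * pos(j, 0) + gy * pos(j, 1) + gz * pos(j, 2));
        double fj = fvals[elemIdx[j]][t] * scale[j];
        re += fj * std::cos(ph);
        im += fj * std::sin(ph);
      }
      out(t, r) = re * re + im * im;
    }
  }
  return out;
}

// sequential dart-throwing water placement.  Accepts a point when its
// distance to the nearest solute atom lies in [contact, contact + thickness]
// and it keeps min_separation from previously accepted waters.  A first
// phase of darts estimates the shell volume by the hit fraction; acceptance
// then stops at targetDensity * volume (or at jamming, whichever is lower).
// [[Rcpp::export]]
NumericMatrix cpp_place_waters(NumericMatrix solute, double contact,
                               double thickness, double minSep, int nAttempts,
                               double targetDensity) {
  int ns = solute.nrow();
  double lo[3], hi[3];
  for (int d = 0; d < 3; ++d) {
    lo[d] = R_PosInf;
    hi[d] = R_NegInf;
    for (int j = 0; j < ns; ++j) {
      lo[d] = std::min(lo[d], solute(j, d));
      hi[d] = std::max(hi[d], solute(j, d));
    }
    lo[d] -= contact + thickness;
    hi[d] += contact + thickness;
  }
  double cell = std::max(minSep, 1e-6);
  int nx[3];
  for (int d = 0; d < 3; ++d)
    nx[d] = std::max(1, (int)std::ceil((hi[d] - lo[d]) / cell));
  // cell list over solute atoms with cell size contact+thickness for nearest-
  // distance queries
  double scell = contact + thickness;
  int sx[3];
  for (int d = 0; d < 3; ++d)
    sx[d] = std::max(1, (int)std::ceil((hi[d] - lo[d]) / scell));
  std::vector<std::vector<int> > sbins((size_t)sx[0] * sx[1] * sx[2]);
  for (int j = 0; j < ns; ++j) {
    int ix = std::min(sx[0] - 1, std::max(0, (int)((solute(j, 0) - lo[0]) / scell)));
    int iy = std::min(sx[1] - 1, std::max(0, (int)((solute(j, 1) - lo[1]) / scell)));
    int iz = std::min(sx[2] - 1, std::max(0, (int)((solute(j, 2) - lo[2]) / scell)));
    sbins[ix + (size_t)sx[0] * (iy + (size_t)sx[1] * iz)].push_back(j);
  }
  std::vector<std::vector<int> > wbins((size_t)nx[0] * nx[1] * nx[2]);
  std::vector<double> wx, wy, wz;
  double lo2 = contact * contact, hi2 = (contact + thickness) * (contact + thickness);
  double ms2 = minSep * minSep;
  double boxVol = (hi[0] - lo[0]) * (hi[1] - lo[1]) * (hi[2] - lo[2]);
  long nShellHits = 0;
  int phase1 = std::max(20000, nAttempts / 20);
  long target = -1;  // unknown until the volume estimate is in
  for (int a = 0; a < nAttempts; ++a) {
    if (a == phase1 && targetDensity > 0) {
      double vhat = boxVol * (double)nShellHits / phase1;
      target = (long)std::floor(targetDensity * vhat + 0.5);
      if ((long)wx.size() >= target) break;
    }
    if (target >= 0 && (long)wx.size() >= target) break;
    double p[3];
    for (int d = 0; d < 3; ++d) p[d] = lo[d] + unif_rand() * (hi[d] - lo[d]);
    // nearest solute distance (squared), early exit if below contact
    double best = R_PosInf;
    int ix = std::min(sx[0] - 1, std::max(0, (int)((p[0] - lo[0]) / scell)));
    int iy = std::min(sx[1] - 1, std::max(0, (int)((p[1] - lo[1]) / scell)));
    int iz = std::min(sx[2] - 1, std::max(0, (int)((p[2] - lo[2]) / scell)));
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          int jx = ix + dx, jy = iy + dy, jz = iz + dz;
          if (jx < 0 || jy < 0 || jz < 0 || jx >= sx[0] || jy >= sx[1] ||
              jz >= sx[2])
            continue;
          const std::vector<int> &b =
              sbins[jx + (size_t)sx[0] * (jy + (size_t)sx[1] * jz)];
          for (size_t k = 0; k < b.size(); ++k) {
            int j = b[k];
            double ddx = p[0] - solute(j, 0), ddy = p[1] - solute(j, 1),
                   ddz = p[2] - solute(j, 2);
            double d2 = ddx * ddx + ddy * ddy + ddz * ddz;
            if (d2 < best) best = d2;
          }
        }
    if (!(best >= lo2 && best <= hi2)) continue;
    ++nShellHits;
    // min separation against accepted waters
    int wix = std::min(nx[0] - 1, std::max(0, (int)((p[0] - lo[0]) / cell)));
    int wiy = std::min(nx[1] - 1, std::max(0, (int)((p[1] - lo[1]) / cell)));
    int wiz = std::min(nx[2] - 1, std::max(0, (int)((p[2] - lo[2]) / cell)));
    bool ok = true;
    for (int dz = -1; dz <= 1 && ok; ++dz)
      for (int dy = -1; dy <= 1 && ok; ++dy)
        for (int dx = -1; dx <= 1 && ok; ++dx) {
          int jx = wix + dx, jy = wiy + dy, jz = wiz + dz;
          if (jx < 0 || jy < 0 || jz < 0 || jx >= nx[0] || jy >= nx[1] ||
              jz >= nx[2])
            continue;
          const std::vector<int> &b =
              wbins[jx + (size_t)nx[0] * (jy + (size_t)nx[1] * jz)];
          for (size_t k = 0; k < b.size(); ++k) {
            int j = b[k];
            double ddx = p[0] - wx[j], ddy = p[1] - wy[j], ddz = p[2] - wz[j];
            if (ddx * ddx + ddy * ddy + ddz * ddz < ms2) {
              ok = false;
              break;
            }
          }
        }
    if (!ok) continue;
    wbins[wix + (size_t)nx[0] * (wiy + (size_t)nx[1] * wiz)].push_back(wx.size());
    wx.push_back(p[0]);
    wy.push_back(p[1]);
    wz.push_back(p[2]);
  }
  int nw = wx.size();
  NumericMatrix out(nw, 3);
  for (int i = 0; i < nw; ++i) {
    out(i, 0) = wx[i];
    out(i, 1) = wy[i];
    out(i, 2) = wz[i];
  }
  return out;
}

// sparse part of the Poisson log-likelihood: out(r, d) = sum_t K_td log
// tomoT(r, t); K passed as dgCMatrix slots (column = pattern), tomoT is the
// R x Npix log-tomogram matrix
// [[Rcpp::export]]
NumericMatrix cpp_spmm_ll(IntegerVector Kp, IntegerVector Ki, NumericVector Kx,
                          int npat, NumericMatrix logTomoT) {
  int nrot = logTomoT.nrow();
  NumericMatrix out(nrot, npat);
  const double *__restrict lt = &logTomoT(0, 0);
  double *po = &out(0, 0);
  const int *kp = INTEGER(Kp), *ki = INTEGER(Ki);
  const double *kx = REAL(Kx);
  const int CH = 512;  // rotation blocking keeps tomogram slices cache-hot
  for (int c0 = 0; c0 < nrot; c0 += CH) {
    int cl = std::min(CH, nrot - c0);
    for (int d = 0; d < npat; ++d) {
      double *__restrict col = po + (size_t)nrot * d + c0;
      for (int p = kp[d]; p < kp[d + 1]; ++p) {
        int t = ki[p];
        double k = kx[p];
        const double *__restrict src = lt + (size_t)nrot * t + c0;
        for (int r = 0; r < cl; ++r) col[r] += k * src[r];
      }
    }
  }
  return out;
}

// tomogram update numerator: out(r, t) = sum_d P(r, d) K_td
// [[Rcpp::export]]
NumericMatrix cpp_spmm_update(IntegerVector Kp, IntegerVector Ki, NumericVector Kx,
                              int npat, NumericMatrix P, int npix) {
  int nrot = P.nrow();
  NumericMatrix out(nrot, npix);
  const double *pp = &P(0, 0);
  double *po = &out(0, 0);
  const int *kp = INTEGER(Kp), *ki = INTEGER(Ki);
  const double *kx = REAL(Kx);
  const int CH = 512;
  for (int c0 = 0; c0 < nrot; c0 += CH) {
    int cl = std::min(CH, nrot - c0);
    for (int d = 0; d < npat; ++d) {
      const double *__restrict pcol = pp + (size_t)nrot * d + c0;
      for (int p = kp[d]; p < kp[d + 1]; ++p) {
        int t = ki[p];
        double k = kx[p];
        double *__restrict dst = po + (size_t)nrot * t + c0;
        for (int r = 0; r < cl; ++r) dst[r] += k * pcol[r];
      }
    }
  }
  return out;
}

// in-place tempered softmax over rotations (rows) per pattern (column):
// A(r, d) <- normalized exp(beta * A(r, d) + offset(r)); returns the
// per-pattern log-normalizer log sum_r exp(beta A + offset)
// [[Rcpp::export]]
NumericVector cpp_softmax_cols(NumericMatrix A, double beta, NumericVector offset) {
  int nrot = A.nrow(), npat = A.ncol();
  NumericVector ll(npat);
  double *pa = &A(0, 0);
  for (int d = 0; d < npat; ++d) {
    double *col = pa + (size_t)nrot * d;
    double m = R_NegInf;
    for (int r = 0; r < nrot; ++r) {
      col[r] = beta * col[r] + offset[r];
      if (col[r] > m) m = col[r];
    }
    double s = 0;
    for (int r = 0; r < nrot; ++r) {
      col[r] = std::exp(col[r] - m);
      s += col[r];
    }
    for (int r = 0; r < nrot; ++r) col[r] /= s;
    ll[d] = m + std::log(s);
  }
  return ll;
}

// [[Rcpp::export]]
NumericMatrix cpp_log_transpose(NumericMatrix tomo, double floorVal) {
  int npix = tomo.nrow(), nrot = tomo.ncol();
  NumericMatrix out(nrot, npix);
  for (int r = 0; r < nrot; ++r)
    for (int t = 0; t < npix; ++t) {
      double v = tomo(t, r);
      out(r, t) = std::log(v > floorVal ? v : floorVal);
    }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_transpose(NumericMatrix x) {
  int n = x.nrow(), m = x.ncol();
  NumericMatrix out(m, n);
  for (int j = 0; j < m; ++j)
    for (int i = 0; i < n; ++i) out(j, i) = x(i, j);
  return out;
}

// fused EMC expectation-maximization step.  Single-precision internals for
// the two sparse products (the responsibilities are ratios of like
// quantities; float precision is ample), double-precision normalizers.
// Returns the updated tomograms, per-pattern log-evidence, most probable
// rotation (1-based), responsibility entropy and optionally the full
// responsibility matrix.
// [[Rcpp::export]]
List cpp_emc_step(NumericMatrix tomo, IntegerVector Kp, IntegerVector Ki,
                  NumericVector Kx, int npat, double beta,
                  NumericVector offset, double floorVal,
                  bool wantResponsibilities) {
  int npix = tomo.nrow(), nrot = tomo.ncol();
  const double *pt = &tomo(0, 0);
  std::vector<float> logTf((size_t)nrot * npix);
  const int B = 64;  // blocked transpose
  for (int tb = 0; tb < npix; tb += B)
    for (int rb = 0; rb < nrot; rb += B) {
      int tmax = std::min(tb + B, npix), rmax = std::min(rb + B, nrot);
      for (int t = tb; t < tmax; ++t)
        for (int r = rb; r < rmax; ++r) {
          double v = pt[(size_t)npix * r + t];
          logTf[(size_t)nrot * t + r] = logf((float)(v > floorVal ? v : floorVal));
        }
    }
  std::vector<float> L((size_t)nrot * npat, 0.0f);
  const int *kp = INTEGER(Kp), *ki = INTEGER(Ki);
  const double *kx = REAL(Kx);
  const int CH = 1024;
  for (int c0 = 0; c0 < nrot; c0 += CH) {
    int cl = std::min(CH, nrot - c0);
    for (int d = 0; d < npat; ++d) {
      float *__restrict col = &L[(size_t)nrot * d + c0];
      for (int p = kp[d]; p < kp[d + 1]; ++p) {
        float k = (float)kx[p];
        const float *__restrict src = &logTf[(size_t)nrot * ki[p] + c0];
        for (int r = 0; r < cl; ++r) col[r] += k * src[r];
      }
    }
  }
  NumericVector ll(npat), ent(npat);
  IntegerVector best(npat);
  const double *off = REAL(offset);
  for (int d = 0; d < npat; ++d) {
    float *__restrict col = &L[(size_t)nrot * d];
    double m = R_NegInf; int bi = 0;
    for (int r = 0; r < nrot; ++r) {
      double a = beta * (double)col[r] + off[r];
      if (a > m) { m = a; bi = r; }
    }
    double s = 0;
    for (int r = 0; r < nrot; ++r) {
      double p = std::exp(beta * (double)col[r] + off[r] - m);
      col[r] = p > 1e-30 ? (float)p : 0.0f;  // flush: avoids float denormals
      s += p;
    }
    double e = 0;
    double inv = 1.0 / s;
    for (int r = 0; r < nrot; ++r) {
      double p = (double)col[r] * inv;
      col[r] = p > 1e-30 ? (float)p : 0.0f;
      if (p > 1e-30) e -= p * std::log(p);
    }
    ll[d] = m + std::log(s);
    ent[d] = e;
    best[d] = bi + 1;
  }
  // tomogram update: W_rt = sum_d P K / sum_d P
  std::vector<float> numT((size_t)nrot * npix, 0.0f);
  std::vector<double> denom(nrot, 0.0);
  for (int d = 0; d < npat; ++d) {
    const float *__restrict pcol = &L[(size_t)nrot * d];
    for (int r = 0; r < nrot; ++r) denom[r] += (double)pcol[r];
  }
  for (int c0 = 0; c0 < nrot; c0 += CH) {
    int cl = std::min(CH, nrot - c0);
    for (int d = 0; d < npat; ++d) {
      const float *__restrict pcol = &L[(size_t)nrot * d + c0];
      for (int p = kp[d]; p < kp[d + 1]; ++p) {
        float k = (float)kx[p];
        float *__restrict dst = &numT[(size_t)nrot * ki[p] + c0];
        for (int r = 0; r < cl; ++r) dst[r] += k * pcol[r];
      }
    }
  }
  NumericMatrix tomoNew(npix, nrot);
  double *pn = &tomoNew(0, 0);
  for (int tb = 0; tb < npix; tb += B)
    for (int rb = 0; rb < nrot; rb += B) {
      int tmax = std::min(tb + B, npix), rmax = std::min(rb + B, nrot);
      for (int r = rb; r < rmax; ++r) {
        double dn = denom[r] > 1e-300 ? 1.0 / denom[r] : 0.0;
        for (int t = tb; t < tmax; ++t)
          pn[(size_t)npix * r + t] = (double)numT[(size_t)nrot * t + r] * dn;
      }
    }
  List out = List::create(Named("tomograms") = tomoNew, Named("ll") = ll,
                          Named("best") = best, Named("entropy") = ent);
  if (wantResponsibilities) {
    NumericMatrix P(nrot, npat);
    double *pp = &P(0, 0);
    for (size_t i = 0; i < (size_t)nrot * npat; ++i) pp[i] = (double)L[i];
    out["responsibilities"] = P;
  }
  return out;
}

// orientation-disconcurrence double sum.  For candidate overall orientation
// qc (applied on the right of the A-support rotations as Omega_A^{-1}) and
// each sentinel, computes
//   Theta^2 = sum_{i in A} sum_{j in B} wA_i wB_j
//             min_{sigma in s, zeta in z} theta(sigma (qA_i qc) zeta, qB_j)^2
// Supports are ragged: qA holds all sentinels' support quaternions stacked,
// offA (length S+1) gives the 0-based slice per sentinel.
// [[Rcpp::export]]
NumericMatrix cpp_theta_sq(NumericMatrix cand, NumericMatrix qA, NumericVector wA,
                           IntegerVector offA, NumericMatrix qB, NumericVector wB,
                           IntegerVector offB, NumericMatrix sQ, NumericMatrix zQ) {
  int ncand = cand.nrow(), nsent = offA.size() - 1;
  int ns = sQ.nrow(), nz = zQ.nrow(), ncomb = ns * nz;
  NumericMatrix out(ncand, nsent);
  std::vector<double> trans;  // ncomb * mA * 4
  for (int c = 0; c < ncand; ++c) {
    double qc[4] = {cand(c, 0), cand(c, 1), cand(c, 2), cand(c, 3)};
    for (int k = 0; k < nsent; ++k) {
      int a0 = offA[k], a1 = offA[k + 1], b0 = offB[k], b1 = offB[k + 1];
      int mA = a1 - a0, mB = b1 - b0;
      trans.assign((size_t)ncomb * mA * 4, 0.0);
      for (int i = 0; i < mA; ++i) {
        double ai[4] = {qA(a0 + i, 0), qA(a0 + i, 1), qA(a0 + i, 2), qA(a0 + i, 3)};
        double aiq[4];
        quat_mult(ai, qc, aiq);
        for (int si = 0; si < ns; ++si) {
          double sg[4] = {sQ(si, 0), sQ(si, 1), sQ(si, 2), sQ(si, 3)};
          double sa[4];
          quat_mult(sg, aiq, sa);
          for (int zi = 0; zi < nz; ++zi) {
            double zt[4] = {zQ(zi, 0), zQ(zi, 1), zQ(zi, 2), zQ(zi, 3)};
            double *dst = &trans[(((size_t)(si * nz + zi) * mA) + i) * 4];
            quat_mult(sa, zt, dst);
          }
        }
      }
      double acc = 0;
      for (int j = 0; j < mB; ++j) {
        double bj[4] = {qB(b0 + j, 0), qB(b0 + j, 1), qB(b0 + j, 2), qB(b0 + j, 3)};
        double wj = wB[b0 + j];
        for (int i = 0; i < mA; ++i) {
          double mx = 0;
          for (int cb = 0; cb < ncomb; ++cb) {
            const double *a = &trans[(((size_t)cb * mA) + i) * 4];
            double dot = std::fabs(a[0] * bj[0] + a[1] * bj[1] + a[2] * bj[2] +
                                   a[3] * bj[3]);
            if (dot > mx) mx = dot;
          }
          if (mx > 1) mx = 1;
          double th = 2 * std::acos(mx);
          acc += wA[a0 + i] * wj * th * th;
        }
      }
      out(c, k) = acc;
    }
  }
  return out;
}
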