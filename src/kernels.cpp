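#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Conventions (shared with the R side, see ?cryovertex):
//  * volumes are cubic arrays indexed [x, y, z]; the physical centre sits at
//    0-based voxel index N/2 along each axis (integer division, N even).
//  * a pose rotation R maps reference-frame coordinates to the laboratory
//    frame; a particle with pose R shows the density V(R^T r).
//  * projections integrate along the laboratory z axis; in-plane shifts
//    (in pixels here) move the projected feature towards +x/+y.

static inline double keys(double t);

static inline void scatter2(NumericMatrix &out, int N, double qx, double qy,
                            double val) {
  int ix = (int)std::floor(qx), iy = (int)std::floor(qy);
  double fx = qx - ix, fy = qy - iy;
  // bilinear scatter with per-corner bounds checks so that points landing
  // exactly on the last row/column are kept
  double w;
  if (ix >= 0 && ix < N && iy >= 0 && iy < N) {
    w = (1 - fx) * (1 - fy); if (w != 0) out(ix, iy) += val * w;
  }
  if (ix + 1 >= 0 && ix + 1 < N && iy >= 0 && iy < N) {
    w = fx * (1 - fy); if (w != 0) out(ix + 1, iy) += val * w;
  }
  if (ix >= 0 && ix < N && iy + 1 >= 0 && iy + 1 < N) {
    w = (1 - fx) * fy; if (w != 0) out(ix, iy + 1) += val * w;
  }
  if (ix + 1 >= 0 && ix + 1 < N && iy + 1 >= 0 && iy + 1 < N) {
    w = fx * fy; if (w != 0) out(ix + 1, iy + 1) += val * w;
  }
}

// Project a (possibly cropped) volume along laboratory z by trilinear
// scattering of every non-zero voxel into the image plane.
// offset: position of the cropped volume's centre voxel relative to the
// full-volume centre, in voxels.
// [[Rcpp::export]]
NumericMatrix cpp_project(NumericVector vol, NumericMatrix Rmat,
                          NumericVector offset, int outN,
                          double sx, double sy) {
  IntegerVector d = vol.attr("dim");
  int nx = d[0], ny = d[1], nz = d[2];
  int cx = nx / 2, cy = ny / 2, cz = nz / 2, co = outN / 2;
  NumericMatrix out(outN, outN);
  double r00 = Rmat(0, 0), r01 = Rmat(0, 1), r02 = Rmat(0, 2);
  double r10 = Rmat(1, 0), r11 = Rmat(1, 1), r12 = Rmat(1, 2);
  double ox = offset[0], oy = offset[1], oz = offset[2];
  const double *v = vol.begin();
  for (int k = 0; k < nz; k++) {
    double pz = k - cz + oz;
    for (int j = 0; j < ny; j++) {
      double py = j - cy + oy;
      size_t base = (size_t)k * nx * ny + (size_t)j * nx;
      for (int i = 0; i < nx; i++) {
        double val = v[base + i];
        if (val == 0.0) continue;
        double px = i - cx + ox;
        double qx = r00 * px + r01 * py + r02 * pz + co + sx;
        double qy = r10 * px + r11 * py + r12 * pz + co + sy;
        scatter2(out, outN, qx, qy, val);
      }
    }
  }
  return out;
}

static inline double gather3(const double *v, int N, double x, double y,
                             double z) {
  // trilinear gather, zero outside
  int ix = (int)std::floor(x), iy = (int)std::floor(y), iz = (int)std::floor(z);
  double fx = x - ix, fy = y - iy, fz = z - iz;
  double acc = 0.0;
  for (int dz = 0; dz < 2; dz++) {
    int kz = iz + dz;
    if (kz < 0 || kz >= N) continue;
    double wz = dz ? fz : 1 - fz;
    if (wz == 0) continue;
    for (int dy = 0; dy < 2; dy++) {
      int ky = iy + dy;
      if (ky < 0 || ky >= N) continue;
      double wy = dy ? fy : 1 - fy;
      if (wy == 0) continue;
      for (int dx = 0; dx < 2; dx++) {
        int kx = ix + dx;
        if (kx < 0 || kx >= N) continue;
        double wx = dx ? fx : 1 - fx;
        if (wx == 0) continue;
        acc += wx * wy * wz * v[(size_t)kz * N * N + (size_t)ky * N + kx];
      }
    }
  }
  return acc;
}

// Keys-cubic resample of a cubic volume: out(p) = vol(M p), centred.
// [[Rcpp::export]]
NumericVector cpp_resample_vol_cubic(NumericVector vol, NumericMatrix M) {
  IntegerVector d = vol.attr("dim");
  int N = d[0];
  int c = N / 2;
  NumericVector out(N * N * N);
  out.attr("dim") = d;
  double m00 = M(0, 0), m01 = M(0, 1), m02 = M(0, 2);
  double m10 = M(1, 0), m11 = M(1, 1), m12 = M(1, 2);
  double m20 = M(2, 0), m21 = M(2, 1), m22 = M(2, 2);
  const double *v = vol.begin();
  double *o = out.begin();
  double wx[4], wy[4], wz[4];
  for (int k = 0; k < N; k++) {
    double pz = k - c;
    for (int j = 0; j < N; j++) {
      double py = j - c;
      size_t base = (size_t)k * N * N + (size_t)j * N;
      for (int i = 0; i < N; i++) {
        double px = i - c;
        double x = m00 * px + m01 * py + m02 * pz + c;
        double y = m10 * px + m11 * py + m12 * pz + c;
        double z = m20 * px + m21 * py + m22 * pz + c;
        int ix = (int)std::floor(x), iy = (int)std::floor(y),
            iz = (int)std::floor(z);
        double acc = 0.0;
        for (int t = 0; t < 4; t++) {
          wx[t] = keys(x - (ix - 1 + t));
          wy[t] = keys(y - (iy - 1 + t));
          wz[t] = keys(z - (iz - 1 + t));
        }
        for (int dz = 0; dz < 4; dz++) {
          int kz = iz - 1 + dz;
          if (kz < 0 || kz >= N || wz[dz] == 0) continue;
          for (int dy = 0; dy < 4; dy++) {
            int ky = iy - 1 + dy;
            if (ky < 0 || ky >= N || wy[dy] == 0) continue;
            double wyz = wy[dy] * wz[dz];
            size_t b2 = (size_t)kz * N * N + (size_t)ky * N;
            for (int dx = 0; dx < 4; dx++) {
              int kx = ix - 1 + dx;
              if (kx < 0 || kx >= N) continue;
              acc += wx[dx] * wyz * v[b2 + kx];
            }
          }
        }
        o[base + i] = acc;
      }
    }
  }
  return out;
}

// Resample a cubic volume: out(p) = vol(M p), coordinates centred.
// [[Rcpp::export]]
NumericVector cpp_resample_vol(NumericVector vol, NumericMatrix M) {
  IntegerVector d = vol.attr("dim");
  int N = d[0];
  int c = N / 2;
  NumericVector out(N * N * N);
  out.attr("dim") = d;
  double m00 = M(0, 0), m01 = M(0, 1), m02 = M(0, 2);
  double m10 = M(1, 0), m11 = M(1, 1), m12 = M(1, 2);
  double m20 = M(2, 0), m21 = M(2, 1), m22 = M(2, 2);
  const double *v = vol.begin();
  double *o = out.begin();
  for (int k = 0; k < N; k++) {
    double pz = k - c;
    for (int j = 0; j < N; j++) {
      double py = j - c;
      size_t base = (size_t)k * N * N + (size_t)j * N;
      for (int i = 0; i < N; i++) {
        double px = i - c;
        double x = m00 * px + m01 * py + m02 * pz + c;
        double y = m10 * px + m11 * py + m12 * pz + c;
        double z = m20 * px + m21 * py + m22 * pz + c;
        o[base + i] = gather3(v, N, x, y, z);
      }
    }
  }
  return out;
}

// In-plane resample of an image: out(p) = img(M2 (p - s)), centred coords,
// s = (sx, sy) in pixels.
// [[Rcpp::export]]
NumericMatrix cpp_resample_image(NumericMatrix img, NumericMatrix M2,
                                 double sx, double sy) {
  int N = img.nrow();
  int c = N / 2;
  NumericMatrix out(N, N);
  double m00 = M2(0, 0), m01 = M2(0, 1), m10 = M2(1, 0), m11 = M2(1, 1);
  for (int j = 0; j < N; j++) {
    double py = j - c - sy;
    for (int i = 0; i < N; i++) {
      double px = i - c - sx;
      double x = m00 * px + m01 * py + c;
      double y = m10 * px + m11 * py + c;
      int ix = (int)std::floor(x), iy = (int)std::floor(y);
      double fx = x - ix, fy = y - iy;
      double acc = 0.0;
      for (int dy = 0; dy < 2; dy++) {
        int ky = iy + dy;
        if (ky < 0 || ky >= N) continue;
        double wy = dy ? fy : 1 - fy;
        for (int dx = 0; dx < 2; dx++) {
          int kx = ix + dx;
          if (kx < 0 || kx >= N) continue;
          double wx = dx ? fx : 1 - fx;
          double w = wx * wy;
          if (w != 0) acc += w * img(kx, ky);
        }
      }
      out(i, j) = acc;
    }
  }
  return out;
}

// Accumulate one Fourier central slice into a centred 3-D transform.
// accRe/accIm/accW are N^3 arrays (modified in place); fre/fim the centred
// 2-D transform of one image; A = R^T (the slice at image frequency
// (kx, ky) lands at 3-D frequency A %*% c(kx, ky, 0)).
// [[Rcpp::export]]
void cpp_insert_slice(NumericVector accRe, NumericVector accIm,
                      NumericVector accW, NumericMatrix fre,
                      NumericMatrix fim, NumericMatrix A) {
  IntegerVector d = accRe.attr("dim");
  int N = d[0];
  int c = N / 2;
  double a00 = A(0, 0), a01 = A(0, 1);
  double a10 = A(1, 0), a11 = A(1, 1);
  double a20 = A(2, 0), a21 = A(2, 1);
  double *re = accRe.begin(), *im = accIm.begin(), *wt = accW.begin();
  double rmax = c - 1.0;
  for (int j = 0; j < N; j++) {
    double ky = j - c;
    for (int i = 0; i < N; i++) {
      double kx = i - c;
      double qx = a00 * kx + a01 * ky;
      double qy = a10 * kx + a11 * ky;
      double qz = a20 * kx + a21 * ky;
      if (qx * qx + qy * qy + qz * qz > rmax * rmax) continue;
      double vr = fre(i, j), vi = fim(i, j);
      double x = qx + c, y = qy + c, z = qz + c;
      int ix = (int)std::floor(x), iy = (int)std::floor(y),
          iz = (int)std::floor(z);
      double fx = x - ix, fy = y - iy, fz = z - iz;
      for (int dz = 0; dz < 2; dz++) {
        int kz2 = iz + dz;
        if (kz2 < 0 || kz2 >= N) continue;
        double wz = dz ? fz : 1 - fz;
        if (wz == 0) continue;
        for (int dy = 0; dy < 2; dy++) {
          int ky2 = iy + dy;
          if (ky2 < 0 || ky2 >= N) continue;
          double wy = dy ? fy : 1 - fy;
          if (wy == 0) continue;
          for (int dx = 0; dx < 2; dx++) {
            int kx2 = ix + dx;
            if (kx2 < 0 || kx2 >= N) continue;
            double wx = dx ? fx : 1 - fx;
            double w = wx * wy * wz;
            if (w == 0) continue;
            size_t idx = (size_t)kz2 * N * N + (size_t)ky2 * N + kx2;
            re[idx] += w * vr;
            im[idx] += w * vi;
            wt[idx] += w;
          }
        }
      }
    }
  }
}

// Keys cubic interpolation kernel (a = -0.5)
static inline double keys(double t) {
  t = std::fabs(t);
  if (t < 1.0) return 1.0 + t * t * (1.5 * t - 2.5);
  if (t < 2.0) return 2.0 - t * (4.0 - t * (2.5 - 0.5 * t));
  return 0.0;
}

// Cubic (Catmull-Rom) interpolation of a cubic volume at arbitrary points
// (voxel coordinates relative to the volume centre); used for Fourier
// central-slice extraction, where trilinear interpolation leaves
// grid-locked artifacts comparable to weak angular signal.
// [[Rcpp::export]]
NumericVector cpp_interp3_cubic(NumericVector vol, NumericMatrix pts) {
  IntegerVector d = vol.attr("dim");
  int N = d[0];
  int c = N / 2;
  int M = pts.nrow();
  NumericVector out(M);
  const double *v = vol.begin();
  for (int m = 0; m < M; m++) {
    double x = pts(m, 0) + c, y = pts(m, 1) + c, z = pts(m, 2) + c;
    int ix = (int)std::floor(x), iy = (int)std::floor(y),
        iz = (int)std::floor(z);
    double acc = 0.0;
    double wx[4], wy[4], wz[4];
    for (int k = 0; k < 4; k++) {
      wx[k] = keys(x - (ix - 1 + k));
      wy[k] = keys(y - (iy - 1 + k));
      wz[k] = keys(z - (iz - 1 + k));
    }
    for (int dz = 0; dz < 4; dz++) {
      int kz = iz - 1 + dz;
      if (kz < 0 || kz >= N || wz[dz] == 0) continue;
      for (int dy = 0; dy < 4; dy++) {
        int ky = iy - 1 + dy;
        if (ky < 0 || ky >= N || wy[dy] == 0) continue;
        double wyz = wy[dy] * wz[dz];
        size_t base = (size_t)kz * N * N + (size_t)ky * N;
        for (int dx = 0; dx < 4; dx++) {
          int kx = ix - 1 + dx;
          if (kx < 0 || kx >= N) continue;
          acc += wx[dx] * wyz * v[base + kx];
        }
      }
    }
    out[m] = acc;
  }
  return out;
}

// Trilinear interpolation of a cubic volume at arbitrary points (voxel
// coordinates relative to the volume centre).
// [[Rcpp::export]]
NumericVector cpp_interp3(NumericVector vol, NumericMatrix pts) {
  IntegerVector d = vol.attr("dim");
  int N = d[0];
  int c = N / 2;
  int M = pts.nrow();
  NumericVector out(M);
  const double *v = vol.begin();
  for (int m = 0; m < M; m++) {
    out[m] = gather3(v, N, pts(m, 0) + c, pts(m, 1) + c, pts(m, 2) + c);
  }
  return out;
}
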