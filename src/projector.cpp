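#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

// Trilinear sample of a zero-padded volume at continuous voxel index (x,y,z)
// (0-based voxel centres). Corners outside the grid contribute zero.
static inline double sample_trilinear(const double *vox, int nx, int ny, int nz,
                                      double x, double y, double z) {
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
  double fx = x - x0, fy = y - y0, fz = z - z0;
  double acc = 0.0;
  for (int dz = 0; dz <= 1; ++dz) {
    int zi = z0 + dz;
    if (zi < 0 || zi >= nz) continue;
    double wz = dz ? fz : 1.0 - fz;
    for (int dy = 0; dy <= 1; ++dy) {
      int yi = y0 + dy;
      if (yi < 0 || yi >= ny) continue;
      double wy = dy ? fy : 1.0 - fy;
      for (int dx = 0; dx <= 1; ++dx) {
        int xi = x0 + dx;
        if (xi < 0 || xi >= nx) continue;
        double wx = dx ? fx : 1.0 - fx;
        acc += wx * wy * wz * vox[xi + (size_t)nx * (yi + (size_t)ny * zi)];
      }
    }
  }
  return acc;
}

// Ray-casting line-integral projector. Pixel (i,j) of the returned matrix
// holds the integral of attenuation along the ray from the X-ray source to
// detector position  C + u*px(i) + v*py(j), sampled every `step` mm with
// trilinear interpolation (midpoint rule). R is the pose rotation; the
// source sits at -sid * nu and the detector centre at (sdd - sid) * nu,
// shifted by (tx, ty) along the rotated in-plane axes u, v.
// support_lo/support_hi: world-space box enclosing the nonzero voxels
// (plus interpolation margin); rays are integrated only inside it.
// [[Rcpp::export(name = ".project_cpp")]]
NumericMatrix project_cpp(NumericVector voxels, IntegerVector dims,
                          NumericVector spacing, NumericVector origin,
                          NumericVector support_lo, NumericVector support_hi,
                          NumericMatrix R, double tx, double ty,
                          double sdd, double sid, double det_size,
                          int nres, double step) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double *vox = voxels.begin();
  const double ux = R(0, 0), uy = R(1, 0), uz = R(2, 0);
  const double vx = R(0, 1), vy = R(1, 1), vz = R(2, 1);
  const double wx = R(0, 2), wy = R(1, 2), wz = R(2, 2);

  const double Sx = -sid * wx, Sy = -sid * wy, Sz = -sid * wz;
  const double dcd = sdd - sid; // isocenter to detector centre
  const double Cx = dcd * wx + tx * ux + ty * vx;
  const double Cy = dcd * wy + tx * uy + ty * vy;
  const double Cz = dcd * wz + tx * uz + ty * vz;
  const double pitch = det_size / nres;

  // integration box: the nonzero support, never beyond the grid box
  double lo[3], hi[3];
  for (int k = 0; k < 3; ++k) {
    double glo = origin[k] - spacing[k];
    double ghi = origin[k] + dims[k] * spacing[k];
    lo[k] = std::max(glo, (double)support_lo[k]);
    hi[k] = std::min(ghi, (double)support_hi[k]);
    // source must be outside the volume grid
    if (k == 0 && Sx > glo && Sx < ghi && Sy > origin[1] - spacing[1] &&
        Sy < origin[1] + dims[1] * spacing[1] &&
        Sz > origin[2] - spacing[2] && Sz < origin[2] + dims[2] * spacing[2]) {
      stop("degenerate geometry: X-ray source lies inside the volume");
    }
  }
  if (lo[0] >= hi[0] || lo[1] >= hi[1] || lo[2] >= hi[2]) {
    return NumericMatrix(nres, nres); // empty support: all-zero image
  }

  NumericMatrix img(nres, nres);
  const double half = (nres - 1) / 2.0;
  for (int j = 0; j < nres; ++j) {
    double py = (j - half) * pitch;
    for (int i = 0; i < nres; ++i) {
      double px = (i - half) * pitch;
      double Px = Cx + px * ux + py * vx;
      double Py = Cy + px * uy + py * vy;
      double Pz = Cz + px * uz + py * vz;
      double dx = Px - Sx, dy = Py - Sy, dz = Pz - Sz;
      double len = std::sqrt(dx * dx + dy * dy + dz * dz);
      dx /= len; dy /= len; dz /= len;
      // clip ray to the bounding box (slab method)
      double t0 = 0.0, t1 = len;
      const double d[3] = {dx, dy, dz};
      const double S[3] = {Sx, Sy, Sz};
      bool miss = false;
      for (int k = 0; k < 3; ++k) {
        if (std::fabs(d[k]) < 1e-12) {
          if (S[k] <= lo[k] || S[k] >= hi[k]) { miss = true; break; }
        } else {
          double ta = (lo[k] - S[k]) / d[k];
          double tb = (hi[k] - S[k]) / d[k];
          if (ta > tb) std::swap(ta, tb);
          if (ta > t0) t0 = ta;
          if (tb < t1) t1 = tb;
          if (t0 >= t1) { miss = true; break; }
        }
      }
      double val = 0.0;
      if (!miss) {
        int nstep = (int)std::ceil((t1 - t0) / step);
        double dt = (t1 - t0) / nstep;
        // march incrementally in continuous voxel coordinates
        double t = t0 + 0.5 * dt;
        double gx = (S[0] + t * dx - origin[0]) / spacing[0];
        double gy = (S[1] + t * dy - origin[1]) / spacing[1];
        double gz = (S[2] + t * dz - origin[2]) / spacing[2];
        const double sx = dt * dx / spacing[0];
        const double sy = dt * dy / spacing[1];
        const double sz = dt * dz / spacing[2];
        // endpoints strictly interior -> skip per-corner bounds checks
        double ex = gx + (nstep - 1) * sx, ey = gy + (nstep - 1) * sy,
               ez = gz + (nstep - 1) * sz;
        bool interior =
            std::min(gx, ex) >= 0 && std::max(gx, ex) < nx - 1 &&
            std::min(gy, ey) >= 0 && std::max(gy, ey) < ny - 1 &&
            std::min(gz, ez) >= 0 && std::max(gz, ez) < nz - 1;
        if (interior) {
          for (int s = 0; s < nstep; ++s) {
            int x0 = (int)gx, y0 = (int)gy, z0 = (int)gz;
            double fx = gx - x0, fy = gy - y0, fz = gz - z0;
            const double *p000 = vox + x0 + (size_t)nx * (y0 + (size_t)ny * z0);
            const double *p001 = p000 + (size_t)nx * ny;
            double c00 = p000[0] + fx * (p000[1] - p000[0]);
            double c10 = p000[nx] + fx * (p000[nx + 1] - p000[nx]);
            double c01 = p001[0] + fx * (p001[1] - p001[0]);
            double c11 = p001[nx] + fx * (p001[nx + 1] - p001[nx]);
            double c0 = c00 + fy * (c10 - c00);
            double c1 = c01 + fy * (c11 - c01);
            val += c0 + fz * (c1 - c0);
            gx += sx; gy += sy; gz += sz;
          }
        } else {
          for (int s = 0; s < nstep; ++s) {
            val += sample_trilinear(vox, nx, ny, nz, gx, gy, gz);
            gx += sx; gy += sy; gz += sz;
          }
        }
        val *= dt;
      }
      img(i, j) = val;
    }
  }
  return img;
}
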