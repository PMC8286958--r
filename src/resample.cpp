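#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

// Bilinear affine resampler shared by the augmentation ops. Output pixel at
// centred coordinate q (pixels, origin at the image centre) samples the
// input at  A * q + b  (also centred input pixels). pad = 0 -> zero padding,
// pad = 1 -> clamp to edge.
// [[Rcpp::export(name = ".resample_affine_cpp")]]
NumericMatrix resample_affine_cpp(NumericMatrix img, NumericMatrix A,
                                  NumericVector b, int out_nx, int out_ny,
                                  int pad) {
  const int nx = img.nrow(), ny = img.ncol();
  const double cx_in = (nx - 1) / 2.0, cy_in = (ny - 1) / 2.0;
  const double cx_out = (out_nx - 1) / 2.0, cy_out = (out_ny - 1) / 2.0;
  const double a11 = A(0, 0), a12 = A(0, 1), a21 = A(1, 0), a22 = A(1, 1);
  NumericMatrix out(out_nx, out_ny);
  for (int j = 0; j < out_ny; ++j) {
    double qy = j - cy_out;
    for (int i = 0; i < out_nx; ++i) {
      double qx = i - cx_out;
      double x = a11 * qx + a12 * qy + b[0] + cx_in;
      double y = a21 * qx + a22 * qy + b[1] + cy_in;
      double val = 0.0;
      if (pad == 1) {
        if (x < 0) x = 0; else if (x > nx - 1) x = nx - 1;
        if (y < 0) y = 0; else if (y > ny - 1) y = ny - 1;
      }
      int x0 = (int)std::floor(x), y0 = (int)std::floor(y);
      double fx = x - x0, fy = y - y0;
      for (int dy = 0; dy <= 1; ++dy) {
        int yi = y0 + dy;
        if (yi < 0 || yi >= ny) continue;
        double wy = dy ? fy : 1.0 - fy;
        for (int dx = 0; dx <= 1; ++dx) {
          int xi = x0 + dx;
          if (xi < 0 || xi >= nx) continue;
          double wx = dx ? fx : 1.0 - fx;
          val += wx * wy * img(xi, yi);
        }
      }
      out(i, j) = val;
    }
  }
  return out;
}
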