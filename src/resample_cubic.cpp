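#include <Rcpp.h>
using namespace Rcpp;

// Keys cubic-convolution kernel, a = -0.5 (Catmull-Rom). Better frequency
// response than trilinear, which matters inside the registration loop:
// linear interpolation attenuates high frequencies by an amount that
// depends on the sub-voxel offset, biasing similarity optima toward zero
// motion.
static inline double keys(double s) {
  s = std::fabs(s);
  if (s < 1.0) return 1.5 * s * s * s - 2.5 * s * s + 1.0;
  if (s < 2.0) return -0.5 * s * s * s + 2.5 * s * s - 4.0 * s + 2.0;
  return 0.0;
}

// [[Rcpp::export]]
NumericVector cpp_resample_cubic(NumericVector values, IntegerVector dims,
                                 NumericVector spacing, NumericVector origin,
                                 NumericMatrix rot, NumericVector center,
                                 NumericVector translation) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  NumericVector out(values.size());
  const double r11 = rot(0, 0), r12 = rot(0, 1), r13 = rot(0, 2);
  const double r21 = rot(1, 0), r22 = rot(1, 1), r23 = rot(1, 2);
  const double r31 = rot(2, 0), r32 = rot(2, 1), r33 = rot(2, 2);
  const double ox = origin[0], oy = origin[1], oz = origin[2];
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  const double cx = center[0], cy = center[1], cz = center[2];
  const double tx = translation[0] + cx, ty = translation[1] + cy,
               tz = translation[2] + cz;
  R_xlen_t idx = 0;
  for (int k = 0; k < d3; ++k) {
    const double pz = oz + k * sz - cz;
    for (int j = 0; j < d2; ++j) {
      const double py = oy + j * sy - cy;
      for (int i = 0; i < d1; ++i, ++idx) {
        const double px = ox + i * sx - cx;
        const double fx = (r11 * px + r12 * py + r13 * pz + tx - ox) / sx;
        const double fy = (r21 * px + r22 * py + r23 * pz + ty - oy) / sy;
        const double fz = (r31 * px + r32 * py + r33 * pz + tz - oz) / sz;
        if (fx < 0 || fx > d1 - 1 || fy < 0 || fy > d2 - 1 ||
            fz < 0 || fz > d3 - 1)
          continue;  // outside the field of view -> 0
        const int i0 = (int)std::floor(fx), j0 = (int)std::floor(fy),
                  k0 = (int)std::floor(fz);
        double wxs[4], wys[4], wzs[4];
        for (int c = -1; c <= 2; ++c) {
          wxs[c + 1] = keys(fx - (i0 + c));
          wys[c + 1] = keys(fy - (j0 + c));
          wzs[c + 1] = keys(fz - (k0 + c));
        }
        double acc = 0.0, wsum = 0.0;
        for (int ck = -1; ck <= 2; ++ck) {
          int kk = k0 + ck;
          if (kk < 0) kk = 0; else if (kk > d3 - 1) kk = d3 - 1;  // clamp
          const double wk = wzs[ck + 1];
          for (int cj = -1; cj <= 2; ++cj) {
            int jj = j0 + cj;
            if (jj < 0) jj = 0; else if (jj > d2 - 1) jj = d2 - 1;
            const double wjk = wk * wys[cj + 1];
            for (int ci = -1; ci <= 2; ++ci) {
              int ii = i0 + ci;
              if (ii < 0) ii = 0; else if (ii > d1 - 1) ii = d1 - 1;
              const double w = wjk * wxs[ci + 1];
              acc += w * values[(R_xlen_t)ii +
                                (R_xlen_t)d1 * ((R_xlen_t)jj +
                                                (R_xlen_t)d2 * (R_xlen_t)kk)];
              wsum += w;
            }
          }
        }
        out[idx] = (wsum != 0.0) ? acc / wsum : 0.0;
      }
    }
  }
  return out;
}
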