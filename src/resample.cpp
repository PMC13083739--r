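#include <Rcpp.h>
using namespace Rcpp;

// Pull-back resampling of a 3-D volume onto its own lattice.
// Each output voxel at world position x takes the interpolated value of
// the input at R (x - center) + center + translation; samples outside the
// field of view are 0. Grids are axis-aligned RAS, mm.
// [[Rcpp::export]]
NumericVector cpp_resample(NumericVector values, IntegerVector dims,
                           NumericVector spacing, NumericVector origin,
                           NumericMatrix rot, NumericVector center,
                           NumericVector translation, bool nearest) {
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
        const double qx = r11 * px + r12 * py + r13 * pz + tx;
        const double qy = r21 * px + r22 * py + r23 * pz + ty;
        const double qz = r31 * px + r32 * py + r33 * pz + tz;
        const double fx = (qx - ox) / sx;
        const double fy = (qy - oy) / sy;
        const double fz = (qz - oz) / sz;
        if (nearest) {
          const double ri = std::nearbyint(fx), rj = std::nearbyint(fy),
                       rk = std::nearbyint(fz);
          if (ri >= 0 && ri <= d1 - 1 && rj >= 0 && rj <= d2 - 1 &&
              rk >= 0 && rk <= d3 - 1)
            out[idx] = values[(R_xlen_t)ri +
                              (R_xlen_t)d1 * ((R_xlen_t)rj +
                                              (R_xlen_t)d2 * (R_xlen_t)rk)];
        } else {
          const double flx = std::floor(fx), fly = std::floor(fy),
                       flz = std::floor(fz);
          const int i0 = (int)flx, j0 = (int)fly, k0 = (int)flz;
          const double wx = fx - flx, wy = fy - fly, wz = fz - flz;
          double acc = 0.0;
          for (int ck = 0; ck <= 1; ++ck) {
            const int kk = k0 + ck;
            if (kk < 0 || kk > d3 - 1) continue;
            const double wk = ck ? wz : 1.0 - wz;
            if (wk == 0.0) continue;
            for (int cj = 0; cj <= 1; ++cj) {
              const int jj = j0 + cj;
              if (jj < 0 || jj > d2 - 1) continue;
              const double wjk = wk * (cj ? wy : 1.0 - wy);
              if (wjk == 0.0) continue;
              for (int ci = 0; ci <= 1; ++ci) {
                const int ii = i0 + ci;
                if (ii < 0 || ii > d1 - 1) continue;
                const double w = wjk * (ci ? wx : 1.0 - wx);
                if (w == 0.0) continue;
                acc += w * values[(R_xlen_t)ii +
                                  (R_xlen_t)d1 * ((R_xlen_t)jj +
                                                  (R_xlen_t)d2 * (R_xlen_t)kk)];
              }
            }
          }
          out[idx] = acc;
        }
      }
    }
  }
  return out;
}
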