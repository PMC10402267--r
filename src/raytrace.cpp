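#include <Rcpp.h>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Exact voxel traversal (Amanatides-Woo stepping with Siddon-style exact
// segment lengths) of one ray from `src` to `dst` through a regular grid.
// `mu` is a column-major (nx, ny, nz) array; `bmin` is the world position of
// the minimal outer corner of the grid (voxel center i sits at
// bmin + (i + 0.5) * spacing).
// Returns the line integral sum(mu * segment_length) in the units of
// `spacing` (mm).
static double trace_ray(const double* mu, const int* dim,
                        const double* spacing, const double* bmin,
                        const double* src, const double* dst) {
  double dir[3], bmax[3];
  for (int a = 0; a < 3; ++a) {
    dir[a] = dst[a] - src[a];
    bmax[a] = bmin[a] + dim[a] * spacing[a];
  }
  const double len = std::sqrt(dir[0]*dir[0] + dir[1]*dir[1] + dir[2]*dir[2]);
  if (len <= 0.0) return 0.0;

  // clip parameter range [t0, t1] against the volume bounding box
  double t0 = 0.0, t1 = 1.0;
  for (int a = 0; a < 3; ++a) {
    if (dir[a] == 0.0) {
      if (src[a] <= bmin[a] || src[a] >= bmax[a]) return 0.0;
    } else {
      double ta = (bmin[a] - src[a]) / dir[a];
      double tb = (bmax[a] - src[a]) / dir[a];
      if (ta > tb) std::swap(ta, tb);
      if (ta > t0) t0 = ta;
      if (tb < t1) t1 = tb;
    }
  }
  if (t0 >= t1) return 0.0;

  // entry voxel index
  int idx[3], step[3];
  double tnext[3], tdelta[3];
  const double inf = std::numeric_limits<double>::infinity();
  const double tmid = 0.5 * (t0 + t1);
  for (int a = 0; a < 3; ++a) {
    double p = src[a] + tmid * dir[a];  // midpoint avoids boundary rounding
    int i = (int)std::floor((p - bmin[a]) / spacing[a]);
    if (i < 0) i = 0;
    if (i >= dim[a]) i = dim[a] - 1;
    // re-derive entry voxel from t0 for robustness
    double pe = src[a] + t0 * dir[a];
    int ie = (int)std::floor((pe - bmin[a]) / spacing[a]);
    if (dir[a] > 0 && ie < 0) ie = 0;
    if (dir[a] < 0 && ie >= dim[a]) ie = dim[a] - 1;
    if (ie >= 0 && ie < dim[a]) i = ie;
    idx[a] = i;
    if (dir[a] > 0.0) {
      step[a] = 1;
      tnext[a] = ((bmin[a] + (i + 1) * spacing[a]) - src[a]) / dir[a];
      tdelta[a] = spacing[a] / dir[a];
    } else if (dir[a] < 0.0) {
      step[a] = -1;
      tnext[a] = ((bmin[a] + i * spacing[a]) - src[a]) / dir[a];
      tdelta[a] = -spacing[a] / dir[a];
    } else {
      step[a] = 0;
      tnext[a] = inf;
      tdelta[a] = inf;
    }
  }

  const int nx = dim[0], nxy = dim[0] * dim[1];
  double acc = 0.0, tcur = t0;
  while (tcur < t1) {
    int a = 0;
    if (tnext[1] < tnext[a]) a = 1;
    if (tnext[2] < tnext[a]) a = 2;
    double tstop = tnext[a] < t1 ? tnext[a] : t1;
    if (tstop > tcur) {
      double m = mu[idx[0] + idx[1] * nx + idx[2] * nxy];
      acc += m * (tstop - tcur) * len;
      tcur = tstop;
    }
    if (tnext[a] >= t1) break;
    idx[a] += step[a];
    if (idx[a] < 0 || idx[a] >= dim[a]) break;
    tnext[a] += tdelta[a];
  }
  return acc;
}

// [[Rcpp::export(name = ".siddon_project")]]
NumericMatrix siddon_project_cpp(NumericVector mu, IntegerVector dim,
                                 NumericVector spacing, NumericVector origin,
                                 NumericVector source, NumericVector det_center,
                                 NumericVector u_axis, NumericVector v_axis,
                                 int panel_rows, int panel_cols,
                                 double pixel_pitch) {
  double bmin[3];
  for (int a = 0; a < 3; ++a) bmin[a] = origin[a];
  NumericMatrix out(panel_rows, panel_cols);
  const double r0 = (panel_rows - 1) / 2.0, c0 = (panel_cols - 1) / 2.0;
  double src[3] = { source[0], source[1], source[2] };
  for (int c = 0; c < panel_cols; ++c) {
    for (int r = 0; r < panel_rows; ++r) {
      double du = (c - c0) * pixel_pitch, dv = (r - r0) * pixel_pitch;
      double dst[3];
      for (int a = 0; a < 3; ++a)
        dst[a] = det_center[a] + du * u_axis[a] + dv * v_axis[a];
      out(r, c) = trace_ray(REAL(mu), INTEGER(dim), REAL(spacing), bmin,
                            src, dst);
    }
  }
  return out;
}
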