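// Affine resampling of 3D / 4D (multi-channel) arrays. The 3x4 matrix A maps
// 0-based output voxel indices (i,j,k,1) to 0-based continuous input indices.
// Out-of-range samples clamp to the edge (replicate padding).
#include <Rcpp.h>
using namespace Rcpp;

static inline double clampd(double v, double lo, double hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// [[Rcpp::export(name = ".resample_affine")]]
NumericVector resample_affine(NumericVector src, NumericMatrix A,
                              IntegerVector outdim, bool nearest) {
  IntegerVector d = src.attr("dim");
  const int ndim = d.size();
  if (ndim != 3 && ndim != 4) stop("src must be 3D or 4D");
  const int nx = d[0], ny = d[1], nz = d[2];
  const int nc = (ndim == 4) ? d[3] : 1;
  const int ox = outdim[0], oy = outdim[1], oz = outdim[2];
  const long ovol = (long)ox * oy * oz;
  const long ivol = (long)nx * ny * nz;
  NumericVector out(ovol * nc);
  const double* sp = REAL(src);
  double* op = REAL(out);
  const long iplane = (long)nx * ny;

  for (int k = 0; k < oz; ++k)
    for (int j = 0; j < oy; ++j)
      for (int i = 0; i < ox; ++i) {
        double u = A(0,0)*i + A(0,1)*j + A(0,2)*k + A(0,3);
        double v = A(1,0)*i + A(1,1)*j + A(1,2)*k + A(1,3);
        double w = A(2,0)*i + A(2,1)*j + A(2,2)*k + A(2,3);
        const long oo = (long)k * ox * oy + (long)j * ox + i;
        if (nearest) {
          int xi = (int)clampd(std::floor(u + 0.5), 0, nx - 1);
          int yi = (int)clampd(std::floor(v + 0.5), 0, ny - 1);
          int zi = (int)clampd(std::floor(w + 0.5), 0, nz - 1);
          const long ii = (long)zi * iplane + (long)yi * nx + xi;
          for (int c = 0; c < nc; ++c)
            op[oo + (long)c * ovol] = sp[ii + (long)c * ivol];
        } else {
          u = clampd(u, 0, nx - 1); v = clampd(v, 0, ny - 1); w = clampd(w, 0, nz - 1);
          int x0 = (int)std::floor(u), y0 = (int)std::floor(v), z0 = (int)std::floor(w);
          int x1 = std::min(x0 + 1, nx - 1), y1 = std::min(y0 + 1, ny - 1),
              z1 = std::min(z0 + 1, nz - 1);
          double fx = u - x0, fy = v - y0, fz = w - z0;
          for (int c = 0; c < nc; ++c) {
            const double* s = sp + (long)c * ivol;
            #define AT(X,Y,Z) s[(long)(Z) * iplane + (long)(Y) * nx + (X)]
            double c00 = AT(x0,y0,z0) * (1-fx) + AT(x1,y0,z0) * fx;
            double c10 = AT(x0,y1,z0) * (1-fx) + AT(x1,y1,z0) * fx;
            double c01 = AT(x0,y0,z1) * (1-fx) + AT(x1,y0,z1) * fx;
            double c11 = AT(x0,y1,z1) * (1-fx) + AT(x1,y1,z1) * fx;
            #undef AT
            double c0 = c00 * (1-fy) + c10 * fy;
            double c1 = c01 * (1-fy) + c11 * fy;
            op[oo + (long)c * ovol] = c0 * (1-fz) + c1 * fz;
          }
        }
      }
  if (ndim == 4)
    out.attr("dim") = IntegerVector::create(ox, oy, oz, nc);
  else
    out.attr("dim") = IntegerVector::create(ox, oy, oz);
  return out;
}
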