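// 2x2x2 max pooling (stride 2) with argmax bookkeeping for backprop.
#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export(name = ".maxpool3d_fw")]]
List maxpool3d_fw(NumericVector x) {
  IntegerVector d = x.attr("dim");
  const int nx = d[0], ny = d[1], nz = d[2], nc = d[3];
  if (nx % 2 || ny % 2 || nz % 2) stop("spatial dims must be even for 2x2x2 pooling");
  const int ox = nx / 2, oy = ny / 2, oz = nz / 2;
  const long on = (long)ox * oy * oz * nc;
  NumericVector y(on);
  IntegerVector idx(on);  // 0-based linear index into x
  const double* xp = REAL(x);
  double* yp = REAL(y);
  const long plane = (long)nx * ny, volsz = plane * nz;
  long o = 0;
  for (int c = 0; c < nc; ++c) {
    const long cb = (long)c * volsz;
    for (int z = 0; z < oz; ++z)
      for (int y2 = 0; y2 < oy; ++y2)
        for (int x2 = 0; x2 < ox; ++x2) {
          double best = -1e300; long bi = 0;
          for (int dz = 0; dz < 2; ++dz)
            for (int dy = 0; dy < 2; ++dy)
              for (int dx = 0; dx < 2; ++dx) {
                long li = cb + (long)(2 * z + dz) * plane +
                          (long)(2 * y2 + dy) * nx + (2 * x2 + dx);
                if (xp[li] > best) { best = xp[li]; bi = li; }
              }
          yp[o] = best; idx[o] = (int)bi; ++o;
        }
  }
  y.attr("dim") = IntegerVector::create(ox, oy, oz, nc);
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".maxpool3d_bw")]]
NumericVector maxpool3d_bw(IntegerVector idx, NumericVector dy, IntegerVector xdim) {
  long n = 1; for (int i = 0; i < xdim.size(); ++i) n *= xdim[i];
  NumericVector dx(n);
  dx.attr("dim") = xdim;
  double* dxp = REAL(dx);
  const double* dyp = REAL(dy);
  for (long i = 0; i < idx.size(); ++i) dxp[idx[i]] += dyp[i];
  return dx;
}
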