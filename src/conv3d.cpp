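// 3x3x3 "same" convolution for 4D (x,y,z,channel) arrays, implemented as
// im2col + GEMM so the inner loop is a BLAS call. Column order within the
// unrolled kernel axis: channel-major, then dz, dy, dx (dx fastest); the
// weight matrix must use the same order (it only has to be consistent).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static arma::mat im2col3(const double* x, int nx, int ny, int nz, int cin) {
  const int n = nx * ny * nz;
  arma::mat cols(n, 27 * cin, arma::fill::zeros);
  const long plane = (long)nx * ny;
  const long volsz = plane * nz;
  for (int c = 0; c < cin; ++c) {
    const double* xc = x + (long)c * volsz;
    for (int dz = -1; dz <= 1; ++dz) {
      for (int dy = -1; dy <= 1; ++dy) {
        for (int dx = -1; dx <= 1; ++dx) {
          const int k = ((c * 3 + (dz + 1)) * 3 + (dy + 1)) * 3 + (dx + 1);
          double* col = cols.colptr(k);
          for (int z = 0; z < nz; ++z) {
            const int zz = z + dz;
            if (zz < 0 || zz >= nz) continue;
            for (int y = 0; y < ny; ++y) {
              const int yy = y + dy;
              if (yy < 0 || yy >= ny) continue;
              const long obase = (long)z * plane + (long)y * nx;
              const long ibase = (long)zz * plane + (long)yy * nx;
              const int x0 = (dx < 0) ? 1 : 0;
              const int x1 = (dx > 0) ? nx - 1 : nx;
              for (int xi = x0; xi < x1; ++xi)
                col[obase + xi] = xc[ibase + xi + dx];
            }
          }
        }
      }
    }
  }
  return cols;
}

// [[Rcpp::export(name = ".conv3d_fw")]]
NumericVector conv3d_fw(NumericVector x, NumericMatrix W, NumericVector b) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("input must be a 4D (x,y,z,channel) array");
  const int nx = d[0], ny = d[1], nz = d[2], cin = d[3];
  const int cout = W.ncol();
  if (W.nrow() != 27 * cin) stop("weight matrix row count must be 27*cin");
  arma::mat cols = im2col3(REAL(x), nx, ny, nz, cin);
  arma::mat Wm(W.begin(), W.nrow(), cout, false);
  arma::mat y = cols * Wm;
  y.each_row() += arma::rowvec(b.begin(), cout);
  NumericVector out(y.begin(), y.end());
  out.attr("dim") = IntegerVector::create(nx, ny, nz, cout);
  return out;
}

// [[Rcpp::export(name = ".conv3d_bw")]]
List conv3d_bw(NumericVector x, NumericMatrix W, NumericVector dy) {
  IntegerVector d = x.attr("dim");
  const int nx = d[0], ny = d[1], nz = d[2], cin = d[3];
  const int cout = W.ncol();
  const long n = (long)nx * ny * nz;
  arma::mat cols = im2col3(REAL(x), nx, ny, nz, cin);
  arma::mat dYm(REAL(dy), n, cout, false);
  arma::mat Wm(W.begin(), W.nrow(), cout, false);
  arma::mat dW = cols.t() * dYm;
  arma::rowvec db = arma::sum(dYm, 0);
  arma::mat dXcol = dYm * Wm.t();  // n x 27*cin

  // col2im: scatter-add each unrolled column back to its source voxel
  NumericVector dx(x.size());
  dx.attr("dim") = d;
  double* dxp = REAL(dx);
  const long plane = (long)nx * ny;
  const long volsz = plane * nz;
  for (int c = 0; c < cin; ++c) {
    double* dxc = dxp + (long)c * volsz;
    for (int dz = -1; dz <= 1; ++dz) {
      for (int dyy = -1; dyy <= 1; ++dyy) {
        for (int dxx = -1; dxx <= 1; ++dxx) {
          const int k = ((c * 3 + (dz + 1)) * 3 + (dyy + 1)) * 3 + (dxx + 1);
          const double* col = dXcol.colptr(k);
          for (int z = 0; z < nz; ++z) {
            const int zz = z + dz;
            if (zz < 0 || zz >= nz) continue;
            for (int y = 0; y < ny; ++y) {
              const int yy = y + dyy;
              if (yy < 0 || yy >= ny) continue;
              const long obase = (long)z * plane + (long)y * nx;
              const long ibase = (long)zz * plane + (long)yy * nx;
              const int x0 = (dxx < 0) ? 1 : 0;
              const int x1 = (dxx > 0) ? nx - 1 : nx;
              for (int xi = x0; xi < x1; ++xi)
                dxc[ibase + xi + dxx] += col[obase + xi];
            }
          }
        }
      }
    }
  }
  return List::create(_["dW"] = wrap(dW), _["db"] = wrap(db), _["dx"] = dx);
}
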