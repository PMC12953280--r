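#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Voxel arrays are channel-last, column-major: dim = (X, Y, Z, C).
// Kernels are dim = (kx, ky, kz, Cin, Cout) with odd spatial extents and
// "same" zero padding, so output grids match input grids.

static inline R_xlen_t vidx(int i, int j, int k, int c,
                            int X, int Y, int Z) {
  return (R_xlen_t)i + (R_xlen_t)X * ((R_xlen_t)j + (R_xlen_t)Y *
         ((R_xlen_t)k + (R_xlen_t)Z * (R_xlen_t)c));
}

// [[Rcpp::export(name = ".cpp_conv3d_fw")]]
NumericVector cpp_conv3d_fw(NumericVector x, NumericVector w, NumericVector b,
                            IntegerVector xdim, IntegerVector wdim) {
  const int X = xdim[0], Y = xdim[1], Z = xdim[2], Cin = xdim[3];
  const int kx = wdim[0], ky = wdim[1], kz = wdim[2], Cout = wdim[4];
  const int ox = kx / 2, oy = ky / 2, oz = kz / 2;
  NumericVector out((R_xlen_t)X * Y * Z * Cout);
  const double *px = x.begin(), *pw = w.begin();
  double *po = out.begin();
  for (int co = 0; co < Cout; ++co) {
    const double bias = b[co];
    for (int k = 0; k < Z; ++k) {
      for (int j = 0; j < Y; ++j) {
        for (int i = 0; i < X; ++i) {
          double acc = bias;
          for (int ci = 0; ci < Cin; ++ci) {
            for (int d = 0; d < kz; ++d) {
              const int kk = k + d - oz;
              if (kk < 0 || kk >= Z) continue;
              for (int bb = 0; bb < ky; ++bb) {
                const int jj = j + bb - oy;
                if (jj < 0 || jj >= Y) continue;
                const R_xlen_t wbase = (R_xlen_t)kx * (bb + (R_xlen_t)ky *
                    (d + (R_xlen_t)kz * (ci + (R_xlen_t)Cin * co)));
                const R_xlen_t xbase = vidx(0, jj, kk, ci, X, Y, Z);
                for (int a = 0; a < kx; ++a) {
                  const int ii = i + a - ox;
                  if (ii < 0 || ii >= X) continue;
                  acc += px[xbase + ii] * pw[wbase + a];
                }
              }
            }
          }
          po[vidx(i, j, k, co, X, Y, Z)] = acc;
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(X, Y, Z, Cout);
  return out;
}

// Gradients of the same-padded convolution w.r.t. input, weights and bias.
// [[Rcpp::export(name = ".cpp_conv3d_bw")]]
List cpp_conv3d_bw(NumericVector x, NumericVector w, NumericVector dy,
                   IntegerVector xdim, IntegerVector wdim) {
  const int X = xdim[0], Y = xdim[1], Z = xdim[2], Cin = xdim[3];
  const int kx = wdim[0], ky = wdim[1], kz = wdim[2], Cout = wdim[4];
  const int ox = kx / 2, oy = ky / 2, oz = kz / 2;
  NumericVector dx((R_xlen_t)X * Y * Z * Cin);
  NumericVector dw(w.size());
  NumericVector db(Cout);
  const double *px = x.begin(), *pw = w.begin(), *pdy = dy.begin();
  double *pdx = dx.begin(), *pdw = dw.begin();
  for (int co = 0; co < Cout; ++co) {
    double bacc = 0.0;
    for (int k = 0; k < Z; ++k)
      for (int j = 0; j < Y; ++j)
        for (int i = 0; i < X; ++i) {
          const double g = pdy[vidx(i, j, k, co, X, Y, Z)];
          if (g == 0.0) { continue; }
          bacc += g;
          for (int ci = 0; ci < Cin; ++ci) {
            for (int d = 0; d < kz; ++d) {
              const int kk = k + d - oz;
              if (kk < 0 || kk >= Z) continue;
              for (int bb = 0; bb < ky; ++bb) {
                const int jj = j + bb - oy;
                if (jj < 0 || jj >= Y) continue;
                const R_xlen_t wbase = (R_xlen_t)kx * (bb + (R_xlen_t)ky *
                    (d + (R_xlen_t)kz * (ci + (R_xlen_t)Cin * co)));
                const R_xlen_t xbase = vidx(0, jj, kk, ci, X, Y, Z);
                for (int a = 0; a < kx; ++a) {
                  const int ii = i + a - ox;
                  if (ii < 0 || ii >= X) continue;
                  pdw[wbase + a] += px[xbase + ii] * g;
                  pdx[xbase + ii] += pw[wbase + a] * g;
                }
              }
            }
          }
        }
    db[co] = bacc;
  }
  dx.attr("dim") = IntegerVector::create(X, Y, Z, Cin);
  dw.attr("dim") = wdim;
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// Resample a 3D volume onto an out_dim grid: source continuous 0-based index
// of output voxel (i,j,k) is M %*% (i,j,k,1) with M a 3x4 matrix.
// mode 0 = trilinear, 1 = nearest; outside voxels take `fill`.
// [[Rcpp::export(name = ".cpp_resample_affine")]]
NumericVector cpp_resample_affine(NumericVector src, IntegerVector sdim,
                                  NumericMatrix M, IntegerVector out_dim,
                                  int mode, double fill) {
  const int X = sdim[0], Y = sdim[1], Z = sdim[2];
  const int OX = out_dim[0], OY = out_dim[1], OZ = out_dim[2];
  NumericVector out((R_xlen_t)OX * OY * OZ);
  const double *ps = src.begin();
  double *po = out.begin();
  R_xlen_t q = 0;
  for (int k = 0; k < OZ; ++k)
    for (int j = 0; j < OY; ++j)
      for (int i = 0; i < OX; ++i, ++q) {
        const double sx = M(0,0)*i + M(0,1)*j + M(0,2)*k + M(0,3);
        const double sy = M(1,0)*i + M(1,1)*j + M(1,2)*k + M(1,3);
        const double sz = M(2,0)*i + M(2,1)*j + M(2,2)*k + M(2,3);
        if (mode == 1) {
          const int ii = (int)std::lround(sx), jj = (int)std::lround(sy),
                    kk = (int)std::lround(sz);
          po[q] = (ii < 0 || ii >= X || jj < 0 || jj >= Y ||
                   kk < 0 || kk >= Z)
                      ? fill
                      : ps[vidx(ii, jj, kk, 0, X, Y, Z)];
        } else {
          const int i0 = (int)std::floor(sx), j0 = (int)std::floor(sy),
                    k0 = (int)std::floor(sz);
          const double fx = sx - i0, fy = sy - j0, fz = sz - k0;
          double acc = 0.0;
          for (int dz = 0; dz <= 1; ++dz)
            for (int dyy = 0; dyy <= 1; ++dyy)
              for (int dxx = 0; dxx <= 1; ++dxx) {
                const int ii = i0 + dxx, jj = j0 + dyy, kk = k0 + dz;
                const double wgt = (dxx ? fx : 1 - fx) *
                                   (dyy ? fy : 1 - fy) *
                                   (dz ? fz : 1 - fz);
                if (wgt == 0.0) continue;
                const double v = (ii < 0 || ii >= X || jj < 0 || jj >= Y ||
                                  kk < 0 || kk >= Z)
                                     ? fill
                                     : ps[vidx(ii, jj, kk, 0, X, Y, Z)];
                acc += wgt * v;
              }
          po[q] = acc;
        }
      }
  out.attr("dim") = out_dim;
  return out;
}
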