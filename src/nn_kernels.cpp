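// Hot kernels for the conv-net engine. The im2col patch matrix is a pure
// gather with zero fill at the volume boundary; doing it in C avoids the
// interpreter's intermediate allocations, which dominate training time
// otherwise.

#include <Rcpp.h>
using namespace Rcpp;

// im2col for a 3x3x3 window with zero padding 1 on a batch of volumes.
// x: (S*N) x C activation matrix, column-major, rows sample-major with the
// spatial index running (Z, Y, X) column-major. buf receives the
// (S*N) x (27*C) patch matrix with columns ordered (ci-1)*27 + k, where
// k enumerates offsets (dz, dy, dx) with dz fastest. Sequential writes and
// block reads make this memory-bandwidth-bound rather than index-bound.
// [[Rcpp::export]]
NumericVector cpp_im2col3(NumericVector x, IntegerVector spdim, int N,
                          int C, NumericVector buf) {
  const int Z = spdim[0], Y = spdim[1], X = spdim[2];
  const long S = (long)Z * Y * X;
  const long SN = S * N;
  if ((long)x.size() != SN * C) stop("im2col3: x size mismatch");
  if ((long)buf.size() != SN * 27L * C) stop("im2col3: buffer mismatch");
  const double* xp = REAL(x);
  double* bp = REAL(buf);
  long col = 0;
  for (int ci = 0; ci < C; ++ci)
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dz = -1; dz <= 1; ++dz, ++col)
          for (int n = 0; n < N; ++n) {
            const double* xs = xp + (long)ci * SN + (long)n * S;
            double* out = bp + col * SN + (long)n * S;
            for (int xx = 0; xx < X; ++xx) {
              int sx = xx + dx;
              bool okx = sx >= 0 && sx < X;
              for (int yy = 0; yy < Y; ++yy) {
                int sy = yy + dy;
                long ob = ((long)xx * Y + yy) * Z;
                if (!okx || sy < 0 || sy >= Y) {
                  for (int zz = 0; zz < Z; ++zz) out[ob + zz] = 0.0;
                  continue;
                }
                long ib = ((long)sx * Y + sy) * Z + dz;
                int z0 = (dz < 0) ? 1 : 0;
                int z1 = (dz > 0) ? Z - 1 : Z;
                for (int zz = 0; zz < z0; ++zz) out[ob + zz] = 0.0;
                for (int zz = z0; zz < z1; ++zz) out[ob + zz] = xs[ib + zz];
                for (int zz = z1; zz < Z; ++zz) out[ob + zz] = 0.0;
              }
            }
          }
  return buf;
}

// col2im: scatter-add the patch matrix back onto the volume grid (the
// exact adjoint of cpp_im2col3). acc must be a zeroed (S*N) x C matrix;
// modified in place and returned.
// [[Rcpp::export]]
NumericVector cpp_col2im3(NumericVector dP, IntegerVector spdim, int N,
                          int C, NumericVector acc) {
  const int Z = spdim[0], Y = spdim[1], X = spdim[2];
  const long S = (long)Z * Y * X;
  const long SN = S * N;
  if ((long)dP.size() != SN * 27L * C) stop("col2im3: dP size mismatch");
  if ((long)acc.size() != SN * C) stop("col2im3: acc size mismatch");
  const double* dp = REAL(dP);
  double* ap = REAL(acc);
  long col = 0;
  for (int ci = 0; ci < C; ++ci)
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dz = -1; dz <= 1; ++dz, ++col)
          for (int n = 0; n < N; ++n) {
            double* as = ap + (long)ci * SN + (long)n * S;
            const double* in = dp + col * SN + (long)n * S;
            for (int xx = 0; xx < X; ++xx) {
              int sx = xx + dx;
              if (sx < 0 || sx >= X) continue;
              for (int yy = 0; yy < Y; ++yy) {
                int sy = yy + dy;
                if (sy < 0 || sy >= Y) continue;
                long ob = ((long)xx * Y + yy) * Z;
                long ib = ((long)sx * Y + sy) * Z + dz;
                int z0 = (dz < 0) ? 1 : 0;
                int z1 = (dz > 0) ? Z - 1 : Z;
                for (int zz = z0; zz < z1; ++zz) as[ib + zz] += in[ob + zz];
              }
            }
          }
  return acc;
}

// 2D analogues: 3x3 window, zero padding 1, columns (ci-1)*9 + k with k
// over (dy, dx), dy fastest.
// [[Rcpp::export]]
NumericVector cpp_im2col2(NumericVector x, IntegerVector spdim, int N,
                          int C, NumericVector buf) {
  const int Y = spdim[0], X = spdim[1];
  const long S = (long)Y * X;
  const long SN = S * N;
  if ((long)x.size() != SN * C) stop("im2col2: x size mismatch");
  if ((long)buf.size() != SN * 9L * C) stop("im2col2: buffer mismatch");
  const double* xp = REAL(x);
  double* bp = REAL(buf);
  long col = 0;
  for (int ci = 0; ci < C; ++ci)
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy, ++col)
        for (int n = 0; n < N; ++n) {
          const double* xs = xp + (long)ci * SN + (long)n * S;
          double* out = bp + col * SN + (long)n * S;
          for (int xx = 0; xx < X; ++xx) {
            int sx = xx + dx;
            long ob = (long)xx * Y;
            if (sx < 0 || sx >= X) {
              for (int yy = 0; yy < Y; ++yy) out[ob + yy] = 0.0;
              continue;
            }
            long ib = (long)sx * Y + dy;
            int y0 = (dy < 0) ? 1 : 0;
            int y1 = (dy > 0) ? Y - 1 : Y;
            for (int yy = 0; yy < y0; ++yy) out[ob + yy] = 0.0;
            for (int yy = y0; yy < y1; ++yy) out[ob + yy] = xs[ib + yy];
            for (int yy = y1; yy < Y; ++yy) out[ob + yy] = 0.0;
          }
        }
  return buf;
}

// [[Rcpp::export]]
NumericVector cpp_col2im2(NumericVector dP, IntegerVector spdim, int N,
                          int C, NumericVector acc) {
  const int Y = spdim[0], X = spdim[1];
  const long S = (long)Y * X;
  const long SN = S * N;
  if ((long)dP.size() != SN * 9L * C) stop("col2im2: dP size mismatch");
  if ((long)acc.size() != SN * C) stop("col2im2: acc size mismatch");
  const double* dp = REAL(dP);
  double* ap = REAL(acc);
  long col = 0;
  for (int ci = 0; ci < C; ++ci)
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy, ++col)
        for (int n = 0; n < N; ++n) {
          double* as = ap + (long)ci * SN + (long)n * S;
          const double* in = dp + col * SN + (long)n * S;
          for (int xx = 0; xx < X; ++xx) {
            int sx = xx + dx;
            if (sx < 0 || sx >= X) continue;
            long ob = (long)xx * Y;
            long ib = (long)sx * Y + dy;
            int y0 = (dy < 0) ? 1 : 0;
            int y1 = (dy > 0) ? Y - 1 : Y;
            for (int yy = y0; yy < y1; ++yy) as[ib + yy] += in[ob + yy];
          }
        }
  return acc;
}
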