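#include <Rcpp.h>
using namespace Rcpp;

// im2col / col2im for 3D convolution with 'same'-style padding.
//
// x is stored as a (C, nvox) matrix, voxel linear index i + nx*(j + ny*k)
// (x fastest), matching how R arrays of dim c(nx, ny, nz) flatten.
// The column matrix has k^3 * C rows; row index = c*k^3 + dk*k^2 + dj*k + di,
// and one column per output voxel. Convolution is then a single GEMM in R.

// [[Rcpp::export(name = ".cpp_im2col3d")]]
NumericMatrix cpp_im2col3d(NumericMatrix x, IntegerVector in_dims,
                           IntegerVector out_dims, int ksz,
                           IntegerVector stride, IntegerVector pad_beg) {
  const int C = x.nrow();
  const int ix = in_dims[0], iy = in_dims[1], iz = in_dims[2];
  const int ox = out_dims[0], oy = out_dims[1], oz = out_dims[2];
  const int k3 = ksz * ksz * ksz;
  NumericMatrix col((R_xlen_t)C * k3, (R_xlen_t)ox * oy * oz);
  const double* xp = REAL(x);
  double* cp = REAL(col);
  const R_xlen_t nrow = (R_xlen_t)C * k3;
  for (int okz = 0; okz < oz; ++okz)
    for (int oky = 0; oky < oy; ++oky)
      for (int okx = 0; okx < ox; ++okx) {
        R_xlen_t ocol = okx + (R_xlen_t)ox * (oky + (R_xlen_t)oy * okz);
        double* colc = cp + ocol * nrow;
        for (int dk = 0; dk < ksz; ++dk) {
          int pz = okz * stride[2] - pad_beg[2] + dk;
          for (int dj = 0; dj < ksz; ++dj) {
            int py = oky * stride[1] - pad_beg[1] + dj;
            for (int di = 0; di < ksz; ++di) {
              int px = okx * stride[0] - pad_beg[0] + di;
              int off = dk * ksz * ksz + dj * ksz + di;
              if (px < 0 || px >= ix || py < 0 || py >= iy ||
                  pz < 0 || pz >= iz) {
                for (int c = 0; c < C; ++c) colc[(R_xlen_t)c * k3 + off] = 0.0;
              } else {
                R_xlen_t vox = px + (R_xlen_t)ix * (py + (R_xlen_t)iy * pz);
                const double* xv = xp + vox * C;
                for (int c = 0; c < C; ++c) colc[(R_xlen_t)c * k3 + off] = xv[c];
              }
            }
          }
        }
      }
  return col;
}

// Adjoint of im2col: scatter-add a column matrix back onto the input grid.
// [[Rcpp::export(name = ".cpp_col2im3d")]]
NumericMatrix cpp_col2im3d(NumericMatrix col, int C, IntegerVector in_dims,
                           IntegerVector out_dims, int ksz,
                           IntegerVector stride, IntegerVector pad_beg) {
  const int ix = in_dims[0], iy = in_dims[1], iz = in_dims[2];
  const int ox = out_dims[0], oy = out_dims[1], oz = out_dims[2];
  const int k3 = ksz * ksz * ksz;
  NumericMatrix x(C, (R_xlen_t)ix * iy * iz);
  double* xp = REAL(x);
  const double* cp = REAL(col);
  const R_xlen_t nrow = (R_xlen_t)C * k3;
  for (int okz = 0; okz < oz; ++okz)
    for (int oky = 0; oky < oy; ++oky)
      for (int okx = 0; okx < ox; ++okx) {
        R_xlen_t ocol = okx + (R_xlen_t)ox * (oky + (R_xlen_t)oy * okz);
        const double* colc = cp + ocol * nrow;
        for (int dk = 0; dk < ksz; ++dk) {
          int pz = okz * stride[2] - pad_beg[2] + dk;
          if (pz < 0 || pz >= iz) continue;
          for (int dj = 0; dj < ksz; ++dj) {
            int py = oky * stride[1] - pad_beg[1] + dj;
            if (py < 0 || py >= iy) continue;
            for (int di = 0; di < ksz; ++di) {
              int px = okx * stride[0] - pad_beg[0] + di;
              if (px < 0 || px >= ix) continue;
              int off = dk * ksz * ksz + dj * ksz + di;
              R_xlen_t vox = px + (R_xlen_t)ix * (py + (R_xlen_t)iy * pz);
              double* xv = xp + vox * C;
              for (int c = 0; c < C; ++c) xv[c] += colc[(R_xlen_t)c * k3 + off];
            }
          }
        }
      }
  return x;
}
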