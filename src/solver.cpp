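#include <Rcpp.h>
using namespace Rcpp;

// Voxel linear index convention matches R arrays dim = c(nx, ny, nz):
// idx = i + nx * (j + ny * k), zero-based here.

static inline int lin(int i, int j, int k, int nx, int ny) {
  return i + nx * (j + ny * k);
}

// Diagonal of the discrete operator -lap with Robin ghost closure:
// interior-neighbour face contributes 1/d^2, exposed face h/(k_cond*d).
static std::vector<double> robin_diag(const IntegerVector& mask,
                                      int nx, int ny, int nz,
                                      double dx, double dy, double dz,
                                      double kc, double h, bool caps_insulated) {
  const double id2[3] = {1.0 / (dx * dx), 1.0 / (dy * dy), 1.0 / (dz * dz)};
  double rb[3]  = {h / (kc * dx), h / (kc * dy), h / (kc * dz)};
  if (caps_insulated) rb[2] = 0.0;
  std::vector<double> diag((size_t)nx * ny * nz, 0.0);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        int c = lin(i, j, k, nx, ny);
        if (!mask[c]) continue;
        double d = 0.0;
        // x faces
        d += (i > 0      && mask[lin(i - 1, j, k, nx, ny)]) ? id2[0] : rb[0];
        d += (i < nx - 1 && mask[lin(i + 1, j, k, nx, ny)]) ? id2[0] : rb[0];
        d += (j > 0      && mask[lin(i, j - 1, k, nx, ny)]) ? id2[1] : rb[1];
        d += (j < ny - 1 && mask[lin(i, j + 1, k, nx, ny)]) ? id2[1] : rb[1];
        d += (k > 0      && mask[lin(i, j, k - 1, nx, ny)]) ? id2[2] : rb[2];
        d += (k < nz - 1 && mask[lin(i, j, k + 1, nx, ny)]) ? id2[2] : rb[2];
        diag[c] = d;
      }
  return diag;
}

// [[Rcpp::export(name = ".cpp_poisson_solve")]]
List cpp_poisson_solve(NumericVector S_over_k, IntegerVector mask,
                       IntegerVector dims, NumericVector spacing,
                       double kc, double h, double tol, int max_iter,
                       std::string method, double omega, bool caps_insulated) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double dx = spacing[0], dy = spacing[1], dz = spacing[2];
  const double id2[3] = {1.0 / (dx * dx), 1.0 / (dy * dy), 1.0 / (dz * dz)};
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<double> diag = robin_diag(mask, nx, ny, nz, dx, dy, dz, kc, h, caps_insulated);

  NumericVector T(n, 0.0);
  std::vector<double> Told;
  const bool jacobi = (method == "jacobi");
  if (jacobi) Told.assign(n, 0.0);

  double max_upd = R_PosInf, prev_upd = R_PosInf;
  int it = 0;
  bool converged = false;
  // ring buffer of recent update ratios for a conservative estimate of the
  // iteration's convergence rate rho; the remaining error after stopping is
  // ~ upd * rho / (1 - rho), which is what `tol` bounds.
  const int RW = 8;
  double ratios[RW];
  for (int q = 0; q < RW; ++q) ratios[q] = 0.0;
  int rpos = 0, rcount = 0;

  for (it = 1; it <= max_iter; ++it) {
    prev_upd = max_upd;
    max_upd = 0.0;
    if (jacobi) std::copy(T.begin(), T.end(), Told.begin());
    const double* src = jacobi ? Told.data() : REAL(T);
    // red-black sweep degenerates to a single pass for Jacobi
    const int ncolor = jacobi ? 1 : 2;
    for (int color = 0; color < ncolor; ++color) {
      for (int k = 0; k < nz; ++k)
        for (int j = 0; j < ny; ++j)
          for (int i = 0; i < nx; ++i) {
            if (!jacobi && (((i + j + k) & 1) != color)) continue;
            int c = lin(i, j, k, nx, ny);
            if (!mask[c]) continue;
            double num = S_over_k[c];
            if (i > 0      && mask[c - 1])       num += id2[0] * src[c - 1];
            if (i < nx - 1 && mask[c + 1])       num += id2[0] * src[c + 1];
            if (j > 0      && mask[c - nx])      num += id2[1] * src[c - nx];
            if (j < ny - 1 && mask[c + nx])      num += id2[1] * src[c + nx];
            if (k > 0      && mask[c - nx * ny]) num += id2[2] * src[c - nx * ny];
            if (k < nz - 1 && mask[c + nx * ny]) num += id2[2] * src[c + nx * ny];
            double tnew = num / diag[c];
            if (!jacobi) tnew = (1.0 - omega) * T[c] + omega * tnew;
            double upd = std::fabs(tnew - T[c]);
            if (upd > max_upd) max_upd = upd;
            T[c] = tnew;
          }
    }
    if (max_upd == 0.0) { converged = true; break; }
    if (R_FINITE(prev_upd) && prev_upd > 0.0) {
      ratios[rpos] = max_upd / prev_upd;
      rpos = (rpos + 1) % RW;
      if (rcount < RW) ++rcount;
    }
    if (max_upd < tol && rcount == RW) {
      double rho = 0.0;
      for (int q = 0; q < RW; ++q) if (ratios[q] > rho) rho = ratios[q];
      double err_est = (rho < 1.0) ? max_upd * rho / (1.0 - rho) : R_PosInf;
      if (err_est < tol) { converged = true; break; }
    }
  }

  return List::create(_["T"] = T, _["iterations"] = std::min(it, max_iter),
                      _["converged"] = converged, _["last_update"] = max_upd);
}

// 7-point Laplacian of a field with the same Robin ghost closure the solver
// uses; zero outside the mask. Self-adjoint on the masked interior.
// [[Rcpp::export(name = ".cpp_robin_laplacian")]]
NumericVector cpp_robin_laplacian(NumericVector T, IntegerVector mask,
                                  IntegerVector dims, NumericVector spacing,
                                  double kc, double h, bool caps_insulated) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double dx = spacing[0], dy = spacing[1], dz = spacing[2];
  const double id2[3] = {1.0 / (dx * dx), 1.0 / (dy * dy), 1.0 / (dz * dz)};
  double rb[3]  = {h / (kc * dx), h / (kc * dy), h / (kc * dz)};
  if (caps_insulated) rb[2] = 0.0;
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector L(n, 0.0);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        int c = lin(i, j, k, nx, ny);
        if (!mask[c]) continue;
        double acc = 0.0;
        if (i > 0      && mask[c - 1])       acc += id2[0] * (T[c - 1] - T[c]);       else acc -= rb[0] * T[c];
        if (i < nx - 1 && mask[c + 1])       acc += id2[0] * (T[c + 1] - T[c]);       else acc -= rb[0] * T[c];
        if (j > 0      && mask[c - nx])      acc += id2[1] * (T[c - nx] - T[c]);      else acc -= rb[1] * T[c];
        if (j < ny - 1 && mask[c + nx])      acc += id2[1] * (T[c + nx] - T[c]);      else acc -= rb[1] * T[c];
        if (k > 0      && mask[c - nx * ny]) acc += id2[2] * (T[c - nx * ny] - T[c]); else acc -= rb[2] * T[c];
        if (k < nz - 1 && mask[c + nx * ny]) acc += id2[2] * (T[c + nx * ny] - T[c]); else acc -= rb[2] * T[c];
        L[c] = acc;
      }
  return L;
}
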