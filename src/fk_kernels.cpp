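// Finite-difference kernels for the Fisher-Kolmogorov model on a masked
// Cartesian grid, plus the Crank-Nicolson residual and its adjoint.
//
// Conventions: volumes are flat arrays in R's column-major order with x
// fastest, i.e. index(i,j,k) = i + nx*(j + ny*k), 0-based here. The 4D field
// stacks time slices contiguously: slice n occupies [n*nvox, (n+1)*nvox).
// `omega` marks the diffusible-tissue region; faces with at least one
// endpoint outside omega carry zero diffusion coefficient (no-flux).

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline int vox(int i, int j, int k, int nx, int ny) {
  return i + nx * (j + ny * k);
}

// A(u): conservative diffusion stencil with face coefficients averaged from
// voxel values, accumulated flux-wise so symmetry is exact.
static void apply_A(const double* u, const double* m, const int* om,
                    int nx, int ny, int nz, const double* invh2, double* out) {
  const int nvox = nx * ny * nz;
  for (int v = 0; v < nvox; ++v) out[v] = 0.0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        const int v = vox(i, j, k, nx, ny);
        if (!om[v]) continue;
        if (i + 1 < nx && om[v + 1]) {
          const double f = 0.5 * (m[v] + m[v + 1]) * (u[v + 1] - u[v]) * invh2[0];
          out[v] += f; out[v + 1] -= f;
        }
        if (j + 1 < ny && om[v + nx]) {
          const double f = 0.5 * (m[v] + m[v + nx]) * (u[v + nx] - u[v]) * invh2[1];
          out[v] += f; out[v + nx] -= f;
        }
        if (k + 1 < nz && om[v + nx * ny]) {
          const double f = 0.5 * (m[v] + m[v + nx * ny]) * (u[v + nx * ny] - u[v]) * invh2[2];
          out[v] += f; out[v + nx * ny] -= f;
        }
      }
}

// [[Rcpp::export]]
NumericVector cpp_apply_A(NumericVector u, NumericVector m, IntegerVector omega,
                          IntegerVector dim, NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const double invh2[3] = {1.0 / (spacing[0] * spacing[0]),
                           1.0 / (spacing[1] * spacing[1]),
                           1.0 / (spacing[2] * spacing[2])};
  NumericVector out(u.size());
  apply_A(u.begin(), m.begin(), omega.begin(), nx, ny, nz, invh2, out.begin());
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_fk_step(NumericVector u, NumericVector m, IntegerVector omega,
                          IntegerVector dim, NumericVector spacing,
                          double rho, double dt) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int nvox = nx * ny * nz;
  const double invh2[3] = {1.0 / (spacing[0] * spacing[0]),
                           1.0 / (spacing[1] * spacing[1]),
                           1.0 / (spacing[2] * spacing[2])};
  std::vector<double> a(nvox);
  apply_A(u.begin(), m.begin(), omega.begin(), nx, ny, nz, invh2, a.data());
  NumericVector out(nvox);
  for (int v = 0; v < nvox; ++v) {
    if (!omega[v]) { out[v] = 0.0; continue; }
    double val = u[v] + dt * (a[v] + rho * u[v] * (1.0 - u[v]));
    if (val < 0.0) val = 0.0;
    if (val > 1.0) val = 1.0;
    out[v] = val;
  }
  return out;
}

// Explicit Euler run; returns the saved slices (columns) at step counts
// `save_at` (0-based, ascending, save_at[0] may be 0 for the initial state).
// [[Rcpp::export]]
NumericVector cpp_fk_simulate(NumericVector u0, NumericVector m, IntegerVector omega,
                              IntegerVector dim, NumericVector spacing,
                              double rho, double dt, int nsteps,
                              IntegerVector save_at) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int nvox = nx * ny * nz;
  const double invh2[3] = {1.0 / (spacing[0] * spacing[0]),
                           1.0 / (spacing[1] * spacing[1]),
                           1.0 / (spacing[2] * spacing[2])};
  const int nsave = save_at.size();
  NumericVector out((R_xlen_t)nvox * nsave);
  std::vector<double> u(u0.begin(), u0.end()), a(nvox);
  for (int v = 0; v < nvox; ++v) if (!omega[v]) u[v] = 0.0;
  int si = 0;
  if (si < nsave && save_at[si] == 0) {
    std::copy(u.begin(), u.end(), out.begin());
    ++si;
  }
  for (int s = 1; s <= nsteps; ++s) {
    apply_A(u.data(), m.begin(), omega.begin(), nx, ny, nz, invh2, a.data());
    double chk = 0.0;
    for (int v = 0; v < nvox; ++v) {
      if (!omega[v]) continue;
      double val = u[v] + dt * (a[v] + rho * u[v] * (1.0 - u[v]));
      if (val < 0.0) val = 0.0;
      if (val > 1.0) val = 1.0;
      u[v] = val;
      chk += val;
    }
    if (!std::isfinite(chk))
      stop("forward solver diverged (non-finite density) at step %d", s);
    if (si < nsave && save_at[si] == s) {
      std::copy(u.begin(), u.end(), out.begin() + (R_xlen_t)si * nvox);
      ++si;
    }
  }
  return out;
}

// Crank-Nicolson residual between two consecutive slices.
// [[Rcpp::export]]
NumericVector cpp_cn_residual(NumericVector u0, NumericVector u1,
                              NumericVector m, IntegerVector omega,
                              IntegerVector dim, NumericVector spacing,
                              double rho, double dt) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int nvox = nx * ny * nz;
  const double invh2[3] = {1.0 / (spacing[0] * spacing[0]),
                           1.0 / (spacing[1] * spacing[1]),
                           1.0 / (spacing[2] * spacing[2])};
  std::vector<double> a0(nvox), a1(nvox);
  apply_A(u0.begin(), m.begin(), omega.begin(), nx, ny, nz, invh2, a0.data());
  apply_A(u1.begin(), m.begin(), omega.begin(), nx, ny, nz, invh2, a1.data());
  NumericVector K(nvox);
  for (int v = 0; v < nvox; ++v) {
    if (!omega[v]) { K[v] = 0.0; continue; }
    const double b0 = rho * u0[v] * (1.0 - u0[v]);
    const double b1 = rho * u1[v] * (1.0 - u1[v]);
    K[v] = (u1[v] - u0[v]) / dt - 0.5 * (a1[v] + a0[v]) - 0.5 * (b1 + b0);
  }
  return K;
}

// Sum of squared CN residuals over all slice pairs, with adjoint gradients
// with respect to the 4D field, the voxelwise diffusion coefficient, and rho.
// The diffusion operator is self-adjoint under the face construction, so the
// field gradient reuses apply_A on the residual-weight slices.
// [[Rcpp::export]]
List cpp_pde_loss_grad(NumericVector u4d, NumericVector m, IntegerVector omega,
                       IntegerVector dim4, NumericVector spacing,
                       double rho, double dt, bool want_grad) {
  const int nx = dim4[0], ny = dim4[1], nz = dim4[2], nt = dim4[3];
  const int nvox = nx * ny * nz;
  const double invh2[3] = {1.0 / (spacing[0] * spacing[0]),
                           1.0 / (spacing[1] * spacing[1]),
                           1.0 / (spacing[2] * spacing[2])};
  std::vector<double> A_all((size_t)nvox * nt);
  for (int n = 0; n < nt; ++n)
    apply_A(u4d.begin() + (R_xlen_t)n * nvox, m.begin(), omega.begin(),
            nx, ny, nz, invh2, A_all.data() + (size_t)n * nvox);

  std::vector<double> K((size_t)nvox * (nt - 1), 0.0);
  double loss = 0.0;
  for (int n = 0; n + 1 < nt; ++n) {
    const double* u0 = u4d.begin() + (R_xlen_t)n * nvox;
    const double* u1 = u0 + nvox;
    const double* a0 = A_all.data() + (size_t)n * nvox;
    const double* a1 = a0 + nvox;
    double* Kn = K.data() + (size_t)n * nvox;
    for (int v = 0; v < nvox; ++v) {
      if (!omega[v]) continue;
      const double b0 = rho * u0[v] * (1.0 - u0[v]);
      const double b1 = rho * u1[v] * (1.0 - u1[v]);
      const double r = (u1[v] - u0[v]) / dt - 0.5 * (a1[v] + a0[v]) - 0.5 * (b1 + b0);
      Kn[v] = r;
      loss += r * r;
    }
  }
  if (!want_grad)
    return List::create(_["loss"] = loss);

  NumericVector grad_u(u4d.size());
  NumericVector grad_m(nvox);
  double grad_rho = 0.0;
  // direct time-difference and reaction paths
  for (int n = 0; n + 1 < nt; ++n) {
    const double* u0 = u4d.begin() + (R_xlen_t)n * nvox;
    const double* u1 = u0 + nvox;
    const double* Kn = K.data() + (size_t)n * nvox;
    double* g0 = grad_u.begin() + (R_xlen_t)n * nvox;
    double* g1 = g0 + nvox;
    for (int v = 0; v < nvox; ++v) {
      if (!omega[v]) continue;
      const double W = 2.0 * Kn[v];
      g0[v] += W * (-1.0 / dt - 0.5 * rho * (1.0 - 2.0 * u0[v]));
      g1[v] += W * (1.0 / dt - 0.5 * rho * (1.0 - 2.0 * u1[v]));
      grad_rho -= 0.5 * W * (u0[v] * (1.0 - u0[v]) + u1[v] * (1.0 - u1[v]));
    }
  }
  // diffusion path: slice s enters the loss linearly through A(u_s) with
  // coefficient c_s = -(K_{s-1} + K_s); A is self-adjoint, so the field
  // gradient is A(c_s), and the same face sweep accumulates grad_m.
  std::vector<double> c(nvox);
  const int nxy = nx * ny;
  for (int s = 0; s < nt; ++s) {
    const double* u_s = u4d.begin() + (R_xlen_t)s * nvox;
    double* gs = grad_u.begin() + (R_xlen_t)s * nvox;
    const double* Km = (s > 0) ? K.data() + (size_t)(s - 1) * nvox : nullptr;
    const double* Kp = (s < nt - 1) ? K.data() + (size_t)s * nvox : nullptr;
    for (int v = 0; v < nvox; ++v)
      c[v] = -((Km ? Km[v] : 0.0) + (Kp ? Kp[v] : 0.0));
    double* gm = grad_m.begin();
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j) {
        const int base = nx * (j + ny * k);
        for (int i = 0; i < nx; ++i) {
          const int v = base + i;
          if (!omega[v]) continue;
          if (i + 1 < nx && omega[v + 1]) {
            const double dc = c[v + 1] - c[v];
            const double f = 0.5 * (m[v] + m[v + 1]) * dc * invh2[0];
            gs[v] += f; gs[v + 1] -= f;
            const double gf = -dc * (u_s[v + 1] - u_s[v]) * invh2[0] * 0.5;
            gm[v] += gf; gm[v + 1] += gf;
          }
          if (j + 1 < ny && omega[v + nx]) {
            const double dc = c[v + nx] - c[v];
            const double f = 0.5 * (m[v] + m[v + nx]) * dc * invh2[1];
            gs[v] += f; gs[v + nx] -= f;
            const double gf = -dc * (u_s[v + nx] - u_s[v]) * invh2[1] * 0.5;
            gm[v] += gf; gm[v + nx] += gf;
          }
          if (k + 1 < nz && omega[v + nxy]) {
            const double dc = c[v + nxy] - c[v];
            const double f = 0.5 * (m[v] + m[v + nxy]) * dc * invh2[2];
            gs[v] += f; gs[v + nxy] -= f;
            const double gf = -dc * (u_s[v + nxy] - u_s[v]) * invh2[2] * 0.5;
            gm[v] += gf; gm[v + nxy] += gf;
          }
        }
      }
  }
  return List::create(_["loss"] = loss, _["grad_u"] = grad_u,
                      _["grad_m"] = grad_m, _["grad_rho"] = grad_rho);
}
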