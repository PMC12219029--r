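#' Gaussian focal initial condition
#'
#' `G(x) = C1 * exp(-|x - x0|^2 / C2)` with `C1 = 50 / (60*pi)^(3/2)` and
#' `C2 = 60` (mm^2), zero outside the diffusible region. The constants fix the
#' initial lesion mass and width to a small focal seed.
#'
#' @param domain an [fk_domain()]
#' @param center seed center (x0, y0, z0) in mm
#' @param native evaluate on the native-resolution ROI grid instead of the
#'   solver grid
#' @return 3D array
#' @export
gaussian_ic <- function(domain, center, native = FALSE) {
  g <- domain_grid(domain, native)
  if (!center_in_omega(g, center))
    stop("seed center (", paste(signif(center, 4), collapse = ", "),
         ") lies outside the diffusible region omega1")
  gaussian_field(g$shape, g$origin, g$spacing, center, g$omega)
}

# grid descriptor for solver or native ROI resolution
domain_grid <- function(domain, native = FALSE) {
  if (native)
    list(shape = domain$native$shape, origin = domain$origin_mm,
         spacing = domain$spacing_native, omega = domain$native$omega1,
         wm = domain$native$wm, gm = domain$native$gm)
  else
    list(shape = domain$solver_shape, origin = domain$origin_mm,
         spacing = domain$spacing, omega = domain$omega1,
         wm = domain$wm, gm = domain$gm)
}

gaussian_field <- function(shape, origin, spacing, center, omega = NULL,
                           c1 = 50 / (60 * pi)^1.5, c2 = 60) {
  x <- origin[1] + (seq_len(shape[1]) - 1) * spacing[1]
  y <- origin[2] + (seq_len(shape[2]) - 1) * spacing[2]
  z <- origin[3] + (seq_len(shape[3]) - 1) * spacing[3]
  dx2 <- (x - center[1])^2
  dy2 <- (y - center[2])^2
  dz2 <- (z - center[3])^2
  r2 <- outer(outer(dx2, dy2, "+"), dz2, "+")
  g <- c1 * exp(-r2 / c2)
  if (!is.null(omega)) g[!omega] <- 0
  g
}

center_in_omega <- function(g, center) {
  idx <- round((center - g$origin) / g$spacing) + 1
  if (any(idx < 1) || any(idx > g$shape)) return(FALSE)
  g$omega[idx[1], idx[2], idx[3]]
}

#' Stable explicit time step for the reaction-diffusion solver
#'
#' 3D diffusion CFL bound `dt <= h^2 / (6 * max D)` combined with the logistic
#' bound `dt <= 0.5 / rho`.
#'
#' @param D diffusion field (or its maximum)
#' @param rho proliferation rate
#' @param spacing voxel spacing in mm
#' @return scalar dt
#' @export
stable_dt <- function(D, rho, spacing) {
  dmax <- max(D)
  dt_d <- if (dmax > 0) min(spacing)^2 / (6 * dmax) else Inf
  dt_r <- if (rho > 0) 0.5 / rho else Inf
  min(dt_d, dt_r)
}

#' Single explicit Euler step of the Fisher-Kolmogorov equation
#'
#' `u' = clip(u + dt * (A(u) + rho*u*(1-u)), 0, 1)` with the conservative
#' face-averaged diffusion stencil `A` and no-flux boundaries at the edge of
#' the diffusible region.
#'
#' @param u density volume
#' @param D voxelwise diffusion field
#' @param omega1 diffusible-tissue mask
#' @param rho proliferation rate
#' @param dt time step
#' @param spacing voxel spacing (mm)
#' @param stability `"error"`, `"warn"`, or `"none"` when `dt` violates the
#'   explicit stability bound
#' @return updated density volume
#' @export
fk_step <- function(u, D, omega1, rho, dt, spacing, stability = "error") {
  bound <- stable_dt(D, rho, spacing)
  if (dt > bound * (1 + 1e-12)) {
    msg <- sprintf("dt = %g exceeds the stability bound %g", dt, bound)
    if (stability == "error") stop(msg)
    if (stability == "warn") warning(msg)
  }
  array(cpp_fk_step(as.numeric(u), as.numeric(D), as.integer(omega1),
                    as.integer(dim(u)), as.numeric(spacing), rho, dt),
        dim = dim(u))
}

#' Forward simulation of tumor growth
#'
#' Explicit Euler integration of the Fisher-Kolmogorov equation from the
#' Gaussian focal seed (or a supplied initial condition), storing snapshots on
#' a uniform temporal grid.
#'
#' @param domain an [fk_domain()]
#' @param params an [fk_params()]
#' @param t_final total simulated time (default 1: normalized timescale)
#' @param n_store number of stored time points including the initial state
#' @param dt time step; defaults to the stability bound
#' @param native run at native ROI resolution instead of the solver grid
#' @param ic optional initial condition (defaults to [gaussian_ic()])
#' @return object of class `fk_trajectory`: list with 4D array `u`
#'   (x, y, z, time), `times`, `dt`, `spacing`, `params`
#' @export
fk_simulate <- function(domain, params, t_final = 1, n_store = domain$n_time,
                        dt = NULL, native = FALSE, ic = NULL) {
  g <- domain_grid(domain, native)
  D <- build_diffusion_field_raw(g$wm, g$gm, g$omega, params$d_w, params$r)
  u0 <- if (is.null(ic)) gaussian_ic(domain, params$center, native) else ic
  bound <- stable_dt(D, params$rho, g$spacing)
  if (is.null(dt)) dt <- bound else if (dt > bound * (1 + 1e-12))
    stop(sprintf("dt = %g exceeds the stability bound %g", dt, bound))
  nsteps <- max(as.integer(ceiling(t_final / dt)), n_store - 1L)
  dt <- t_final / nsteps
  save_at <- as.integer(round(seq(0, nsteps, length.out = n_store)))
  stopifnot(all(diff(save_at) >= 1L))
  u <- cpp_fk_simulate(as.numeric(u0), as.numeric(D), as.integer(g$omega),
                       as.integer(g$shape), as.numeric(g$spacing),
                       params$rho, dt, nsteps, save_at)
  structure(list(u = array(u, dim = c(g$shape, n_store)),
                 times = save_at * dt, dt = dt, t_final = t_final,
                 spacing = g$spacing, params = params),
            class = "fk_trajectory")
}

build_diffusion_field_raw <- function(wm, gm, omega, d_w, r) {
  D <- wm * d_w + gm * d_w / r
  D[!omega] <- 0
  D
}

#' @export
print.fk_trajectory <- function(x, ...) {
  d <- dim(x$u)
  cat("<fk_trajectory>", paste(d[1:3], collapse = "x"), "x", d[4],
      sprintf("time points, t_final = %g, dt = %g\n", x$t_final, x$dt))
  invisible(x)
}

#' Implicit Crank-Nicolson forward solve
#'
#' Integrates the growth equation with the same Crank-Nicolson discretization
#' that defines the PDE residual, solving each step's nonlinear system by
#' fixed-point iteration. A trajectory produced here has (near-)zero discrete
#' residual by construction, which makes it the self-consistency reference for
#' the residual loss.
#'
#' @param u0 initial condition
#' @param D,omega1,rho,spacing as in [fk_step()]
#' @param n_time number of time slices on `[0, t_final]`
#' @param t_final total time
#' @param tol fixed-point convergence tolerance (max-norm)
#' @param max_iter maximum fixed-point iterations per step
#' @return 4D array (x, y, z, time) with `n_time` slices
#' @export
cn_simulate <- function(u0, D, omega1, rho, spacing, n_time, t_final = 1,
                        tol = 1e-13, max_iter = 400) {
  dt <- t_final / (n_time - 1)
  shp <- dim(u0)
  dimv <- as.integer(shp)
  om <- as.integer(omega1)
  Dn <- as.numeric(D)
  u <- array(0, dim = c(shp, n_time))
  cur <- as.numeric(u0)
  cur[!omega1] <- 0
  u[, , , 1] <- cur
  for (n in seq_len(n_time - 1)) {
    a0 <- cpp_apply_A(cur, Dn, om, dimv, spacing)
    b0 <- rho * cur * (1 - cur)
    nxt <- cur
    for (it in seq_len(max_iter)) {
      a1 <- cpp_apply_A(nxt, Dn, om, dimv, spacing)
      b1 <- rho * nxt * (1 - nxt)
      upd <- cur + 0.5 * dt * (a0 + b0 + a1 + b1)
      upd[!omega1] <- 0
      delta <- max(abs(upd - nxt))
      nxt <- upd
      if (delta < tol) break
    }
    if (delta >= tol)
      warning(sprintf("CN fixed point not fully converged at step %d (delta=%g)",
                      n, delta))
    cur <- nxt
    u[, , , n + 1] <- cur
  }
  u
}

#' Estimate the traveling-front speed along the x axis
#'
#' Tracks the farthest x position where the density exceeds `level` on the
#' central line of the volume and fits position against time by least squares
#' over the later half of the snapshots (after transients).
#'
#' @param traj an [fk_simulate()] trajectory (quasi-1D slab recommended)
#' @param level density level defining the front (default 0.5)
#' @return estimated speed (mm per unit time)
#' @export
front_speed <- function(traj, level = 0.5) {
  d <- dim(traj$u)
  jmid <- ceiling(d[2] / 2); kmid <- ceiling(d[3] / 2)
  pos <- rep(NA_real_, d[4])
  for (n in seq_len(d[4])) {
    line <- traj$u[, jmid, kmid, n]
    idx <- which(line >= level)
    if (length(idx)) {
      i <- max(idx)
      # linear interpolation of the crossing
      if (i < d[1] && line[i] != line[i + 1]) {
        frac <- (line[i] - level) / (line[i] - line[i + 1])
        pos[n] <- (i - 1 + frac) * traj$spacing[1]
      } else pos[n] <- (i - 1) * traj$spacing[1]
    }
  }
  ok <- which(!is.na(pos))
  ok <- ok[ok > length(pos) / 2]
  if (length(ok) < 3) stop("front not trackable: too few crossings")
  fit <- stats::lm.fit(cbind(1, traj$times[ok]), pos[ok])
  unname(fit$coefficients[2])
}
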