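#' Imaging-model parameters
#'
#' Four adjustable parameters link the simulated cell density to imaging:
#' `theta_down`/`theta_up` are the density thresholds delimiting the edema
#' band and the tumor core, `theta_pet` scales and `theta_bkg` offsets the
#' normalized PET signal.
#'
#' @param theta_down,theta_up thresholds in (0, 1) with `theta_down < theta_up`
#' @param theta_pet positive PET scale
#' @param theta_bkg PET background offset in \[0, 1)
#' @return object of class `fk_imaging`
#' @export
fk_imaging <- function(theta_down = 0.25, theta_up = 0.525,
                       theta_pet = 1, theta_bkg = 0) {
  if (!(theta_down > 0 && theta_up < 1 && theta_down < theta_up))
    stop("need 0 < theta_down < theta_up < 1")
  if (theta_pet <= 0) stop("theta_pet must be positive")
  if (theta_bkg < 0 || theta_bkg >= 1) stop("theta_bkg must lie in [0, 1)")
  structure(list(theta_down = theta_down, theta_up = theta_up,
                 theta_pet = theta_pet, theta_bkg = theta_bkg),
            class = "fk_imaging")
}

#' Loss weights
#'
#' The PDE weight is fixed at 1 by calibration on the synthetic benchmark; the
#' initial-condition term gets a deliberately low weight because the focal
#' single-seed assumption is uncertain.
#'
#' @param lambda_pde,lambda_ic,lambda_core,lambda_edema,lambda_pet,lambda_params
#'   non-negative weights
#' @return named list of class `fk_weights`
#' @export
fk_weights <- function(lambda_pde = 1, lambda_ic = 1e-2, lambda_core = 1,
                       lambda_edema = 1, lambda_pet = 1, lambda_params = 1e-2) {
  w <- list(lambda_pde = lambda_pde, lambda_ic = lambda_ic,
            lambda_core = lambda_core, lambda_edema = lambda_edema,
            lambda_pet = lambda_pet, lambda_params = lambda_params)
  if (any(unlist(w) < 0)) stop("loss weights must be non-negative")
  structure(w, class = "fk_weights")
}

#' Data masks at the imaging time slice
#'
#' The imaging slice (`omega2`) is the final time slice of the space-time
#' field. `omega3`, where the PET term applies, is the metabolically active
#' subset: (enhancing union edema) minus necrotic.
#'
#' @param domain an [fk_domain()]
#' @return list with logical solver-grid volumes `core` (enhancing + necrotic),
#'   `edema`, `omega3`
#' @export
fk_data_masks <- function(domain) {
  core <- domain$seg_enhancing | domain$seg_necrotic
  list(core = core,
       edema = domain$seg_edema,
       omega3 = (domain$seg_enhancing | domain$seg_edema) & !domain$seg_necrotic)
}

#' Normalize a PET volume to \[0, 1\]
#'
#' Divides by the maximum over the brain mask and clips.
#' @param pet raw PET volume
#' @param brain logical brain mask
#' @return volume in \[0, 1\]
#' @export
normalize_pet <- function(pet, brain) {
  m <- max(pet[brain], 0)
  if (m <= 0) {
    warning("PET volume is zero over the brain mask")
    return(array(0, dim = dim(pet)))
  }
  pmin(pmax(pet / m, 0), 1)
}

#' Numerically stable steep sigmoid
#'
#' `sigmoid(x, beta) = 1 / (1 + exp(-beta * x))`; `beta = 50` sets the
#' steepness of the soft threshold transitions in the imaging model.
#'
#' @param x numeric
#' @param beta steepness
#' @return values in (0, 1), saturating without overflow
#' @export
sigmoid <- function(x, beta = 50) stats::plogis(beta * x)

# threshold offset of the segmentation penalties
FK_ALPHA <- 0.05

#' Crank-Nicolson residual between two time slices
#'
#' `K = (u1 - u0)/dt - (A(u1) + A(u0))/2 - (B(u1) + B(u0))/2`, evaluated over
#' the diffusible region with no-flux face coefficients; zero outside.
#'
#' @param u0,u1 density volumes at consecutive time points
#' @param D voxelwise diffusion field
#' @param omega1 diffusible-tissue mask
#' @param rho proliferation rate
#' @param dt time step
#' @param spacing voxel spacing (mm)
#' @return residual volume
#' @export
residual_cn <- function(u0, u1, D, omega1, rho, dt, spacing) {
  array(cpp_cn_residual(as.numeric(u0), as.numeric(u1), as.numeric(D),
                        as.integer(omega1), as.integer(dim(u0)),
                        as.numeric(spacing), rho, dt),
        dim = dim(u0))
}

#' PDE residual loss
#'
#' Sum of squared Crank-Nicolson residuals over all voxels of the diffusible
#' region and all consecutive time-slice pairs.
#'
#' @param u4d 4D array (x, y, z, time) on the normalized time interval
#' @param D voxelwise diffusion field
#' @param omega1 diffusible-tissue mask
#' @param rho proliferation rate
#' @param spacing voxel spacing (mm)
#' @param t_final total time spanned by the slices (default 1)
#' @return scalar loss
#' @export
loss_pde <- function(u4d, D, omega1, rho, spacing, t_final = 1) {
  d <- dim(u4d)
  dt <- t_final / (d[4] - 1)
  res <- cpp_pde_loss_grad(as.numeric(u4d), as.numeric(D), as.integer(omega1),
                           as.integer(d), as.numeric(spacing), rho, dt, FALSE)
  res$loss
}

#' Initial-condition loss
#'
#' Squared deviation of the first time slice from the Gaussian focal seed,
#' summed over the diffusible region; smooth in the seed center.
#'
#' @param u0 first time slice
#' @param center seed center (mm)
#' @param domain an [fk_domain()]
#' @return scalar loss
#' @export
loss_ic <- function(u0, center, domain) {
  g <- domain_grid(domain)
  G <- gaussian_field(g$shape, g$origin, g$spacing, center, g$omega)
  sum(((u0 - G)[g$omega])^2)
}

#' Tumor-core segmentation loss
#'
#' Penalizes density below `theta_up` inside the core: each core voxel
#' contributes `sigmoid(theta_up - u - alpha)`, approximately 1 when the
#' density undershoots the core threshold and 0 once it exceeds it.
#'
#' @param u_final density at the imaging slice
#' @param core_mask logical core (enhancing + necrotic) mask
#' @param theta_up upper density threshold
#' @param beta sigmoid steepness
#' @param alpha threshold offset
#' @return scalar loss
#' @export
loss_core <- function(u_final, core_mask, theta_up, beta = 50, alpha = FK_ALPHA) {
  if (!any(core_mask)) return(0)
  sum(sigmoid(theta_up - u_final[core_mask] - alpha, beta))
}

#' Edema segmentation loss
#'
#' Band constraint: edema voxels should carry density between `theta_down`
#' and `theta_up`; both escape directions are penalized.
#'
#' @param u_final density at the imaging slice
#' @param edema_mask logical edema mask
#' @param theta_down,theta_up density band
#' @param beta sigmoid steepness
#' @param alpha threshold offset
#' @return scalar loss
#' @export
loss_edema <- function(u_final, edema_mask, theta_down, theta_up,
                       beta = 50, alpha = FK_ALPHA) {
  if (theta_down >= theta_up) stop("theta_down must be below theta_up")
  if (!any(edema_mask)) return(0)
  u <- u_final[edema_mask]
  sum(sigmoid(theta_down - u - alpha, beta) +
        (1 - sigmoid(theta_up - u + alpha, beta)))
}

#' PET data loss
#'
#' Matches the density to the affinely mapped normalized PET signal
#' `p = theta_pet * (y - theta_bkg)` over the metabolically active region.
#'
#' @param u_final density at the imaging slice
#' @param pet_norm PET volume normalized to \[0, 1\]
#' @param omega3 logical metabolically active mask (necrosis excluded)
#' @param theta_pet PET scale
#' @param theta_bkg PET background offset
#' @return scalar loss
#' @export
loss_pet <- function(u_final, pet_norm, omega3, theta_pet, theta_bkg) {
  if (!any(omega3)) {
    warning("PET loss region omega3 is empty; returning 0")
    return(0)
  }
  p <- theta_pet * (pet_norm[omega3] - theta_bkg)
  sum((u_final[omega3] - p)^2)
}

widen_range <- function(rng, factor = 0.5, lo_min = -Inf) {
  w <- diff(rng)
  c(max(rng[1] - factor * w, lo_min), rng[2] + factor * w)
}

#' Default plausibility bounds for the regularizer
#'
#' Growth rates are expressed on the normalized timescale (rate times total
#' simulated time), so the synthetic-benchmark generation ranges scaled by the
#' simulated duration anchor the plausible range; ranges are widened by half
#' their width on each side. Seed-center bounds default to the ROI box and are
#' filled in by the optimizer.
#'
#' @param t_scale timescale converting per-unit-time generation ranges to
#'   normalized rates (default 100)
#' @return named list of `c(lo, hi)` bounds
#' @export
default_param_bounds <- function(t_scale = 100) {
  list(
    d_w = widen_range(c(0.035, 0.2) * t_scale, lo_min = 0.0035 * t_scale),
    rho = widen_range(c(0.035, 0.2) * t_scale, lo_min = 0.0035 * t_scale),
    r = widen_range(c(10, 30), lo_min = 1.5),
    theta_down = widen_range(c(0.15, 0.35), lo_min = 0.01),
    theta_up = widen_range(c(0.45, 0.6)),
    theta_pet = widen_range(c(0.5, 1.5), lo_min = 0.05),
    theta_bkg = c(0, 0.5)
  )
}

hinge_sq <- function(p, rng) {
  w <- diff(rng)
  (max(0, rng[1] - p)^2 + max(0, p - rng[2])^2) / w^2
}

#' Parameter plausibility regularizer
#'
#' Squared hinge distance outside each parameter's plausible interval, scaled
#' by the inverse squared interval width (a parameter one full width outside
#' contributes 1). An additional ordering hinge penalizes
#' `theta_up < theta_down`, scaled by the `theta_up` interval width.
#'
#' @param params an [fk_params()]
#' @param imaging an [fk_imaging()]-like list (ordering not enforced here)
#' @param bounds named list of `c(lo, hi)`; see [default_param_bounds()].
#'   May include `x0`, `y0`, `z0` entries bounding the seed center.
#' @return scalar loss, zero when everything is inside its bounds
#' @export
loss_params <- function(params, imaging, bounds = default_param_bounds()) {
  for (rng in bounds) if (rng[1] >= rng[2]) stop("invalid bounds: lo >= hi")
  total <- hinge_sq(params$d_w, bounds$d_w) +
    hinge_sq(params$rho, bounds$rho) +
    hinge_sq(params$r, bounds$r) +
    hinge_sq(imaging$theta_down, bounds$theta_down) +
    hinge_sq(imaging$theta_up, bounds$theta_up) +
    hinge_sq(imaging$theta_pet, bounds$theta_pet) +
    hinge_sq(imaging$theta_bkg, bounds$theta_bkg)
  for (i in 1:3) {
    nm <- c("x0", "y0", "z0")[i]
    if (!is.null(bounds[[nm]])) total <- total + hinge_sq(params$center[i], bounds[[nm]])
  }
  # ordering hinge: active only when theta_up dips below theta_down
  gap <- imaging$theta_down - imaging$theta_up
  if (gap > 0) total <- total + (gap / diff(bounds$theta_up))^2
  total
}

#' Total loss
#'
#' Weighted sum of the PDE residual, initial-condition, segmentation, PET, and
#' parameter-plausibility terms.
#'
#' @param u4d 4D density field on the solver grid (final slice = imaging slice)
#' @param domain an [fk_domain()]
#' @param params an [fk_params()] (normalized-timescale rates)
#' @param imaging an [fk_imaging()]
#' @param weights an [fk_weights()]
#' @param bounds plausibility bounds for [loss_params()]
#' @return object of class `fk_loss_report`: named per-term values and the
#'   weighted `total`
#' @export
total_loss <- function(u4d, domain, params, imaging, weights = fk_weights(),
                       bounds = default_param_bounds()) {
  d <- dim(u4d)
  masks <- fk_data_masks(domain)
  D <- build_diffusion_field(domain, params)
  uT <- u4d[, , , d[4]]
  terms <- c(
    L_PDE = loss_pde(u4d, D, domain$omega1, params$rho, domain$spacing),
    L_IC = loss_ic(u4d[, , , 1], params$center, domain),
    L_CORE = loss_core(uT, masks$core, imaging$theta_up),
    L_EDEMA = loss_edema(uT, masks$edema, imaging$theta_down, imaging$theta_up),
    L_PET = if (is.null(domain$pet) || weights$lambda_pet == 0) 0 else
      loss_pet(uT, normalize_pet(domain$pet, domain$brain), masks$omega3,
               imaging$theta_pet, imaging$theta_bkg),
    L_PARAMS = loss_params(params, imaging, bounds)
  )
  lam <- c(weights$lambda_pde, weights$lambda_ic, weights$lambda_core,
           weights$lambda_edema, weights$lambda_pet, weights$lambda_params)
  structure(list(terms = terms, weights = lam,
                 per_voxel = terms / (sum(domain$omega1) * max(d[4] - 1, 1)),
                 total = sum(lam * terms)),
            class = "fk_loss_report")
}

#' @export
print.fk_loss_report <- function(x, ...) {
  cat("<fk_loss_report> total =", format(x$total, digits = 6), "\n")
  for (i in seq_along(x$terms))
    cat(sprintf("  %-9s %-12.6g (lambda = %g)\n", names(x$terms)[i],
                x$terms[i], x$weights[i]))
  invisible(x)
}
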