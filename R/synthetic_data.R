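#' Procedural brain tissue phantom
#'
#' A self-contained stand-in for a tissue atlas: an ellipsoidal brain with a
#' gray-matter cortical shell, white-matter interior, and two ventricle-like
#' CSF lobes. Any user-supplied atlas volumes can be used in its place; the
#' generator only requires the `wm`/`gm`/`csf`/`brain` fields.
#'
#' The default grid spans the 240 x 240 x 156 mm frame of a standard
#' registered head volume (at 2 mm rather than 1 mm voxels), so that seed
#' centers expressed in that frame's millimeter coordinates fall
#' mid-hemisphere, surrounded by tissue, rather than at the cortical margin.
#'
#' @param shape grid size (default 120 x 120 x 78)
#' @param spacing voxel spacing in mm (default 2)
#' @return list of class `fk_phantom` with tissue volumes and `spacing`
#' @export
fk_phantom <- function(shape = c(120, 120, 78), spacing = c(2, 2, 2)) {
  shape <- as.integer(rep_len(shape, 3))
  spacing <- as.numeric(rep_len(spacing, 3))
  ctr <- (shape - 1) * spacing / 2
  semi <- pmin((shape - 1) * spacing / 2 * 0.97, c(82, 97, 64))
  x <- (seq_len(shape[1]) - 1) * spacing[1]
  y <- (seq_len(shape[2]) - 1) * spacing[2]
  z <- (seq_len(shape[3]) - 1) * spacing[3]
  nx2 <- ((x - ctr[1]) / semi[1])^2
  ny2 <- ((y - ctr[2]) / semi[2])^2
  nz2 <- ((z - ctr[3]) / semi[3])^2
  rn <- sqrt(outer(outer(nx2, ny2, "+"), nz2, "+"))
  brain <- rn <= 1
  vent <- function(cv, sv) {
    vx2 <- ((x - cv[1]) / sv[1])^2
    vy2 <- ((y - cv[2]) / sv[2])^2
    vz2 <- ((z - cv[3]) / sv[3])^2
    outer(outer(vx2, vy2, "+"), vz2, "+") <= 1
  }
  csf <- (vent(ctr + c(-14, -4, 4), c(9, 22, 12)) |
            vent(ctr + c(14, -4, 4), c(9, 22, 12))) & brain
  # cortical gray-matter shell, white matter inside; tissue sums to 0.96
  gm <- 0.92 * stats::plogis((rn - 0.8) / 0.045)
  wm <- pmax(0.96 - gm, 0)
  gm[!brain | csf] <- 0
  wm[!brain | csf] <- 0
  structure(list(wm = wm, gm = gm,
                 csf = array(csf, dim = shape),
                 brain = array(brain, dim = shape),
                 spacing = spacing, shape = shape),
            class = "fk_phantom")
}

phantom_omega <- function(phantom, tissue_threshold = 0.1) {
  (phantom$wm + phantom$gm > tissue_threshold) & phantom$brain & !phantom$csf
}

draw_center_in_omega <- function(phantom, omega, lo, hi, base = NULL,
                                 offset = NULL, max_retries = 200) {
  for (i in seq_len(max_retries)) {
    c_mm <- if (is.null(base)) runif(3, lo, hi)
    else base + runif(3, -offset, offset)
    idx <- round(c_mm / phantom$spacing) + 1
    if (any(idx < 1) || any(idx > phantom$shape)) next
    if (omega[idx[1], idx[2], idx[3]]) return(c_mm)
  }
  stop("no valid in-tissue tumor center found after ", max_retries, " draws")
}

#' Draw ground-truth generation parameters
#'
#' Uniform draws over the benchmark generation ranges: `D_w, rho` in
#' \[0.035, 0.2\] (per unit time), `R` in \[10, 30\], `theta_necro` in
#' \[0.70, 0.85\], `theta_up` in \[0.45, 0.60\], `theta_down` in
#' \[0.15, 0.35\], simulated duration 100, seed centers uniform in
#' \[57.6, 96\] mm per axis (resampled until inside the diffusible tissue).
#' Multifocal cases draw 3 centers, each offset from the previous by uniform
#' +-9.6 mm per axis. Uses the current R random stream; call `set.seed()`
#' first for reproducible draws.
#'
#' @param phantom an [fk_phantom()] (or atlas-like list)
#' @param multifocal draw 3 linked foci instead of 1
#' @param center_range per-axis center range in mm
#' @param offset_mm per-axis multifocal offset bound in mm
#' @return list with `d_w`, `rho`, `r`, `centers` (matrix, one row per focus),
#'   `imaging` ([fk_imaging()] with the identity PET mapping), `theta_necro`,
#'   `t_sim`
#' @export
sample_params <- function(phantom, multifocal = FALSE,
                          center_range = c(57.6, 96), offset_mm = 9.6) {
  omega <- phantom_omega(phantom)
  d_w <- runif(1, 0.035, 0.2)
  rho <- runif(1, 0.035, 0.2)
  r <- runif(1, 10, 30)
  theta_necro <- runif(1, 0.70, 0.85)
  theta_up <- runif(1, 0.45, 0.60)
  theta_down <- runif(1, 0.15, 0.35)
  c1 <- draw_center_in_omega(phantom, omega, center_range[1], center_range[2])
  centers <- matrix(c1, nrow = 1)
  if (multifocal) {
    c2 <- draw_center_in_omega(phantom, omega, NA, NA, base = c1, offset = offset_mm)
    c3 <- draw_center_in_omega(phantom, omega, NA, NA, base = c2, offset = offset_mm)
    centers <- rbind(centers, c2, c3)
  }
  rownames(centers) <- NULL
  list(d_w = d_w, rho = rho, r = r, centers = centers,
       imaging = fk_imaging(theta_down, theta_up, theta_pet = 1, theta_bkg = 0),
       theta_necro = theta_necro, t_sim = 100)
}

#' Grow the ground-truth density field
#'
#' Sums the per-focus Gaussian seeds (clipped at 1), then integrates the
#' growth equation on the phantom grid with the explicit solver up to `t_sim`.
#' Deterministic given the parameters.
#'
#' @param phantom an [fk_phantom()]
#' @param params a [sample_params()] draw
#' @param n_store stored snapshots (the last is the imaging-time truth)
#' @return list with `u_final`, the snapshot array `u`, and `times`
#' @export
generate_truth <- function(phantom, params, n_store = 5) {
  omega <- phantom_omega(phantom)
  u0 <- array(0, dim = phantom$shape)
  for (i in seq_len(nrow(params$centers)))
    u0 <- u0 + gaussian_field(phantom$shape, c(0, 0, 0), phantom$spacing,
                              params$centers[i, ], omega)
  u0 <- pmin(u0, 1)
  D <- build_diffusion_field_raw(phantom$wm, phantom$gm, omega,
                                 params$d_w, params$r)
  dt <- stable_dt(D, params$rho, phantom$spacing)
  nsteps <- max(as.integer(ceiling(params$t_sim / dt)), n_store - 1L)
  dt <- params$t_sim / nsteps
  save_at <- as.integer(round(seq(0, nsteps, length.out = n_store)))
  u <- cpp_fk_simulate(as.numeric(u0), as.numeric(D), as.integer(omega),
                       as.integer(phantom$shape), phantom$spacing,
                       params$rho, dt, nsteps, save_at)
  u <- array(u, dim = c(phantom$shape, n_store))
  list(u_final = u[, , , n_store], u = u, times = save_at * dt)
}

#' Threshold-derived segmentation labels
#'
#' Band membership of the ground-truth density: necrotic core at
#' `u >= theta_necro`, enhancing core in `[theta_up, theta_necro)`, edema in
#' `[theta_down, theta_up)`. The labels are disjoint and partition the
#' supra-threshold region.
#'
#' @param u density volume
#' @param theta_up,theta_down,theta_necro thresholds with
#'   `theta_down < theta_up < theta_necro`
#' @return list of logical volumes `necrotic`, `enhancing`, `edema`
#' @export
derive_segmentations <- function(u, theta_up, theta_down, theta_necro) {
  if (!(theta_down < theta_up && theta_up < theta_necro))
    stop("need theta_down < theta_up < theta_necro")
  list(necrotic = u >= theta_necro,
       enhancing = u >= theta_up & u < theta_necro,
       edema = u >= theta_down & u < theta_up)
}

#' Spatially correlated Gaussian noise (Gibbs sampler)
#'
#' Raster sweeps of a Gaussian Markov random field: each voxel is redrawn
#' from `Normal(coupling * mean(6-neighbors), sigma^2)`. `coupling = 0`
#' yields i.i.d. noise; larger coupling lengthens the spatial correlation.
#' Driven by the R random stream (`set.seed()` for reproducibility).
#'
#' @param shape volume dimensions
#' @param coupling neighbor coupling in \[0, 1)
#' @param sigma conditional standard deviation
#' @param n_sweeps raster passes
#' @return noise volume (zero mean in expectation)
#' @export
gibbs_noise <- function(shape, coupling = 0.8, sigma = 0.1, n_sweeps = 10) {
  if (coupling < 0 || coupling >= 1) stop("coupling must lie in [0, 1)")
  array(cpp_gibbs(as.integer(rep_len(shape, 3)), coupling, sigma,
                  as.integer(n_sweeps)),
        dim = rep_len(shape, 3))
}

block_degrade <- function(vol, factor = 4) {
  d <- dim(vol)
  dp <- as.integer(ceiling(d / factor) * factor)
  ix <- pmin(seq_len(dp[1]), d[1])
  iy <- pmin(seq_len(dp[2]), d[2])
  iz <- pmin(seq_len(dp[3]), d[3])
  p <- vol[ix, iy, iz]
  nb <- dp / factor
  dim(p) <- c(factor, nb[1], factor, nb[2], factor, nb[3])
  means <- apply(p, c(2, 4, 6), mean)
  up <- means[rep(seq_len(nb[1]), each = factor),
              rep(seq_len(nb[2]), each = factor),
              rep(seq_len(nb[3]), each = factor)]
  up[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])]
}

#' Degrade a density field into a synthetic PET volume
#'
#' Emulates amino-acid PET acquisition: adds spatially correlated noise,
#' removes the metabolically inactive necrotic core, then applies the
#' partial-volume pipeline — block-average downsampling by `factor` followed
#' by zeroth-order (nearest) upsampling, leaving the output piecewise
#' constant on `factor^3` blocks.
#'
#' @param truth_u ground-truth density
#' @param necrotic logical necrotic-core mask
#' @param coupling,sigma,n_sweeps noise settings, see [gibbs_noise()]
#' @param factor partial-volume block size in voxels
#' @return degraded PET volume in \[0, 1\]
#' @export
degrade_pet <- function(truth_u, necrotic, coupling = 0.8, sigma = 0.1,
                        n_sweeps = 10, factor = 4) {
  pet <- pmin(pmax(truth_u + gibbs_noise(dim(truth_u), coupling, sigma,
                                         n_sweeps), 0), 1)
  pet[necrotic] <- 0
  block_degrade(pet, factor)
}

#' Generate a complete synthetic patient
#'
#' Composes the pipeline: parameter draw, ground-truth growth, threshold
#' segmentations, PET degradation, case assembly. Draws whose density never
#' reaches the core threshold (no enhancing core) or produces no edema are
#' redrawn from the same stream, so every patient carries the non-empty
#' labels the inference requires. Fully reproducible from `seed`; the final
#' case re-zeros PET on necrotic voxels so the stored volume respects the
#' no-metabolism invariant.
#'
#' @param phantom an [fk_phantom()]
#' @param seed integer seed
#' @param multifocal generate 3 linked foci
#' @param noise list overriding `coupling`, `sigma`, `n_sweeps`, `factor`
#' @param max_draws redraw budget for degenerate segmentations
#' @return object of class `fk_synth_patient`: `case` ([fk_case()]),
#'   `truth_u`, `truth_params`, `seed`, `multifocal`
#' @export
generate_patient <- function(phantom, seed, multifocal = FALSE,
                             noise = list(), max_draws = 20) {
  noise <- modifyList(list(coupling = 0.8, sigma = 0.1, n_sweeps = 10,
                           factor = 4), noise)
  set.seed(seed)
  for (draw in seq_len(max_draws)) {
    params <- sample_params(phantom, multifocal)
    truth <- generate_truth(phantom, params)
    segs <- derive_segmentations(truth$u_final, params$imaging$theta_up,
                                 params$imaging$theta_down, params$theta_necro)
    if (any(segs$enhancing | segs$necrotic) && any(segs$edema)) break
    if (draw == max_draws)
      stop("no parameter draw produced non-degenerate segmentations")
  }
  pet <- degrade_pet(truth$u_final, segs$necrotic, noise$coupling,
                     noise$sigma, noise$n_sweeps, noise$factor)
  pet[segs$necrotic] <- 0
  case <- fk_case(phantom$wm, phantom$gm, phantom$csf, phantom$brain,
                  segs$edema, segs$enhancing, segs$necrotic,
                  pet = pet, spacing = phantom$spacing)
  structure(list(case = case, truth_u = truth$u_final,
                 truth_params = params, seed = as.integer(seed),
                 multifocal = multifocal, noise = noise),
            class = "fk_synth_patient")
}

#' @export
print.fk_synth_patient <- function(x, ...) {
  cat("<fk_synth_patient> seed", x$seed,
      if (x$multifocal) "(multifocal)" else "(single focal)", "\n")
  cat(sprintf("  truth: D_w=%.3f rho=%.3f R=%.1f foci=%d\n",
              x$truth_params$d_w, x$truth_params$rho, x$truth_params$r,
              nrow(x$truth_params$centers)))
  print(x$case)
  invisible(x)
}

#' Write a synthetic patient to disk
#'
#' Volumes as NIfTI, ground-truth record as JSON.
#' @param patient an [generate_patient()] result
#' @param dir output directory
#' @return `dir`, invisibly
#' @export
save_patient <- function(patient, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cs <- patient$case
  sp <- cs$spacing
  write_volume(cs$wm, file.path(dir, "wm.nii.gz"), sp)
  write_volume(cs$gm, file.path(dir, "gm.nii.gz"), sp)
  write_volume(cs$csf, file.path(dir, "csf.nii.gz"), sp, mask = TRUE)
  write_volume(cs$brain, file.path(dir, "brain.nii.gz"), sp, mask = TRUE)
  write_volume(cs$seg_edema, file.path(dir, "edema.nii.gz"), sp, mask = TRUE)
  write_volume(cs$seg_enhancing, file.path(dir, "enhancing.nii.gz"), sp, mask = TRUE)
  write_volume(cs$seg_necrotic, file.path(dir, "necrotic.nii.gz"), sp, mask = TRUE)
  if (!is.null(cs$pet)) write_volume(cs$pet, file.path(dir, "pet.nii.gz"), sp)
  write_volume(patient$truth_u, file.path(dir, "truth_u.nii.gz"), sp)
  tp <- patient$truth_params
  rec <- list(seed = patient$seed, multifocal = patient$multifocal,
              d_w = tp$d_w, rho = tp$rho, r = tp$r,
              centers = tp$centers,
              theta_down = tp$imaging$theta_down,
              theta_up = tp$imaging$theta_up,
              theta_pet = tp$imaging$theta_pet,
              theta_bkg = tp$imaging$theta_bkg,
              theta_necro = tp$theta_necro, t_sim = tp$t_sim,
              noise = patient$noise)
  jsonlite::write_json(rec, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
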