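#' @useDynLib fkodil, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif optim uniroot median sd cor
#' @importFrom utils modifyList write.csv
NULL

vol_names <- c("wm", "gm", "csf", "brain", "edema", "enhancing", "necrotic")

#' Read a 3D volume from a NIfTI file
#'
#' Returns the voxel data as a plain 3D array with a `spacing` attribute
#' (mm per voxel along each axis, taken from the NIfTI header).
#'
#' @param path path to a `.nii` or `.nii.gz` file
#' @return 3D numeric array with attribute `spacing`
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("volume file not found: ", path)
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)[1:3]
  arr <- array(as.numeric(img), dim = dim(img)[1:3])
  attr(arr, "spacing") <- as.numeric(sp)
  arr
}

#' Write a 3D (or 4D) volume to a NIfTI-1 file
#'
#' Continuous volumes are stored as float32, masks as uint8.
#'
#' @param vol numeric or logical array
#' @param path output path (`.nii` or `.nii.gz`)
#' @param spacing voxel spacing in mm (length 3)
#' @param mask logical; store as uint8 instead of float32
#' @export
write_volume <- function(vol, path, spacing = c(1, 1, 1), mask = FALSE) {
  v <- if (mask) array(as.integer(vol != 0), dim = dim(vol)) else
    array(as.numeric(vol), dim = dim(vol))
  attr(v, "pixdim") <- rep_len(spacing, length(dim(vol)))
  img <- RNifti::asNifti(v, datatype = if (mask) "uint8" else "float")
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Assemble and validate a patient case
#'
#' A case bundles everything the inference consumes for one subject, on a
#' common voxel grid: white/gray-matter fraction maps, CSF and brain masks,
#' the three tumor segmentation labels (edema, enhancing core, necrotic core)
#' and an optional PET volume.
#'
#' @param wm,gm white/gray-matter fraction volumes in \[0, 1\]
#' @param csf,brain binary masks
#' @param edema,enhancing,necrotic binary tumor segmentation labels
#' @param pet optional non-negative PET intensity volume
#' @param spacing voxel spacing (dx, dy, dz) in mm
#' @return object of class `fk_case`
#' @export
fk_case <- function(wm, gm, csf, brain, edema, enhancing, necrotic,
                    pet = NULL, spacing = c(1, 1, 1)) {
  vols <- list(wm = wm, gm = gm, csf = csf, brain = brain,
               edema = edema, enhancing = enhancing, necrotic = necrotic)
  shp <- dim(wm)
  if (length(shp) != 3L) stop("volumes must be 3D")
  for (nm in names(vols)) {
    if (!identical(dim(vols[[nm]]), shp))
      stop("shape mismatch: '", nm, "' has dimensions (",
           paste(dim(vols[[nm]]), collapse = ","), ") but expected (",
           paste(shp, collapse = ","), ")")
  }
  if (!is.null(pet)) {
    if (!identical(dim(pet), shp)) stop("shape mismatch: 'pet'")
    if (any(!is.finite(pet))) stop("pet volume contains non-finite values")
    if (any(pet < 0)) stop("pet volume must be non-negative")
  }
  bad <- sum(wm + gm > 1 + 1e-3)
  if (bad > 0)
    stop("tissue fractions invalid: wm + gm > 1 at ", bad, " voxel(s)")
  for (nm in c("csf", "brain", "edema", "enhancing", "necrotic")) {
    v <- vols[[nm]] > 0.5
    if (any(abs(vols[[nm]] - as.numeric(v)) > 1e-6))
      stop("segmentation '", nm, "' is not binary after 0.5-thresholding")
    vols[[nm]] <- array(v, dim = shp)
  }
  for (nm in c("edema", "enhancing", "necrotic")) {
    out <- sum(vols[[nm]] & !vols$brain)
    if (out > 0)
      stop("segmentation '", nm, "' extends outside the brain mask (",
           out, " voxel(s))")
  }
  structure(list(wm = vols$wm, gm = vols$gm, csf = vols$csf, brain = vols$brain,
                 seg_edema = vols$edema, seg_enhancing = vols$enhancing,
                 seg_necrotic = vols$necrotic, pet = pet,
                 spacing = as.numeric(rep_len(spacing, 3)), shape = shp),
            class = "fk_case")
}

#' Load a patient case from NIfTI files
#'
#' @param paths named list/vector of file paths with elements `wm`, `gm`,
#'   `csf`, `brain`, `edema`, `enhancing`, `necrotic` and optionally `pet`,
#'   or a directory containing files `<name>.nii.gz`
#' @return an [fk_case()]
#' @export
load_case <- function(paths) {
  if (length(paths) == 1L && is.character(paths) && dir.exists(paths)) {
    nm <- c(vol_names, "pet")
    f <- file.path(paths, paste0(nm, ".nii.gz"))
    f2 <- file.path(paths, paste0(nm, ".nii"))
    f[!file.exists(f)] <- f2[!file.exists(f)]
    names(f) <- nm
    paths <- as.list(f[file.exists(f)])
  }
  paths <- as.list(paths)
  missing <- setdiff(vol_names, names(paths))
  if (length(missing))
    stop("missing volume path(s): ", paste(missing, collapse = ", "))
  vols <- lapply(paths[c(vol_names, intersect("pet", names(paths)))], read_volume)
  sp <- attr(vols$wm, "spacing")
  for (nm in names(vols)) {
    spi <- attr(vols[[nm]], "spacing")
    if (max(abs(spi - sp)) > 1e-4)
      stop("voxel spacing of '", nm, "' disagrees with 'wm'")
  }
  fk_case(vols$wm, vols$gm, vols$csf, vols$brain,
          vols$edema, vols$enhancing, vols$necrotic,
          pet = vols$pet, spacing = sp)
}

#' @export
print.fk_case <- function(x, ...) {
  cat("<fk_case> grid", paste(x$shape, collapse = "x"),
      "spacing", paste(signif(x$spacing, 3), collapse = "x"), "mm\n")
  cat("  segmentation voxels: edema", sum(x$seg_edema),
      "| enhancing", sum(x$seg_enhancing), "| necrotic", sum(x$seg_necrotic),
      if (is.null(x$pet)) "| no PET" else "| PET present", "\n")
  invisible(x)
}

#' Growth parameters of the reaction-diffusion model
#'
#' `d_w` is the white-matter diffusivity (mm^2 per unit time), `rho` the
#' logistic proliferation rate (1/unit time), `r > 1` the white-to-gray
#' diffusivity ratio, and `center` the seed location in mm. With a single
#' imaging time point the rates are identifiable only up to a timescale, so
#' inside the inference the time axis is normalized to \[0, 1\] and `d_w`,
#' `rho` are rates per normalized unit.
#'
#' @param d_w,rho,r scalars; `d_w > 0`, `rho > 0`, `r > 1`
#' @param center numeric length-3, seed center (x0, y0, z0) in mm
#' @return object of class `fk_params`
#' @export
fk_params <- function(d_w, rho, r, center) {
  if (d_w <= 0) stop("d_w must be positive")
  if (rho <= 0) stop("rho must be positive")
  if (r <= 1) stop("r must exceed 1")
  structure(list(d_w = d_w, rho = rho, r = r, center = as.numeric(center)),
            class = "fk_params")
}

#' @export
print.fk_params <- function(x, ...) {
  cat(sprintf("<fk_params> D_w=%.4g rho=%.4g R=%.4g center=(%s) mm\n",
              x$d_w, x$rho, x$r, paste(signif(x$center, 4), collapse = ", ")))
  invisible(x)
}

seg_union <- function(case) case$seg_edema | case$seg_enhancing | case$seg_necrotic

resample_to <- function(vol, out_shape, nearest = FALSE) {
  array(cpp_resample3(as.numeric(vol), as.integer(dim(vol)),
                      as.integer(out_shape), nearest),
        dim = out_shape)
}

#' Build the tumor-focused computational domain
#'
#' Crops a region of interest around the union of the tumor segmentations
#' (bounding box dilated by `margin_mm`, clipped to the volume), resamples all
#' case volumes onto the solver grid (trilinear for continuous volumes,
#' nearest-neighbor for masks), and defines the diffusible-tissue region
#' `omega1` as voxels with `wm + gm > tissue_threshold` inside the brain mask
#' and outside CSF.
#'
#' @param case an [fk_case()]
#' @param margin_mm ROI margin around the segmentation bounding box (mm)
#' @param solver_shape spatial solver resolution, at least 8 per axis
#' @param n_time number of temporal grid points of the space-time field
#' @param tissue_threshold minimum wm+gm fraction for diffusible tissue
#' @return object of class `fk_domain` carrying solver-grid tissue maps,
#'   masks, PET, the ROI geometry, and native-resolution ROI fields for
#'   forward replays
#' @export
build_domain <- function(case, margin_mm = 30, solver_shape = c(48, 48, 48),
                         n_time = 192, tissue_threshold = 0.1) {
  stopifnot(inherits(case, "fk_case"))
  solver_shape <- as.integer(rep_len(solver_shape, 3))
  if (any(solver_shape < 8L)) stop("solver_shape must be at least 8 per axis")
  if (n_time < 2L) stop("n_time must be at least 2")
  seg <- seg_union(case)
  if (!any(seg)) stop("empty segmentation union: cannot define the ROI")
  idx <- which(seg, arr.ind = TRUE)
  lo <- unname(apply(idx, 2, min))
  hi <- unname(apply(idx, 2, max))
  mvox <- ceiling(margin_mm / case$spacing)
  lo <- pmax(lo - mvox, 1L)
  hi <- pmin(hi + mvox, case$shape)
  crop <- function(v) v[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  nat <- lapply(list(wm = case$wm, gm = case$gm, csf = case$csf,
                     brain = case$brain, edema = case$seg_edema,
                     enhancing = case$seg_enhancing,
                     necrotic = case$seg_necrotic), crop)
  nat_shape <- hi - lo + 1L
  if (any(nat_shape < 2L)) stop("ROI degenerate along an axis; increase margin_mm")
  omega_nat <- (nat$wm + nat$gm > tissue_threshold) & (nat$brain > 0) & !(nat$csf > 0)
  cont <- function(v) resample_to(v, solver_shape, nearest = FALSE)
  msk <- function(v) resample_to(v, solver_shape, nearest = TRUE) > 0.5
  wm_s <- cont(nat$wm); gm_s <- cont(nat$gm)
  brain_s <- msk(nat$brain); csf_s <- msk(nat$csf)
  omega1 <- (wm_s + gm_s > tissue_threshold) & brain_s & !csf_s
  spacing_solver <- (nat_shape - 1) * case$spacing / (solver_shape - 1)
  pet_s <- NULL
  if (!is.null(case$pet)) pet_s <- cont(crop(case$pet))
  structure(list(
    roi_lo = lo, roi_hi = hi,
    origin_mm = (lo - 1) * case$spacing,
    solver_shape = solver_shape, n_time = as.integer(n_time),
    spacing = spacing_solver, spacing_native = case$spacing,
    tissue_threshold = tissue_threshold,
    wm = wm_s, gm = gm_s, brain = brain_s, csf = csf_s, omega1 = omega1,
    seg_edema = msk(nat$edema), seg_enhancing = msk(nat$enhancing),
    seg_necrotic = msk(nat$necrotic), pet = pet_s,
    native = list(shape = nat_shape, wm = nat$wm, gm = nat$gm,
                  omega1 = omega_nat, edema = nat$edema,
                  enhancing = nat$enhancing, necrotic = nat$necrotic)
  ), class = "fk_domain")
}

#' @export
print.fk_domain <- function(x, ...) {
  cat("<fk_domain> solver grid", paste(x$solver_shape, collapse = "x"),
      "x", x$n_time, "time points\n")
  cat("  ROI native extent", paste(x$native$shape, collapse = "x"),
      "| solver spacing", paste(signif(x$spacing, 3), collapse = "x"), "mm\n")
  cat("  |omega1| =", sum(x$omega1), "voxels\n")
  invisible(x)
}

#' Physical coordinates of solver voxel centers
#'
#' Voxel-centered convention: 0-based index times spacing plus the ROI origin.
#' @param domain an [fk_domain()]
#' @return list of numeric vectors `x`, `y`, `z` (mm)
#' @export
solver_coords <- function(domain) {
  list(x = domain$origin_mm[1] + (seq_len(domain$solver_shape[1]) - 1) * domain$spacing[1],
       y = domain$origin_mm[2] + (seq_len(domain$solver_shape[2]) - 1) * domain$spacing[2],
       z = domain$origin_mm[3] + (seq_len(domain$solver_shape[3]) - 1) * domain$spacing[3])
}

#' Voxelwise diffusion coefficient field
#'
#' `D = wm * D_w + gm * D_g` with `D_g = D_w / R`; zero outside the diffusible
#' region.
#'
#' @param obj an [fk_domain()] (solver grid) or [fk_case()] (native grid)
#' @param params an [fk_params()]
#' @param tissue_threshold used only for `fk_case` inputs
#' @return 3D array of diffusivities (mm^2 per unit time)
#' @export
build_diffusion_field <- function(obj, params, tissue_threshold = 0.1) {
  if (params$r <= 1) stop("r must exceed 1")
  if (inherits(obj, "fk_domain")) {
    wm <- obj$wm; gm <- obj$gm; om <- obj$omega1
  } else if (inherits(obj, "fk_case")) {
    wm <- obj$wm; gm <- obj$gm
    om <- (wm + gm > tissue_threshold) & (obj$brain > 0) & !(obj$csf > 0)
  } else stop("obj must be an fk_domain or fk_case")
  D <- (wm * params$d_w + gm * params$d_w / params$r)
  D[!om] <- 0
  D
}

#' Face-centered diffusion coefficients
#'
#' Each face coefficient is the arithmetic mean of its two adjacent voxel
#' values; faces touching a voxel outside the diffusible region are zero,
#' which enforces the no-flux condition at the tissue boundary.
#'
#' @param D voxelwise diffusion field
#' @param omega1 logical diffusible-tissue mask
#' @return list of arrays `x` (nx-1,ny,nz), `y` (nx,ny-1,nz), `z` (nx,ny,nz-1)
#' @export
face_diffusion <- function(D, omega1) {
  d <- dim(D)
  fx <- 0.5 * (D[-d[1], , , drop = FALSE] + D[-1, , , drop = FALSE]) *
    (omega1[-d[1], , , drop = FALSE] & omega1[-1, , , drop = FALSE])
  fy <- 0.5 * (D[, -d[2], , drop = FALSE] + D[, -1, , drop = FALSE]) *
    (omega1[, -d[2], , drop = FALSE] & omega1[, -1, , drop = FALSE])
  fz <- 0.5 * (D[, , -d[3], drop = FALSE] + D[, , -1, drop = FALSE]) *
    (omega1[, , -d[3], drop = FALSE] & omega1[, , -1, drop = FALSE])
  list(x = fx, y = fy, z = fz)
}
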