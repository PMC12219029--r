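#' Dice overlap coefficient
#'
#' `2|A∩B| / (|A| + |B|)` between two binary volumes. Two empty masks are in
#' perfect agreement, so `dice(∅, ∅) = 1`.
#'
#' @param a,b logical/binary volumes of identical shape
#' @return value in \[0, 1\]
#' @export
dice <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("dice: shape mismatch")
  a <- a != 0; b <- b != 0
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(1)
  2 * sum(a & b) / (sa + sb)
}

#' Pearson correlation between PET signal and cell density
#'
#' Evaluated over the region where a tight coupling is expected (enhancing
#' core plus edema). Degenerate (constant) inputs yield `NaN` with a warning.
#'
#' @param u density volume
#' @param pet PET volume
#' @param region logical mask
#' @return correlation in \[-1, 1\], or `NaN`
#' @export
pet_correlation <- function(u, pet, region) {
  uu <- u[region]; pp <- pet[region]
  if (length(uu) < 2) {
    warning("pet_correlation: region has fewer than 2 voxels")
    return(NaN)
  }
  if (sd(uu) == 0 || sd(pp) == 0) {
    warning("pet_correlation: constant input in region")
    return(NaN)
  }
  cor(uu, pp)
}

#' Euclidean distance map to a voxel set
#'
#' Exact distance in mm honoring anisotropic spacing (separable squared
#' distance transform). Voxels in the set get 0; if the set is empty, `Inf`.
#'
#' @param mask logical volume
#' @param spacing voxel spacing in mm
#' @return numeric volume of distances (mm)
#' @export
distance_map <- function(mask, spacing = c(1, 1, 1)) {
  d2 <- cpp_edt_sq(as.integer(mask != 0), as.integer(dim(mask)),
                   as.numeric(rep_len(spacing, 3)))
  d <- sqrt(d2)
  d[d > 1e14] <- Inf
  array(d, dim = dim(mask))
}

new_plan <- function(mask, source) {
  structure(list(mask = mask, volume_voxels = sum(mask), source = source),
            class = "fk_plan")
}

#' @export
print.fk_plan <- function(x, ...) {
  cat("<fk_plan>", x$source, "|", x$volume_voxels, "voxels\n")
  invisible(x)
}

#' Standard-of-care clinical target volume
#'
#' Dilates the pre-operative tumor core (enhancing plus necrotic labels) by a
#' uniform margin (default 15 mm) using true Euclidean distance, then
#' restricts to brain tissue excluding CSF.
#'
#' @param core binary tumor-core volume (enhancing + necrotic)
#' @param brain,csf binary masks
#' @param margin_mm dilation margin (mm)
#' @param spacing voxel spacing (mm)
#' @return an `fk_plan` with source `"standard_ctv"`
#' @export
standard_plan_ctv <- function(core, brain, csf, margin_mm = 15,
                              spacing = c(1, 1, 1)) {
  if (!any(core != 0)) stop("empty tumor core: cannot build the CTV")
  d <- distance_map(core, spacing)
  mask <- (d <= margin_mm) & (brain != 0) & !(csf != 0)
  new_plan(mask, "standard_ctv")
}

#' Volume-matched density-based radiotherapy plan
#'
#' Selects exactly `target_voxels` voxels with the highest predicted cell
#' density inside the brain, so plans from different models occupy identical
#' total volumes and coverage comparisons are fair. Ties (plateaued density)
#' are broken by smaller Euclidean distance to `center` (typically the tumor
#' core centroid), then by voxel index.
#'
#' @param u_final predicted density volume
#' @param target_voxels plan size in voxels (e.g. the Standard Plan volume)
#' @param brain binary mask limiting plan placement
#' @param spacing voxel spacing (mm)
#' @param center tie-break reference point in mm (0-based voxel-center
#'   coordinates of this volume); defaults to the density-weighted centroid
#' @return an `fk_plan` with source `"topk_density"`
#' @export
volume_matched_plan <- function(u_final, target_voxels, brain,
                                spacing = c(1, 1, 1), center = NULL) {
  idx <- which(brain != 0)
  if (target_voxels > length(idx))
    stop("target_voxels exceeds the brain volume")
  shp <- dim(u_final)
  ai <- arrayInd(idx, shp)
  pos <- sweep(ai - 1, 2, rep_len(spacing, 3), "*")
  if (is.null(center)) {
    w <- pmax(u_final[idx], 0)
    center <- if (sum(w) > 0) colSums(pos * w) / sum(w) else colMeans(pos)
  }
  d2 <- (pos[, 1] - center[1])^2 + (pos[, 2] - center[2])^2 +
    (pos[, 3] - center[3])^2
  ord <- order(-u_final[idx], d2, idx)
  mask <- array(FALSE, shp)
  mask[idx[ord[seq_len(target_voxels)]]] <- TRUE
  new_plan(mask, "topk_density")
}

#' Recurrence coverage of a radiotherapy plan
#'
#' Percentage of recurrence voxels contained in the plan. The recurrence
#' volume may follow the broad definition (edema + enhancing + necrotic
#' follow-up labels) or the narrow one (enhancing core only); the caller
#' supplies the corresponding binary volume.
#'
#' @param plan an `fk_plan` or binary volume
#' @param recurrence binary follow-up recurrence volume (pre-registered to
#'   the planning grid)
#' @return percent in \[0, 100\], or `NaN` when the recurrence is empty
#' @export
recurrence_coverage <- function(plan, recurrence) {
  mask <- if (inherits(plan, "fk_plan")) plan$mask else plan != 0
  if (!identical(dim(mask), dim(recurrence))) stop("shape mismatch")
  n <- sum(recurrence != 0)
  if (n == 0) {
    warning("empty recurrence volume: coverage undefined")
    return(NaN)
  }
  100 * sum(mask & (recurrence != 0)) / n
}

#' Patient-level comparison against the Standard Plan
#'
#' @param coverage_model,coverage_standard recurrence coverage percentages
#' @param tol tie tolerance
#' @return `"Better"`, `"Worse"`, or `"Equal"`
#' @export
compare_to_standard <- function(coverage_model, coverage_standard, tol = 1e-9) {
  if (is.na(coverage_model) || is.na(coverage_standard))
    stop("coverage values must be defined")
  if (coverage_model > coverage_standard + tol) "Better"
  else if (coverage_model < coverage_standard - tol) "Worse"
  else "Equal"
}
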