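#' Multiresolution decomposition of the 4D field
#'
#' The unknown space-time density is represented as a sum of fields on
#' progressively coarser grids, `u = u_1 + T_1 u_2 + T_1 T_2 u_3 + ...`, where
#' `T_i` interpolates from level `i+1` to level `i`. Coarse levels let the
#' optimizer move large-scale structure in few iterations while fine levels
#' add detail; the decomposition is purely a reparameterization (composition
#' is linear in every level).
#'
#' @name multigrid
NULL

#' Level shapes for a fine grid
#'
#' Each subsequent level ceil-halves every axis (space and time).
#' @param fine_shape integer length-4 (nx, ny, nz, nt)
#' @param L number of levels
#' @return list of integer length-4 shapes
#' @export
mg_shapes <- function(fine_shape, L) {
  shapes <- vector("list", L)
  s <- as.integer(fine_shape)
  for (i in seq_len(L)) {
    shapes[[i]] <- s
    s <- as.integer(ceiling(s / 2))
  }
  shapes
}

#' Default number of levels
#'
#' The largest level count for which every axis of the coarsest grid keeps at
#' least 4 nodes.
#' @param fine_shape integer length-4
#' @return integer >= 1
#' @export
mg_default_levels <- function(fine_shape) {
  L <- 1L
  s <- as.integer(ceiling(fine_shape / 2))
  while (all(s >= 4L)) {
    L <- L + 1L
    s <- as.integer(ceiling(s / 2))
  }
  L
}

#' Initialize a multigrid field
#'
#' With `init` given, level 1 holds it and deeper levels are zero, so the
#' composition reproduces `init` exactly; otherwise all levels are zero.
#'
#' @param fine_shape integer length-4 (nx, ny, nz, nt)
#' @param L number of levels (default: [mg_default_levels()])
#' @param init optional 4D array embedded at level 1
#' @return object of class `fk_mg`: list of level arrays plus shapes
#' @export
mg_init <- function(fine_shape, L = NULL, init = NULL) {
  fine_shape <- as.integer(fine_shape)
  if (is.null(L)) L <- mg_default_levels(fine_shape)
  shapes <- mg_shapes(fine_shape, L)
  if (any(shapes[[L]] < 4L))
    stop("coarsest level would drop below 4 nodes per axis; reduce L")
  levels <- lapply(shapes, function(s) array(0, dim = s))
  if (!is.null(init)) {
    stopifnot(identical(as.integer(dim(init)), fine_shape))
    levels[[1]] <- init
  }
  structure(list(levels = levels, shapes = shapes, L = L), class = "fk_mg")
}

#' @export
print.fk_mg <- function(x, ...) {
  cat("<fk_mg>", x$L, "levels:",
      paste(vapply(x$shapes, function(s) paste(s, collapse = "x"), ""),
            collapse = " | "), "\n")
  invisible(x)
}

#' Multilinear interpolation of a 4D array to a finer shape
#'
#' Endpoint-aligned linear interpolation in all four dimensions; exact on
#' constants and axis-aligned linear ramps.
#'
#' @param coarse 4D array
#' @param fine_shape target shape
#' @return 4D array of shape `fine_shape`
#' @export
mg_interp <- function(coarse, fine_shape) {
  fine_shape <- as.integer(fine_shape)
  cd <- as.integer(dim(coarse))
  if (length(cd) != 4L || length(fine_shape) != 4L)
    stop("mg_interp expects 4D shapes")
  if (any(fine_shape < cd))
    stop("fine shape must not be smaller than the coarse shape")
  if (!is.double(coarse)) storage.mode(coarse) <- "double"
  out <- cpp_interp4(coarse, cd, fine_shape)
  dim(out) <- fine_shape
  out
}

#' Compose a multigrid field into the fine-grid array
#'
#' Evaluates `u_1 + T_1 (u_2 + T_2 (u_3 + ...))`.
#' @param field an [mg_init()] object
#' @return 4D array at the finest shape
#' @export
mg_compose <- function(field) {
  L <- field$L
  u <- field$levels[[L]]
  if (L > 1) for (i in (L - 1):1)
    u <- field$levels[[i]] + mg_interp(u, field$shapes[[i]])
  u
}

#' Adjoint of [mg_compose()]
#'
#' Pulls a fine-grid gradient back onto every level: level `i` receives
#' `(T_1 ... T_{i-1})^T g`. Together with the linearity of the composition
#' this is the exact gradient of any scalar loss through the decomposition.
#'
#' @param grad_fine 4D gradient array at the finest shape
#' @param field an [mg_init()] object (for the level shapes)
#' @return list of per-level gradient arrays
#' @export
mg_compose_adj <- function(grad_fine, field) {
  grads <- vector("list", field$L)
  grads[[1]] <- grad_fine
  if (field$L > 1) for (i in 2:field$L) {
    prev <- grads[[i - 1]]
    if (!is.double(prev)) storage.mode(prev) <- "double"
    g <- cpp_interp4_adj(prev, as.integer(dim(prev)),
                         as.integer(field$shapes[[i]]))
    dim(g) <- field$shapes[[i]]
    grads[[i]] <- g
  }
  grads
}
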