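# Shared fixtures, built once per test run and memoized.

.fix <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fix[[key]])) .fix[[key]] <- force(expr)
  .fix[[key]]
}

fix_phantom <- function() memo("phantom", fk_phantom())

# smaller phantom for gradient/optimizer unit tests (coarser voxels, same
# physical frame so the generation center ranges stay valid)
fix_phantom_small <- function() memo("phantom_coarse",
                                     fk_phantom(shape = c(60, 60, 39),
                                                spacing = c(4, 4, 4)))

fix_patient <- function(seed = 3, multifocal = FALSE, small = FALSE) {
  key <- paste0("patient_", seed, "_", multifocal, "_", small)
  memo(key, generate_patient(if (small) fix_phantom_small() else fix_phantom(),
                             seed = seed, multifocal = multifocal))
}

fix_domain <- function(seed = 3, shape = c(24, 24, 24), nt = 32,
                       small = FALSE) {
  key <- paste0("domain_", seed, "_", paste(shape, collapse = "x"), "_", nt,
                "_", small)
  memo(key, build_domain(fix_patient(seed, small = small)$case,
                         margin_mm = 30, solver_shape = shape, n_time = nt))
}

# hand-built minimal case: uniform tissue, one tumor blob, for contract tests
make_mini_case <- function(shape = c(20, 20, 20), spacing = c(1, 1, 1),
                           wm_frac = 0.6, gm_frac = 0.3, pet = NULL) {
  brain <- array(TRUE, shape)
  csf <- array(FALSE, shape)
  wm <- array(wm_frac, shape)
  gm <- array(gm_frac, shape)
  edema <- array(FALSE, shape)
  enhancing <- array(FALSE, shape)
  necrotic <- array(FALSE, shape)
  mid <- round(shape / 2)
  enhancing[(mid[1] - 1):(mid[1] + 1), (mid[2] - 1):(mid[2] + 1), mid[3]] <- TRUE
  edema[(mid[1] - 3):(mid[1] + 3), (mid[2] - 3):(mid[2] + 3), mid[3]] <- TRUE
  edema <- edema & !enhancing
  fk_case(wm, gm, csf, brain, edema, enhancing, necrotic,
          pet = pet, spacing = spacing)
}

# quasi-1D slab domain with homogeneous tissue for solver physics tests
make_slab_domain <- function(shape = c(64, 16, 16), spacing = c(1, 1, 1),
                             n_time = 17) {
  shape <- as.integer(shape)
  omega <- array(TRUE, shape)
  structure(list(
    roi_lo = c(1L, 1L, 1L), roi_hi = shape,
    origin_mm = c(0, 0, 0),
    solver_shape = shape, n_time = as.integer(n_time),
    spacing = as.numeric(spacing), spacing_native = as.numeric(spacing),
    tissue_threshold = 0.1,
    wm = array(1, shape), gm = array(0, shape),
    brain = omega, csf = array(FALSE, shape), omega1 = omega,
    seg_edema = array(FALSE, shape), seg_enhancing = array(FALSE, shape),
    seg_necrotic = array(FALSE, shape), pet = NULL,
    native = list(shape = shape, wm = array(1, shape), gm = array(0, shape),
                  omega1 = omega, edema = array(FALSE, shape),
                  enhancing = array(FALSE, shape),
                  necrotic = array(FALSE, shape))
  ), class = "fk_domain")
}

# independent loop-based diffusion stencil (oracle for the C++ kernel)
apply_A_loop <- function(u, m, om, h) {
  d <- dim(u)
  out <- array(0, d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (!om[i, j, k]) next
    acc <- 0
    nbs <- list(c(i + 1, j, k, 1), c(i - 1, j, k, 1), c(i, j + 1, k, 2),
                c(i, j - 1, k, 2), c(i, j, k + 1, 3), c(i, j, k - 1, 3))
    for (q in nbs) {
      if (q[1] < 1 || q[1] > d[1] || q[2] < 1 || q[2] > d[2] ||
          q[3] < 1 || q[3] > d[3]) next
      if (!om[q[1], q[2], q[3]]) next
      Df <- 0.5 * (m[i, j, k] + m[q[1], q[2], q[3]])
      acc <- acc + Df * (u[q[1], q[2], q[3]] - u[i, j, k]) / h[q[4]]^2
    }
    out[i, j, k] <- acc
  }
  out
}

# independent 1D endpoint-aligned linear interpolation (oracle)
interp1_oracle <- function(v, nf) {
  nc <- length(v)
  if (nc == 1 || nf == 1) return(rep(v[1], nf))
  sapply(seq_len(nf), function(i) {
    pos <- (i - 1) * (nc - 1) / (nf - 1)
    lo <- min(floor(pos), nc - 2)
    w <- pos - lo
    (1 - w) * v[lo + 1] + w * v[lo + 2]
  })
}

# independent nested 4D interpolation oracle built on interp1_oracle
interp4_oracle <- function(coarse, fshape) {
  cur <- coarse
  for (d in 1:4) {
    dm <- dim(cur)
    out_dim <- dm; out_dim[d] <- fshape[d]
    out <- array(0, out_dim)
    idx <- expand.grid(lapply(dm[-d], seq_len))
    for (r in seq_len(nrow(idx))) {
      sel <- as.list(rep(TRUE, 4)); sel[-d] <- as.list(as.integer(idx[r, ]))
      line <- do.call(`[`, c(list(cur), sel))
      out <- do.call(`[<-`, c(list(out), sel, list(interp1_oracle(line, fshape[d]))))
    }
    cur <- out
  }
  cur
}
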