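test_that("volume save/load round-trips values and spacing at float32 precision", {
  vol <- array(runif(8 * 7 * 6), c(8, 7, 6))
  f <- tempfile(fileext = ".nii.gz")
  write_volume(vol, f, spacing = c(1.5, 2, 2.5))
  back <- read_volume(f)
  expect_equal(dim(back), dim(vol))
  expect_equal(attr(back, "spacing"), c(1.5, 2, 2.5), tolerance = 1e-5)
  expect_lt(max(abs(back - vol)), 1e-6)  # float32 storage
  fm <- tempfile(fileext = ".nii.gz")
  write_volume(vol > 0.5, fm, spacing = c(1, 1, 1), mask = TRUE)
  expect_identical(read_volume(fm) > 0.5, vol > 0.5)
  unlink(c(f, fm))
})

test_that("case validation rejects inconsistent inputs", {
  cs <- make_mini_case()
  expect_s3_class(cs, "fk_case")
  shape <- cs$shape
  # shape mismatch
  expect_error(
    fk_case(cs$wm, cs$gm, cs$csf, cs$brain,
            array(FALSE, c(10, 10, 10)), cs$seg_enhancing, cs$seg_necrotic,
            spacing = cs$spacing),
    "shape mismatch.*edema")
  # tissue fractions above one, error reports voxel count
  wm_bad <- cs$wm; wm_bad[1:3, 1, 1] <- 0.95
  expect_error(
    fk_case(wm_bad, cs$gm, cs$csf, cs$brain, cs$seg_edema, cs$seg_enhancing,
            cs$seg_necrotic, spacing = cs$spacing),
    "wm \\+ gm > 1 at 3 voxel")
  # non-binary segmentation
  seg_bad <- array(0, shape); seg_bad[10, 10, 10] <- 0.7
  expect_error(
    fk_case(cs$wm, cs$gm, cs$csf, cs$brain, seg_bad, cs$seg_enhancing,
            cs$seg_necrotic, spacing = cs$spacing),
    "not binary")
  # segmentation outside the brain
  brain_small <- cs$brain; brain_small[8:12, 8:12, 8:12] <- FALSE
  expect_error(
    fk_case(cs$wm, cs$gm, cs$csf, brain_small, cs$seg_edema, cs$seg_enhancing,
            cs$seg_necrotic, spacing = cs$spacing),
    "outside the brain")
})

test_that("load_case reads a saved patient directory back consistently", {
  p <- fix_patient(seed = 7, small = TRUE)
  d <- file.path(tempdir(), "case_io")
  save_patient(p, d)
  back <- load_case(d)
  expect_identical(back$seg_edema, p$case$seg_edema)
  expect_identical(back$seg_necrotic, p$case$seg_necrotic)
  expect_lt(max(abs(back$pet - p$case$pet)), 1e-6)
  expect_equal(back$spacing, p$case$spacing, tolerance = 1e-5)
  unlink(d, recursive = TRUE)
})

test_that("ROI box arithmetic: margins dilate and clip correctly", {
  shape <- c(64, 64, 64)
  cs0 <- make_mini_case(shape, spacing = c(1, 1, 1))
  seg <- array(FALSE, shape); seg[31, 31, 31] <- TRUE  # 0-based index 30
  cs <- fk_case(cs0$wm, cs0$gm, cs0$csf, cs0$brain,
                edema = seg, enhancing = seg, necrotic = array(FALSE, shape),
                spacing = c(1, 1, 1))
  dom <- build_domain(cs, margin_mm = 10, solver_shape = c(16, 16, 16), n_time = 8)
  expect_equal(unname(dom$roi_lo), rep(21, 3))  # 0-based 20
  expect_equal(unname(dom$roi_hi), rep(41, 3))  # 0-based 40
  # huge margin clips to the full volume without error
  dom2 <- build_domain(cs, margin_mm = 500, solver_shape = c(16, 16, 16), n_time = 8)
  expect_equal(unname(dom2$roi_lo), rep(1, 3))
  expect_equal(unname(dom2$roi_hi), shape)
  # empty segmentation is rejected
  cs_empty <- tryCatch(
    fk_case(cs0$wm, cs0$gm, cs0$csf, cs0$brain, array(FALSE, shape),
            array(FALSE, shape), array(FALSE, shape), spacing = c(1, 1, 1)),
    error = function(e) NULL)
  if (!is.null(cs_empty)) expect_error(build_domain(cs_empty), "empty segmentation")
})

test_that("default solver resolution is 48^3 with 192 time points", {
  cs <- make_mini_case(c(24, 24, 24))
  dom <- build_domain(cs)
  expect_equal(unname(dom$solver_shape), c(48L, 48L, 48L))
  expect_equal(dom$n_time, 192L)
})

test_that("diffusion field mixes tissue compartments as w*D_w + g*D_w/R", {
  shape <- c(6, 6, 6)
  mk <- function(w, g) {
    dom <- make_slab_domain(shape)
    dom$wm <- array(w, shape); dom$gm <- array(g, shape)
    dom
  }
  p <- fk_params(d_w = 0.2, rho = 0.1, r = 10, center = c(2, 2, 2))
  expect_equal(build_diffusion_field(mk(1, 0), p)[1, 1, 1], 0.2)
  expect_equal(build_diffusion_field(mk(0, 1), p)[1, 1, 1], 0.02)
  expect_equal(build_diffusion_field(mk(0.5, 0.5), p)[1, 1, 1], 0.11)
  expect_error(fk_params(d_w = 0.2, rho = 0.1, r = 0.9, center = c(2, 2, 2)),
               "r must exceed 1")
  # bounded by D_w, non-negative, zero outside omega1 on random tissue
  for (rep in 1:3) {
    dom <- fix_domain(seed = 7, small = TRUE)
    pr <- fk_params(runif(1, 0.05, 3), 1, runif(1, 5, 30), c(60, 60, 60))
    D <- build_diffusion_field(dom, pr)
    expect_true(all(D >= 0))
    expect_true(all(D <= pr$d_w + 1e-12))
    expect_true(all(D[!dom$omega1] == 0))
  }
})

test_that("face coefficients average neighbors and vanish at the tissue boundary", {
  shape <- c(5, 4, 4)
  om <- array(TRUE, shape); om[5, , ] <- FALSE
  D <- array(0.2, shape)
  D[1, 1, 1] <- 0.1; D[2, 1, 1] <- 0.3
  f <- face_diffusion(D, om)
  expect_equal(f$x[1, 1, 1], 0.2)           # mean of 0.1 and 0.3
  expect_true(all(f$x[4, , ] == 0))          # face into non-tissue
  expect_equal(f$y[2, 2, 2], 0.2)            # constant region
  # symmetry: recompute from the flipped volume
  ff <- face_diffusion(D[shape[1]:1, , ], om[shape[1]:1, , ])
  expect_equal(f$x, ff$x[(shape[1] - 1):1, , , drop = FALSE])
})
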