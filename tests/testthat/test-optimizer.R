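test_that("parameter transforms are bijective and always feasible", {
  raw0 <- rep(0, 10); names(raw0) <- fkodil:::raw_names
  p0 <- fk_transform_params(raw0)
  expect_gt(p0$growth$d_w, 0)
  expect_gt(p0$growth$r, 1)
  expect_lt(p0$imaging$theta_down, p0$imaging$theta_up)
  set.seed(41)
  for (i in 1:5) {
    g <- fk_params(runif(1, 0.1, 30), runif(1, 0.1, 30), runif(1, 1.1, 40),
                   runif(3, -50, 150))
    im <- fk_imaging(runif(1, 0.05, 0.4), runif(1, 0.45, 0.9),
                     runif(1, 0.2, 3), runif(1, 0.01, 0.8))
    back <- fk_transform_params(fk_untransform_params(g, im))
    expect_equal(back$growth$d_w, g$d_w, tolerance = 1e-10)
    expect_equal(back$growth$rho, g$rho, tolerance = 1e-10)
    expect_equal(back$growth$r, g$r, tolerance = 1e-10)
    expect_equal(back$growth$center, g$center, tolerance = 1e-10)
    expect_equal(back$imaging$theta_down, im$theta_down, tolerance = 1e-10)
    expect_equal(back$imaging$theta_up, im$theta_up, tolerance = 1e-10)
  }
  # extreme raw values keep positivity without overflow to zero crossings
  raw_neg <- raw0; raw_neg[["log_dw"]] <- -60
  expect_gt(fk_transform_params(raw_neg)$growth$d_w, 0)
})

test_that("characteristic diffusivity is the edema-to-core volume ratio", {
  shape <- c(40, 40, 40)
  cs0 <- make_mini_case(shape, spacing = c(2, 2, 2))
  enhancing <- array(FALSE, shape); edema <- array(FALSE, shape)
  enhancing[19:21, 19:21, 19:20] <- TRUE           # 18-voxel core
  edema[19:21, 19:21, 17:22] <- TRUE
  edema <- edema & !enhancing                       # 36 voxels: ratio 2
  cs <- fk_case(cs0$wm, cs0$gm, cs0$csf, cs0$brain, edema, enhancing,
                array(FALSE, shape), spacing = c(2, 2, 2))
  dom <- build_domain(cs, margin_mm = 20, solver_shape = c(16, 16, 16),
                      n_time = 8)
  ig <- fk_initial_guess(dom)
  # the characteristic run uses the native-resolution labels
  v_core <- sum(dom$native$enhancing | dom$native$necrotic)
  v_edema <- sum(dom$native$edema)
  # normalized rates keep the ratio D_ch = V_edema / V_core ( = 2 here)
  expect_equal(ig$params$d_w / ig$params$rho, v_edema / v_core,
               tolerance = 1e-10)
  # the returned field satisfies the growth equation with the returned rates
  D <- build_diffusion_field(dom, ig$params)
  per_vs <- loss_pde(ig$u4d, D, dom$omega1, ig$params$rho, dom$spacing) /
    (sum(dom$omega1) * (dom$n_time - 1))
  expect_lt(per_vs, 1e-2)
})

test_that("initial guess errors name the missing structure", {
  shape <- c(20, 20, 20)
  cs0 <- make_mini_case(shape)
  seg <- array(FALSE, shape); seg[9:11, 9:11, 9:11] <- TRUE
  cs_noedema <- fk_case(cs0$wm, cs0$gm, cs0$csf, cs0$brain,
                        array(FALSE, shape), seg, array(FALSE, shape))
  dom <- build_domain(cs_noedema, margin_mm = 8, solver_shape = c(12, 12, 12),
                      n_time = 8)
  expect_error(fk_initial_guess(dom), "edema")
  cs_nocore <- fk_case(cs0$wm, cs0$gm, cs0$csf, cs0$brain,
                       seg, array(FALSE, shape), array(FALSE, shape))
  dom2 <- build_domain(cs_nocore, margin_mm = 8, solver_shape = c(12, 12, 12),
                       n_time = 8)
  expect_error(fk_initial_guess(dom2), "core")
})

test_that("initial guess recovers a simulated patient's core", {
  dom <- fix_domain(seed = 3, shape = c(24, 24, 24), nt = 32)
  ig <- fk_initial_guess(dom)
  core <- dom$seg_enhancing | dom$seg_necrotic
  uT <- ig$u4d[, , , dom$n_time]
  expect_gt(dice(uT >= 0.525, core), 0.5)
})

test_that("optimization is deterministic and never loses the best state", {
  dom <- fix_domain(seed = 3, shape = c(16, 16, 16), nt = 16, small = TRUE)
  init <- fk_initial_guess(dom)
  cfg <- fk_optim_config(max_iters = 40, log_every = 10)
  f1 <- fk_optimize(dom, init = init, config = cfg)
  f2 <- fk_optimize(dom, init = init, config = cfg)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$params, f2$params)
  expect_lte(f1$best_loss, min(f1$history$total))
})

test_that("with dominant PDE weight the field converges to a discrete solution", {
  dom <- fix_domain(seed = 3, shape = c(16, 16, 16), nt = 16, small = TRUE)
  init <- fk_initial_guess(dom)
  w <- fk_weights(lambda_pde = 1e6, lambda_ic = 0, lambda_core = 0,
                  lambda_edema = 0, lambda_pet = 0, lambda_params = 0)
  cfg <- fk_optim_config(max_iters = 150, polish_iters = 250, weights = w,
                         log_every = 50)
  fit <- fk_optimize(dom, init = init, config = cfg)
  per_vs <- fit$terms[["L_PDE"]] / (sum(dom$omega1) * (dom$n_time - 1))
  expect_lt(per_vs, 1e-6)
})

test_that("forward replay is deterministic and tracks the generating simulation", {
  p <- fix_patient(seed = 3)
  dom <- fix_domain(seed = 3, shape = c(24, 24, 24), nt = 32)
  tp <- p$truth_params
  pars <- fk_params(tp$d_w * tp$t_sim, tp$rho * tp$t_sim, tp$r,
                    tp$centers[1, ])
  r1 <- fk_replay(dom, pars, native = TRUE, n_store = 5)
  r2 <- fk_replay(dom, pars, native = TRUE, n_store = 5)
  expect_identical(r1$u, r2$u)
  # native ROI replay of the truth parameters reproduces the ground truth
  crop <- p$truth_u[dom$roi_lo[1]:dom$roi_hi[1], dom$roi_lo[2]:dom$roi_hi[2],
                    dom$roi_lo[3]:dom$roi_hi[3]]
  uT <- r1$u[, , , 5]
  expect_gt(dice(uT >= 0.5, crop >= 0.5), 0.8)
  # vanishing proliferation conserves mass
  slab <- make_slab_domain(c(16, 16, 16), n_time = 3)
  tr <- fk_simulate(slab, fk_params(0.5, 1e-9, 2, c(8, 8, 8)), t_final = 2,
                    n_store = 3)
  expect_lt(abs(sum(tr$u[, , , 3]) - sum(tr$u[, , , 1])) / sum(tr$u[, , , 1]),
            1e-6)
})
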