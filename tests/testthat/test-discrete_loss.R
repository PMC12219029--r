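test_that("CN residual matches an independent loop-based stencil", {
  set.seed(11)
  shape <- c(8, 8, 8)
  om <- array(TRUE, shape); om[1, , ] <- FALSE; om[, 8, ] <- FALSE
  m <- array(runif(prod(shape), 0.05, 0.3), shape); m[!om] <- 0
  u0 <- array(runif(prod(shape)), shape)
  u1 <- array(runif(prod(shape)), shape)
  h <- c(1.3, 0.9, 1.1); rho <- 0.7; dt <- 0.05
  K_oracle <- (u1 - u0) / dt -
    0.5 * (apply_A_loop(u1, m, om, h) + apply_A_loop(u0, m, om, h)) -
    0.5 * rho * (u1 * (1 - u1) + u0 * (1 - u0))
  K_oracle[!om] <- 0
  K <- residual_cn(u0, u1, m, om, rho, dt, h)
  expect_lt(max(abs(K - K_oracle)), 1e-10)
})

test_that("stationary constants and scalar CN roots have zero residual", {
  shape <- c(6, 6, 6)
  om <- array(TRUE, shape)
  m <- array(0.3, shape)
  cc <- array(0.42, shape)
  K <- residual_cn(cc, cc, m, om, rho = 0, dt = 0.1, spacing = c(1, 1, 1))
  expect_lt(max(abs(K)), 1e-14)
  # diffusion-free voxel: u1 solving the scalar CN relation zeroes K there
  rho <- 1.4; dt <- 0.2; u0v <- 0.5
  root <- uniroot(function(u1) (u1 - u0v) / dt -
                    0.5 * rho * (u0v * (1 - u0v) + u1 * (1 - u1)),
                  c(u0v, 1), tol = 1e-14)$root
  Dz <- array(0, shape)
  K2 <- residual_cn(array(u0v, shape), array(root, shape), Dz, om, rho, dt,
                    c(1, 1, 1))
  expect_lt(max(abs(K2)), 1e-10)
})

test_that("implicit CN forward solves have near-zero residual loss", {
  dom <- fix_domain(seed = 3, shape = c(10, 10, 10), nt = 12, small = TRUE)
  p <- fk_params(d_w = 2, rho = 3, r = 15,
                 center = dom$origin_mm + (dom$solver_shape - 1) *
                   dom$spacing / 2)
  ctr <- fkodil:::snap_to_omega(dom, p$center)
  D <- build_diffusion_field(dom, p)
  u0 <- fkodil:::gaussian_field(dom$solver_shape, dom$origin_mm, dom$spacing,
                                ctr, dom$omega1)
  u4d <- cn_simulate(u0, D, dom$omega1, p$rho, dom$spacing, n_time = 12)
  lp <- loss_pde(u4d, D, dom$omega1, p$rho, dom$spacing)
  per_vs <- lp / (sum(dom$omega1) * 11)
  expect_lt(per_vs, 1e-8)
  expect_gte(lp, 0)
})

test_that("residual loss scales quadratically in a residual-doubling perturbation", {
  shape <- c(6, 6, 6); nt <- 5
  om <- array(TRUE, shape)
  m <- array(0.2, shape)
  base <- array(0.3, c(shape, nt))  # constant in time: K = 0 when rho = 0
  set.seed(5)
  delta <- array(rnorm(prod(shape) * nt, sd = 0.01), c(shape, nt))
  l1 <- loss_pde(base + delta, m, om, rho = 0, spacing = c(1, 1, 1))
  l2 <- loss_pde(base + 2 * delta, m, om, rho = 0, spacing = c(1, 1, 1))
  expect_equal(l2, 4 * l1, tolerance = 1e-10)
})

test_that("initial-condition loss vanishes on the exact seed and sums G^2 otherwise", {
  dom <- fix_domain(seed = 3, small = TRUE)
  ctr <- fkodil:::snap_to_omega(
    dom, dom$origin_mm + (dom$solver_shape - 1) * dom$spacing / 2)
  G <- gaussian_ic(dom, ctr)
  expect_equal(loss_ic(G, ctr, dom), 0)
  expect_equal(loss_ic(array(0, dom$solver_shape), ctr, dom),
               sum(G[dom$omega1]^2))
})

test_that("sigmoid is exact at the midpoint and saturates stably", {
  expect_equal(sigmoid(0), 0.5)
  expect_equal(sigmoid(0.1, beta = 50), 0.993307, tolerance = 1e-6)
  expect_equal(sigmoid(-10, beta = 50), 0)
  expect_equal(sigmoid(10, beta = 50), 1)
  expect_true(all(is.finite(sigmoid(c(-1e4, 1e4), beta = 50))))
})

test_that("segmentation losses encode the core floor and edema band", {
  shape <- c(5, 5, 5)
  core <- array(FALSE, shape); core[2:4, 2:4, 2:4] <- TRUE
  ncore <- sum(core)
  expect_lt(loss_core(array(1, shape), core, theta_up = 0.6), 1e-8 * ncore)
  expect_equal(loss_core(array(0, shape), core, theta_up = 0.6), ncore,
               tolerance = 1e-9)
  expect_equal(loss_core(array(1, shape), array(FALSE, shape), 0.6), 0)
  edema <- core
  mid <- (0.2 + 0.6) / 2
  expect_lt(loss_edema(array(mid, shape), edema, 0.2, 0.6), 1e-3 * ncore)
  expect_equal(loss_edema(array(0, shape), edema, 0.2, 0.6), ncore,
               tolerance = 1e-3)
  expect_equal(loss_edema(array(1, shape), edema, 0.2, 0.6), ncore,
               tolerance = 1e-3)
  expect_error(loss_edema(array(0, shape), edema, 0.6, 0.2), "theta_down")
})

test_that("steep sigmoids converge to hard threshold counting", {
  set.seed(9)
  shape <- c(8, 8, 8)
  core <- array(runif(prod(shape)) > 0.5, shape)
  tu <- 0.525; td <- 0.25; a <- fkodil:::FK_ALPHA
  u <- array(runif(prod(shape)), shape)
  # keep values away from the decision boundaries
  u[abs(tu - u - a) < 0.01] <- 0.9
  u[abs(td - u - a) < 0.01] <- 0.9
  u[abs(tu - u + a) < 0.01] <- 0.9
  count_core <- sum(u[core] < tu - a)
  expect_equal(loss_core(u, core, tu, beta = 5000), count_core, tolerance = 1e-6)
  count_edema <- sum(u[core] < td - a) + sum(u[core] > tu + a)
  expect_equal(loss_edema(u, core, td, tu, beta = 5000), count_edema,
               tolerance = 1e-6)
})

test_that("PET loss matches the affine signal model and skips necrosis", {
  shape <- c(6, 6, 6)
  om3 <- array(FALSE, shape); om3[2:5, 2:5, 2:5] <- TRUE
  y <- array(runif(prod(shape)), shape)
  tp <- 1.3; tb <- 0.2
  u <- tp * (y - tb)
  expect_equal(loss_pet(u, y, om3, tp, tb), 0)
  expect_equal(loss_pet(array(0, shape), array(1, shape), om3, 1, 0), sum(om3))
  expect_warning(z <- loss_pet(u, y, array(FALSE, shape), tp, tb), "empty")
  expect_equal(z, 0)
  # omega3 from the data masks excludes necrotic voxels
  dom <- fix_domain(seed = 3, small = TRUE)
  masks <- fk_data_masks(dom)
  expect_false(any(masks$omega3 & dom$seg_necrotic))
})

test_that("parameter regularizer is zero inside bounds and a scaled hinge outside", {
  b <- default_param_bounds()
  p_in <- fk_params(d_w = 10, rho = 10, r = 20, center = c(0, 0, 0))
  im_in <- fk_imaging(0.25, 0.5, 1, 0.2)
  expect_equal(loss_params(p_in, im_in, b), 0)
  w <- diff(b$d_w)
  p_out <- fk_params(d_w = b$d_w[2] + w, rho = 10, r = 20, center = c(0, 0, 0))
  expect_equal(loss_params(p_out, im_in, b), 1)
  # reversed thresholds activate the ordering hinge
  im_rev <- list(theta_down = 0.5, theta_up = 0.3, theta_pet = 1, theta_bkg = 0.2)
  expect_gt(loss_params(p_in, im_rev, b), 0)
  expect_error(loss_params(p_in, im_in, list(d_w = c(2, 1))), "lo >= hi")
})

test_that("total loss is the weighted sum of its terms", {
  dom <- fix_domain(seed = 3, small = TRUE)
  set.seed(2)
  u4d <- array(runif(prod(dom$solver_shape) * dom$n_time, 0, 0.5),
               c(dom$solver_shape, dom$n_time))
  p <- fk_params(5, 8, 20, fkodil:::snap_to_omega(
    dom, dom$origin_mm + (dom$solver_shape - 1) * dom$spacing / 2))
  im <- fk_imaging(0.25, 0.525, 1, 0.2)
  rep0 <- total_loss(u4d, dom, p, im, fk_weights(0, 0, 0, 0, 0, 0))
  expect_equal(rep0$total, 0)
  w1 <- fk_weights()
  r1 <- total_loss(u4d, dom, p, im, w1)
  expect_equal(r1$total, sum(r1$terms * r1$weights), tolerance = 1e-12)
  # perturbing one weight moves the total by exactly lambda * term
  w2 <- fk_weights(lambda_core = 3)
  r2 <- total_loss(u4d, dom, p, im, w2)
  expect_equal(r2$total - r1$total, 2 * r1$terms[["L_CORE"]], tolerance = 1e-9)
  # PET weight zero: pipeline still reports a zero PET term
  expect_equal(total_loss(u4d, dom, p, im,
                          fk_weights(lambda_pet = 0))$terms[["L_PET"]], 0)
})
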