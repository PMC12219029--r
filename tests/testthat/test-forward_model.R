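test_that("Gaussian seed has the prescribed amplitude and width", {
  c1 <- 50 / (60 * pi)^1.5
  # center value, 1/e point at distance sqrt(60), far tail
  g <- fkodil:::gaussian_field(c(3, 1, 1), c(0, 0, 0), c(sqrt(60), 1, 1),
                               center = c(0, 0, 0))
  expect_equal(g[1, 1, 1], c1)
  expect_equal(g[1, 1, 1], 1.932e-2, tolerance = 1e-3)
  expect_equal(g[2, 1, 1], c1 / exp(1))
  expect_equal(g[2, 1, 1], 7.11e-3, tolerance = 1e-3)
  far <- fkodil:::gaussian_field(c(2, 1, 1), c(0, 0, 0), c(60, 1, 1), c(0, 0, 0))
  expect_lt(far[2, 1, 1], 1e-25)
  # center outside the diffusible region is rejected
  dom <- fix_domain(seed = 3, small = TRUE)
  expect_error(gaussian_ic(dom, dom$origin_mm - 50), "outside the diffusible")
})

test_that("explicit step reduces to the logistic update without diffusion", {
  shape <- c(4, 4, 4)
  om <- array(TRUE, shape)
  Dz <- array(0, shape)
  u <- array(0.5, shape)
  up <- fk_step(u, Dz, om, rho = 1, dt = 0.1, spacing = c(1, 1, 1))
  expect_equal(up[2, 2, 2], 0.525)
  expect_equal(fk_step(array(1, shape), Dz, om, 1, 0.1, c(1, 1, 1)),
               array(1, shape))
  expect_equal(fk_step(array(0, shape), Dz, om, 1, 0.1, c(1, 1, 1)),
               array(0, shape))
  expect_error(fk_step(u, array(1, shape), om, 1, 0.5, c(1, 1, 1)),
               "stability bound")
})

test_that("pure diffusion conserves total density under no-flux boundaries", {
  dom <- make_slab_domain(c(16, 16, 16), n_time = 5)
  u0 <- fkodil:::gaussian_field(dom$solver_shape, c(0, 0, 0), dom$spacing,
                                center = c(7, 7, 7), dom$omega1)
  D <- array(0.4, dom$solver_shape)
  traj <- fkodil:::cpp_fk_simulate(as.numeric(u0), as.numeric(D),
                                   as.integer(dom$omega1),
                                   as.integer(dom$solver_shape), dom$spacing,
                                   0, 0.3, 60L, c(0L, 60L))
  traj <- array(traj, c(dom$solver_shape, 2))
  drift <- abs(sum(traj[, , , 2]) - sum(traj[, , , 1])) / sum(traj[, , , 1])
  expect_lt(drift, 1e-6)
})

test_that("logistic-only dynamics rise monotonically toward saturation", {
  shape <- c(4, 4, 4)
  om <- array(TRUE, shape)
  Dz <- array(0, shape)
  u <- array(runif(prod(shape), 0.01, 0.2), shape)
  prev <- u
  for (s in 1:200) {
    u <- fk_step(u, Dz, om, rho = 1, dt = 0.4, spacing = c(1, 1, 1))
    expect_true(all(u >= prev - 1e-12))
    prev <- u
  }
  expect_true(all(u > 0.99))
})

test_that("front speed on a homogeneous slab matches the Fisher-KPP value", {
  # long slab: convergence to the asymptotic wave speed is slow (the relative
  # deficit decays like width/travel-distance), so the domain must allow a
  # travel distance of many front widths
  dom <- make_slab_domain(c(320, 8, 8), n_time = 41)
  Dv <- 2; rho <- 0.5
  ic <- array(0, dom$solver_shape)
  ic[1:10, , ] <- 1
  traj <- fk_simulate(dom, fk_params(Dv, rho, r = 1e9, center = c(5, 4, 4)),
                      t_final = 140, n_store = 41, ic = ic)
  v <- front_speed(traj, level = 0.5)
  expect_equal(v, 2 * sqrt(Dv * rho), tolerance = 0.1)
})

test_that("one explicit step matches a sparse-matrix build of the same stencil", {
  shape <- c(10, 10, 10)
  n <- prod(shape)
  set.seed(42)
  om <- array(runif(n) > 0.15, shape)
  m <- array(runif(n, 0.05, 0.4), shape); m[!om] <- 0
  h <- c(1.2, 1, 0.8)
  u <- array(runif(n, 0.1, 0.2), shape); u[!om] <- 0
  rho <- 0.3; dt <- 0.05
  # independent route: assemble the operator as a sparse matrix
  idx <- function(i, j, k) i + (j - 1) * shape[1] + (k - 1) * shape[1] * shape[2]
  trip <- list(i = integer(0), j = integer(0), x = numeric(0))
  add <- function(i, j, x) {
    trip$i <<- c(trip$i, i); trip$j <<- c(trip$j, j); trip$x <<- c(trip$x, x)
  }
  for (i in 1:shape[1]) for (j in 1:shape[2]) for (k in 1:shape[3]) {
    if (!om[i, j, k]) next
    v <- idx(i, j, k)
    nbs <- list(c(i + 1, j, k, 1), c(i - 1, j, k, 1), c(i, j + 1, k, 2),
                c(i, j - 1, k, 2), c(i, j, k + 1, 3), c(i, j, k - 1, 3))
    for (q in nbs) {
      if (q[1] < 1 || q[1] > shape[1] || q[2] < 1 || q[2] > shape[2] ||
          q[3] < 1 || q[3] > shape[3]) next
      if (!om[q[1], q[2], q[3]]) next
      w <- idx(q[1], q[2], q[3])
      Df <- 0.5 * (m[i, j, k] + m[q[1], q[2], q[3]]) / h[q[4]]^2
      add(v, w, Df); add(v, v, -Df)
    }
  }
  A <- Matrix::sparseMatrix(i = trip$i, j = trip$j, x = trip$x, dims = c(n, n))
  expected <- as.numeric(u) + dt * (as.numeric(A %*% as.numeric(u)) +
                                      rho * as.numeric(u) * (1 - as.numeric(u)))
  expected[!om] <- 0
  got <- fk_step(u, m, om, rho, dt, h)
  expect_lt(max(abs(as.numeric(got) - expected)), 1e-10)
})

test_that("halving the time step shrinks the discretization error", {
  dom <- make_slab_domain(c(16, 8, 8), n_time = 3)
  p <- fk_params(0.3, 0.5, r = 1e9, center = c(7.5, 3.5, 3.5))
  final <- function(dt) {
    tr <- fk_simulate(dom, p, t_final = 4, n_store = 3, dt = dt)
    tr$u[, , , 3]
  }
  u1 <- final(0.2); u2 <- final(0.1); u4 <- final(0.05)
  e1 <- max(abs(u1 - u4)); e2 <- max(abs(u2 - u4))
  expect_lt(e2, 0.75 * e1)  # first-order: ratio should approach 1/2... 2/3
})
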