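#' Optimizer configuration
#'
#' @param max_iters Adam iteration budget
#' @param learning_rate Adam step size for the scalar parameters
#'   (cosine-decayed to zero)
#' @param field_learning_rate Adam step size for the field levels; kept an
#'   order of magnitude below `learning_rate` because field perturbations are
#'   amplified by the inverse time step in the residual
#' @param polish_iters L-BFGS refinement iterations after Adam (0 disables)
#' @param weights an [fk_weights()]
#' @param bounds plausibility bounds (default [default_param_bounds()];
#'   seed-center bounds are added from the ROI box)
#' @param log_every record the loss report every this many iterations
#' @param plateau_tol,plateau_window stop early when the best total loss
#'   improves by less than `plateau_tol` (relative) over `plateau_window`
#'   iterations
#' @param levels number of multigrid levels (default [mg_default_levels()])
#' @param seed stored with the run for provenance; the optimizer itself is
#'   deterministic
#' @return list of class `fk_optim_config`
#' @export
fk_optim_config <- function(max_iters = 2000, learning_rate = 1e-2,
                            field_learning_rate = 1e-3,
                            polish_iters = 0, weights = fk_weights(),
                            bounds = NULL, log_every = 50,
                            plateau_tol = 1e-6, plateau_window = 200,
                            levels = NULL, seed = 0L) {
  stopifnot(max_iters > 0, learning_rate > 0, field_learning_rate > 0)
  structure(list(max_iters = as.integer(max_iters),
                 learning_rate = learning_rate,
                 field_learning_rate = field_learning_rate,
                 polish_iters = as.integer(polish_iters),
                 weights = weights, bounds = bounds,
                 log_every = as.integer(log_every),
                 plateau_tol = plateau_tol,
                 plateau_window = as.integer(plateau_window),
                 levels = levels, seed = as.integer(seed)),
            class = "fk_optim_config")
}

# --- unconstrained parameterization -----------------------------------------
# d_w, rho positive via exp; r > 1 via 1 + exp; thresholds in (0,1) with
# theta_up = theta_down + (1 - theta_down) * logistic(gap); center in mm.

raw_names <- c("log_dw", "log_rho", "log_rm1", "x0", "y0", "z0",
               "q_down", "q_gap", "log_pet", "q_bkg")

#' Map unconstrained optimizer variables to model parameters
#'
#' The inverse of [fk_untransform_params()]; every output satisfies its
#' invariant (positivity, `r > 1`, threshold ordering) for any real input.
#'
#' @param raw named numeric vector with elements
#'   `log_dw, log_rho, log_rm1, x0, y0, z0, q_down, q_gap, log_pet, q_bkg`
#' @return list with elements `growth` ([fk_params()]) and `imaging`
#'   ([fk_imaging()])
#' @export
fk_transform_params <- function(raw) {
  td <- stats::plogis(raw[["q_down"]])
  tu <- td + (1 - td) * stats::plogis(raw[["q_gap"]])
  list(growth = fk_params(exp(raw[["log_dw"]]), exp(raw[["log_rho"]]),
                          1 + exp(raw[["log_rm1"]]),
                          c(raw[["x0"]], raw[["y0"]], raw[["z0"]])),
       imaging = fk_imaging(td, tu, exp(raw[["log_pet"]]),
                            stats::plogis(raw[["q_bkg"]])))
}

#' Map model parameters to unconstrained optimizer variables
#'
#' @param growth an [fk_params()]
#' @param imaging an [fk_imaging()] with `theta_bkg > 0`
#' @return named numeric vector accepted by [fk_transform_params()]
#' @export
fk_untransform_params <- function(growth, imaging) {
  gap <- (imaging$theta_up - imaging$theta_down) / (1 - imaging$theta_down)
  c(log_dw = log(growth$d_w), log_rho = log(growth$rho),
    log_rm1 = log(growth$r - 1),
    x0 = growth$center[1], y0 = growth$center[2], z0 = growth$center[3],
    q_down = stats::qlogis(imaging$theta_down),
    q_gap = stats::qlogis(gap),
    log_pet = log(imaging$theta_pet),
    q_bkg = stats::qlogis(max(imaging$theta_bkg, 1e-8)))
}

# hinge loss and derivative for one parameter
hinge_sq_grad <- function(p, rng) {
  w <- diff(rng)
  if (p < rng[1]) c((rng[1] - p)^2, -2 * (rng[1] - p)) / w^2
  else if (p > rng[2]) c((p - rng[2])^2, 2 * (p - rng[2])) / w^2
  else c(0, 0)
}

# Builds the objective closure: value + exact gradient of the weighted total
# loss with respect to [level values, raw parameters].
make_objective <- function(domain, weights, bounds, field_template, beta = 50) {
  dims <- c(domain$solver_shape, domain$n_time)
  nvox <- prod(domain$solver_shape)
  nt <- domain$n_time
  dt <- 1 / (nt - 1)
  om_log <- domain$omega1
  om_int <- as.integer(om_log)
  sp <- as.numeric(domain$spacing)
  wm <- as.numeric(domain$wm); gm <- as.numeric(domain$gm)
  masks <- fk_data_masks(domain)
  core_idx <- which(masks$core); edema_idx <- which(masks$edema)
  omega3_idx <- which(masks$omega3)
  has_pet <- !is.null(domain$pet) && weights$lambda_pet > 0 &&
    length(omega3_idx) > 0
  y3 <- if (has_pet) normalize_pet(domain$pet, domain$brain)[omega3_idx] else NULL
  crd <- solver_coords(domain)
  Xc <- array(crd$x, dim = domain$solver_shape)
  Yc <- array(rep(crd$y, each = dims[1]), dim = domain$solver_shape)
  Zc <- array(rep(crd$z, each = dims[1] * dims[2]), dim = domain$solver_shape)
  om_idx <- which(om_log)
  alpha <- FK_ALPHA
  c2 <- 60
  level_sizes <- vapply(field_template$shapes, prod, 0)
  n_field <- sum(level_sizes)
  lam <- weights

  function(theta, want_grad = TRUE) {
    # unpack
    field <- field_template
    off <- 0L
    for (i in seq_len(field$L)) {
      lv <- theta[(off + 1):(off + level_sizes[i])]
      dim(lv) <- field$shapes[[i]]
      field$levels[[i]] <- lv
      off <- off + level_sizes[i]
    }
    raw <- theta[(n_field + 1):length(theta)]
    names(raw) <- raw_names
    pars <- fk_transform_params(raw)
    gp <- pars$growth; im <- pars$imaging
    u4d <- mg_compose(field)

    D <- (wm * gp$d_w + gm * gp$d_w / gp$r) * om_int
    pde <- cpp_pde_loss_grad(u4d, D, om_int, as.integer(dims),
                             sp, gp$rho, dt, want_grad)
    u0 <- u4d[, , , 1]
    G <- gaussian_field(domain$solver_shape, domain$origin_mm, domain$spacing,
                        gp$center, om_log)
    r0 <- (u0 - G) * om_log
    l_ic <- sum(r0^2)
    uT <- u4d[, , , nt]
    uc <- uT[core_idx]; ue <- uT[edema_idx]
    s_c <- stats::plogis(beta * (im$theta_up - uc - alpha))
    l_core <- sum(s_c)
    s1 <- stats::plogis(beta * (im$theta_down - ue - alpha))
    s2 <- stats::plogis(beta * (im$theta_up - ue + alpha))
    l_edema <- sum(s1) + sum(1 - s2)
    if (has_pet) {
      r3 <- uT[omega3_idx] - im$theta_pet * (y3 - im$theta_bkg)
      l_pet <- sum(r3^2)
    } else l_pet <- 0
    hb <- list(d_w = hinge_sq_grad(gp$d_w, bounds$d_w),
               rho = hinge_sq_grad(gp$rho, bounds$rho),
               r = hinge_sq_grad(gp$r, bounds$r),
               theta_down = hinge_sq_grad(im$theta_down, bounds$theta_down),
               theta_up = hinge_sq_grad(im$theta_up, bounds$theta_up),
               theta_pet = hinge_sq_grad(im$theta_pet, bounds$theta_pet),
               theta_bkg = hinge_sq_grad(im$theta_bkg, bounds$theta_bkg),
               x0 = hinge_sq_grad(gp$center[1], bounds$x0),
               y0 = hinge_sq_grad(gp$center[2], bounds$y0),
               z0 = hinge_sq_grad(gp$center[3], bounds$z0))
    l_par <- sum(vapply(hb, `[`, 0, 1))
    terms <- c(L_PDE = pde$loss, L_IC = l_ic, L_CORE = l_core,
               L_EDEMA = l_edema, L_PET = l_pet, L_PARAMS = l_par)
    total <- lam$lambda_pde * pde$loss + lam$lambda_ic * l_ic +
      lam$lambda_core * l_core + lam$lambda_edema * l_edema +
      lam$lambda_pet * l_pet + lam$lambda_params * l_par
    if (!want_grad)
      return(list(loss = total, terms = terms, params = gp, imaging = im))

    gu <- pde$grad_u
    if (lam$lambda_pde != 1) gu <- gu * lam$lambda_pde
    dim(gu) <- dims
    # initial-condition slice
    gu[, , , 1] <- gu[, , , 1] + lam$lambda_ic * 2 * r0
    # imaging slice
    gT <- array(0, dim = domain$solver_shape)
    dsc <- beta * s_c * (1 - s_c)
    gT[core_idx] <- gT[core_idx] - lam$lambda_core * dsc
    ds1 <- beta * s1 * (1 - s1); ds2 <- beta * s2 * (1 - s2)
    gT[edema_idx] <- gT[edema_idx] + lam$lambda_edema * (-ds1 + ds2)
    if (has_pet)
      gT[omega3_idx] <- gT[omega3_idx] + lam$lambda_pet * 2 * r3
    gu[, , , nt] <- gu[, , , nt] + gT
    level_grads <- mg_compose_adj(gu, field)

    # parameter gradients (model scale)
    g_dw <- lam$lambda_pde * sum(pde$grad_m * (wm + gm / gp$r) * om_int) +
      lam$lambda_params * hb$d_w[2]
    g_r <- lam$lambda_pde * sum(pde$grad_m * (-gm * gp$d_w / gp$r^2) * om_int) +
      lam$lambda_params * hb$r[2]
    g_rho <- lam$lambda_pde * pde$grad_rho + lam$lambda_params * hb$rho[2]
    gfac <- -2 * r0 * G * (2 / c2)
    g_center <- c(lam$lambda_ic * sum(gfac * (Xc - gp$center[1])) +
                    lam$lambda_params * hb$x0[2],
                  lam$lambda_ic * sum(gfac * (Yc - gp$center[2])) +
                    lam$lambda_params * hb$y0[2],
                  lam$lambda_ic * sum(gfac * (Zc - gp$center[3])) +
                    lam$lambda_params * hb$z0[2])
    g_tu <- lam$lambda_core * sum(dsc) - lam$lambda_edema * sum(ds2) +
      lam$lambda_params * hb$theta_up[2]
    g_td <- lam$lambda_edema * sum(ds1) + lam$lambda_params * hb$theta_down[2]
    if (has_pet) {
      g_tpet <- -lam$lambda_pet * 2 * sum(r3 * (y3 - im$theta_bkg)) +
        lam$lambda_params * hb$theta_pet[2]
      g_tbkg <- lam$lambda_pet * 2 * im$theta_pet * sum(r3) +
        lam$lambda_params * hb$theta_bkg[2]
    } else {
      g_tpet <- lam$lambda_params * hb$theta_pet[2]
      g_tbkg <- lam$lambda_params * hb$theta_bkg[2]
    }
    # chain through the unconstrained transforms
    td <- im$theta_down; gapf <- stats::plogis(raw[["q_gap"]])
    d_td_q1 <- td * (1 - td)
    g_raw <- c(
      log_dw = g_dw * gp$d_w,
      log_rho = g_rho * gp$rho,
      log_rm1 = g_r * (gp$r - 1),
      x0 = g_center[1], y0 = g_center[2], z0 = g_center[3],
      q_down = g_td * d_td_q1 + g_tu * d_td_q1 * (1 - gapf),
      q_gap = g_tu * (1 - td) * gapf * (1 - gapf),
      log_pet = g_tpet * im$theta_pet,
      q_bkg = g_tbkg * im$theta_bkg * (1 - im$theta_bkg)
    )
    grad <- numeric(length(theta))
    off <- 0L
    for (i in seq_len(field$L)) {
      grad[(off + 1):(off + level_sizes[i])] <- level_grads[[i]]
      off <- off + level_sizes[i]
    }
    grad[(n_field + 1):length(theta)] <- g_raw
    list(loss = total, grad = grad, terms = terms, params = gp, imaging = im)
  }
}

#' Personalized initial guess
#'
#' Runs a characteristic forward simulation seeded at the tumor-core centroid
#' with diffusivity `D_ch = V_edema / V_core` and unit proliferation, tracking
#' the segmentation-volume-weighted sum of the core and edema Dice scores
#' (fixed mid-range thresholds). The run stops at the first local maximum of
#' that weighted sum (a drop after at least three consecutive rises); the time
#' reached defines the characteristic timescale `T_ch`. The trajectory up to
#' `T_ch` is resampled onto the solver's time grid spanning the normalized
#' interval \[0, 1\], and the rates are rescaled accordingly
#' (`d_w = D_ch * T_ch`, `rho = T_ch`), so the returned field and parameters
#' are mutually consistent under the discretized growth equation.
#'
#' @param domain an [fk_domain()]
#' @param theta_up,theta_down fixed thresholds for Dice tracking
#' @param r_init white/gray diffusivity ratio for the characteristic run
#' @param max_steps forward-step budget
#' @return list with `u4d` (solver-grid space-time field), `params`
#'   ([fk_params()], normalized timescale), `t_ch`, and the tracked `dice`
#'   history
#' @export
fk_initial_guess <- function(domain, theta_up = 0.525, theta_down = 0.25,
                             r_init = 20, max_steps = 300) {
  # the characteristic run happens at native ROI resolution: the reaction
  # front (width ~ sqrt(D/rho)) is marginal even at native voxels, and a
  # trajectory grown directly on the coarse solver grid carries a visibly
  # smaller apparent diffusivity, which would seed the optimizer in the
  # wrong basin
  g <- domain_grid(domain, native = TRUE)
  core <- domain$native$enhancing | domain$native$necrotic
  edema <- domain$native$edema
  if (!any(core)) stop("empty tumor core segmentation: cannot build initial guess")
  if (!any(edema)) stop("empty edema segmentation: cannot build initial guess")
  voxvol <- prod(g$spacing)
  v_core <- sum(core) * voxvol
  v_edema <- sum(edema) * voxvol
  # volume-ratio heuristic, clipped to the plausible diffusivity scale: a
  # near-threshold core (a few voxels) can blow the ratio up to values whose
  # diffusion annihilates the focal seed before it ever reaches the
  # segmentation thresholds
  d_ch <- min(v_edema / v_core, 30)
  ci <- which(core, arr.ind = TRUE)
  center <- g$origin + (colMeans(ci) - 1) * g$spacing
  center <- snap_to_omega(domain, center, native = TRUE)

  D <- build_diffusion_field_raw(g$wm, g$gm, g$omega, d_ch, r_init)
  dt <- stable_dt(D, 1, g$spacing)
  u0 <- gaussian_ic(domain, center, native = TRUE)
  dimv <- as.integer(g$shape); omv <- as.integer(g$omega)
  Dn <- as.numeric(D); spn <- as.numeric(g$spacing)
  # pass 1: track the volume-weighted Dice sum, store nothing
  u <- as.numeric(u0)
  wdice <- numeric(0)
  rises <- 0L; stop_at <- NA_integer_
  for (s in seq_len(max_steps)) {
    u <- cpp_fk_step(u, Dn, omv, dimv, spn, 1, dt)
    dc <- dice_vec(u >= theta_up, core)
    de <- dice_vec(u >= theta_down & u < theta_up, edema)
    wdice[s] <- (v_core * dc + v_edema * de) / (v_core + v_edema)
    if (s >= 2) {
      if (wdice[s] > wdice[s - 1]) rises <- rises + 1L
      else if (wdice[s] < wdice[s - 1] && rises >= 3L) { stop_at <- s - 1L; break }
      else if (wdice[s] < wdice[s - 1]) rises <- 0L
    }
  }
  if (max(wdice) <= 0)
    stop("characteristic forward run never overlapped the segmentations")
  if (is.na(stop_at)) stop_at <- which.max(wdice)
  t_ch <- stop_at * dt
  # pass 2: rerun storing only the steps bracketing the solver time grid
  nt <- domain$n_time
  tau <- seq(0, stop_at, length.out = nt)
  need <- sort(unique(c(floor(tau), pmin(ceiling(tau), stop_at))))
  snaps <- cpp_fk_simulate(as.numeric(u0), Dn, omv, dimv, spn, 1, dt,
                           stop_at, as.integer(need))
  snaps <- array(snaps, dim = c(g$shape, length(need)))
  pos <- match(floor(tau), need)
  u4d <- array(0, dim = c(domain$solver_shape, nt))
  for (j in seq_len(nt)) {
    w <- tau[j] - floor(tau[j])
    a <- snaps[, , , pos[j]]
    if (w > 0) a <- (1 - w) * a + w * snaps[, , , pos[j] + 1L]
    u4d[, , , j] <- resample_to(a, domain$solver_shape)
  }
  params <- fk_params(d_w = d_ch * t_ch, rho = t_ch, r = r_init, center = center)
  list(u4d = u4d, params = params, t_ch = t_ch, dice = wdice[seq_len(stop_at)])
}

# dice between a numeric/logical vector and a logical mask (no dim checks)
dice_vec <- function(a, b) {
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(1)
  2 * sum(a & b) / (sa + sb)
}

snap_to_omega <- function(domain, center, native = FALSE) {
  g <- domain_grid(domain, native)
  if (center_in_omega(g, center)) return(center)
  idx <- which(g$omega, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("omega1 is empty")
  cx <- g$origin[1] + (idx[, 1] - 1) * g$spacing[1]
  cy <- g$origin[2] + (idx[, 2] - 1) * g$spacing[2]
  cz <- g$origin[3] + (idx[, 3] - 1) * g$spacing[3]
  d2 <- (cx - center[1])^2 + (cy - center[2])^2 + (cz - center[3])^2
  i <- which.min(d2)
  c(cx[i], cy[i], cz[i])
}

#' Joint inference of the density field and model parameters
#'
#' Minimizes the weighted discrete loss over the multigrid field levels and
#' the (transformed) growth and imaging parameters with Adam, optionally
#' refined by L-BFGS. Deterministic given the configuration.
#'
#' @param domain an [fk_domain()] carrying the observed data
#' @param init optional initial guess from [fk_initial_guess()]; computed
#'   internally when `NULL`
#' @param config an [fk_optim_config()]
#' @param imaging_init starting imaging parameters (default mid-range)
#' @return object of class `fk_fit` with the composed best field `u4d`
#'   (values clipped to \[0, 1\] and zeroed outside omega1 in `u4d_clipped`),
#'   inferred `params` and `imaging`, iteration `history`, and the final
#'   loss `report`
#' @export
fk_optimize <- function(domain, init = NULL, config = fk_optim_config(),
                        imaging_init = fk_imaging(theta_down = 0.25,
                                                  theta_up = 0.525,
                                                  theta_pet = 1,
                                                  theta_bkg = 0.25)) {
  if (is.null(init)) init <- fk_initial_guess(domain)
  bounds <- config$bounds
  if (is.null(bounds)) bounds <- default_param_bounds()
  crd <- solver_coords(domain)
  if (is.null(bounds$x0)) bounds$x0 <- range(crd$x)
  if (is.null(bounds$y0)) bounds$y0 <- range(crd$y)
  if (is.null(bounds$z0)) bounds$z0 <- range(crd$z)

  dims <- c(domain$solver_shape, domain$n_time)
  field <- mg_init(dims, L = config$levels, init = init$u4d)
  objective <- make_objective(domain, config$weights, bounds, field)
  theta0 <- c(unlist(lapply(field$levels, as.numeric), use.names = FALSE),
              fk_untransform_params(init$params, imaging_init))
  n <- length(theta0)

  # Adam with cosine-decayed step size; the field block moves with a smaller
  # base step than the scalar parameters
  theta <- theta0
  n_field <- n - 10L
  lr_scale <- c(rep(config$field_learning_rate, n_field),
                rep(config$learning_rate, 10L))
  m <- numeric(n); v <- numeric(n)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  best_loss <- Inf; best_theta <- theta0
  hist_it <- integer(0); hist_total <- numeric(0); hist_terms <- list()
  plateau_ref <- Inf
  for (it in seq_len(config$max_iters)) {
    res <- objective(theta)
    if (!is.finite(res$loss)) {
      warning("non-finite loss at iteration ", it, "; returning best state")
      break
    }
    if (res$loss < best_loss) { best_loss <- res$loss; best_theta <- theta }
    if (it %% config$log_every == 1L || it == config$max_iters) {
      hist_it <- c(hist_it, it); hist_total <- c(hist_total, res$loss)
      hist_terms[[length(hist_terms) + 1L]] <- res$terms
    }
    decay <- 0.5 * (1 + cos(pi * (it - 1) / config$max_iters))
    m <- b1 * m + (1 - b1) * res$grad
    v <- b2 * v + (1 - b2) * res$grad^2
    mhat <- m / (1 - b1^it); vhat <- v / (1 - b2^it)
    theta <- theta - (decay * lr_scale) * mhat / (sqrt(vhat) + eps)
    if (it %% config$plateau_window == 0L) {
      if (is.finite(plateau_ref) &&
          (plateau_ref - best_loss) <= config$plateau_tol * abs(plateau_ref)) break
      plateau_ref <- best_loss
    }
  }
  if (config$polish_iters > 0) {
    env <- new.env()
    fn <- function(p) {
      r <- objective(p)
      env$last <- list(p = p, r = r)
      r$loss
    }
    gr <- function(p) {
      if (!is.null(env$last) && identical(env$last$p, p)) return(env$last$r$grad)
      objective(p)$grad
    }
    opt <- stats::optim(best_theta, fn, gr, method = "L-BFGS-B",
                        control = list(maxit = config$polish_iters))
    if (is.finite(opt$value) && opt$value < best_loss) {
      best_loss <- opt$value
      best_theta <- opt$par
    }
  }
  res <- objective(best_theta, want_grad = FALSE)
  level_sizes <- vapply(field$shapes, prod, 0)
  off <- 0L
  for (i in seq_len(field$L)) {
    field$levels[[i]] <- array(best_theta[(off + 1):(off + level_sizes[i])],
                               dim = field$shapes[[i]])
    off <- off + level_sizes[i]
  }
  u4d <- mg_compose(field)
  u_clip <- pmin(pmax(u4d, 0), 1)
  u_clip <- u_clip * array(domain$omega1, dim = dims)
  history <- data.frame(iteration = hist_it, total = hist_total)
  tm <- do.call(rbind, hist_terms)
  if (!is.null(tm)) history <- cbind(history, as.data.frame(tm))
  structure(list(u4d = u4d, u4d_clipped = u_clip, field = field,
                 params = res$params, imaging = res$imaging,
                 best_loss = best_loss, history = history,
                 terms = res$terms, init = init, config = config,
                 domain_shape = dims),
            class = "fk_fit")
}

#' @export
print.fk_fit <- function(x, ...) {
  cat("<fk_fit> total loss", format(x$best_loss, digits = 6), "after",
      if (nrow(x$history)) max(x$history$iteration) else 0, "logged iterations\n")
  print(x$params)
  cat(sprintf("  imaging: theta_down=%.3f theta_up=%.3f theta_pet=%.3f theta_bkg=%.3f\n",
              x$imaging$theta_down, x$imaging$theta_up,
              x$imaging$theta_pet, x$imaging$theta_bkg))
  invisible(x)
}

#' Forward replay with inferred parameters
#'
#' Runs the forward solver with the inferred growth parameters over the
#' normalized time interval, by default at the native ROI resolution (the
#' strict-PDE companion solution to the relaxed field estimate).
#'
#' @param domain an [fk_domain()]
#' @param params inferred [fk_params()] (normalized-timescale rates)
#' @param native use the native ROI resolution (default) or the solver grid
#' @param n_store stored time points
#' @return an `fk_trajectory`
#' @export
fk_replay <- function(domain, params, native = TRUE, n_store = 33) {
  g <- domain_grid(domain, native)
  ctr <- params$center
  if (!center_in_omega(g, ctr)) ctr <- snap_to_omega(domain, ctr, native)
  p <- fk_params(params$d_w, params$rho, params$r, ctr)
  fk_simulate(domain, p, t_final = 1, n_store = n_store, native = native)
}
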