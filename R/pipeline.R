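default_config <- function() {
  list(
    solver_shape = c(48, 48, 48), n_time = 192,
    roi_margin_mm = 30, tissue_threshold = 0.1,
    max_iters = 10000, learning_rate = 1e-2, polish_iters = 0,
    log_every = 50, levels = NA,
    lambda_pde = 1, lambda_ic = 1e-2, lambda_core = 1, lambda_edema = 1,
    lambda_pet = 1, lambda_params = 1e-2,
    ctv_margin_mm = 15, seed = 0
  )
}

#' Read and validate a run configuration
#'
#' Flat key-value YAML; unknown keys are an error so typos fail loudly.
#' `overrides` (e.g. parsed command-line flags) take precedence.
#'
#' @param path YAML file or `NULL` for defaults
#' @param overrides named list overriding file values
#' @return named list of resolved settings
#' @export
read_config <- function(path = NULL, overrides = list()) {
  cfg <- default_config()
  user <- if (!is.null(path)) yaml::read_yaml(path) else list()
  user <- modifyList(user, overrides)
  bad <- setdiff(names(user), names(cfg))
  if (length(bad))
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  modifyList(cfg, user)
}

config_to_optim <- function(cfg) {
  fk_optim_config(
    max_iters = cfg$max_iters, learning_rate = cfg$learning_rate,
    polish_iters = cfg$polish_iters, log_every = cfg$log_every,
    levels = if (length(cfg$levels) == 1 && is.na(cfg$levels)) NULL else cfg$levels,
    seed = cfg$seed,
    weights = fk_weights(cfg$lambda_pde, cfg$lambda_ic, cfg$lambda_core,
                         cfg$lambda_edema, cfg$lambda_pet, cfg$lambda_params))
}

#' End-to-end inference for one case
#'
#' Loads (or accepts) a patient case, builds the tumor-focused domain, runs
#' the initial guess, the joint optimization, and the strict-PDE forward
#' replay, and derives a volume-matched radiotherapy plan against the
#' Standard Plan CTV. When `out_dir` is given, writes the density maps
#' (NIfTI), parameters and loss history (JSON), plan masks, and the resolved
#' configuration.
#'
#' @param case an [fk_case()], [generate_patient()] result, or a directory
#'   for [load_case()]
#' @param config resolved configuration list from [read_config()], or a path
#'   to a YAML file
#' @param out_dir optional artifact directory
#' @return list with `fit` ([fk_optimize()] result), `domain`, `replay`
#'   final-time density, `plans` (standard CTV and volume-matched model plan),
#'   and `config`
#' @export
run_infer <- function(case, config = read_config(), out_dir = NULL) {
  if (is.character(config)) config <- read_config(config)
  patient <- NULL
  if (inherits(case, "fk_synth_patient")) { patient <- case; case <- case$case }
  if (is.character(case)) case <- load_case(case)
  stopifnot(inherits(case, "fk_case"))
  if (is.null(case$pet) && config$lambda_pet > 0)
    warning("no PET volume present; the PET data term is disabled for this run")
  domain <- build_domain(case, margin_mm = config$roi_margin_mm,
                         solver_shape = config$solver_shape,
                         n_time = config$n_time,
                         tissue_threshold = config$tissue_threshold)
  init <- fk_initial_guess(domain)
  fit <- fk_optimize(domain, init = init, config = config_to_optim(config))
  replay <- fk_replay(domain, fit$params, native = TRUE, n_store = 9)
  uT_native <- replay$u[, , , dim(replay$u)[4]]
  core_solver <- domain$seg_enhancing | domain$seg_necrotic
  ctv <- standard_plan_ctv(core_solver, domain$brain, domain$csf,
                           margin_mm = config$ctv_margin_mm,
                           spacing = domain$spacing)
  uT <- fit$u4d_clipped[, , , domain$n_time]
  plan <- volume_matched_plan(uT, ctv$volume_voxels, domain$brain,
                              spacing = domain$spacing)
  out <- list(fit = fit, domain = domain, init = init,
              replay_final = uT_native,
              plans = list(standard = ctv, model = plan),
              config = config, patient = patient)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    sp <- domain$spacing
    write_volume(uT, file.path(out_dir, "density_final.nii.gz"), sp)
    write_volume(uT_native, file.path(out_dir, "density_final_pde_replay.nii.gz"),
                 domain$spacing_native)
    write_volume(ctv$mask, file.path(out_dir, "plan_standard_ctv.nii.gz"), sp,
                 mask = TRUE)
    write_volume(plan$mask, file.path(out_dir, "plan_model.nii.gz"), sp,
                 mask = TRUE)
    jsonlite::write_json(
      list(d_w = fit$params$d_w, rho = fit$params$rho, r = fit$params$r,
           center = fit$params$center,
           theta_down = fit$imaging$theta_down, theta_up = fit$imaging$theta_up,
           theta_pet = fit$imaging$theta_pet, theta_bkg = fit$imaging$theta_bkg,
           best_loss = fit$best_loss, t_ch = init$t_ch),
      file.path(out_dir, "parameters.json"), auto_unbox = TRUE, digits = NA)
    con <- file(file.path(out_dir, "loss_history.jsonl"), "w")
    for (i in seq_len(nrow(fit$history)))
      writeLines(jsonlite::toJSON(as.list(fit$history[i, ]), auto_unbox = TRUE,
                                  digits = NA), con)
    close(con)
    yaml::write_yaml(config, file.path(out_dir, "config_resolved.yaml"))
  }
  out
}

# solver-grid resampling of a native (full-volume) field into the domain ROI
resample_truth <- function(domain, truth_u) {
  crop <- truth_u[domain$roi_lo[1]:domain$roi_hi[1],
                  domain$roi_lo[2]:domain$roi_hi[2],
                  domain$roi_lo[3]:domain$roi_hi[3], drop = FALSE]
  resample_to(crop, domain$solver_shape, nearest = FALSE)
}

#' Synthetic benchmark over a cohort and a PDE-weight grid
#'
#' Generates `n_patients` synthetic patients, runs the full inference for
#' each value of `lambda_pde_grid`, and scores every run against the known
#' ground truth: Dice at the 10 percent density level, RMSE of the density
#' over the low-concentration region (diffusible tissue outside the visible
#' segmentations), and relative errors of the timescale-invariant parameter
#' products. The default weight (`lambda_pde = 1`) sits between a
#' physics-dominated and a data-dominated extreme.
#'
#' @param n_patients cohort size
#' @param seeds patient seeds (default `seq_len(n_patients)`)
#' @param lambda_pde_grid PDE-weight values to sweep
#' @param multifocal generate multifocal patients
#' @param config resolved configuration (desk-scale settings recommended)
#' @param phantom tissue phantom (default [fk_phantom()])
#' @param out_dir optional directory for the per-run CSV
#' @return data.frame with one row per (patient, lambda) run
#' @export
run_benchmark <- function(n_patients = 10, seeds = NULL,
                          lambda_pde_grid = c(0.001, 1, 1000),
                          multifocal = FALSE,
                          config = read_config(NULL,
                                               list(solver_shape = c(32, 32, 32),
                                                    n_time = 64,
                                                    max_iters = 2000)),
                          phantom = fk_phantom(), out_dir = NULL) {
  if (is.null(seeds)) seeds <- seq_len(n_patients)
  rows <- list()
  for (s in seeds) {
    patient <- generate_patient(phantom, seed = s, multifocal = multifocal)
    domain <- build_domain(patient$case, margin_mm = config$roi_margin_mm,
                           solver_shape = config$solver_shape,
                           n_time = config$n_time,
                           tissue_threshold = config$tissue_threshold)
    init <- fk_initial_guess(domain)
    truth_s <- resample_truth(domain, patient$truth_u)
    seg_s <- domain$seg_edema | domain$seg_enhancing | domain$seg_necrotic
    low_region <- domain$omega1 & !seg_s
    uT_init <- init$u4d[, , , domain$n_time]
    for (lam in lambda_pde_grid) {
      cfgl <- config
      cfgl$lambda_pde <- lam
      fit <- fk_optimize(domain, init = init, config = config_to_optim(cfgl))
      uT <- fit$u4d_clipped[, , , domain$n_time]
      tp <- patient$truth_params
      rows[[length(rows) + 1L]] <- data.frame(
        seed = s, multifocal = multifocal, lambda_pde = lam,
        dice10 = dice(uT >= 0.1, truth_s >= 0.1),
        dice10_init = dice(uT_init >= 0.1, truth_s >= 0.1),
        rmse_low = sqrt(mean((uT - truth_s)[low_region]^2)),
        rel_err_dwT = abs(fit$params$d_w - tp$d_w * tp$t_sim) / (tp$d_w * tp$t_sim),
        rel_err_rhoT = abs(fit$params$rho - tp$rho * tp$t_sim) / (tp$rho * tp$t_sim),
        rel_err_r = abs(fit$params$r - tp$r) / tp$r,
        best_loss = fit$best_loss)
    }
  }
  res <- do.call(rbind, rows)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(res, file.path(out_dir, "benchmark.csv"), row.names = FALSE)
    yaml::write_yaml(c(config, list(seeds = seeds,
                                    lambda_pde_grid = lambda_pde_grid)),
                     file.path(out_dir, "config_resolved.yaml"))
  }
  res
}
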