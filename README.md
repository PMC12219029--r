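# fkodil

Full-brain tumor-cell-density inference from a single imaging time point, for
computational oncology and radiotherapy-planning research.

Gliomas infiltrate well beyond the tumor margins visible on MRI, but clinical
radiotherapy targets are still drawn by dilating the visible tumor core by a
uniform 15 mm margin. `fkodil` estimates the continuous tumor-cell density
`u(x) ∈ [0,1]` — including the occult infiltration front — from one
pre-treatment snapshot: tissue fraction maps, tumor segmentation labels
(edema, enhancing core, necrotic core) and, optionally, an amino-acid PET
volume.

## Method

Growth is modeled by the Fisher–Kolmogorov reaction–diffusion equation

    ∂u/∂t = ∇·(D ∇u) + ρ u (1 − u),
    D(x)  = wm(x)·D_w + gm(x)·D_w/R,

with no-flux boundaries at the edge of diffusible tissue and a focal Gaussian
initial condition. Rather than solving inverse problems by repeated forward
simulation, the space–time density is itself optimized on a 4D
multiresolution grid: the Crank–Nicolson residual of the equation enters the
objective as a soft penalty (`L_PDE`), alongside sigmoid segmentation-matching
terms, a PET-matching term, a focal-seed term and a parameter-plausibility
regularizer:

    L = λ_PDE·L_PDE + λ_IC·L_IC + λ_CORE·L_CORE + λ_EDEMA·L_EDEMA
      + λ_PET·L_PET + λ_PARAMS·L_PARAMS,     λ_PDE = 1.

Minimization is by Adam over the field levels, the growth parameters
(D_w, ρ, R, seed center) and the imaging parameters (density thresholds
θ_down < θ_up, PET scale/offset), with hand-derived adjoint gradients
(finite-difference-verified). With single-time-point data the rates are
identifiable only up to a timescale, so results are reported as the products
`D_w·T`, `ρ·T` and the ratio `R`.

The package also ships the full synthetic-patient generator used to validate
the estimator (threshold-derived segmentations, spatially correlated
Gaussian-Markov PET noise, factor-4 partial-volume degradation on a
procedural 240 mm brain phantom) and the radiotherapy evaluation toolbox
(Dice, PET correlation, exact-Euclidean 15 mm CTV construction,
volume-matched density plans, recurrence coverage).

## Worked example

Generate a synthetic patient, infer the density field, and build a
volume-matched radiotherapy plan:

```r
library(fkodil)

phantom <- fk_phantom()                      # 240x240x156 mm procedural atlas
patient <- generate_patient(phantom, seed = 3)
patient
#> <fk_synth_patient> seed 3 (single focal)
#>   truth: D_w=0.063 rho=0.168 R=17.7 foci=1
#> <fk_case> grid 120x120x78 spacing 2x2x2 mm
#>   segmentation voxels: edema 943 | enhancing 735 | necrotic 5995 | PET present

domain <- build_domain(patient$case, solver_shape = c(32, 32, 32), n_time = 64)
fit    <- fk_optimize(domain, config = fk_optim_config(max_iters = 300))
fit
#> <fk_fit> total loss 130.015 after 300 logged iterations
#> <fk_params> D_w=1.808 rho=14.13 R=29.58 center=(67.02, 71.78, 79.38) mm
#>   imaging: theta_down=0.109 theta_up=0.304 theta_pet=1.028 theta_bkg=0.128

truth <- fkodil:::resample_truth(domain, patient$truth_u)
uT <- fit$u4d_clipped[, , , domain$n_time]
dice(uT >= 0.1, truth >= 0.1)                # occult-infiltration overlap
#> [1] 0.9473043
```

`fit$params` are the normalized-timescale rates (here `ρ·T = 14.1` against
the generating value `0.168·100 = 16.8`; the density field is recovered much
more reliably than `D_w·T`, whose weak identifiability the vignette
discusses). `fk_replay(domain, fit$params)` produces the strict-PDE
companion solution at native ROI resolution. The final density drives
planning:

```r
core <- domain$seg_enhancing | domain$seg_necrotic
ctv  <- standard_plan_ctv(core, domain$brain, domain$csf,
                          margin_mm = 15, spacing = domain$spacing)
plan <- volume_matched_plan(uT, ctv$volume_voxels, domain$brain,
                            spacing = domain$spacing)
c(standard = recurrence_coverage(ctv,  truth >= 0.1),
  model    = recurrence_coverage(plan, truth >= 0.1))
#> standard    model
#> 97.64919 97.64919
```

Both plans occupy exactly the same volume. For this compact single-focal
tumor the uniform 15 mm margin already encloses essentially the whole
infiltration region and the density-ranked plan ties it; the density plan
earns its keep on complex shapes (multifocal growth, anatomical barriers)
where a uniform margin spends volume in the wrong places — the benchmark
harness (`run_benchmark(multifocal = TRUE, ...)`) quantifies this via
low-concentration RMSE.

See `vignettes/tumor-density-inference.Rmd` for the model, the loss terms,
the synthetic-data pipeline and all numerical choices.

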