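# spectdose

Quantitative SPECT calibration, partial-volume correction, voxel dosimetry
and uncertainty budgeting for ¹³¹I radiopharmaceutical therapy — with a
synthetic digital-phantom generator so the whole chain runs and validates
without any scanner data.

## Who this is for

Medical physicists and imaging scientists who commission or study
image-based dosimetry pipelines for radionuclide therapy. The package
reproduces, in silico, the three phantom studies such a commissioning
rests on — a uniform calibration cylinder, a hot-sphere Jaszczak phantom,
and an anthropomorphic head-and-neck phantom with a ~22.8-ml tumor — and
implements every quantitative step between a reconstructed count-rate
image and a mean tumor dose with its uncertainty.

## The model in brief

* **Calibration**: `Q = R̄ / (V · C · e^{−λΔt})` converts voxel count
  rate to activity, decay-correcting the syringe assay to scan time.
* **Recovery coefficients**: `RC = measured / true` concentration per
  hot-sphere volume, fitted with the plateau curve
  `RC(v) = R_plateau − R_plateau / (1 + (v/β)^γ)`; partial-volume
  correction divides a VOI mean by the RC at its volume.
* **Dosimetry**: single-timepoint exponential decay gives cumulated
  activity `Ã = A/λ`; dose engines are local energy deposition
  (`D = Ã·E·k/ρ`) and an analytic photon attenuation kernel
  `μ e^{−μr}/(4πr²)`, both validated by energy conservation.
* **Uncertainty**: per-VOI fractional budget — volume
  `u(v)/v = 3a/(√6·D)`, calibration, RC via the bordered fit covariance
  `gᵀV_c g`, mean counts `(φ/2RC)·u(v)/v` with the Gaussian count
  fraction φ, combined in quadrature minus the shared-volume covariance.

The methods vignette (`vignettes/spectdose-methods.Rmd`) derives and
motivates each piece.

## Worked example

```r
library(spectdose)

grid  <- grid_spec(64, 4.42)            # 64³ voxels, 4.42 mm isotropic
model <- imaging_model("on", noise = "none")  # resolution recovery on

# hot-sphere study: simulate, measure recovery, fit the curve
pts <- simulate_rc_points(phantom_jaszczak(), model, grid)
fit <- fit_rc_curve(pts)
fit
#> <rc_fit> RC(v) = 1.5 - 1.5 / (1 + (v/124.4)^0.4565), fitted on 6 points (0.5-16 ml)
rc_eval_and_derivative(fit, 22.8)
#>   volume_ml    RC  dRC_dv extrapolated
#> 1      22.8 0.473 0.00649 TRUE

# dosimetry validation scenarios on the anthropomorphic phantom
apts <- simulate_rc_points(phantom_anthro(), model, grid)
run_validation_scenarios(
  phantom_anthro(), model,
  rc_sources = list(jaszczak = fit, anthro = apts$RC[apts$name == "tumor"]),
  grid = grid)
#>   scenario     cdr_mode rc_used mean_tumor_dose_Gy percent_diff_vs_gt
#> 1 ground_truth on        NA                   23.8           0
#> 2 no_pvc       on        NA                   11.3         -52.4
#> 3 jaszczak_pvc on         0.473               23.9           0.583
#> 4 anthro_pvc   on         0.476               23.8           0.0000
```

Reading: without partial-volume correction the simulated SPECT
underestimates the mean tumor dose by 52%; dividing the tumor VOI by
either RC source (the extrapolated sphere fit, 0.473, or the phantom's
own measured RC, 0.476) closes the gap to under 1%. The uncertainty
budget for the 16-ml sphere and the tumor volume:

```r
budget_table(tibble::tibble(name = c("sphere_16ml", "tumor"),
                            volume_ml = c(16, 22.8)), fit)
#>   name        volume_ml  D_mm    RC   phi u_v_frac u_q_frac u_RC_frac u_C_frac
#> 1 sphere_16ml      16    31.3 0.422 0.847    0.173     0.05    0.0603    0.174
#> 2 tumor            22.8  35.2 0.473 0.864    0.154     0.05    0.0588    0.140
```

`autoplot(fit)`, `plot_uncertainty_budget()` and `plot_scenarios()` turn
these tables into the corresponding figures, and
`run_pipeline(run_config("out/"))` writes the full CSV/JSON report
bundle. A thin CLI lives at `inst/cli/rptq`.

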