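---
title: "Quantitative SPECT dosimetry with digital phantoms: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative SPECT dosimetry with digital phantoms: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 4)
library(spectdose)
```

## The problem

Radiopharmaceutical therapy with ^131^I delivers absorbed dose through
short-range beta particles while the 364-keV gamma emission makes the
activity distribution imageable with SPECT/CT. Converting a reconstructed
SPECT image into absorbed dose requires a chain of calibrations whose every
link carries error: a count-rate-to-activity calibration factor, a
partial-volume correction for structures comparable in size to the
system resolution, a time-integration model for the activity, a dose
engine, and an uncertainty budget that tells the physician how much to
trust the number. `spectdose` implements this chain end to end, together
with a synthetic digital-phantom generator that stands in for the physical
phantoms (uniform calibration cylinder, hot-sphere Jaszczak phantom,
anthropomorphic head-and-neck phantom) on which such chains are
commissioned, so every stage can be exercised and validated without
scanner data.

## Quantification model

**Calibration factor.** For a voxel in a uniform volume of interest,

$$Q = \frac{\bar R}{V \, C \, e^{-\lambda \Delta t}} \quad
  \left[\tfrac{\mathrm{cps}}{\mathrm{MBq}}\right],$$

where $\bar R$ is the mean voxel count rate, $V$ the voxel volume, $C$ the
syringe-assayed concentration, and the exponential decay-corrects $C$ from
assay time to scan time. The decay term divides because physical decay
lowers the concentration actually imaged; with $\Delta t$ of one
half-life the same counts imply a doubled sensitivity
(`calibration_factor(2, 0.1, 0.2, delta_t = half_life)` returns 200, not
50).

**Recovery coefficients.** Partial-volume spill-out makes small hot
structures read low. The measured-over-true concentration ratio
$RC = \bar A_\mathrm{meas} / A_\mathrm{true}$ is tabulated per sphere
volume and fitted with the three-parameter plateau curve

$$RC_\mathrm{fit}(v) = R_\mathrm{plateau} -
  \frac{R_\mathrm{plateau}}{1 + (v/\beta)^{\gamma}},$$

which rises from zero through $R_\mathrm{plateau}/2$ at $v = \beta$ and
saturates at $R_\mathrm{plateau}$. `fit_rc_curve()` uses
Levenberg–Marquardt least squares (`minpack.lm`), initialized at
$R_\mathrm{plateau,0} = \max RC$, $\beta_0 = \mathrm{median}(v)$,
$\gamma_0 = 1$, with box bounds $R_\mathrm{plateau} \in (0, 1.5]$,
$\beta \in (0, 10^3]$ ml, $\gamma \in (0, 10]$. The fit is unweighted by
default, the minimal reading of a least-squares RC fit; a `weights`
argument accepts variance-matched weights (for multiplicative noise,
$1/RC^2$), which our replicate experiments show are needed for nominal
confidence-interval coverage. Evaluation beyond the fitted volume range is
permitted but flagged `extrapolated`. The partial-volume correction itself
is a single VOI-level division by $RC$ (`apply_pvc()`), not a voxelwise
deconvolution.

## The synthetic phantoms

The generator reproduces three study geometries as declarative
`phantom_spec` documents (packaged as YAML under `inst/extdata/`):

* a 20-cm diameter, 5.64-L uniform cylinder at 105 kBq/ml, for
  calibration;
* a Jaszczak-style cylinder with 0.5/1/2/4/8/16-ml hot spheres (insert
  diameters 9.9–31.3 mm) at a 9.9:1 concentration ratio over a
  25.9 kBq/ml background;
* an anthropomorphic head: a water-filled ellipsoid with a dense
  bone-resin skull shell, fillable glands (parotid, lacrimal, thyroid,
  with the measured chamber volumes), and a 22.8-ml spherical tumor at
  259 kBq/ml over a 26.2 kBq/ml background. Solid resin compartments are
  impermeable and carry no activity.

Rasterization uses supersampled antialiasing: each voxel is split into
$3^3$ subvoxels (configurable) and each subvoxel contributes a fraction
that ramps linearly with its signed distance to the compartment boundary,
treating the boundary as locally planar. This keeps occupancy-integrated
volumes within a fraction of a percent of the analytic volumes down to
half-millilitre spheres. Binary VOI masks threshold occupancy at 0.5, and
ground-truth maps assign concentrations binarily by mask so that mask
means reproduce nominal concentrations exactly — the property a
ground-truth scenario needs.

**Imaging model.** Reconstruction is emulated by an effective-resolution
isotropic Gaussian blur of the scaled activity map (the default backend),
with OSEM emulation (`emulate_osem()`, a slice-wise parallel-beam rotation
projector over 360°/120 views feeding an ordered-subset EM loop) as an
optional alternative that can exhibit the edge overshoot of
resolution-recovery reconstruction. Defaults: effective FWHM 22 mm with
collimator-detector-response modeling ("resolution recovery") on,
26 mm off; sensitivities 104.2 and 21.4 cps/MBq respectively. With these
defaults the emergent 16-ml sphere recovery is ≈0.43 (cdr on), verified in
the tests against the closed-form Gaussian-blurred-ball profile. Poisson
noise is applied to expected counts accumulated over a configurable
`count_time` (default 60 s, a typical seconds-per-frame); each noisy image
draws from a substream derived from the study seed plus a stream label, so
`noise = "none"` is bit-reproducible and fixed seeds give bit-identical
noisy images. Scatter and attenuation are not explicitly simulated — the
emulated images play the role of scatter- and attenuation-corrected
reconstructions — but a uniform `scatter_background_fraction` pedestal is
available for robustness experiments.

**CT companions.** Each phantom yields an HU map and a density map from
the material registry (water −4.05 HU / 1.00 g/cc; soft printing resin
292.48 HU / 1.21 g/cc; bone resin 876.36 HU / 1.61 g/cc).
`hu_to_density()` applies a piecewise-linear calibration (default nodes
form a generic external-beam-planning curve, which slightly overpredicts
the resin densities, as clinical curves do for printed materials);
`hu_to_mu()` applies a bilinear HU-to-attenuation map at 364 keV fitted
through the water point to the two resin measurements (residuals < 0.1%).

## Dosimetry

With a single imaging timepoint and no biological clearance, activity
decays physically and the cumulated activity is $\tilde A = A/\lambda$ per
voxel (I-131 half-life 8.0252 d). Two dose engines are provided:

* **Local deposition** (`dose_local()`): $D = \tilde A \, E \, k / \rho$
  with $k = 1.602\times10^{-13}$ J/MeV; `beta_only` deposits the mean beta
  energy (0.1916 MeV/decay), `all_energy` additionally deposits the photon
  energy (0.382 MeV/decay) locally — exact in the infinite-uniform-medium
  limit and exactly energy-conserving on any grid.
* **Photon kernel** (`dose_kernel()`): beta local plus the analytic
  attenuation point kernel $\mu e^{-\mu r} / (4 \pi r^2)$, FFT-convolved.
  The kernel is truncated at 30 cm and renormalized to unit integral so
  the uniform-medium limit reproduces the all-energy local dose; the
  pre-normalization discrete deficit is reported, with a warning above 5%
  (at 364 keV in water the 30-cm truncation plus center-sampling drops
  ~22%, so the warning fires on default settings — the renormalization
  carries the physics). The kernel mean free path at 364 keV is ~11 cm,
  so genuine infinite-medium behaviour is only observable in tests with
  artificially large $\mu$; the conservation tests use $\mu = 1$–3 cm⁻¹
  for exactly that reason.

The choice of these engines over Monte Carlo transport is deliberate: the
package validates by conservation and closure properties, not by
reproducing any transport-code dose value.

**Validation scenarios.** `run_validation_scenarios()` mirrors a
four-scenario tumor-dose validation: ground truth from the known activity
map; SPECT-based dosimetry without PVC; with a Jaszczak-fitted RC
extrapolated to the tumor volume; and with an RC measured on the
anthropomorphic phantom itself. Percent differences use the ground-truth
denominator. On the packaged phantoms at default settings the uncorrected
scenario underestimates the mean tumor dose by ~50% while either matched
correction lands within a few percent — the ordering the tests assert over
20 noise seeds.

## Uncertainty budget

Per VOI, five dimensionless fractions are propagated:

* volume: $u(v)/v = 3a / (\sqrt6 \, D)$ with voxel size $a$ and equivalent
  sphere diameter $D = 10\,(6v/\pi)^{1/3}$ mm — 17.3% for the 31.3-mm
  sphere at $a = 4.42$ mm, 54.7% at 9.9 mm;
* calibration: quadrature of the calibrator assay error (default 5%) and
  the repeat-scan count-rate error;
* recovery coefficient: $u^2(RC) = g_c^\top V_c \, g_c$, where $g_c$ is
  the gradient of the fitted curve in
  $(R_\mathrm{plateau}, \beta, \gamma, v)$ and $V_c$ the fit covariance
  bordered by the volume variance;
* mean counts: $u(C)/C = \frac{\varphi}{2\,RC} \cdot \frac{u(v)}{v}$, with
  the Gaussian count fraction
  $\varphi = \mathrm{erf}\!\left(\frac{r}{\sqrt2\sigma}\right) -
  \frac{\sqrt2\sigma}{r\sqrt\pi}\left(1 - e^{-r^2/2\sigma^2}\right)$
  at the equivalent radius $r = D/2$ and PSF width $\sigma$ (default 3 mm,
  configurable);
* combined cumulated activity: quadrature of the calibration, RC and
  counts terms minus the covariance of counts and RC on the shared volume
  error, $2 \cdot \frac{\varphi}{2RC} \cdot \frac{v\,\partial RC/\partial
  v}{RC}\cdot\left(\frac{u(v)}{v}\right)^2$, clamped with an error if it
  would over-subtract.

The algebraic forms of the counts, $\varphi$ and covariance expressions
were chosen among the readings consistent with published endpoint values
(the 17.3%/54.7% volume endpoints and the 14.3% counts endpoint with
$RC = 0.514$) and with the required limits ($\varphi \to 0$ as
$r \to 0$, $\varphi \to 1$ as $r/\sigma \to \infty$, monotone between).
Numerically, $\varphi$ is *not* the in-sphere count fraction of a blurred
uniform ball (that integral evaluates to 0.773 at $r = 15.65$, $\sigma =
3$, against $\varphi = 0.847$); it is treated as the guideline-defined
coupling factor it is, and only its limits, monotonicity and endpoint
reproductions are asserted. Reconciliation against the underlying
guideline document remains a known open point.

## Numerical and design choices

* Grids: SPECT default $128^3$ at 4.42 mm isotropic; CT/dose default
  256×256×128 at 0.977×0.977×2.0 mm. Coordinates place the image origin
  at the corner of the first voxel, centers at $(i - \tfrac12)\Delta$;
  all images and masks of a study share one grid. Unit tests and the
  acceptance checks run the simulation stages on $48^3$–$64^3$ grids
  (283 mm extent), which hold every packaged phantom with margin;
  problem sizes are stated in each test.
* Resampling: separable interpolation with `nearest` (label-exact),
  `linear`, and order-3 Lanczos (the operational choice for SPECT-to-CT
  upsampling; the kernel order is our choice, windowed-sinc order 3 being
  the common default). Against a direct fine-grid computation of the same
  blurred sphere, Lanczos agrees to <1% on the 16-ml VOI mean where
  trilinear is ~3% low.
* Masks follow the CT-drawn contour convention: drawn on (or resampled
  to) the finer grid before VOI statistics when grids differ.
* The RC-fit upper bound $R_\mathrm{plateau} \le 1.5$ tolerates
  noise-driven overshoot above 1; with the default 22-mm effective FWHM
  the packaged sphere set is still far from plateau at 16 ml, so the
  plateau parameter is weakly identified and can rail at its bound — the
  uncertainty propagation carries this through the covariance rather than
  hiding it.
* Percent-difference conventions: volume comparisons use
  (contour − measured)/measured; dose scenarios use the ground-truth
  denominator. Both are fixed by the reporting structure they mirror and
  recorded in the output tables.

## What passing tests do and do not show

The generator emulates system blur, Poisson counting noise, calibration
scaling and partial-volume loss — the dominant effects the quantification
chain corrects. It does not emulate scatter, attenuation artifacts,
collimator septal penetration, reconstruction convergence
nonuniformity, registration error, or respiratory/positioning variability.
Closure of the pipeline on these phantoms therefore validates the
*machinery* (calibration recovery, RC fitting and application, dose
integration, uncertainty propagation), not the accuracy of any specific
clinical reconstruction; emergent quantities that depend on unreleased
scan data (fitted RC values, absolute dose levels, fitted-covariance
uncertainty ranges) are deliberately not asserted as equalities.

## A worked example

```{r example, eval = FALSE}
library(spectdose)

grid <- grid_spec(64, 4.42)
model <- imaging_model("on", noise = "none")

# recovery curve from the hot-sphere phantom
pts <- simulate_rc_points(phantom_jaszczak(), model, grid)
fit <- fit_rc_curve(pts)
autoplot(fit)

# uncertainty budget over the sphere set plus the tumor volume
vois <- dplyr::bind_rows(pts[, c("name", "volume_ml")],
                         tibble::tibble(name = "tumor", volume_ml = 22.8))
budget <- budget_table(vois, fit)
plot_uncertainty_budget(budget)

# dosimetry validation scenarios
apts <- simulate_rc_points(phantom_anthro(), model, grid)
scen <- run_validation_scenarios(
  phantom_anthro(), model,
  rc_sources = list(jaszczak = fit,
                    anthro = apts$RC[apts$name == "tumor"]),
  grid = grid)
plot_scenarios(scen)
```
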