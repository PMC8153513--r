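# vfbayes

Bayesian estimation of vocal-fold material properties from glottal area
waveforms, using a two-dimensional three-layer viscoelastic finite-element
model of self-sustained vocal-fold oscillation.

## What it does, and for whom

High-speed videoendoscopy (HSV) of the larynx yields the glottal area
waveform (GAW): the projected open area between the vibrating vocal folds,
frame by frame.  Tissue stiffness, density, viscosity and the driving lung
pressure are not observable directly, yet they are exactly what a clinician
or a voice scientist wants for subject-specific modeling.  `vfbayes` solves
this inverse problem for the laboratory setting in which it can be
validated: silicone vocal-fold replicas whose layer-by-layer elastic moduli
are known from manufacture.  The package is aimed at voice-science and
computational-biomechanics researchers who need a transparent, fully
scriptable forward model plus a Bayesian fitting pipeline with honest
uncertainty reporting.

## The model in brief

* **Structure.** A 2D M5-style cross-section (8.40 mm medial-lateral,
  10.51 mm inferior-superior, 17.00 mm glottal length) with body, ligament
  and cover layers, meshed deterministically into linear triangles.  Plane
  strain, in-plane isotropy, Poisson ratio 0.4995; the damping matrix is
  stiffness-proportional through the viscosity substitution
  `mu -> mu + eta d/dt`.  The nearly incompressible limit is handled with a
  mean-dilatation (B-bar) volumetric treatment; fully integrated elements
  are available for comparison.
* **Aerodynamics.** Quasi-1D Bernoulli flow with separation at
  `A_sep = 1.3 A_min`; stations above the minimum section sit in the
  separated jet at supraglottal pressure.  `Q = 1.3 A_min sqrt(2 dp / rho)`
  gives the flow rate.
* **Dynamics.** `M theta'' + D theta' + K theta = F(theta)` integrated with
  average-acceleration Newmark at `h = 0.05` ms (20,000 samples/s), midline
  collision by projection with exact constraint-force recovery, and a
  static active-set pre-stress solve for medial compression (`x0`).
* **Inference.** Importance sampling from independent uniform priors over
  `E_bdy, E_cvr, E_lig, p_sub, rho, eta` (optionally `x0`); Gaussian GAW
  likelihood with `sigma_e = 1` mm^2; log-sum-exp weights, multinomial
  resampling, resampled means and standard deviations as point and
  uncertainty estimates.

See the methods vignette (`vignettes/vfbayes-methods.Rmd`) for assumptions,
numerical choices and known limitations.

## Worked example

```r
library(vfbayes)

# a synthetic "measured" waveform with known ground truth:
# 300 ms at 2000 fps, 1 mm^2 additive camera noise
obs <- generate_observation(seed = 7)

# waveform metrics of the underlying clean signal
gaw_metrics(obs$clean)
#> # A tibble: 1 x 5
#>      f0 max_area open_quotient speed_quotient n_cycles
#>   <dbl>    <dbl>         <dbl>          <dbl>    <int>
#> 1  120.     6.84         0.580           6.5        35
# (cycle detection at 1% of peak also counts brief micro-openings during
# the closed phase, so f0 here sits above the ~56 Hz principal cycle rate)

# scaled-down estimation: 2000 prior draws, 120-element fitting mesh
post <- vf_estimate(obs$gaw, vf_prior(),
                    vf_config(n_ens = 2000, seed = 42, mesh_target = 120))
tidy(post)
glance(post)
```

The `tidy()` summary lists, per parameter, the posterior mean, standard
deviation and relative uncertainty in the prior's native units (kPa, Pa,
kg/m^3, Poise); `glance()` reports the ensemble size, the effective sample
size (ESS) and the count of unstable forward runs.  **Read the ESS before
trusting the standard deviations**: with the default sharp likelihood a
single draw can dominate the weights (ESS near 1), in which case the means
are best-fit values but the spread is not a calibrated uncertainty; the
methods vignette discusses this regime and the `sigma_e` field that
controls it.

A thin command-line interface wraps the same functions:

```sh
Rscript inst/cli/vfbayes synth    --config cfg.yaml --out gaw.csv --truth truth.json
Rscript inst/cli/vfbayes estimate --gaw gaw.csv --config cfg.yaml --out results/
Rscript inst/cli/vfbayes metrics  --gaw gaw.csv --out metrics.json
```

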