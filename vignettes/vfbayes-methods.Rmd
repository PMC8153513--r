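---
title: "Methods: a 2D finite-element vocal-fold model and Bayesian property estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a 2D finite-element vocal-fold model and Bayesian property estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

High-speed videoendoscopy of vibrating vocal folds yields one robust scalar
observable per frame: the projected open area between the folds, the glottal
area waveform (GAW).  `vfbayes` fits a physics-based forward model of
self-sustained vocal-fold oscillation to a measured GAW and returns posterior
distributions over the tissue parameters that generated it: the Young's
moduli of the body, ligament and cover layers, tissue density, viscosity,
the driving subglottal pressure, and optionally a medial pre-compression
offset.  Because the data source here is silicone vocal-fold replicas (whose
layer modulus and density are known from their manufacture), recovered
parameters can be compared against ground truth; the same pipeline applies
unchanged to any externally supplied GAW.

# Forward model

## Geometry and layers

The cross-section is an M5-style profile, 8.40 mm medial-lateral by
10.51 mm inferior-superior, with an anterior-posterior glottal length of
17.00 mm.  The coordinate origin sits at the inferior-lateral corner and `x`
increases medially, so the contact plane (glottal midline) is the vertical
line `x = 8.40` mm.  Three tissue layers are modeled: a cover shell along
the free (glottal) surface, a ligament band beneath it, and the body
occupying the remainder.  Exact interface coordinates for the physical
replicas are not available, so the shell thicknesses are configurable
inputs with defaults of 0.8 mm (cover) and 1.2 mm (ligament), read
qualitatively from the published cross-section; they are treated as known,
not estimated.

The mesher slices the domain with horizontal rays from the free-surface
polyline to the lateral wall, placing ray nodes exactly at the two layer
interfaces so that no element straddles a layer and the triangulated area
equals the polygon area to machine precision.  Meshing is fully
deterministic.  A 205-element target is the full-scale resolution (realized: 204
elements, 126 nodes); 120 elements is the scaled-down default used for
ensemble runs.

The default clamped boundary is the lateral wall only.  We also provide
`fixed_boundary = "attachment"`, which additionally clamps the inferior and
superior faces, but do not recommend it: with a nearly incompressible
material every medial push on the inferior slope must then be accommodated
by the single free face, the medial surface bulges into the midline, and
the fold seals statically instead of oscillating.  With lateral-wall
clamping the reference configuration self-oscillates with peak glottal
areas of 16-20 mm^2, matching the regime of the silicone experiments.

## Elasticity, damping and locking

Each layer is linear, isotropic in the plane, in plane strain, with
`mu = E / (2(1+nu))`, `lambda = nu E / ((1+nu)(1-2nu))` and Poisson ratio
fixed at `nu = 0.4995` (silicone is nearly incompressible).  Viscous
damping follows the substitution `mu -> mu + eta d/dt` in the factored
constitutive matrix, giving an element damping matrix proportional to the
element stiffness: `D = eta_SI * 2(1+nu) * K(E = 1)`, layer-wise.
Viscosity is entered in Poise and converted to Pa s at assembly.

At `nu = 0.4995`, fully integrated linear triangles lock volumetrically: we
measured static medial-surface deflections roughly 40 times smaller than
expected for this load level, and no parameter set inside the prior then
oscillates.  The default assembly therefore uses a mean-dilatation (B-bar)
treatment: the volumetric part of the stiffness is integrated with the
area-weighted average divergence over each quad patch of the structured
mesh (each patch is one quad split into two triangles), while the
deviatoric part is integrated exactly.  This is the standard remedy in the
displacement-based setting; it leaves the patch test intact (averaging a
uniform field is exact) and places the lowest structural modes at
101/132/160 Hz for the reference properties, the observed range for
silicone folds of this family.  `formulation = "full"` restores the
verbatim element for comparison.

## Aerodynamic load

The glottal channel is quasi-one-dimensional: each free-surface station at
medial position `x` has local area `A(s) = 2 (8.4 - x) * 17` mm^2 (symmetric
halves).  The Bernoulli law with flow separation sets the driving pressure;
the separation area is `A_sep = 1.3 A_min`, with `A_min` the true minimum
area (zero during contact).  Four profiles are implemented
(`separation_mode`):

* `"jet"` (default): stations superior to the minimum section sit in the
  separated jet at `p_sup`; stations at and below it follow the branch rule
  `p = p_sub - (p_sub - p_sup)(A_sep/A)^2` where `A < A_sep`, else `p_sub`.
* `"verbatim"`: the branch rule applied to every station by area alone.
  This variant feeds `p_sub` to wide stations even downstream of the
  constriction; it removes the convergent/divergent pressure asymmetry that
  drives self-oscillation, and in our experiments produces only a
  small-amplitude flutter.
* `"smooth"`: the fully continuous attached/separated channel law (the
  attached Bernoulli value equals `p_sup` exactly at the separation point);
  physically cleanest, but the attached-divergent suction weakens the drive
  and roughly halves the oscillation amplitude.
* `"closed_phase"`: like `"jet"`, but with an explicit stagnation rule
  during closure.

Because `A_sep` is tied to the *unfloored* minimum, full closure gives
`A_sep = 0`, every station satisfies `A >= A_sep`, and the surface feels
stagnation pressure: the seal is pried open and no division by zero can
occur.  (Flooring the minimum instead puts a `-0.69 p_sub` suction on a
closed glottis, which is a self-locking fixed point: the glottis then never
reopens.)  The small positive floor `a_floor = 0.001` mm^2 is used only for
reported area profiles.  The area ratio in the branch rule is intrinsically
bounded by `1.69`, so suction never exceeds `0.69 (p_sub - p_sup)`.

Station pressures are integrated edgewise (constant edge pressure equal to
the mean of the end stations, load split equally between end nodes) along
the inward surface normal.  Tractions integrate over the *reference* edges:
a follower load on a cover whose shear modulus (200 Pa) is five times
smaller than the driving pressure feeds back through the stretched edge
length and inflates without bound in a linear model.  Deformed-surface
loading remains available (`follower_loads = TRUE`) for small-amplitude
studies.

## Time integration and contact

The semi-discrete system `M theta'' + D theta' + K theta = F(theta)` is
advanced with the average-acceleration Newmark scheme written as a
three-term recurrence with the aerodynamic load evaluated explicitly at the
current state; the constant iteration matrix `M/h^2 + D/(2h) + K/4` is
factorized once per simulation.  An explicit central-difference scheme is
not usable here: at `nu = 0.4995` the dilatational wave speed puts the CFL
limit near 0.01-0.02 ms, far below the standard step `h = 0.05` ms (20,000
samples per second).  Newmark average acceleration is unconditionally
stable, second-order, and conserves the discrete energy of the undamped
free problem (verified to below 1% over 1000 steps).  A dissipative member
(`newmark_gamma > 1/2`) is available; it is not the default because it
damps the oscillation itself at the levels needed to alter contact noise.

Collision with the symmetric opposing fold is the projection rule: any node
whose x-position would cross the midline is placed exactly on it.  The
constraint force is read off as the residual of the discrete momentum
balance at the clamped degree of freedom (this is exact, and is tested
against an independent recomputation from stored trajectories); a clamped
node whose residual turns tensile is released within the same step.
Contact pressure divides the nodal constraint force by the tributary
free-surface edge length times the glottal length.  Contact statistics
(per-cycle mean and maximum contact pressure) are averaged over an 800 ms
window (1050 ms simulations trimmed at 250 ms); shorter windows leave
visible cycle-count noise in the cycle-averaged maxima.

## Pre-compression

Medial compression is a static pre-stress: the equilibrium `K theta0 = f_c`
subject to `x <= x0` for every node, with `x0 = 8.4` mm meaning no
compression.  We solve the constrained equilibrium by active-set iteration
on the contact complementarity conditions (pin violating nodes, relax the
rest, release tensile pins), which converges to the same fixed point as
micro-stepped pushing but in a handful of linear solves — relevant because
the solve runs once per prior draw.  Stored energy grows monotonically as
`x0` decreases (tested), and the dynamic simulation starts from this state
at rest.

# Observation model

The simulated GAW is `A_s(t) = 17 mm * 2 * max(0, 8.4 - max_i x_i(t))`
over the free-surface nodes, at the solver rate.  To compare with a camera
recording: decimate by integer stride to the camera rate (20,000 to 2,000
fps keeps every 10th sample; no anti-alias filter, the signal is smooth),
discard the first 250 ms (start-up transient), and phase-align by the
integer-sample shift maximizing the cross-correlation of the first two
(mean-removed) cycles.  Cycle boundaries for metrics use upward crossings
of a threshold at 1% of the maximum area — the simulated folds close fully
while measured ones may not, and a relative threshold treats both.  Metrics
are the fundamental frequency (reciprocal mean period), maximum area, open
quotient and speed quotient, averaged per cycle.

# Inference

The likelihood is the unbiased additive Gaussian error model,
`log L = -||A_m - A_s||^2 / (2 sigma_e^2)`, with `sigma_e = 1` mm^2 by
default (about 6% of the waveform peak, deliberately generous to absorb
model error).  Estimation is plain importance sampling from independent
uniform priors — E_bdy (9, 15) kPa; E_cvr (250, 950) Pa; E_lig (0.5, 3)
kPa; p_sub (400, 1800) Pa; rho (950, 1200) kg/m^3; eta (1, 7) Poise; and
optionally x0 (7.4, 8.4) mm — followed by log-sum-exp weight normalization,
multinomial resampling, and resampled-ensemble means and standard
deviations as the point and uncertainty estimates.  Unstable draws get
weight zero and are counted.  Every random element derives from one master
seed, and per-draw work depends only on the draw index, so results are
identical for any worker count.

Two implementation details matter numerically.  First, weights are computed
in log space: squared residuals over 600 samples reach thousands, and raw
likelihood ratios underflow double precision.  Second, each forward run
simulates a 40 ms pad on both sides of the nominal 300 ms comparison
window, so that after phase alignment every draw is compared over exactly
600 samples.  Without the pad, draws aligned with a large shift would be
compared over fewer samples and their log-likelihood would be biased
upward by exactly the number of dropped terms — enough to reorder the
ensemble.

## Scaled-down default conditions

Package defaults are a desk-scale configuration: ensembles of 2,000 draws
on a 120-element mesh (the full-scale configuration is 50,000 draws on 205
elements), 550 ms simulations at `h = 0.05` ms, 300 ms comparison windows
at 2,000 fps.  The synthetic-data generator, by contrast, defaults to the
full 205-element mesh: its role is to stand in for the physical experiment,
and generating and fitting with the *same* discretization makes the inverse
crime variant of the problem (see below).

## Known limitations

The collisional limit cycle of this model is weakly chaotic: cycle periods
fluctuate with a coefficient of variation near 1.3% regardless of mesh
density or step size, traceable to the contact events themselves.  Two
consequences follow.

First, identification from *self-generated* data at the same mesh is a
needle problem: a parameter perturbation of 0.2% already decorrelates the
opening flanks and costs hundreds of log-likelihood units, so the exact
posterior concentrates on a region far smaller than any feasible ensemble
can hit.  Generating at 205 elements and fitting at 120 (the default
pairing) reintroduces honest model error and a smoother landscape, which
is also the situation the method faces with real recordings.

Second, even under the cross-mesh pairing the likelihood at
`sigma_e = 1` mm^2 remains sharp enough that a single draw can carry
essentially all weight at ensemble sizes in the thousands (effective
sample sizes near 1).  Point estimates then land within roughly 10-30% of
the truth (the best draw in the ensemble), but the resampled standard
deviation collapses and is not a calibrated uncertainty; downstream
trend statements that divide by it inherit the problem.  The effective
sample size is reported precisely so users can detect this regime, and
`sigma_e` is a configuration field: inflating it spreads the weights (the
effective sample size is non-decreasing in `sigma_e`, tested) at the cost
of a flatter posterior.  We deliberately keep `sigma_e = 1` as the default
rather than auto-calibrating it, so that reported uncertainties always
refer to a stated error model.

The synthetic generator emulates frame-rate, duration, additive
camera-noise and transient-trimming aspects of the physical recordings; it
does not emulate segmentation artifacts, incomplete closure of real folds,
left-right asymmetry, or anterior-posterior variation (the model is 2D and
symmetric by construction), so recovery results on synthetic data bound
what real data can deliver from above.

# Worked example

```{r example}
library(vfbayes)

# synthetic "measured" waveform with known truth
obs <- generate_observation(seed = 7)
autoplot(obs$gaw)

# scaled-down estimation
post <- vf_estimate(obs$gaw, vf_prior(),
                    vf_config(n_ens = 2000, seed = 42, mesh_target = 120))
tidy(post)
glance(post)
autoplot(post)

# forward model at the recovered means
props <- reference_truth()
sim <- vf_simulate(props, vf_triangulate(vf_geometry(), 205))
gaw_metrics(trim_transient(downsample(sim$gaw, 2000), 250))
contact_stats(sim)
```
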