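---
title: "Methods: forward model, reconstruction family, and the functional battery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: forward model, reconstruction family, and the functional battery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the modelling choices behind `lungeit`: the governing
equations, where defaults come from, what the synthetic phantom does and does
not emulate, and the numerical decisions a maintainer would want written
down.

## Forward model

Time-difference EIT linearizes the map from conductivity to boundary
voltages around a background `sigma0`. We solve the forward problem with
linear triangular finite elements and the **complete electrode model**
(CEM): finite-width electrode arcs, a contact impedance `z` (default 0.01
model units) coupling the electrode potential to the boundary potential
beneath it, and a zero-sum constraint on electrode potentials enforced by a
Lagrange multiplier. CEM is the standard quantitative model for EIT; the
published description of the device geometry (circular contact regions on a
thorax belt) reduces in 2D to boundary arcs. Neither the electrode width
nor the contact impedance used in the original simulations is reported
anywhere we could recover, so both are configurable; the defaults (0.15 rad
arcs, z = 0.01) put the contact voltage drop at a few percent of a typical
inter-electrode voltage, consistent with good gel electrodes.

The mesh is a deterministic structured triangulation: concentric node rings
with counts growing in proportion to radius, the boundary ring aligned with
electrode arc endpoints, annuli triangulated by an angular merge sweep.
There is no randomness and no external mesh generator, so identical inputs
give byte-identical meshes — which the movement Jacobian exploits by
rebuilding the same topology with one electrode slid along the boundary.
`density` counts rings: 16 (default) gives ~1500 elements, 6 gives the
~200-element meshes used for brute-force oracles.

Two properties worth recording:

* **Reciprocity** (drive and measurement pairs interchangeable) holds to
  machine precision because the discrete system is symmetric — it is a
  structural property, not a tolerance.
* **Homogeneity**: boundary voltages scale as `1/c` when conductivity
  scales by `c` *only* in the shunt limit `z -> 0`; with finite contact
  impedance the joint scaling `(sigma, z) -> (c*sigma, z/c)` is the exact
  invariance. The test suite checks the joint form exactly and the
  sigma-only form at `z = 1e-8`, where it holds to ~1e-7. The same applies
  to the Euler identity `J sigma0 = -v(sigma0)`.

The conductivity Jacobian uses the adjoint identity: with drive field
`u_d` and unit-current measurement field `u_m`,
`dv/dsigma_k = -area_k * grad(u_d).grad(u_m)` on element `k`. Under the
adjacent protocol every measurement pair is also a drive pair, so the 16
field solves serve both roles. The movement Jacobian is by central finite
differences of the electrode centre angle (step 1e-4 radius units);
electrodes are constrained to the circular boundary, so Cartesian columns
are tangential projections of the arc-length derivative.

## Reconstruction family

All one-step solvers share `x = (J'WJ + lambda^2 R)^(-1) J'W y`. The design
axes and their defaults:

* **Data**: normalized difference `(v - v_ref)/v_ref` by default; its
  Jacobian has rows scaled by the reference voltages. Plain difference (F2)
  uses the raw Jacobian. Normalization cancels fixed per-channel gains
  exactly — the mechanism the gain-invariance tests exercise.
* **Background** (F3-2D): bilateral elliptic lungs at 0.2 of the background
  conductivity. The published lung-to-background ratio is not recoverable
  from the text we had; 0.2 sits in the usual range quoted for inflated
  lung and is configurable. Recomputing `J` at this background boosts
  sensitivity inside the lungs and measurably deepens the inter-lung valley
  of the tidal image (tested on the horizontal midline profile).
* **Priors**: NOSER diagonal `diag(J'J)^p` with `p = 0.5` (the exponent is
  also unreported; 0.5 is the convention of that algorithm family, and `p`
  is a parameter). The high-pass prior (I3) is `R = (I-G)'(I-G)` with `G` a
  row-normalized, area-weighted Gaussian over element centroids whose width
  is set so the half-power wavelength is 10% of the medium diameter;
  row-normalization makes the DC annihilation exact rather than
  approximate.
* **Noise models**: reciprocity weights (I1)
  `w_i = exp(-(e_i/tau)^2)` with `e_i` the relative mismatch of reciprocal
  channel pairs averaged over frames, `tau = 0.1` by default (the published
  value is unknown; the weights are logged in provenance). Movement
  augmentation (F4) adds `M Sigma_m M'` with isotropic `Sigma_m`; its scale
  defaults to trace-matching the base covariance (`"auto"`), again because
  no quantitative value is available.
* **Iterative solvers**: robust L1 (I2) minimizes
  `sum w_i sqrt(r_i^2 + eps^2) + lambda^2 x'Rx` by IRLS;
  `eps = 1e-4 * median|r|`, floored at `1e-6 * mean|y|` so a near-perfect
  fit cannot make the reweighted system numerically singular. TV (I5)
  minimizes a quadratic misfit plus edge-length-weighted
  `sum len_ij sqrt((x_i-x_j)^2 + beta^2)` by lagged diffusivity,
  `beta = 1e-4` of the initial dynamic range. Both are majorize-minimize
  schemes, so the objective is non-increasing by construction; tests assert
  it. Non-convergence within `max_iter = 50` at relative tolerance 1e-6
  returns the best iterate with a warning and a `converged = FALSE` flag.

A caveat we chose to document rather than hide: with `eps` four orders of
magnitude below the residual scale the robust loss is essentially exact L1,
and its minimizer is *not* close to any single quadratic solution even for
Gaussian-only residuals (the IRLS weights `1/|r_i|` span decades). The
"L1 ~ L2 for light tails" intuition is recovered exactly in the
large-smoothing limit: for `eps` far above the residual scale the loss is
Huber-quadratic and the IRLS fixed point equals `gn_one_step` at
`lambda * sqrt(2*eps)`. The test suite checks that limit to < 5% and checks
outlier resistance on noise-figure-matched models; it does not assert
pathwise closeness at the exact-L1 smoothing, which would be false.

## Noise-figure calibration

Algorithms are compared at matched noise performance: the hyperparameter of
every preset is tuned until the **noise figure** — data SNR over image SNR
for a small contrast at half the radius — reaches a common target. The
original study tied this target to the backprojection algorithm's
performance, which is out of scope here (that reconstruction matrix is
famously unrecoverable); the default target is 0.5 and every calibrated
value is recorded in the model's provenance. "Signal" is the mean absolute
response (image-sum vs mean-absolute is not decidable from the available
text; mean-absolute is less sign-cancellation-prone). Noise propagation is
closed-form for linear models (`E|b'n| = sqrt(2/pi)||b||` for unit-variance
noise) and a seeded, linearized Monte-Carlo (30 draws at 1% of the signal
scale) for iterative solvers; a 1e4-draw Monte-Carlo oracle cross-checks
the closed form to 2%. Bisection runs on `log lambda` (NF is monotone in
lambda); the TSVD rank is searched exhaustively with ties towards smaller
rank, i.e. more regularization. A numerically failing evaluation deep in
the under-regularized bracket is treated as NF = Inf, which steers the
bisection rather than aborting it.

## Functional measures

Tidal images reconstruct (mean end-inspiratory minus mean end-expiratory
data) against the mean end-expiration reference and are rasterized to
32x32 by an area-weighted interpolation matrix (8x8 subsampling per pixel,
cached per mesh; integral preservation is tested to 1%). Ventilated lung is
a conductivity *decrease*; the ventilation signal negates the tidal image
so that ROI thresholding, `V_T` and `CoV` operate on positive quantities.

Breath detection takes the global signal (channel mean of normalized
difference data against the sequence mean), finds extrema with minimum
separation of half the expected breath period, forces
inspiration/expiration alternation, and rejects candidates whose tidal
amplitude leaves the 50-200% band around the running median — an automatic
surrogate for the human operator review used with real recordings, which a
library cannot reproduce.

The lung ROI keeps pixels at >= 20% of each image's maximum (absolute
value — whether the original threshold applied to signed or absolute
values is not stated; absolute is the conservative choice) and unions over
a subject's six recordings. `V_T` is the ROI sum. `CoV` is the
amplitude-weighted mean dorsoventral coordinate with the pixel-centre
convention `(33 - 2i)/32` for row `i`: centre 0, most ventral row
0.96875. This scaling is pinned by the published equivalence margin of
0.03 "half a pixel height" (2/32/2 = 0.03125).

## Statistical battery

Twelve hypotheses per algorithm over the six stages
(`Z21a, P21a, Z100, P100, Z21b, P21b`): V_T equivalence under PEEP, under
FiO2, and across repetitions; CoV decrease with PEEP (both FiO2 levels);
CoV increase with 100% O2 (both pressures); CoV equivalence across
repetitions. Equivalence is realized as TOST (two one-sided paired t-tests
against the margin, reported p = max of the pair) — the original
description of margin-based "equality" testing is ambiguous in the text
available to us, and TOST is the standard operationalization; the margin is
10% relative (resolved against the grand mean of the two conditions) for
V_T and 0.03 absolute for CoV. Directional tests are one-tailed paired
t-tests. Every row carries a Kolmogorov-Smirnov normality p-value of the
paired differences and a Wilcoxon signed-rank recomputation. alpha = 0.05
throughout with no multiplicity correction, matching the row-wise reporting
convention of the study design. Degenerate zero-variance differences are
decided exactly (p = 0.5 for zero difference in a one-tailed test; 0/1 for
equivalence by comparing the exact difference to the margin).

## The phantom: what it emulates, what it does not

The generator reproduces the acquisition's statistical structure: 16
electrodes, 13 frames/s, 60 s per recording, 20 breaths/min raised-cosine
breathing with 1:2 inspiration:expiration, six stages per subject with
repeated ZEEP-21/PEEP-21 stages, per-channel multiplicative gains (SD 1%,
fixed within a recording), additive Gaussian channel noise (SD 0.1% of the
mean absolute voltage), and optional breathing-synchronized electrode
displacement injected to first order through the movement Jacobian.
Ventilation is a modulation `sigma_lung * (1 - a_region * s(t))` of two
elliptic lung regions split into dorsal/ventral halves at the lung elements'
median height; the condition-dependent dorsal fractions are ZEEP-21 0.50,
PEEP-21 0.60, ZEEP-100 0.35, PEEP-100 0.50, with the total amplitude
conserved across conditions by construction. The magnitudes of these shifts
are free parameters — the study reports only p-values, not effect sizes —
chosen once so the effects are detectable at n = 8 with the battery's
margins, and are configurable. Per-subject jitter: 5% geometry, 0.02 dorsal
fraction, 10% amplitude.

What a green battery does **not** establish: anything about anatomical
fidelity (the phantom is a circular 2D section with elliptic lungs, not a
thorax); robustness to baseline drift, cardiac-frequency signals, or
posture change (not modelled); performance on 3D current paths (a 2D
forward model generates the data, so the 2D/3D model mismatch of real
recordings is absent); or behaviour at noise levels beyond the small
defaults. The battery validates the *pipeline logic* — that each
algorithm's functional measures respond to encoded redistribution effects
and conserve encoded volumes — not clinical performance.

Two implementation notes for reproducibility: the noise-free signal is
exactly periodic (20/min at 13 Hz gives a 39-frame period), so each unique
breath phase is solved once and tiled before noise is added — bit-identical
to the naive frame loop and ~20x faster; and all randomness (subject
jitter, gains, noise, Monte-Carlo NF draws) descends from explicit seeds
recorded in metadata and provenance, with `.Random.seed` restored so
library calls never perturb a caller's RNG state.

## Degenerate inputs and tie-breaks

* Electrode overlap, n < 4 electrodes, non-positive conductivity, zero
  reference voltages under normalization, empty ROIs, all-zero ventilation
  images, missing battery cells: all rejected with messages naming the
  offending channel/cell/field.
* TSVD rank ties at equal NF distance resolve to the smaller rank.
* Rasterized pixels claimed by no element (outside the mesh polygon) are
  masked NA; a pixel's value averages only its inside subsamples.
* `detect_breaths` requires at least one extremum and one plausible
  inspiration; a constant signal is an error, not an empty result.
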