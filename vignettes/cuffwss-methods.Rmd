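---
title: "Shear metrics of atherogenic flow in the cuffed carotid: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shear metrics of atherogenic flow in the cuffed carotid: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cuffwss)
```

## The problem

A tapered constrictive cuff placed around one carotid artery of a
hypercholesterolemic mouse creates three well-defined flow disturbances:
reduced (low) wall shear stress upstream of the cuff, high shear inside the
taper, and oscillatory, multidirectional shear downstream where a
time-varying recirculation forms behind the stenosis. Plaques with a
vulnerable phenotype develop upstream and stable plaques downstream, which
makes the model a workhorse for asking *which* feature of disturbed flow -
shear magnitude, shear direction, or both - drives each plaque type.

Answering that question quantitatively requires post-processing a
time-resolved wall shear stress (WSS) vector field $\tau(x, t)$ (Pa) on the
lumen surface into scalar metrics, comparing the instrumented vessel
against the contralateral control region by region, and doing so with
cohort-level statistics. `cuffwss` implements that post-processing pipeline
end to end, together with a synthetic flow generator that stands in for the
imaging + CFD stack (micro-CT reconstruction, meshing, Navier-Stokes
solution) so that every stage is testable at desk scale.

## The six metrics

All time integrals are taken over one cardiac cycle of period $T$ on the
uniform grid of exported instants (equal-weight rectangle rule; for a
periodic signal on a uniform grid this equals the trapezoidal rule, and no
quadrature choice beyond that is needed). With $\tau_i$ the WSS vector at
instant $i$ of $N$:

* **TAWSS** $= \frac{1}{N}\sum_i \lVert\tau_i\rVert$ - time-averaged shear
  magnitude (Pa).
* **OSI** $= \tfrac12\left(1 -
  \frac{\lVert\sum_i \tau_i\rVert}{\sum_i \lVert\tau_i\rVert}\right)$ -
  degree of $180^\circ$ reversal, 0 (unidirectional) to 0.5 (perfectly
  oscillatory).
* **RRT** $= \left\lVert\frac{1}{N}\sum_i \tau_i\right\rVert^{-1}
  = \left[(1 - 2\,\mathrm{OSI})\,\mathrm{TAWSS}\right]^{-1}$ (1/Pa) -
  relative residence time, a species-transport proxy. The algebraic
  identity between the two forms is enforced in tests to 1e-9.
* **transWSS (tSS)** $= \frac{1}{N}\sum_i |\tau_i \cdot q|$ with
  $q = n \times p / \lVert n \times p\rVert$, $p$ the unit time-mean WSS
  vector and $n$ the outward surface normal - multidirectionality
  excluding pure reversal (Pa). Always $\le$ TAWSS.
* **SAD** - per instant, the mean angle
  $\arccos\!\big(\hat\tau_i(j)\cdot\hat\tau_i(k)\big)$ between node $j$ and
  its edge neighbours $k$, then averaged over instants (rad). The source
  formulation is verbal ("angle change compared with the neighbouring
  points"), so two orderings are defensible; we average per instant first,
  which keeps SAD exactly zero for any spatially uniform direction field at
  every instant.
* **LSI / HSI** - continuous low/high shear indices,
  $\mathrm{LSI} = \max\!\big(0, (\theta_L - \mathrm{TAWSS})/\theta_L\big)$,
  $\mathrm{HSI} = \max\!\big(0, (\mathrm{TAWSS} - \theta_H)/\mathrm{TAWSS}\big)$.

The clamping at zero is implied by the phrase "thresholds for non-zero
values" in the source formulation; we state it explicitly as the contract.
Since $\theta_L \le \theta_H$, the two indices are mutually exclusive and a
window of normal shear separates them.

### Threshold calibration

The thresholds come from the paired control vessel, assumed to carry
non-atherogenic flow. With $m$ and $s$ the mean and sample SD
($n-1$ denominator; the source says only "SD") of $\ln \mathrm{TAWSS}$ over
the control nodes:

$$\theta_L = e^{m - 0.67 s}, \qquad \theta_H = e^{m + 0.67 s}.$$

The multiplier 0.67 is the standard-normal 75th percentile rounded to two
decimals and is used literally (not 0.6745); it isolates the bottom and top
25% of a log-normal shear distribution. Calibration is per mouse from its
own contralateral control by default (`threshold_mode = "per_mouse"`), with
a pooled-cohort option. Both thresholds scale linearly with a common
rescaling of the control shear field, which is what makes LSI/HSI usable
across animals of different size.

### Degenerate inputs

Zero WSS vectors make OSI, tSS and SAD angles undefined; the conventions
are OSI = 0, tSS = 0, and a zero contribution to SAD, each with a logged
count (attributes `n_zero`, `n_zero_pairs`). A vanishing time-mean vector
makes RRT infinite; the value is kept as an `Inf` sentinel and capped at
the display-normalization stage. HSI at TAWSS = 0 is defined as 0.

## Vessel regions and control scaling

The instrumented vessel is segregated by axial position into four regions:
upstream outside the plaque, upstream within the vulnerable-plaque region
(the 1.6 mm immediately proximal to the cuff entrance - a default exposed
as `plaque_extent`, since it derives from a cohort-specific histological
shrinkage correction), the cuff, and downstream. Boundary nodes are
assigned to the more distal region, making the cuff interval closed; the
source is silent on ties. The control vessel has no cuff, so its regions
are placed at the same distances from its *distal* end, giving segments of
comparable length. Axial position is the projection onto a straight axis:
the synthetic vessels are straight tubes and curved-centerline extraction
is out of scope, so the 1.6 mm plaque extent is a straight-line distance.

Regional reduction is the unweighted mean over nodes (node density on the
structured tubes is near-uniform; tests bound the difference from
area-weighted means below 1%). For the instrumented-vs-control comparison,
each metric is first scaled to [0, 1] for display - by its theoretical
maximum (0.5 for OSI, $\pi$ for SAD, 1 for LSI/HSI) or, for TAWSS, tSS and
RRT which have none, by the observed maximum over all vessels of the
cohort. tSS has no stated theoretical maximum anywhere, so the
cohort-observed maximum is used and recorded in the table's
`observed_max` attribute. Per-mouse region means below 0.005 are then
raised to that floor (the source's guard against ratio blow-up near zero,
with "near zero" read as "below the floor value"), and every value is
divided by the cohort mean of the control values for its (region, metric)
cell. Scaled control values therefore average to exactly 1 in every cell -
a construction invariant the acceptance checks verify to machine
precision. Note that a cohort-wide display divisor cancels in this ratio,
so display normalization affects the comparison only through which values
hit the floor.

## Statistics

Each (region, metric) cell is tested with a one-tailed two-sample
equal-variance t test for elevation in the instrumented vessel - the only
direction of interest. The source's phrase "one-way student's t-test" is
read as unpaired; because the vessels are contralateral pairs a paired
option is provided (`t_test = "paired"`). No multiple-testing correction is
applied, deliberately: comparisons are made only between vessels within a
metric, never across metrics, and this choice is documented rather than
silently changed. Velocity/diameter group comparisons use standard one-way
ANOVA. Significance stars follow the usual 0.05 / 0.01 / 0.001 levels;
when both groups are floored constants the test is uninformative and p is
0.5 by convention.

## The synthetic flow generator

The generator replaces micro-CT + Doppler + Navier-Stokes with an analytic
model whose purpose is to emulate the *structure* of the cuffed-vessel flow
field, not any particular animal:

* **Geometry.** Straight tubes of 0.6 mm diameter and 10 mm length
  (carotid scale), meshed as structured rings (81 x 24 nodes by default).
  The instrumented vessel carries the cuff taper, 500 um narrowing to
  250 um over a 1.2 mm sleeve starting at 5.0 mm - a 75% areal stenosis.
* **Waveform.** A two-harmonic strictly positive pulse at the murine heart
  rate of 8 Hz (0.125 s period), discretized into 300 steps with every
  10th step exported (30 instants, 0.0042 s apart). The measured waveform
  shape is not tabulated anywhere, so the harmonic amplitudes
  (0.4, 0.15, phase $\pi/4$) are generic; the sample mean is rescaled to
  the prescribed mean velocity exactly. Mean inlet velocities default to
  112.8 mm/s (instrumented - the stenosis lowers flow) and 153.4 mm/s
  (control), the cohort means reported for this model.
* **Shear closure.** Quasi-steady Poiseuille: with flow
  $Q(t) = U(t)\,\pi R_\mathrm{inlet}^2$ conserved along the tube,
  $|\tau|(s, t) = 4\mu Q(t)/(\pi R(s)^3)$ along the axial direction, with
  $\mu = 3.5$ mPa s and $\rho = 1050$ kg/m$^3$. At Reynolds number ~40 and
  Womersley number ~2-3 this is a defensible amplitude-level
  approximation; it is *not* a Navier-Stokes solution, and no acceptance
  quantity depends on CFD-level accuracy. The mean wall shear rate
  $8U/D$ exceeds 1000 1/s at these conditions, which is also what
  justifies the Newtonian viscosity.
* **Downstream disturbance.** A parametric surrogate for the time-varying
  vortex behind the cuff: inside a 2.5 mm recirculation zone, the axial
  shear is modulated to reverse transiently (reversal amplitude 1.0) and a
  rotating circumferential component is added (amplitude 0.5, vortex
  frequency twice cardiac). The parameters were chosen once so that the
  qualitative regional pattern emerges - downstream OSI/tSS far above
  control, upstream directional metrics at their floor - and are not
  fitted to any reported effect size.
* **Heterogeneity.** Each node's shear is scaled by a time-constant
  log-normal factor (log-SD 0.3 by default, a realistic within-vessel
  spread), which makes control TAWSS log-normal by construction - exactly
  the distributional shape the threshold calibration assumes - and gives
  the calibration a non-degenerate spread to work with.
* **Cohort.** Seven mice by default, matching the imaged cohort size.
  Per-mouse seeds derive deterministically from the master seed, and mean
  velocity and heterogeneity receive uniform +/-10% per-mouse jitter.
  Every stochastic step takes an explicit seed; the entire pipeline is a
  pure function of (config, seed) and re-runs are byte-identical.

### What the generator does not emulate

Real carotid geometry (curvature, the bifurcation, lumen remodelling by
the plaque itself), entrance and exit flow development, fluid-structure
interaction, the measured waveform shape, and any CFD-level secondary flow
other than the parametric vortex. Consequently the pipeline's *pattern*
results (which metrics are elevated where) are meaningful tests of the
metric and statistics code, but the synthetic fold changes are not
predictions of in-vivo magnitudes, which depend on mouse-specific geometry
and a full flow solution.

## Numerical choices

* STL vertex merge tolerance 1e-6 mm (STL stores a triangle soup; merging
  is required to recover adjacency); file normals are discarded and
  recomputed area-weighted from the geometry.
* Metrics at the 30-instant export stride agree with a 300-instant
  computation within 2% on the synthetic fields (tested), quantifying the
  export-stride approximation.
* The vectorized metric implementations are cross-checked against
  independent brute-force loop implementations on random small fields to
  1e-10.
* Problem sizes in the test-suite and acceptance runs: 41 x 12 to
  101 x 32 node tubes, 30-300 instants, cohorts of 2-7 mice - sizes chosen
  so the full suite runs in well under a minute while leaving every
  code path exercised at cohort scale.

## Known limitations

The quasi-steady closure ignores phase lag between flow and wall shear
(finite Womersley number), the disturbance is kinematic rather than
dynamic, and region segmentation assumes a straight vessel axis. The
0.005 floor, applied on display-normalized scales, means cells where both
vessels are at the floor compare as exactly equal (p = 0.5) - the correct
degenerate behaviour, but one that real noisy data would not produce.
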