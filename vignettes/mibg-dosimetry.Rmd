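---
title: "Internal dosimetry for 131I-mIBG therapy with mibgdose"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Internal dosimetry for 131I-mIBG therapy with mibgdose}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mibgdose)
```

## The problem

131I-labelled meta-iodobenzylguanidine (mIBG) is used to treat
neuroblastoma and adult neuroendocrine tumours. Administered activities
vary widely between centres (fixed, weight-based at 444 or 666 MBq/kg, or
dose-based), and toxicity is governed mainly by the absorbed dose to the
red marrow, for which the whole-body absorbed dose is an established
surrogate. `mibgdose` implements the full measurement-to-dose chain a
physicist runs during such a therapy:

1. **Whole-body dosimetry** from serial external-counter (probe) readings,
2. **Camera characterisation** so that 131I SPECT data can be quantified
   (calibration factor, partial-volume recovery, paralysable dead time),
3. **SPECT VOI quantification** (scatter, attenuation, volume delineation),
4. **MIRD dose calculation** for whole body, lesions and organs at risk,
   and **fractionated activity planning**.

All dose arithmetic follows the MIRD schema: the mean absorbed dose over a
dose-integration period is

$$D = \tilde A \, S,$$

where $\tilde A$ (MBq·h) is the time-integrated activity in the region and
$S$ is the region self-dose per unit time-integrated activity. Canonical
internal units are MBq, hours, Gy, kg for the body and g for
lesions/organs; the only S-value unit conversion needed,
mGy/(MBq·s) to Gy/(MBq·h), is the exact factor 3.6 and is centralised in
`convert_s_units()`.

## Whole-body dosimetry

Raw probe readings (counts, duration, view, background flag) are reduced
by `build_retention_curve()`:

* each patient reading is corrected with the **most recent prior
  background**; if none precedes it, the pre-administration background is
  used. Standard practice allows repeated backgrounds but fixes no pairing
  rule, so recency was chosen as the rule that best tracks contamination
  events;
* readings **within 15 min** are treated as replicates of one time point
  and averaged (the recommendation to take multiple readings per time
  point names no window; 15 min is short against the fastest clearance
  phases of interest);
* when both AP and PA views exist at a time point their **geometric mean**
  is used, otherwise the single view; the choice is recorded per point;
* rates are normalised to the first (pre-void) reading, so retention at
  $t=0$ equals the net administered activity; a residual rate from an
  earlier therapy can be subtracted from both numerator and baseline.

Counting statistics follow the Poisson law: a reading of $N$ counts has
relative noise $1/\sqrt N$, and `min_counts_for_precision(0.05)` returns
the familiar 400-count (in practice, >500) floor for 5% precision.

### Time–activity fitting

`fit_exponentials()` fits $A(t)=\sum_j A_j e^{-\lambda_j t}$ (1–3 phases,
$\lambda$ the *effective* decay constant) by Levenberg–Marquardt least
squares (`minpack.lm`), with starting values from classical curve
stripping. Numerical choices that matter:

* **Multi-start.** For two or more phases, geometric spreads (factors 2,
  4, 8) around the mono-exponential rate are tried alongside the stripping
  start, and — when the data rise initially — variants with a negated fast
  amplitude (uptake shapes). The best converged residual sum of squares
  wins. This removes most local-optimum artefacts that otherwise bias
  model comparison.
* **Constraints.** Decay constants are bounded below at $10^{-8}$ h⁻¹.
  A negative fitted amplitude on retention data triggers a refit with one
  phase fewer (with a warning), since retention phases are non-negative;
  uptake-shaped lesion curves keep their negative fast amplitude only if
  explicitly fitted that way.
* **Weighting.** Default is unweighted least squares; inverse-variance
  weighting from per-point sigmas is available and is what makes the
  extra-sum-of-squares F test well calibrated under counting
  (heteroscedastic) noise.

Model order is chosen by `f_test_select()` (extra-sum-of-squares F test,
default $\alpha = 0.05$) or `aic_select()` (small-sample corrected AICc;
ties break toward fewer phases — AICc rather than plain AIC is used because it is the safer variant at the 10–30
point sizes typical here).

The time-integrated activity uses the closed form
$\tilde A = \sum_j A_j/\lambda_j\,(e^{-\lambda_j t_1}-e^{-\lambda_j t_2})$,
verified in the tests against adaptive quadrature to $10^{-6}$ relative.
`coverage_fraction()` reports the measured fraction of $\tilde A(0,\infty)$
with the 80% adequacy threshold. Extrapolation beyond the last scan always
uses the *fitted* effective rate, never forced physical decay; lesion and
organ curves are evaluated from $t=0$ with no rise phase by default (the
clinical example fits a single exponential), and a fitted rise phase is
possible by allowing two phases.

### S value, dose and planning

The whole-body self-dose S value comes from the mass power law
$S = 1.34\times10^{-4}\, m^{-0.921}$ Gy/(MBq·h) ($m$ in kg), an
interpolation across newborn-to-adult phantoms; outside 1–150 kg a warning
is issued. Lesion and organ S values use a mass power law
$S = a\,m^{b}$ fitted to user-supplied (mass, S) tables by log–log least
squares (`fit_s_power_law()`); for unit-density spheres the
fit $0.031\,m^{-0.981}$ mGy/(MBq·s) to sphere-model S-value tables is
the default the CLI uses. Tissue
density is taken as 1 g/ml so organ mass and VOI volume are
interchangeable.

`plan_next_fractions()` implements the fractionation rule
$A_i = (A_1/D_1)\,(D_\mathrm{target}-D_1)/(N-1)$: the dose still needed,
shared over the remaining fractions, converted with fraction 1's
dose-per-activity — which is thereby assumed to hold for later fractions
(the rule's intrinsic assumption; the report states it). The red-marrow
surrogate divides the whole-body dose by the empirical ratio 1.6.

## Camera characterisation

* **Calibration factor** $Q = \dot C_\mathrm{VOI}/(c\,V)$ from a uniform
  cylinder, with a sub-VOI uniformity QC check (default 10% tolerance).
* **Recovery curve.** Measured recovery coefficients
  $R_i=\dot C_i/(Q A_i)$ over insert volume are condensed with a
  saturating power-logistic $R(v)=R_\mathrm{max} v^n/(v^n+v_{50}^n)$ —
  monotone by construction and linear in log-volume around $v_{50}$. Only the
  measurement is standardised, not the interpolant; this form was chosen
  because it fits typical 131I recovery data well with three parameters. Non-convergence falls back to monotone piecewise-linear
  interpolation, flagged in the result. Values below the smallest measured
  insert extrapolate with a warning; predictions are clamped to
  $(0, R_\mathrm{max}]$.
* **Dead time.** The paralysable model
  $\dot C_\mathrm{obs} = \dot C_\mathrm{inc} e^{-\dot C_\mathrm{inc}\tau}$
  is characterised from a graded-activity series: a zero-intercept linear
  fit below 10 kcps provides the starting sensitivity (zero intercept
  because zero activity gives zero rate after background subtraction), and
  a nonlinear fit of the full model refines sensitivity and $\tau$
  jointly — the low-rate points themselves carry percent-level losses, so
  freezing the linear slope would bias $\tau$. $\tau$ is fitted in
  microseconds to keep the Jacobian columns comparable in scale. Cameras
  with a high-count-rate mode carry one $\tau$ per regime with a hard
  switch threshold (20 kcps for the camera of the worked example), and the
  observed rate selects the mode.
* **Dead-time correction factor.** $\mathrm{DTF} = e^{\mathrm{DTF}\,\tau
  \dot C}$ is solved by fixed-point iteration from 1, which converges
  monotonically to the physical branch for $\dot C\tau < e^{-1}$; beyond
  the paralysable maximum no correction exists and an error is raised.
  A Newton fallback guards slow convergence near the peak. The default
  correction is the average-projection-rate correction applied post
  reconstruction; per-projection correction is available through the same
  functions.

## SPECT quantification

* **Scatter.** Triple-energy-window correction
  $C_\mathrm{SC}=C_\mathrm{peak}-\tfrac{W_\mathrm{peak}}{2}
  (C_1/W_1+C_2/W_2)$ with the standard 20%/6% windows at 364 keV;
  negative results clamp to zero per pixel. Images carry a
  corrections-applied provenance list so a correction is not applied
  twice.
* **Attenuation.** First-order Chang correction with uniform
  $\mu = 0.11$ cm⁻¹ (water at 364 keV): each in-mask voxel is multiplied
  by $1/\overline{e^{-\mu d_m}}$ over 64 equally spaced in-plane rays
  (the method's classical 2-D, slice-by-slice form). Rays march in
  half-voxel steps with bilinear mask sampling, and the boundary crossing
  is refined by bisection, which keeps the factor at the axis of a 10-cm
  cylinder within 0.1% of the closed form $e^{\mu R}$.
* **Volume delineation.** `adaptive_threshold_mask()` bisects on the
  threshold (fraction of the local maximum around the seed) until the
  seed's connected component matches the target volume within half a
  voxel. `block27_extrema()` reports the 3×3×3-block mean extrema inside a
  mask, the noise-robust alternative to single-voxel extremes.
* **Activity.** $A = \dot C_v/(Q\,R)\cdot\mathrm{DTF}$ per VOI and scan
  time, assembled by `voi_measurement()` from a camera model.

## Synthetic data: what it emulates, and what it does not

`gen_probe_series()`, `gen_deadtime_series()`, `gen_sphere_phantom()` and
`gen_lesion_tac()` generate every input the pipelines consume, with the
generating truth attached and bitwise reproducibility under a fixed seed
(the seed argument is mandatory). Noise models are the simplest consistent
with the measurement physics: Poisson for detected counts, multiplicative
Gaussian for rates. Defaults mirror the clinical conditions of the worked
example: 6893 MBq administered, probe readings 2-hourly on day one then
6-hourly, counter background 0.5 cps, dead-time series up to ~68 kcps
incident (driving the detector into visible paralysis, as a
graded-activity characterisation does), lesion scans at 2, 5 and 7 days
with 5% noise, and a 15 mm FWHM isotropic Gaussian PSF standing in for the
reconstructed resolution of a high-energy collimator (the PSF is an assumption
of the generator, not a measured system response). Sphere rasterisation uses
8× per-axis edge subsampling, keeping threshold-volume granularity below
one voxel.

What the generators do **not** emulate — and hence what passing round-trip
tests cannot show about real data: projection-domain physics (attenuation,
scatter and collimator response are not simulated, only their corrections'
input formats), reconstruction artefacts (Gibbs ringing, noise
correlation), patient motion, background uptake heterogeneity, and
geometry errors of probe positioning. The measured-data pathway is
validated against the worked clinical example instead.

With three scans and 5% noise — the clinical lesion schedule — the
mono-exponential $\tilde A$ round-trip has an RMS error of about 4–5%
(median ~3%) across seeds; this is a property of the schedule, not of the
fitter, and is why the coverage fraction and $\tilde A$ uncertainty are
always reported.

## Uncertainties

First-order propagation throughout: Poisson sigmas on count rates, the
fit covariance propagated through the closed-form integral for
$\sigma_{\tilde A}$, $\sigma_S = |b|\,(\sigma_m/m)\,S$ through the mass
power laws, and uncorrelated quadrature for the product $\tilde A S$
(`propagate_product_uncertainty()`, with an optional correlation term).
The tests check the product rule against a 10⁶-sample Monte-Carlo oracle.
Published uncertainty tables in this field do not always state their
propagation method; this package's reported sigmas are its own first-order
estimates and need not match any specific published ± value.

## Problem sizes and tolerances in the test-suite

The suite runs entirely on synthetic data built at test time: 20-point
TAC designs for the selection studies (500 replicates for the F-test
calibration, 200 for AICc), 100 replicates for dead-time recovery, 32³–48³
voxel phantoms, and a 128² slice for the Chang closed-form check. These
sizes were chosen so that each statistical property is measured with a
standard error comfortably below the asserted bounds while the whole suite
runs in well under a minute.

## Known limitations

* Image reconstruction is out of scope: the SPECT module consumes
  reconstructed count-rate images; reconstruction parameters are
  provenance metadata only.
* Attenuation correction is uniform-μ Chang only (no CT-derived maps);
  masks are assumed co-registered.
* Tri-exponential models are the ceiling (`n_phases <= 3`); spectral
  analysis and population priors are not implemented.
* Cross-dose between regions is neglected, matching the sphere-model
  S-value approach; BED/EUD radiobiology is out of scope.
* The probe itself is not dead-time corrected; at the rates a 2-m
  geometry sees this is percent-level, and the camera dead-time functions
  can be reused on probe data if a counter needs characterisation.
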