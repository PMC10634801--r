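---
title: "Velocity-nulled laminar fMRI: model, generator and analysis choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Velocity-nulled laminar fMRI: model, generator and analysis choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(layervn)
```

## The vascular physics

Gradient-echo BOLD at laminar resolution is contaminated by draining veins
(intravascular, deep-to-superficial leakage) and by the extravascular field
of pial veins (blooming). `layervn` models the intravascular side with the
IVIM pseudo-diffusion picture: blood stepping through a randomly oriented
vessel network dephases like diffusion with coefficient `D*` determined by
the mean segment length `l` and velocity `v`. We use the convention

    D* = l * v / 10

which reproduces the standard values for all three compartments (capillary
1e-8, penetrating vein 2.5e-7, cortical artery 1.2e-6 m^2/s). The more
common kinetic-theory convention `l*v/6` does *not* reproduce that triplet
simultaneously, so `l*v/10` is adopted deliberately; users supplying their
own `D*` can bypass the convention entirely via `vessel_compartment()`.

A velocity-nulling bipolar gradient with weighting `b` (s/mm^2) retains

    S/S0 = exp(-b (D* + D_blood))

`D_blood` defaults to 0: for flowing compartments `D* >> D_blood`, and the
simplified mono-exponential form is the one the attenuation curves in this
package are built on. Internally all diffusivities are stored in mm^2/s so
the product with `b` in s/mm^2 is dimensionless by construction; the
constructors accept SI input and convert once, on ingestion.

Two critical-velocity routes are provided. When the waveform is known,
`critical_velocity_from_waveform()` evaluates `1/(2 gamma G Delta delta)`
directly. When only `b` is known, `critical_velocity_from_b()` uses the
scaling law for rectangular back-to-back lobes (`Delta = delta`) at fixed
gradient strength, where `b` grows as `delta^3` and `v_c` falls as
`delta^-2`, hence `v_c ~ b^(-2/3)`. The law is anchored at the
b = 6 s/mm^2, 16.8 mm/s operating point; it then yields 15.2 and
13.9 mm/s at b = 7 and 8. Because the actual `G`, `delta`, `Delta` of a
given sequence are rarely reported, the absolute scale is only ever anchored,
never derived; this is an inherent limitation of the b-only route.

The extravascular falloff is inverse-square, referenced to the vessel
*surface* (radius `= diameter/2`): `fold = (distance / radius)^2`. With that
reference a 0.3 mm vessel evaluated one 0.9 mm voxel away gives exactly a
36-fold reduction, which is the convention the package standardises on.

## The synthetic cortical column

`cortical_column_spec()` defines a 20-bin depth grid over `[-0.125, 1.0625]`
(0 = GM/WM, 1 = CSF/GM; the grid deliberately extends slightly past the
ribbon, matching surface-sampling practice, and the bound values are adopted
verbatim from that practice without a deeper geometric rationale). Defaults,
chosen once as representative of 3T submillimetre GE-BOLD and not revisited:

* `baseline = 100` a.u., so amplitudes read directly as percent.
* Task evoked tissue amplitude `amp_task = 2` a.u. (2% signal change).
* Resting laminar fluctuation SD `rest_sd = 1` a.u. (1%).
* `noise_sd = 0.5` a.u. thermal noise; phase noise SD is `noise_sd /
  baseline` radians, the small-angle limit of complex Gaussian noise at
  that SNR.
* `drain_fraction = 0.4`: the leakage model is a geometric cumulative
  drain — the vein compartment at depth k collects
  `sum_{j<=k} drain^(k-j) * laminar_j`, scaled by a vein-density weight
  that rises linearly with depth (`max(depth, 0)`), reflecting the linear
  deep-to-superficial increase of vessel density. This is the simplest
  linear, depth-causal operator consistent with "deep signal is carried
  upward"; the literature names the leakage model without formalising it,
  so the single-parameter geometric form is this package's design choice.
* Pial vessel: diameter 0.3 mm at the CSF/GM boundary, cortical thickness
  2 mm; its magnitude *and* phase perturbations scale as
  `(radius/distance)^2`. Tissue signal carries no phase. This minimal
  phase forward model — phase only where macrovasculature contributes —
  is exactly the assumption under which phase regression is valid, and is
  stated as such rather than hidden.
* Task paradigm: 30 s ON / 30 s OFF blocks at TR 4 s; 18 blocks = 270
  volumes for task, 300 volumes for rest. The default activation profile
  is double-peaked (depths 0.15 and 0.85, Gaussian width 0.1): motor-cortex
  tasks engage superficial input and deep output layers while sparing the
  middle, and the recovered double peak is the standard specificity
  benchmark.

Resting-state sources are unit-variance Gaussian processes band-limited to
0.01-0.1 Hz, one per (region, depth); network edges impose correlations
between depths falling in the canonical layer windows (superficial
0.85-0.9, middle 0.45-0.5, deep 0.1-0.15 — on the 20-bin grid each window
contains exactly one bin). The absolute vein-to-tissue amplitude ratio is
not established quantitatively in the literature; it is exposed as
`amp_vein` (default 1, making the superficial vein contribution comparable
to tissue, consistent with draining veins being the dominant GE-BOLD
contributor).

`make_subject_cohort()` draws one multiplicative parameter jitter per
subject (drainage, vein amplitude; relative SD 0.1) and simulates paired
conditions (default b = 0 and b = 7 s/mm^2) *sharing the subject's neural
sources*, so paired contrasts isolate the gradient effect. The default
cohort size is 14 subjects, the scale at which group-level laminar effects
become reliable.

What the generator does **not** emulate: 3-D vasculature and partial-volume
geometry, EPI/k-space artifacts, motion, physiological noise spectra,
T2*-blurring, and ICA-removable structured artifacts. Passing tests
therefore demonstrate internal consistency of the physics, conditioning and
statistics — not robustness to every real-data failure mode.

## Signal conditioning

Phase regression is OLS of magnitude on the temporally unwrapped phase,
returning residual plus voxel mean; it runs *before* temporal filtering so
magnitude and phase see identical processing up to that point. OLS (rather
than an orthogonal-distance variant) is used because the phase regressor in
this forward model is noise-poor relative to magnitude; ODR would be the
natural extension if phase noise dominated. A constant phase regressor is
degenerate and leaves the magnitude untouched with a warning.

Filters are order-4 Butterworth run forward-backward (zero phase, doubled
effective order), with the series demeaned first so DC is removed exactly:
band-pass 0.01-0.1 Hz for rest, high-pass 0.01 Hz for task. At TR = 4 s the
Nyquist frequency is 0.125 Hz; requesting an edge at or above it is an
error, not a silent clip.

The GLM uses the canonical double-gamma HRF (gamma shapes 6 and 16, unit
rates, undershoot ratio 1/6, peak normalised to 1) — "double gamma" without
stated parameters is taken to mean this community default. Percent signal
change is `100 * beta * peak-to-peak(regressor) / baseline` with baseline
the intercept estimate; confidence intervals are t-quantile times the OLS
standard error.

## Layering and connectivity

Equidistant layering partitions `[-0.125, 1.0625]` into half-open intervals
`[lo + (k-1)w, lo + kw)` with the last interval closed — the closure rule is
a fixed convention, since boundary sites must land somewhere
deterministically. Equivolume layering is out of scope. Nearest-neighbour
in-plane upsampling (default factor 5, e.g. 0.9 mm to 0.18 mm) replicates
voxels without interpolation so layer bins are populated without inventing
values.

Depth-FC matrices are pairwise Pearson correlations Fisher-z transformed,
diagonal masked (self-correlation is uninformative and would distort FDR).
Paired condition contrasts use element-wise paired t-tests with
Benjamini-Hochberg FDR across unmasked cells; BH is used for *all*
synthetic-grid statistics, including map-style outputs where surface-based
Monte-Carlo cluster correction would be used on real anatomy — cluster
geometry does not transfer to the synthetic grid. Seed FC maps follow the
dual convention: GLM t converted to a normal-quantile z for maps, Fisher z
of Pearson correlation for matrices; both are monotone in the underlying
correlation. Depth-FC matrices default to the full 20-depth grid; coarser
grids can be had by sampling layers first.

## Numerical notes

* `atanh`/`tanh` round-trip identically to ~1e-13 for |z| <= 4; beyond
  that, tanh saturation limits attainable accuracy (~1e-9 near |z| = 8),
  which the tests acknowledge rather than fight.
* Correlations at +-1 (constant or duplicated series) are masked as NA
  before the Fisher transform; the connectome path clips at 1 - 1e-15 only
  to guard against floating-point overshoot, never to rescue degenerate
  input.
* Band-limited series have fewer effective degrees of freedom than white
  series of the same length, so empirical correlation recovery is checked
  against a few multiples of the nominal Fisher SE `1/sqrt(n-3)`.
* All generators consume an explicit integer seed and are bit-reproducible;
  stochastic calls without a seed are an error rather than silently
  nondeterministic.

## Problem sizes

The validation suite runs the full pipeline at the generator's native
scale — 14-subject cohorts, 20 depths, 300-volume runs — for the paired
contrast, and repeats smaller cohorts (6-8 subjects) across 50-100 seeds
for the planted-edge recovery and null-calibration studies; these sizes give
stable Monte-Carlo estimates while keeping the whole suite under a minute
on a laptop.

## Limitations

The leakage operator, the phase forward model and the vein/tissue amplitude
ratio are principled but idealised; none is fitted to data. The b-only
critical-velocity route assumes the rectangular equal-lobe waveform. The
generator's noise is white complex Gaussian — real laminar fMRI noise is
structured — so statistical power measured here is an upper bound, and
FDR calibration on real data depends on assumptions (exchangeability across
cells) the synthetic grid satisfies by construction.
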