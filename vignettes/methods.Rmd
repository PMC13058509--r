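---
title: "Models and methods behind pocte"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind pocte}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(pocte)
```

`pocte` models the computational chain of an imaging-guided point-of-care
transient elastography (TE) system on simulated inputs. This vignette
documents the models, their assumptions, the tunable parameters, and the
design decisions taken where the problem was genuinely open, so that every
number the package produces can be traced to an explicit mechanism.

## The forward model

### Tissue phantoms

A phantom is a one-dimensional stack of skin, subcutaneous and liver layers,
each with a Young's modulus $E$ (kPa), an attenuation coefficient
$\alpha_0$ (dB/cm/MHz, linear-in-frequency intensity convention) and a
relative echogenicity; vessels are anechoic disks confined to the liver.
The skin-to-liver-capsule distance (SCD) is by construction the summed skin
and subcutaneous thicknesses. Validation enforces $E \in [1, 100]$ kPa and
$\alpha_0 \in [0, 2]$ dB/cm/MHz; `strict = FALSE` relaxes the attenuation
ceiling to 5 dB/cm/MHz for deliberately non-physiologic stress phantoms used
to probe the output clamp of the attenuation estimator.

### Shear-wave propagation

The 50-Hz surface vibration launches a travelling wave

$$u(z, t) = A(z)\,\sin\!\big(2\pi f\,(t - \tau(z))\big), \qquad t \ge \tau(z),$$

with $u = 0$ before the wavefront arrives (causality), per-layer shear speed
$c_s = \sqrt{E / 3\rho}$ ($\rho$ = 1000 kg/m³, the TE convention), and
piecewise travel time $\tau(z)$. The surface peak-to-peak amplitude equals
the acquisition mode's vibration setting (2 mm standard, 3 mm enhanced).
Amplitude decays as $A(z) = A(0)\,e^{-z/\delta}$ with $\delta$ = 60 mm; no
published value constrains the decay length, so it was chosen once as a
plausible combined geometric/viscous loss over the liver window and is a
config parameter, not a fitted quantity. The model is deliberately
one-dimensional: mode conversion, reflections and diffraction of the shear
wave are out of scope.

### RF synthesis

Each A-line holds uniformly random sub-resolution scatterers at 16 per mm —
about 13 per axial resolution cell at the default pulse, i.e. fully
developed speckle — with Gaussian amplitudes scaled by layer echogenicity
and suppressed (×0.02) inside vessels. The received line is the scatterer
impulse train convolved with a zero-phase Gaussian-modulated 3.5-MHz pulse
(60% fractional bandwidth) at 20 MHz sampling and 1540 m/s sound speed.
Attenuation is applied in the frequency domain per 3-mm depth bin as the
amplitude factor $10^{-A(z)f/10}$, where $A(z)$ accumulates
$\alpha_0 \times \text{path}$ over the traversed layers — so the power
spectrum of gated RF decays at $2\alpha_0 f$ dB per cm of depth, the
round-trip intensity convention the estimator inverts. Layer boundaries
deposit a coherent specular echo (25× unit speckle amplitude) so the
capsule is visible on B-mode. When a displacement field is supplied, each
frame's scatterers are shifted axially by $u(z, t)$ with linear-interpolated
deposition onto the sample grid; the slow-time frame rate is 2000 Hz (40×
the vibration frequency). Lateral beamforming is not modelled: lines are
independent and mapped to a rectilinear grid for masking purposes only.

B-mode formation is analytic-signal envelope detection followed by log
compression plus the mode gain, so gain acts as an exact constant dB offset.

## The stiffness chain

Displacement tracking uses windowed normalized cross-correlation between
consecutive frames (window 1.5 mm, 75% overlap, search ±0.5 mm) with
parabolic sub-sample refinement; ties in the correlation peak resolve to
the first lag so the chain stays bit-reproducible. Windows whose peak
correlation falls below 0.5 are flagged and interpolated along depth. The
resulting depth × slow-time axial-velocity map, restricted to the mode's
measurement range, is the elastogram. The noise floor of this tracker is
set by the sub-sample interpolation, a few µm/ms against wave crests of
hundreds of µm/ms.

Quality control is deterministic and rule-based, replacing the device's
learned classifier with transparent surrogates for the same six criteria.
The primary trajectory is extracted as the first-crest ridge: per depth row,
the first local maximum reaching 70% of the row maximum (rows below 25% of
a robust row-maximum scale are invalid). Scores in $[0,1]$: intensity (95th
percentile of $|m|$ against a 20 µm/ms reference), length (ridge depth
extent over the measurement range), linearity ($R^2$ of the ridge line
fit), continuity ($1 -$ largest gap fraction within the ridge span),
parallelism (slope agreement between depth halves) and background noise
($1 -$ pre-arrival RMS over on-ridge RMS — causality makes the pre-arrival
region the physically meaningful noise reference; the later crests of the
50-Hz cycle are signal, not background). Thresholds default to 0.5 except
continuity at 0.75: with the largest-gap definition, a map missing a third
of its ridge still scores 0.67, so a 0.5 threshold could not reject that
canonical defect while 0.75 cleanly separates clean simulations (which
score above 0.95) from constructed gaps. The device's numeric thresholds
are unpublished; these are calibrated on simulations only.

Trajectory detection is an exhaustive line-integral (Hough/Radon-style)
transform: slopes are gridded uniformly in slowness so that line-timing
resolution is one time bin across the depth span, onsets over every time
bin, and the score is the mean signed velocity along the line. Because all
crests of the periodic wave are equally tall, each row is first masked to a
causal window around its first strong crest (1 ms before to 4 ms after), so
the detected line is the primary wavefront; for synthetic line images the
mask can be disabled. The global maximum is refined by parabolic
interpolation of the slowness profile; exact ties break toward the lower
slope. The search band is 0.5–5.0 m/s (≈0.75–75 kPa). A detection is
accepted only if the mean of the raw map along the detected line exceeds
the raw-map RMS (fit score ≥ 1): a featureless map cannot push this ratio
much above 0.5, while genuine wavefronts sit well above it. Stiffness
follows as $E = 3\rho c_s^2$, and an acquisition is valid only if QC
passed.

## The attenuation chain

Segmentation takes the region below the deepest capsule interface (located
as in SCD measurement) within 20–100 mm, then excludes pixels whose axial
intensity gradient magnitude exceeds the 99th percentile — vessel walls and
bright heterogeneities — from the samples passed to spectral analysis. The
mask-quality liver fraction is assessed on the candidate region *before*
the gradient exclusion: against ground-truth labels when the phantom
geometry is supplied, else by intensity homogeneity (±12 dB of the region
median). Scoring the candidate region keeps the fraction an unbiased
measure of what the ROI contains; scoring after exclusion would let the
denoiser flatter the ROI by discarding exactly the pixels that should count
against it. The qualification rule is strict: liver fraction > 0.80, with
0.80 itself failing.

Spectra: 256 lines in 8 blocks of 32 (the sampling-volume improvement over
single-line devices; the relation between the two published line counts is
our interpretation), 6-mm Hann-gated depth windows at 50% overlap across
20–100 mm, periodograms averaged within blocks, cells with under 50% masked
samples dropped, block average in dB. Attenuation estimation is the
reference-phantom spectral-difference method: the sample/reference
log-spectral ratio is regressed on depth per frequency bin,
$\alpha(f) = -\text{slope}/2$ (dB/cm), and a second regression on frequency
yields the raw slope in dB/cm/MHz relative to the reference. Ratioing
cancels every depth-independent factor — pulse spectrum, gain, diffraction —
which is why the final MAP is exactly invariant to rescaling the RF. The
usable band is where *both* profiles hold power within 20 dB of their
peaks; the symmetric definition makes swapping sample and reference negate
the estimate exactly. A pure adjacent-band variant (`method = "adjacent"`,
no reference) is retained behind a flag. Calibration is a least-squares
affine map from raw slopes to known dB/m at 3.5 MHz (conversion
$\alpha_0 \to \alpha_0 \times 3.5 \times 100$), fitted on at least two
reference phantoms; the reported MAP is clamped to [100, 400] dB/m and
valid only under a qualified mask.

## The exam protocol

A survey B-mode frame measures the SCD on the midline A-line: the envelope
is smoothed (0.15 mm), normalized by a rolling background RMS (±2.5 mm,
excluding the central ±0.6 mm so a specular echo is judged against
surrounding speckle rather than itself), and the deepest local maximum with
ratio above 6 within 0.5–45 mm is the capsule. The mode is selected once
per exam — enhanced strictly above 20 mm — keeping exams deterministic;
whether the device re-evaluates mid-exam is unknown, and a single selection
is the reproducible reading. Acquisitions repeat until ten pass QC or 20
attempts elapse; medians and IQR/median ratios use the first ten valid
acquisitions (the device stops at ten; the ≥10 rule governs validity only),
and an exam with fewer than ten valid measurements is a measurement
failure. Per-acquisition scatter arises entirely from the speckle seed.

## The synthetic cohort generator

The generator emulates the *joint structure* of a biopsy cohort: exact
quota allocation over the configured stage prevalences (largest-remainder
rounding; 15/57/39/17/10 of 138 for fibrosis, 10/43/54/29 over grades for
steatosis), log-normal within-stage true stiffness with per-stage medians
(4.6, 6.2, 8.6, 11.5, 18.5 kPa; within-stage log-SD 0.30) chosen once so
that Youden cut-offs estimated on large synthetic cohorts land in the
clinically used bands — a calibration, not ground truth —, normal
within-grade true attenuation (215, 262, 280, 305 dB/m, SD 28), and
multiplicative log-normal repetition noise per device. The noise scale
targets the *observed* median per-patient IQR/median of ten repetitions
(21% point-of-care LSM, 12% conventional LSM, 10% both attenuation
parameters); because the sample IQR of ten draws is biased low relative to
the population IQR, the calibration divides by the expected finite-sample
IQR fraction, evaluated once by a fixed-seed Monte Carlo.

The conventional device is represented only as a correlated, biased
comparator: its latent value shares the log-scale truth plus an independent
disagreement term whose variance is solved in closed form from the mixture
moments of the bivariate log-normal so that the raw-scale Pearson
correlation between per-patient medians hits the target (0.86 stiffness,
0.80 attenuation), and an offset then sets the mean bias (+0.6 kPa,
+29 dB/m, point-of-care minus conventional). Median-of-ten noise enters
these moments through the asymptotic sample-median variance
$\pi\sigma^2/2n$; the residual approximation error is well inside the ±0.03
self-consistency tolerance checked in the tests. Laboratory values shift
with fibrosis stage so the serum scores (FIB-4, APRI with AST upper limit
of normal fixed at 40 IU/L, NFS and HSI, coefficients from their original
publications) are diagnostically informative; a small missing-serology
fraction propagates to missing scores.

What the generator does **not** emulate: histologic misclassification,
probe-position or operator effects, aetiology structure, longitudinal
change, and any real joint distribution between labs and imaging beyond
the monotone stage trends. Passing tests therefore demonstrate the
correctness and internal calibration of the pipeline, not clinical
performance on real patients.

## Statistics

AUROC uses the midrank (Mann–Whitney) estimator with DeLong placement
variance and a normal 95% CI on the untransformed scale (matching the
symmetric intervals customary in accuracy tables), the positive-call
convention being value ≥ cutoff. Youden ties break toward the lowest
cutoff (maximizing sensitivity at equal J); fixed-operating-point cutoffs
maximize the complementary rate subject to sensitivity (or specificity)
≥ 0.9. The paired DeLong test uses the covariance of placement values, with
identical rankings reported as a degenerate p = 1. The ICC is the two-way
absolute-agreement single-measurement form — the form that penalizes
systematic offsets, which is the relevant property for device agreement;
the published analyses do not state their form. Kappa weights are linear by
default (quadratic behind a flag), Dunn post hoc p-values unadjusted by
default (an adjustment method is a parameter), the Wilcoxon signed-rank
test drops zero differences and is exact up to 25 untied differences. The
Hanley–McNeil sample-size solver returns the smallest n whose SE meets the
target; a CI-width variant divides the width by $2 \times 1.96$. The two
published planning statements (5% SE; CI width 0.125) are mutually
inconsistent, which is why both solvers exist. Note the Hanley–McNeil
variance is not symmetric in prevalence, so the minimizing prevalence sits
above 0.5 for AUROC above one half.

The sufficiency analysis compares median subsets of k = 1..10 repetitions
(first-k, or one random draw per patient per k under a cohort-level seed;
`replicates` averages metrics over several draws since whether published
random columns are single draws is unstated) with the 10-measurement
reference on the same patients — complete-case and paired, as the paired
DeLong test requires. The k = 10 rows are exact self-comparisons by
construction.

## Numerical choices and degenerate inputs

Sub-sample refinements use three-point parabolic interpolation clamped to
±0.5 bin. All RNG flows through scoped seeds that restore the caller's
state. Degenerate inputs have defined behaviour rather than errors where a
flag is more faithful to device behaviour: unqualified masks still report a
(flagged) MAP; failed QC yields an invalid NA stiffness; all-zero paired
differences give p = 1; zero total variance gives an undefined-flag ICC;
all-tied group values give H = 0. Hard errors are reserved for contract
violations (non-physical phantom parameters, missing classes, k outside
1..10, degenerate calibrations).

Problem sizes in the test-suite were chosen to keep the full run in a few
minutes on one CPU while leaving clear margins: stiffness-recovery ladders
use six moduli spanning 2–60 kPa with ten acquisitions each; attenuation
recovery uses 256-line frames over 20–100 mm; cohort-level checks use 138,
500 or 1455 patients depending on whether exactness, trend stability or
correlation calibration is being tested; the DeLong-versus-bootstrap check
uses 2000 resamples at n = 100.

## Known limitations

The forward model is a surrogate: no full-wave acoustics, no beamforming,
no probe-motion artifacts, and the learned components of the real device
(elastogram quality classifier, transformer-based trajectory detector,
segmentation networks) are replaced by classical rule-based counterparts
that honour the same contracts but are not reconstructions of the
proprietary algorithms. Cohort-level accuracy numbers produced on synthetic
cohorts reflect the generator's calibration, not clinical evidence.
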