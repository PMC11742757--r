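---
title: "Spectral parameterization and group inference in periospec"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectral parameterization and group inference in periospec}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(periospec)
library(dplyr)
```

`periospec` analyses resting-state EEG spectra from young clinical
cohorts. This vignette documents the models and procedures the package
implements, the parameters that matter, the design decisions taken where
the design was genuinely open, and what validation on synthetic data does
and does not establish.

## The spectral model

A power spectrum is modeled in log10 space as an aperiodic `1/f^χ`
background plus Gaussian oscillatory peaks:

$$\log_{10} P(f) \;=\; \mathrm{offset} - \chi \log_{10} f
  \;+\; \sum_k a_k \exp\!\left(-\frac{(f - c_k)^2}{2\sigma_k^2}\right)
  \;+\; \varepsilon$$

* **offset** — log10 power at 1 Hz (log10(µV²/Hz)); the height of the
  broadband, non-oscillatory background. Higher offsets indicate more
  broadband neuronal activity.
* **χ (exponent)** — steepness of the background; linked to
  excitation–inhibition balance in the field's interpretation. χ ≥ 0.
* **peaks** — each oscillation has a center frequency `c` (Hz), a height
  `a` in log10 power above the background, and a bandwidth reported as
  `2σ` (Hz). The 2·SD convention makes simulated and fitted bandwidths
  directly comparable with the 0.5–18.0 Hz limits used during fitting.
* **ε** — i.i.d. Gaussian noise per frequency bin, in log10 space.

Noise is placed in log10 space deliberately: parameterization also works
in log10 space, so recovery tolerances are analytically predictable and
the ensemble mean of simulated spectra converges to the noiseless curve.

## Spectral estimation

Recordings are segmented into non-overlapping 2-s epochs (trailing
remainders discarded); epochs in which any channel exceeds 40 µV absolute
amplitude are rejected; and files enter the analysis only if they retain
at least 20 good segments, more than 80% good channels, and a retained
artifact probability strictly below 0.3. Gates whose inputs are missing
produce an explicit `"ungateable"` decision rather than a silent pass.
Artifact probability and channel quality are not computable from
amplitude-only synthetic input, so they may be supplied as pass-through
metadata.

PSDs are estimated by the multitaper method. The stated taper count of
three is realized as discrete prolate spheroidal (Slepian) sequences with
time–bandwidth product NW = 2 (K = 2NW − 1 = 3), computed in-package via
the standard symmetric tridiagonal eigenproblem. Eigenspectra are
combined with equal weights — the simplest defensible convention when no
weighting is stated — and averaged across epochs; with 2-s epochs the
native grid spacing is 0.5 Hz. Epoch overlap is not used. Multitaper
output is checked in the tests against Parseval (sinusoid total power
A²/2) and white-noise (σ²/(fs/2) per Hz) oracles.

Time-series synthesis, used to exercise the estimation stage on raw-like
input, imposes the model PSD on a random-phase Fourier spectrum
(circularly stationary). Bursty or non-stationary oscillations are not
modeled; no analysis stage depends on them.

## Parameterization

`parameterize_spectrum()` decomposes each spectrum over 2–55 Hz in fixed
mode (no spectral knee):

1. **Robust aperiodic fit.** An ordinary straight-line fit of log10 power
   on log10 frequency, then a re-fit restricted to the bins whose
   non-negative-clipped residual lies at or below the 2.5th percentile —
   the bins hugging the 1/f envelope below the oscillatory peaks. This
   reproduces peak-insensitive behavior without borrowing any
   implementation.
2. **Iterative peak detection.** The maximum of the flattened residual is
   taken as a peak candidate; detection stops when the candidate height
   falls below 2 standard deviations of the current residual (the "peak
   threshold 2" convention), below the optional absolute
   `min_peak_height`, or below a 1e-6 numerical floor that suppresses
   floating-point residue on noiseless input. A Gaussian guess (SD from
   the half-height width) is subtracted and the search repeats, up to 7
   peaks. Ties between equal maxima resolve to the lower frequency.
3. **Joint refit.** All Gaussians are refit together by bounded
   Levenberg–Marquardt least squares (centers constrained near their
   guesses, heights non-negative, SDs bounded); peaks whose fitted
   bandwidth leaves 0.5–18.0 Hz are discarded.
4. **Final aperiodic re-fit** on the peak-removed curve, from which the
   periodic spectrum (log10 spectrum minus aperiodic curve) and the
   model R² are computed.

Fits with R² < 0.90 are flagged (`flag_poor_fit`), never dropped: no
goodness cut is part of the analysis definition, so downstream users
decide. Degenerate inputs fail loudly: non-positive power anywhere in the
fit range is an error (log domain), as is a spectrum not covering the
range.

Measured recovery under the package's study conditions (χ between 0.5
and 2, peaks of amplitude ≥ 0.3 at 10 and 20 Hz, noise SD 0.05): offset
and exponent bias below 0.05 and peak-center RMSE below 0.5 Hz — these
are asserted by the test suite, not assumed.

## Features

Band powers are trapezoidal integrals over inclusive band edges — theta
4–5, alpha 6–11, low beta 12–19, high beta 20–29, broad beta 12–29,
gamma 30–44 Hz — computed for three curves: the absolute spectrum and
the fitted aperiodic curve (linear power), and the periodic curve (log10
residual). Inclusive edges are safe because the printed bands are
integer-bounded and non-adjacent on the 0.5 Hz grid, so no bin is counted
twice.

Regions of interest average channels bin-wise: frontal electrodes
{24, 124, 11, 28, 117, 19, 4} and posterior {70, 75, 83, 67, 77}
(high-density geodesic net numbering). Peak search runs on the
ROI-averaged periodic curve, matching per-child, per-ROI reporting;
missing electrodes are tolerated (mean over those present, recorded in
provenance columns) but an empty ROI is an error.

A band peak is the largest *interior* local maximum: a bin strictly
greater than its closest differing neighbors on both sides, with plateaus
assigned to their lowest-frequency bin. Band-edge bins can never be
peaks; a curve with no interior maximum yields an explicit absent-peak
flag rather than an edge value. Peak power is reported in log10 units;
peak frequency stays in Hz — group means in this literature are reported
on the Hz scale, so the log transform is applied to power only. Broad
beta (12–29 Hz) is the primary peak-analysis band because individual
peaks fall on the low/high beta cusp near 20 Hz.

## Clinical scoring

The seizure-severity composite sums three components: seizure frequency
over the last two months on a 0–4 ordinal scale (0 = none, 1 = less than
monthly, 2 = monthly, 3 = weekly/daily, 4 = more than daily — the
intermediate anchors interpolate the two printed endpoints and are a
labeled, configurable convention), the number of current anti-epileptic
medications capped at 6, and the number of distinct seizure types capped
at 5. Classes: low 0–2, moderate 3–7, high ≥ 8. The printed composite
range of 0–12 is inconsistent with the component maxima (4 + 6 + 5 = 15);
totals above 12 are therefore allowed, classed high, and flagged
(`over_printed_range`) instead of truncated. Missing components give an
explicit unscoreable outcome.

Medications map to GABAergic / non-GABAergic mechanism classes through a
config-supplied two-column ontology; a child is `on_gaba` with at least
one GABAergic medication, `unclassified` when an unknown name appears
and no known GABAergic drug does (never a silent default). Developmental
quotients are 100 × age-equivalent / chronological age, averaged into
nonverbal (visual reception, fine motor) and verbal (expressive,
receptive language) scores.

Case–control matching is greedy: the case whose best available same-sex
control is nearest in age is matched first, ties broken by lower subject
id. Greedy matching was chosen over optimal assignment for transparency;
the test suite quantifies the gap against an exhaustive optimum on small
instances (greedy total age gap ≥ optimal, typically equal on
well-populated pools). Unmatched cases are reported, never dropped.

## Group statistics

**Cluster permutation.** Per-bin pooled-variance two-sample t statistics
over 2–44 Hz; bins with |t| above the two-sided critical value at α =
0.05 form clusters, contiguous in frequency with positive and negative
signs clustered separately; the cluster statistic is the summed t. The
null is the distribution of the maximum |cluster sum| under unpaired
label permutation (the cohorts are matched, but no paired scheme is
stated for this test; an unpaired shuffle is the standard default), with
the +1 correction so p-values are never exactly zero. Subjects are
canonicalized by id and group levels sorted alphabetically, making
results invariant to input row order and exactly label-exchange
symmetric. Degenerate bins with zero pooled variance and equal means
carry t = 0. Measured calibration on null cohorts (n = 20/group) puts the
family-wise rate of any cluster p < 0.05 near the nominal 5%.

**Logistic regression** of group status on frontal/posterior offset and
exponent: maximum-likelihood binomial fit, Wald standard errors, odds
ratios with 95% CIs as exp(β ± 1.96 SE). Rank deficiency is an error;
quasi-complete separation is detected (fitted probabilities pinned at the
boundary) and flagged with diagnostics instead of surfacing as a silently
enormous odds ratio — with strong group differences in a small sample
this is a real outcome, not a failure.

**ANOVA.** The frontal broad-beta peak amplitude model
`amplitude ~ severity + GABA + severity:GABA` uses sequential (Type I)
sums of squares by default, with Type II available for unbalanced
sensitivity analysis; severity enters as a three-class factor (the
stratification low/moderate/high is how results are reported, rather
than the raw ordinal score). An empty factorial cell drops the
interaction with a warning recorded in the result. Tukey HSD post-hocs
use the studentized range with Tukey–Kramer handling of unequal cell
sizes; with two groups they reduce exactly to the pooled t-test.

No multiple-testing correction is applied across ROIs or curve types;
results are per-analysis, matching the analysis definition.

## The synthetic cohort generator

`simulate_cohort()` is first-class, tested code that defines the study
conditions. Defaults: 49 children per group (the study's size); TD
children carry alpha (8 Hz, 0.40), low-beta (16 Hz, 0.18) and high-beta
(25 Hz, 0.18) peaks; TSC children carry alpha plus a single ~20 Hz beta
peak whose amplitude receives a +0.3 group increment, +0/+0.05/+0.25 for
low/moderate/high severity class, and +0.15 when on a GABAergic
medication — the increment spacing follows the direction and relative
size of the reported stratified group means, while absolute levels are
free parameters of the generator, not claims about TSC physiology. TSC
posterior channels receive a +0.3 aperiodic offset increment.
Between-subject SDs: 0.1 (offset, exponent, peak amplitude), 0.5 Hz
(peak centers); per-bin noise SD 0.05. Severity components (frequency,
medication count, type count) are drawn jointly so the clinical table
rescoring reproduces the assigned class exactly, medication lists are
consistent with the GABA flag, and ages (12–37 months), sex (51% male)
and Mullen age-equivalents mirror the cohort's demographics. Covariates
act by explicit per-class increments rather than a latent model so ANOVA
recovery tests have exact ground truth.

What the generator does *not* emulate: artifacts (blinks, motion), ICA
residue, channel covariance structure, non-stationary oscillatory bursts,
age-dependent spectra, or raw vendor formats. Passing tests therefore
demonstrate that the pipeline recovers known spectral and covariate
structure under clean, stationary conditions — they do not certify
performance on artifact-laden real recordings.

## Numerical choices and problem sizes

Tolerances: aperiodic recovery is tested at |bias| < 0.05, peak centers
at RMSE < 0.5 Hz (one bin), cluster calibration within [0.02, 0.10]
family-wise. Validation problem sizes were chosen to make Monte-Carlo
error small relative to those tolerances while keeping the default test
run brief: 100 spectra per exponent condition for recovery, 200 null
datasets at 500 permutations for calibration, 50 repeats for cluster
power and for ANOVA effect recovery (48 cases per repeat with balanced
severity classes so all six severity × GABA cells fill). The acceptance
script uses the same machinery at comparable sizes with every random
draw derived from its `--seed`.

## Known limitations

* The aperiodic model is fixed-mode only; spectra with a genuine knee
  will show inflated fit error (and the poor-fit flag) rather than a
  knee estimate.
* Very wide peaks (bandwidth approaching the 18 Hz limit) are hard to
  distinguish from aperiodic curvature; the robust fit protects the
  exponent but wide-peak height estimates are less reliable.
* Greedy matching does not guarantee the minimum total age gap.
* Separation in the logistic model is reported, not resolved; no
  penalized (e.g. Firth) fallback is provided.
* The cluster test assumes a common frequency grid; it does not
  interpolate.
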