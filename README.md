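# periospec

Resting-state EEG spectral biomarkers for early-childhood clinical cohorts,
with a focus on periodic (oscillatory) beta power in Tuberous Sclerosis
Complex (TSC) versus typical development (TD).

## The problem

Young children with TSC show a markedly elevated beta-band oscillation
around 20 Hz in resting EEG, and both seizure burden and GABAergic
anti-epileptic medication are independently associated with its amplitude.
Testing such claims requires a chain of spectral and statistical machinery:
power spectral density estimation, separation of the spectrum into an
aperiodic `1/f^χ` background and oscillatory peaks, band/peak feature
extraction over scalp regions of interest, clinical covariate scoring, and
group-level inference. `periospec` implements that chain as a tested,
reusable, tidyverse-native pipeline, together with a synthetic-cohort
generator with known ground truth so that every stage can be validated
end to end.

## The model

Each power spectrum is modeled in log10 space as

    log10 P(f) = offset − χ · log10(f) + Σ_k a_k · exp(−(f − c_k)² / (2 σ_k²)) + ε

where `offset` and the exponent `χ` describe the aperiodic background,
each Gaussian term is an oscillatory peak with center `c_k` (Hz), height
`a_k` (log10 power above the background) and bandwidth `2σ_k` (Hz), and
`ε` is per-bin noise. Fitting is done in fixed mode (no spectral knee)
over 2–55 Hz with a robust two-pass aperiodic fit, iterative peak
detection (at most 7 peaks, threshold 2 SD of the flattened residual,
bandwidths limited to 0.5–18 Hz), a joint bounded nonlinear refit of all
peaks, and a final aperiodic re-fit on the peak-removed curve. The
periodic spectrum is the log10 spectrum minus the fitted aperiodic curve.

Group-level inference includes cluster-based permutation testing over
2–44 Hz frequency bins (pooled-variance t, max-cluster-statistic null,
1000 permutations), logistic regression of group status on the four
aperiodic features (frontal/posterior offset and exponent) with odds
ratios and Wald CIs, a two-way ANOVA of frontal broad-beta (12–29 Hz)
peak amplitude on seizure-severity class × GABAergic medication use with
Tukey HSD post-hocs, paired t-tests and Pearson correlations. Seizure
severity is an E-Chess-style composite (frequency 0–4, plus number of
anti-epileptic medications capped at 6, plus number of seizure types
capped at 5; low 0–2, moderate 3–7, high ≥ 8).

## Worked example

```r
library(periospec)
library(dplyr)

# A known spectrum: 1/f^1.4 background plus alpha (10 Hz) and beta (20 Hz) peaks
m <- spectrum_model(offset = 0.8, exponent = 1.4,
                    peaks = rbind(gaussian_peak(10, 0.4, 3),
                                  gaussian_peak(20, 0.3, 3)),
                    noise_sd = 0.05)
sp  <- simulate_spectrum(m, seq(1, 64, 0.5), seed = 42)
fit <- parameterize_spectrum(sp)
fit
#> <parameterized_spectrum> offset=0.834 exponent=1.419 R2=0.9913, 2 peak(s)
#> # A tibble: 2 × 3
#>   center_freq amplitude bandwidth
#>         <dbl>     <dbl>     <dbl>
#> 1        10.1     0.324      3.25
#> 2        20.1     0.251      3.17
```

Both injected peaks are recovered within a bin of their true centers, and
the aperiodic offset/exponent within a few percent, at the realistic noise
level. On a synthetic cohort the full chain reproduces the case–control
beta contrast:

```r
coh   <- simulate_cohort(cohort_config(n_per_group = 25, seed = 7))
feats <- extract_features(coh$spectra)
per   <- periodic_table(feats$fits) |> filter(roi == "frontal")
cl    <- cluster_permutation_test(per, "periodic_log10", "group",
                                  "subject_id", n_perm = 1000, seed = 7)
tidy(cl) |> filter(p_value < 0.05)
#> # A tibble: 3 × 5
#>   freq_lo freq_hi cluster_stat  sign  p_value
#>     <dbl>   <dbl>        <dbl> <dbl>    <dbl>
#> 1    12.5    15           24.8     1 0.0320
#> 2    16.5    23.5       -220.     -1 0.000999
#> 3    25      29.5         49.6     1 0.000999
```

The dominant cluster (16.5–23.5 Hz, p ≈ 0.001) is the injected ~20 Hz
case excess; group levels sort alphabetically ("TD" first), so the
negative sign means TSC power exceeds TD there. The flanking positive
clusters are where the two TD beta peaks (16 and 25 Hz) exceed the
single-peak TSC spectrum. Group-mean frontal broad-beta peak amplitudes
(log10 units) come out as TD 0.24 vs TSC 0.58, matching the configured
group-plus-covariate increments.

A full on-disk run (simulate → parameterize → features → clinical →
stats, with JSON logs and checksum-based resumption):

```r
run_pipeline(run_config(output_dir = "run1", seed = 1))
```

or from the shell: `Rscript scripts/periospec-cli.R all --seed 1 --out run1`.

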