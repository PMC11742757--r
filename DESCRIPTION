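Package: periospec
Title: Periodic and Aperiodic EEG Spectral Biomarkers in Early-Childhood Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A tidyverse-native pipeline for resting-state EEG spectral
    biomarker analysis in young clinical cohorts: multitaper power spectral
    density estimation, decomposition of spectra into an aperiodic 1/f
    background and periodic Gaussian peaks, band-power and band-peak feature
    extraction over frontal and posterior regions of interest, seizure
    severity and GABAergic medication stratification, and group-level
    inference (frequency-bin cluster permutation tests, logistic regression
    on aperiodic features, two-way ANOVA with Tukey HSD, paired t-tests,
    correlations). Includes a synthetic-cohort generator with known ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    ggplot2,
    generics,
    stats,
    tools,
    minpack.lm,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    broom,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
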