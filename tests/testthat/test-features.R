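test_that("ROI averaging is the bin-wise mean over available electrodes", {
  freqs <- seq(1, 64, by = 0.5)
  frontal <- c("24", "124", "11", "28", "117", "19", "4")
  base <- simulate_spectrum(spectrum_model(1, 1.2), freqs)
  curves <- dplyr::bind_rows(lapply(frontal, function(ch) {
    dplyr::mutate(base, subject_id = "S1", channel = ch)
  }))
  # identical channels: output equals any input
  frontal_def <- roi_definitions()[roi_definitions()$roi == "frontal", ]
  avg <- roi_average(curves, frontal_def)
  fr <- avg[avg$roi == "frontal", ]
  expect_equal(fr$power_uv2_per_hz, base$power_uv2_per_hz)
  expect_equal(unique(fr$n_missing), 0)

  # posterior has zero channels here: only requesting it errors
  post_only <- roi_definitions()[roi_definitions()$roi == "posterior", ]
  expect_error(roi_average(curves, post_only), "posterior")

  # two channels with values 1 and 3 average to 2; order is irrelevant
  two <- tibble::tibble(subject_id = "S1",
                        channel = rep(c("24", "124"), each = 2),
                        freq_hz = rep(c(10, 11), 2),
                        power_uv2_per_hz = c(1, 1, 3, 3))
  fr2 <- roi_average(two, frontal_def)[, "power_uv2_per_hz"]
  expect_equal(fr2$power_uv2_per_hz, c(2, 2))
  two_rev <- two[rev(seq_len(nrow(two))), ]
  expect_equal(roi_average(two_rev, frontal_def), roi_average(two, frontal_def))
})

test_that("band powers follow the trapezoidal integral", {
  freqs <- seq(2, 55, by = 0.5)
  const <- rep(3, length(freqs))
  expect_equal(band_power(freqs, const, 12, 29), 3 * 17)
  expect_equal(band_power(freqs, rep(0, length(freqs)), 12, 29), 0)
  expect_error(band_power(freqs, const, 50, 60), "support")
  # linearity
  curve <- sin(freqs / 5) + 2
  expect_equal(band_power(freqs, 4 * curve, 6, 11),
               4 * band_power(freqs, curve, 6, 11))
})

test_that("broad beta power dominates low+high beta on absolute spectra", {
  freqs <- seq(1, 64, by = 0.5)
  for (s in 1:10) {
    m <- spectrum_model(runif(1, 0, 1), runif(1, 0.5, 2),
                        gaussian_peak(runif(1, 8, 30), runif(1, 0.1, 0.6),
                                      runif(1, 2, 6)), noise_sd = 0.05)
    sp <- simulate_spectrum(m, freqs, seed = s)
    p <- sp$power_uv2_per_hz
    broad <- band_power(freqs, p, 12, 29)
    lo <- band_power(freqs, p, 12, 19)
    hi <- band_power(freqs, p, 20, 29)
    expect_gte(broad, lo + hi)   # 19-20 Hz gap is non-negative
  }
})

test_that("band peaks are interior local maxima, never edges", {
  freqs <- seq(2, 55, by = 0.5)
  # injected Gaussian at 20 Hz
  curve <- periospec:::gaussian_curve(freqs, 20, 0.5, 1.5)
  pk <- find_band_peak(freqs, curve, 12, 29)
  expect_true(pk$peak_found)
  expect_lte(abs(pk$peak_freq - 20), 0.5)

  # strictly decreasing curve: absent peak, not an edge bin
  dec <- find_band_peak(freqs, -freqs, 12, 29)
  expect_false(dec$peak_found)
  expect_true(is.na(dec$peak_freq))

  # two local maxima: the larger one wins regardless of frequency order
  curve2 <- periospec:::gaussian_curve(freqs, 14, 0.5, 1.5) +
    periospec:::gaussian_curve(freqs, 24, 0.3, 1.5)
  pk2 <- find_band_peak(freqs, curve2, 12, 29)
  expect_equal(pk2$peak_freq, 14)

  # plateau takes its lowest-frequency bin
  flat_top <- rep(0, length(freqs))
  sel <- freqs >= 18 & freqs <= 20
  flat_top[sel] <- 1
  flat_top[freqs > 14 & freqs < 18] <- 0.5
  flat_top[freqs > 20 & freqs < 24] <- 0.5
  pk3 <- find_band_peak(freqs, flat_top, 12, 29)
  expect_equal(pk3$peak_freq, 18)

  # peak frequency invariant to positive scaling of the linear spectrum
  lin <- periospec:::gaussian_curve(freqs, 20, 0.5, 1.5) + 1
  expect_equal(find_band_peak(freqs, 7 * lin, 12, 29, log_transform = TRUE)$peak_freq,
               find_band_peak(freqs, lin, 12, 29, log_transform = TRUE)$peak_freq)
})

test_that("the feature table covers the full cross-product deterministically", {
  coh <- simulate_cohort(cohort_config(n_per_group = 1, seed = 77))
  feats <- extract_features(coh$spectra)
  # 2 subjects x 2 ROIs x 3 curve types x 6 bands
  expect_equal(nrow(feats$band_power), 2 * 2 * 3 * 6)
  expect_equal(nrow(feats$band_peaks), 2 * 2 * 6)
  expect_equal(nrow(feats$aperiodic), 4)
  # determinism
  feats2 <- extract_features(coh$spectra)
  expect_equal(feats$band_power, feats2$band_power)
  expect_equal(feats$band_peaks, feats2$band_peaks)
  # absolute band powers are non-negative
  abs_rows <- feats$band_power[feats$band_power$curve_type == "absolute", ]
  expect_true(all(abs_rows$power >= 0))
})

test_that("ROI-then-band equals band-then-ROI (linearity)", {
  freqs <- seq(2, 55, by = 0.5)
  chans <- c("24", "124", "11")
  set.seed(12)
  curves <- dplyr::bind_rows(lapply(chans, function(ch) {
    tibble::tibble(subject_id = "S1", channel = ch, freq_hz = freqs,
                   power_uv2_per_hz = runif(length(freqs), 0.5, 2))
  }))
  frontal_only <- roi_definitions()[1, ]
  avg <- roi_average(curves, frontal_only)
  bp_after <- band_power(avg$freq_hz, avg$power_uv2_per_hz, 6, 11)
  bp_each <- vapply(chans, function(ch) {
    sub <- curves[curves$channel == ch, ]
    band_power(sub$freq_hz, sub$power_uv2_per_hz, 6, 11)
  }, numeric(1))
  expect_equal(bp_after, mean(bp_each))
})

test_that("case group's frontal beta peak exceeds controls' by the injected effect", {
  coh <- simulate_cohort(cohort_config(n_per_group = 10, seed = 41))
  feats <- extract_features(coh$spectra)
  pk <- feats$band_peaks
  pk <- pk[pk$roi == "frontal" & pk$band == "broad_beta" & pk$peak_found, ]
  m_tsc <- mean(pk$peak_power_log10[pk$group == "TSC"])
  m_td <- mean(pk$peak_power_log10[pk$group == "TD"])
  # injected group delta 0.3 plus average severity/GABA increments
  tr <- coh$truth[coh$truth$group == "TSC", ]
  expected_delta <- mean(tr$beta_amplitude_delta) - 0.05
  expect_gt(m_tsc - m_td, 0)
  expect_lt(abs((m_tsc - m_td) - expected_delta), 0.2)
})
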