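#' Define a generative model for an EEG power spectrum
#'
#' A spectrum model combines a `1/f^chi` aperiodic background with a set of
#' Gaussian oscillatory peaks in log10-power space, plus i.i.d. Gaussian
#' measurement noise per frequency bin (also in log10 space, the space in
#' which spectra are parameterized).
#'
#' The log10 power at frequency `f` is
#' `offset - exponent * log10(f) + sum_k amp_k * exp(-(f - cf_k)^2 / (2 * sd_k^2))`
#' with `sd_k = bandwidth_k / 2` (bandwidth follows the 2-SD convention so
#' that simulated and recovered bandwidths are directly comparable).
#'
#' @param offset log10 power at 1 Hz (log10(uV^2/Hz)).
#' @param exponent aperiodic exponent chi (>= 0); larger is steeper.
#' @param peaks a tibble with columns `center_freq` (Hz), `amplitude`
#'   (log10 power above the aperiodic background, > 0) and `bandwidth`
#'   (Hz, 2 * SD), or a list of [gaussian_peak()] rows, or `NULL` for none.
#' @param noise_sd SD of additive per-bin noise in log10 power (>= 0).
#' @return An object of class `spectrum_model`.
#' @seealso [simulate_spectrum()], [simulate_timeseries()], [simulate_cohort()]
#' @export
#' @examples
#' m <- spectrum_model(offset = 1, exponent = 1.5,
#'                     peaks = gaussian_peak(20, 0.5, 3), noise_sd = 0)
#' simulate_spectrum(m, freqs = seq(1, 55, by = 0.5))
spectrum_model <- function(offset = 0, exponent = 1, peaks = NULL,
                           noise_sd = 0) {
  if (!is.numeric(offset) || length(offset) != 1L || !is.finite(offset)) {
    abort("`offset` must be a single finite number.")
  }
  if (!is.numeric(exponent) || length(exponent) != 1L || exponent < 0) {
    abort("`exponent` must be a single number >= 0.")
  }
  if (!is.numeric(noise_sd) || length(noise_sd) != 1L || noise_sd < 0) {
    abort("`noise_sd` must be a single number >= 0.")
  }
  peaks <- normalize_peaks(peaks)
  structure(
    list(offset = offset, exponent = exponent, peaks = peaks,
         noise_sd = noise_sd),
    class = "spectrum_model"
  )
}

#' @param center_freq peak center frequency (Hz).
#' @param amplitude peak height in log10 power above the aperiodic curve (> 0).
#' @param bandwidth peak bandwidth in Hz (2 * Gaussian SD; > 0).
#' @rdname spectrum_model
#' @export
gaussian_peak <- function(center_freq, amplitude, bandwidth) {
  if (any(amplitude <= 0)) abort("Peak `amplitude` must be > 0.")
  if (any(bandwidth <= 0)) abort("Peak `bandwidth` must be > 0.")
  if (any(center_freq <= 0)) abort("Peak `center_freq` must be > 0.")
  tibble(center_freq = center_freq, amplitude = amplitude,
         bandwidth = bandwidth)
}

normalize_peaks <- function(peaks) {
  if (is.null(peaks)) {
    return(tibble(center_freq = double(), amplitude = double(),
                  bandwidth = double()))
  }
  if (is.data.frame(peaks)) {
    assert_cols(peaks, c("center_freq", "amplitude", "bandwidth"), "`peaks`")
    return(as_tibble(peaks))
  }
  if (is.list(peaks)) return(bind_rows(peaks))
  abort("`peaks` must be NULL, a data frame, or a list of gaussian_peak().")
}

#' @export
print.spectrum_model <- function(x, ...) {
  cat(sprintf("<spectrum_model> offset=%.3g exponent=%.3g noise_sd=%.3g, %d peak(s)\n",
              x$offset, x$exponent, x$noise_sd, nrow(x$peaks)))
  if (nrow(x$peaks) > 0L) print(x$peaks)
  invisible(x)
}

# Noiseless model curve in log10 power at the given frequencies.
model_log_power <- function(model, freqs) {
  y <- model$offset - model$exponent * log10(freqs)
  if (nrow(model$peaks) > 0L) {
    for (k in seq_len(nrow(model$peaks))) {
      p <- model$peaks[k, ]
      sdk <- p$bandwidth / 2
      y <- y + p$amplitude * exp(-(freqs - p$center_freq)^2 / (2 * sdk^2))
    }
  }
  y
}

#' Simulate a power spectrum from a spectrum model
#'
#' Evaluates the model's log10-power curve on a frequency grid and adds
#' i.i.d. Gaussian noise (SD `noise_sd`) per bin, returning linear power.
#' Linear power is strictly positive by construction.
#'
#' @param model a [spectrum_model()].
#' @param freqs strictly increasing, strictly positive frequency grid (Hz).
#' @param seed optional integer; if given, output is reproducible and the
#'   caller's RNG state is untouched.
#' @return A tibble with columns `freq_hz` and `power_uv2_per_hz`.
#' @export
simulate_spectrum <- function(model, freqs, seed = NULL) {
  stopifnot(inherits(model, "spectrum_model"))
  if (!is.numeric(freqs) || length(freqs) < 1L) {
    abort("`freqs` must be a non-empty numeric vector.")
  }
  if (any(freqs <= 0)) abort("`freqs` must be strictly positive.")
  if (is.unsorted(freqs, strictly = TRUE)) {
    abort("`freqs` must be strictly increasing.")
  }
  log_p <- model_log_power(model, freqs)
  noise <- if (model$noise_sd > 0) {
    with_seed(seed, rnorm(length(freqs), 0, model$noise_sd))
  } else {
    rep(0, length(freqs))
  }
  tibble(freq_hz = freqs, power_uv2_per_hz = 10^(log_p + noise))
}

#' Simulate a multichannel EEG-like time series from a spectrum model
#'
#' Synthesizes circularly stationary signals by spectral shaping of white
#' noise: the model's target PSD is imposed on a random-phase Fourier
#' spectrum which is inverse-transformed to the time domain. The expected
#' periodogram of the output matches the model's target spectrum.
#'
#' @param model a [spectrum_model()]. A model whose linear power is zero
#'   everywhere is not representable (log10 space); amplitudes are in uV.
#' @param duration recording length in seconds (>= 4 s, i.e. two 2-s epochs).
#' @param fs sampling rate in Hz (>= 250).
#' @param n_channels number of identically distributed channels.
#' @param amplitude_scale linear scale applied to the signal (uV); 0 yields
#'   an all-zero recording.
#' @param seed optional integer seed.
#' @return A tibble with columns `channel`, `sample_index`, `value_uv`,
#'   `fs_hz` (long format, one row per sample).
#' @export
simulate_timeseries <- function(model, duration, fs = 250, n_channels = 1,
                                amplitude_scale = 1, seed = NULL) {
  stopifnot(inherits(model, "spectrum_model"))
  if (duration < 4) abort("`duration` must be >= 4 s (two 2-s epochs).")
  if (fs < 250) abort("`fs` must be >= 250 Hz.")
  n <- floor(duration * fs)
  nyq <- floor(n / 2)
  freqs <- seq_len(nyq) * fs / n   # positive frequencies, DC excluded
  target_psd <- 10^model_log_power(model, freqs)  # one-sided, uV^2/Hz
  # |X_k| such that the one-sided periodogram 2|X_k|^2/(fs*n) equals the
  # target PSD in expectation.
  amp <- sqrt(target_psd * fs * n / 2)
  with_seed(seed, {
    out <- vector("list", n_channels)
    for (ch in seq_len(n_channels)) {
      phases <- runif(nyq, 0, 2 * pi)
      spec <- complex(real = amp * cos(phases), imaginary = amp * sin(phases))
      full <- complex(length.out = n)
      full[2:(nyq + 1)] <- spec
      if (n %% 2 == 0) full[nyq + 1] <- complex(real = amp[nyq], imaginary = 0)
      full[n:(n - nyq + 2)] <- Conj(full[2:nyq])
      x <- amplitude_scale * Re(fft(full, inverse = TRUE)) / n
      out[[ch]] <- tibble(channel = sprintf("ch%02d", ch),
                          sample_index = seq_len(n), value_uv = x,
                          fs_hz = fs)
    }
    bind_rows(out)
  })
}

#' Configure a synthetic two-group cohort
#'
#' Bundles the generative settings for [simulate_cohort()]: group sizes, base
#' spectrum models for typically developing (TD) and case (TSC) children,
#' group-level deltas, and per-class clinical covariate effects on the beta
#' peak amplitude. Defaults emulate an early-childhood TSC/TD comparison:
#' TD children carry alpha, low-beta and high-beta peaks; TSC children carry
#' a single elevated ~20 Hz beta peak whose amplitude increases with seizure
#' severity class and with GABAergic medication use, and a raised posterior
#' aperiodic offset.
#'
#' @param n_per_group subjects per group (>= 1).
#' @param seed integer seed driving every random draw.
#' @param group_effects list with `tsc_beta_amplitude` (added to the TSC 20 Hz
#'   peak) and `tsc_posterior_offset` (added to TSC posterior-channel offsets).
#' @param covariate_effects list with `severity` (named increments for
#'   low/moderate/high classes) and `gaba` (increment when on a GABAergic
#'   medication), both acting on the TSC beta peak amplitude in log10 units.
#' @param td_model,tsc_model base [spectrum_model()]s per group.
#' @param subject_sd list of between-subject SDs: `offset`, `exponent`,
#'   `peak_amplitude`, `peak_freq` (Hz).
#' @param channel_roles tibble mapping `electrode` to `roi`
#'   (frontal/posterior); defaults to [roi_definitions()].
#' @param freqs simulated frequency grid (Hz).
#' @param severity_probs probabilities of low/moderate/high severity class
#'   within the case group.
#' @param p_gaba probability a medicated case child is on a GABAergic drug.
#' @param age_range_months uniform age range for cases.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_per_group = 49,
                          seed = 1,
                          group_effects = list(tsc_beta_amplitude = 0.3,
                                               tsc_posterior_offset = 0.3),
                          covariate_effects = list(
                            severity = c(low = 0, moderate = 0.05, high = 0.25),
                            gaba = 0.15),
                          td_model = spectrum_model(
                            offset = 0.4, exponent = 1.0,
                            peaks = bind_rows(
                              gaussian_peak(8, 0.40, 4),
                              gaussian_peak(16, 0.18, 4),
                              gaussian_peak(25, 0.18, 4)),
                            noise_sd = 0.05),
                          tsc_model = spectrum_model(
                            offset = 0.4, exponent = 1.0,
                            peaks = bind_rows(
                              gaussian_peak(8, 0.40, 4),
                              gaussian_peak(20, 0.15, 5)),
                            noise_sd = 0.05),
                          subject_sd = list(offset = 0.1, exponent = 0.1,
                                            peak_amplitude = 0.1,
                                            peak_freq = 0.5),
                          channel_roles = NULL,
                          freqs = seq(1, 64, by = 0.5),
                          severity_probs = c(low = 0.25, moderate = 0.48,
                                             high = 0.27),
                          p_gaba = 0.9,
                          age_range_months = c(12, 37)) {
  if (n_per_group < 1) abort("`n_per_group` must be >= 1.")
  if (is.null(channel_roles)) {
    channel_roles <- tidyr::unnest(roi_definitions(), "electrode")
  }
  assert_cols(channel_roles, c("roi", "electrode"), "`channel_roles`")
  bad_roi <- setdiff(unique(channel_roles$roi), c("frontal", "posterior"))
  if (length(bad_roi) > 0L) {
    abort(sprintf("Unknown ROI label(s) in `channel_roles`: %s",
                  paste(bad_roi, collapse = ", ")))
  }
  structure(
    list(n_per_group = n_per_group, seed = seed,
         group_effects = group_effects, covariate_effects = covariate_effects,
         td_model = td_model, tsc_model = tsc_model,
         subject_sd = subject_sd, channel_roles = channel_roles,
         freqs = freqs, severity_probs = severity_probs, p_gaba = p_gaba,
         age_range_months = age_range_months),
    class = "cohort_config"
  )
}

# GABAergic / non-GABAergic anti-epileptic drug names used by the generator;
# must stay in sync with inst/extdata/medication_ontology.csv.
gaba_med_names <- c("vigabatrin", "clobazam", "phenobarbital", "clonazepam")
non_gaba_med_names <- c("oxcarbazepine", "levetiracetam", "lamotrigine",
                        "topiramate", "zonisamide", "ethosuximide")
seizure_type_names <- c("generalized", "focal", "drop", "infantile_spasms",
                        "absence")

# Sample E-Chess components (frequency, n meds, n types) whose total falls in
# the given class range; types require at least one when frequency > 0.
sample_severity_components <- function(class) {
  range <- switch(class, low = c(0, 2), moderate = c(3, 7), high = c(8, 12))
  grid <- expand.grid(freq = 0:4, meds = 0:6, types = 0:5)
  grid <- grid[grid$freq + grid$meds + grid$types >= range[1] &
                 grid$freq + grid$meds + grid$types <= range[2], ]
  # current seizures imply at least one reported type and vice versa
  grid <- grid[(grid$freq > 0) == (grid$types > 0), ]
  grid[sample(nrow(grid), 1L), ]
}

#' Simulate a synthetic two-group cohort (spectra + clinical table)
#'
#' Draws per-subject spectrum models around the configured group bases,
#' applies group deltas (case beta-peak increment on the ~20 Hz peak;
#' posterior offset increment) and clinical covariate effects (severity
#' class and GABAergic medication increments on the beta peak amplitude),
#' simulates per-channel spectra on the configured grid, and assembles a
#' clinical table carrying every field the clinical module scores.
#'
#' Within the case group the expected beta peak amplitude is monotone
#' increasing in severity class and in the GABA flag. Output is bit-for-bit
#' reproducible given `config$seed`.
#'
#' @param config a [cohort_config()].
#' @return A list of class `synthetic_cohort` with elements `spectra`
#'   (tibble: subject_id, group, channel, freq_hz, power_uv2_per_hz),
#'   `clinical` (tibble, one row per child) and `truth` (tibble of
#'   per-subject generative parameters).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_per_group
  sev_eff <- config$covariate_effects$severity
  gaba_eff <- config$covariate_effects$gaba

  with_seed(config$seed, {
    # --- clinical covariates for the case group ---
    classes <- sample(names(config$severity_probs), n, replace = TRUE,
                      prob = config$severity_probs)
    comp <- lapply(classes, sample_severity_components)
    freq_pts <- vapply(comp, function(x) x$freq, numeric(1))
    n_meds <- vapply(comp, function(x) x$meds, numeric(1))
    n_types <- vapply(comp, function(x) x$types, numeric(1))
    on_gaba <- n_meds > 0 & runif(n) < config$p_gaba
    meds <- mapply(function(k, g) {
      if (k == 0) return("")
      if (g) {
        first <- sample(gaba_med_names, 1L)
        rest <- if (k > 1) {
          sample(setdiff(c(gaba_med_names, non_gaba_med_names), first), k - 1L)
        } else character()
        paste(c(first, rest), collapse = ";")
      } else {
        paste(sample(non_gaba_med_names, k), collapse = ";")
      }
    }, n_meds, on_gaba)
    types <- vapply(n_types, function(k) {
      if (k == 0) "" else paste(sample(seizure_type_names, k), collapse = ";")
    }, character(1))
    spasms <- ifelse(grepl("infantile_spasms", types), "current",
                     sample(c("past", "never"), n, replace = TRUE))

    ages <- round(runif(n, config$age_range_months[1],
                        config$age_range_months[2]))
    sexes <- sample(c("M", "F"), n, replace = TRUE, prob = c(0.51, 0.49))

    mullen <- function(mean_dq, sd_dq, age) {
      pmax(1, round(age * rnorm(length(age), mean_dq, sd_dq) / 100))
    }

    clinical <- bind_rows(
      tibble(
        subject_id = sprintf("TSC%03d", seq_len(n)),
        group = "TSC", age_months = ages, sex = sexes,
        seizure_frequency_category = as.integer(freq_pts),
        current_medications = meds, seizure_types = types,
        infantile_spasms = spasms,
        mullen_vr_ae = mullen(73, 22, ages), mullen_fm_ae = mullen(73, 22, ages),
        mullen_el_ae = mullen(63, 24, ages), mullen_rl_ae = mullen(63, 24, ages)
      ),
      tibble(
        subject_id = sprintf("TD%03d", seq_len(n)),
        group = "TD",
        age_months = pmax(12, ages + sample(-1:1, n, replace = TRUE)),
        sex = sexes,
        seizure_frequency_category = 0L,
        current_medications = "", seizure_types = "",
        infantile_spasms = "never",
        mullen_vr_ae = mullen(115, 14, ages), mullen_fm_ae = mullen(115, 14, ages),
        mullen_el_ae = mullen(118, 18, ages), mullen_rl_ae = mullen(118, 18, ages)
      )
    )

    # --- per-subject spectrum models ---
    sev_class <- c(classes, rep(NA_character_, n))
    gaba_flag <- c(on_gaba, rep(FALSE, n))
    groups <- clinical$group
    ssd <- config$subject_sd

    subject_rows <- vector("list", 2L * n)
    spectra_rows <- vector("list", 2L * n)
    for (i in seq_len(2L * n)) {
      base <- if (groups[i] == "TSC") config$tsc_model else config$td_model
      off_i <- base$offset + rnorm(1, 0, ssd$offset)
      exp_i <- max(0, base$exponent + rnorm(1, 0, ssd$exponent))
      pk <- base$peaks
      if (nrow(pk) > 0L) {
        pk$center_freq <- pk$center_freq + rnorm(nrow(pk), 0, ssd$peak_freq)
        pk$amplitude <- pk$amplitude + rnorm(nrow(pk), 0, ssd$peak_amplitude)
      }
      beta_amp_delta <- 0
      if (groups[i] == "TSC") {
        beta_amp_delta <- config$group_effects$tsc_beta_amplitude +
          sev_eff[[sev_class[i]]] + if (gaba_flag[i]) gaba_eff else 0
        # the case beta peak is the one nearest 20 Hz
        k <- which.min(abs(pk$center_freq - 20))
        pk$amplitude[k] <- pk$amplitude[k] + beta_amp_delta
      }
      pk$amplitude <- pmax(0.01, pk$amplitude)
      post_off <- if (groups[i] == "TSC") config$group_effects$tsc_posterior_offset else 0

      subject_rows[[i]] <- tibble(
        subject_id = clinical$subject_id[i], group = groups[i],
        severity_class = sev_class[i], on_gaba = gaba_flag[i],
        offset = off_i, exponent = exp_i,
        posterior_offset_delta = post_off,
        beta_amplitude_delta = beta_amp_delta,
        peaks = list(pk)
      )

      ch_tbl <- config$channel_roles
      per_ch <- vector("list", nrow(ch_tbl))
      for (j in seq_len(nrow(ch_tbl))) {
        m <- spectrum_model(
          offset = off_i + if (ch_tbl$roi[j] == "posterior") post_off else 0,
          exponent = exp_i, peaks = pk, noise_sd = base$noise_sd)
        sp <- simulate_spectrum(m, config$freqs)
        per_ch[[j]] <- mutate(sp,
                              subject_id = clinical$subject_id[i],
                              group = groups[i],
                              channel = ch_tbl$electrode[j],
                              .before = 1)
      }
      spectra_rows[[i]] <- bind_rows(per_ch)
    }

    list_out <- list(
      spectra = bind_rows(spectra_rows),
      clinical = clinical,
      truth = bind_rows(subject_rows)
    )
    structure(list_out, class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d subjects, %d channels, %d frequency bins\n",
              dplyr::n_distinct(x$spectra$subject_id),
              dplyr::n_distinct(x$spectra$channel),
              dplyr::n_distinct(x$spectra$freq_hz)))
  invisible(x)
}
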