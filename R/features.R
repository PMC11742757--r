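#' Canonical frequency-band definitions
#'
#' Theta 4-5 Hz, alpha 6-11, low beta 12-19, high beta 20-29, broad beta
#' 12-29, gamma 30-44. Band membership is inclusive of both endpoints on
#' the 0.5 Hz grid; the printed bands are integer-bounded and non-adjacent
#' (alpha ends at 11, low beta starts at 12) so no double counting arises.
#'
#' @return Tibble with columns `band`, `lo`, `hi` (Hz).
#' @export
band_definitions <- function() {
  tibble(
    band = c("theta", "alpha", "low_beta", "high_beta", "broad_beta", "gamma"),
    lo = c(4, 6, 12, 20, 12, 30),
    hi = c(5, 11, 19, 29, 29, 44)
  )
}

#' Canonical region-of-interest electrode sets
#'
#' Frontal: electrodes 24, 124, 11, 28, 117, 19, 4. Posterior: electrodes
#' 70, 75, 83, 67, 77 (high-density geodesic net numbering).
#'
#' @return Tibble with columns `roi` and list column `electrode`.
#' @export
roi_definitions <- function() {
  tibble(
    roi = c("frontal", "posterior"),
    electrode = list(c("24", "124", "11", "28", "117", "19", "4"),
                     c("70", "75", "83", "67", "77"))
  )
}

#' Average per-channel curves within regions of interest
#'
#' Bin-wise arithmetic mean of the value column across each ROI's available
#' electrodes. Missing electrodes are tolerated (mean over those present)
#' and recorded in the `n_channels`/`n_missing` provenance columns; an ROI
#' with zero available channels is an error.
#'
#' @param curves long tibble with `channel`, `freq_hz`, a value column, and
#'   any id columns (e.g. `subject_id`).
#' @param rois tibble as [roi_definitions()].
#' @param value name of the value column (default `power_uv2_per_hz`).
#' @return Tibble: id columns, `roi`, `freq_hz`, the value column, plus
#'   `n_channels` and `n_missing`.
#' @export
roi_average <- function(curves, rois = roi_definitions(),
                        value = "power_uv2_per_hz") {
  assert_cols(curves, c("channel", "freq_hz", value), "`curves`")
  roi_long <- tidyr::unnest(rois, "electrode")
  id_cols <- setdiff(names(curves), c("channel", "freq_hz", value))
  out <- vector("list", nrow(rois))
  for (k in seq_len(nrow(rois))) {
    roi_k <- rois$roi[k]
    electrodes <- roi_long$electrode[roi_long$roi == roi_k]
    sub <- curves[curves$channel %in% electrodes, , drop = FALSE]
    if (nrow(sub) == 0L) {
      abort(sprintf("No channels available for ROI '%s'.", roi_k))
    }
    present <- unique(sub$channel)
    agg <- sub %>%
      group_by(across(dplyr::all_of(c(id_cols, "freq_hz")))) %>%
      summarise(.value = mean(.data[[value]]), .groups = "drop") %>%
      mutate(roi = roi_k,
             n_channels = length(present),
             n_missing = length(electrodes) - length(present))
    names(agg)[names(agg) == ".value"] <- value
    out[[k]] <- agg
  }
  bind_rows(out)[, c(id_cols, "roi", "freq_hz", value,
                     "n_channels", "n_missing")] %>%
    arrange(across(dplyr::all_of(c(id_cols, "roi", "freq_hz"))))
}

#' Band power as the integral under a curve
#'
#' Trapezoidal integral of the curve over bins with `lo <= f <= hi`
#' (inclusive). For linear-power curves the units are uV^2; for log10
#' periodic curves they are log10-units x Hz.
#'
#' @param freq_hz frequency grid (Hz).
#' @param value curve values on the grid.
#' @param lo,hi band edges (Hz); the curve must cover them.
#' @return A single number.
#' @export
band_power <- function(freq_hz, value, lo, hi) {
  if (lo >= hi) abort("Band must satisfy lo < hi.")
  if (min(freq_hz) > lo || max(freq_hz) < hi) {
    abort("Band lies outside the curve's frequency support.")
  }
  sel <- freq_hz >= lo & freq_hz <= hi
  trapz(freq_hz[sel], value[sel])
}

#' Largest interior local maximum of a curve within a band
#'
#' Finds the largest local maximum strictly inside `[lo, hi]`: a bin whose
#' value exceeds its closest differing neighbours on both sides (plateaus
#' take the lowest-frequency bin of the plateau). Band edge bins can never
#' be peaks; a curve with no interior local maximum yields an absent-peak
#' flag, never an edge value.
#'
#' @inheritParams band_power
#' @param log_transform if `TRUE`, report the peak value as log10 of the
#'   linear value (use for absolute power curves); if `FALSE` the curve is
#'   already in log10 units (periodic curves).
#' @return One-row tibble: `peak_freq` (Hz), `peak_power_log10`,
#'   `peak_found` (logical).
#' @export
find_band_peak <- function(freq_hz, value, lo, hi, log_transform = FALSE) {
  if (min(freq_hz) > lo || max(freq_hz) < hi) {
    abort("Band lies outside the curve's frequency support.")
  }
  sel <- which(freq_hz >= lo & freq_hz <= hi)
  f <- freq_hz[sel]
  v <- value[sel]
  n <- length(v)
  is_peak <- rep(FALSE, n)
  for (i in seq_len(n)) {
    if (i == 1L || i == n) next          # edges are never peaks
    # closest differing neighbour on each side (plateau handling)
    li <- i - 1L
    while (li >= 1L && v[li] == v[i]) li <- li - 1L
    ri <- i + 1L
    while (ri <= n && v[ri] == v[i]) ri <- ri + 1L
    if (li >= 1L && ri <= n && v[li] < v[i] && v[ri] < v[i]) {
      # lowest-frequency bin of a plateau only
      if (i == 1L || v[i - 1L] != v[i]) is_peak[i] <- TRUE
    }
  }
  if (!any(is_peak)) {
    return(tibble(peak_freq = NA_real_, peak_power_log10 = NA_real_,
                  peak_found = FALSE))
  }
  best <- which(is_peak)[which.max(v[is_peak])]
  pv <- if (log_transform) log10(v[best]) else v[best]
  tibble(peak_freq = f[best], peak_power_log10 = pv, peak_found = TRUE)
}

#' Extract the per-subject, per-ROI feature table
#'
#' For each subject the per-channel absolute spectra are averaged within
#' each ROI, the ROI-averaged spectrum is parameterized, and three curves
#' are derived: absolute (linear power), aperiodic (linear power of the
#' fitted 1/f curve) and periodic (log10 residual). Band powers are the
#' integral under each curve for each band; band peaks (frequency in Hz,
#' power in log10 units) are located on the periodic curve.
#'
#' @param spectra long tibble: `subject_id`, `channel`, `freq_hz`,
#'   `power_uv2_per_hz` (extra id columns such as `group` are carried along).
#' @param rois tibble as [roi_definitions()].
#' @param bands tibble as [band_definitions()].
#' @param settings a [specparam_settings()] list.
#' @return An object of class `eeg_features`: a list of tibbles
#'   `band_power` (subject x ROI x curve type x band), `band_peaks`
#'   (subject x ROI x band, periodic curve), and `aperiodic` (subject x ROI
#'   offset/exponent/goodness), each deterministically ordered.
#' @export
extract_features <- function(spectra, rois = roi_definitions(),
                             bands = band_definitions(),
                             settings = specparam_settings()) {
  assert_cols(spectra, c("subject_id", "channel", "freq_hz",
                         "power_uv2_per_hz"), "`spectra`")
  id_cols <- setdiff(names(spectra),
                     c("channel", "freq_hz", "power_uv2_per_hz"))
  roi_avg <- roi_average(spectra, rois)
  fits <- parameterize_spectra(roi_avg, by = c(id_cols, "roi"),
                               settings = settings)

  bp_rows <- list()
  pk_rows <- list()
  for (i in seq_len(nrow(fits))) {
    f <- fits$fit[[i]]
    ids <- fits[i, c(id_cols, "roi"), drop = FALSE]
    freqs <- f$freq_hz
    absolute <- 10^f$log_power
    aperiodic <- 10^(f$aperiodic$offset - f$aperiodic$exponent * log10(freqs))
    periodic <- f$periodic$periodic_log10
    curves <- list(absolute = absolute, aperiodic = aperiodic,
                   periodic = periodic)
    for (ct in names(curves)) {
      for (b in seq_len(nrow(bands))) {
        bp_rows[[length(bp_rows) + 1L]] <- bind_cols(
          ids,
          tibble(curve_type = ct, band = bands$band[b],
                 power = band_power(freqs, curves[[ct]],
                                    bands$lo[b], bands$hi[b])))
      }
    }
    for (b in seq_len(nrow(bands))) {
      pk <- find_band_peak(freqs, periodic, bands$lo[b], bands$hi[b],
                           log_transform = FALSE)
      pk_rows[[length(pk_rows) + 1L]] <- bind_cols(
        ids, tibble(band = bands$band[b]), pk)
    }
  }
  band_power_tbl <- bind_rows(bp_rows) %>%
    arrange(across(dplyr::all_of(c(id_cols, "roi", "curve_type", "band"))))
  band_peaks_tbl <- bind_rows(pk_rows) %>%
    arrange(across(dplyr::all_of(c(id_cols, "roi", "band"))))
  aperiodic_tbl <- fits[, c(id_cols, "roi", "offset", "exponent",
                            "fit_error", "r_squared", "n_peaks",
                            "flag_poor_fit")] %>%
    arrange(across(dplyr::all_of(c(id_cols, "roi"))))

  structure(list(band_power = band_power_tbl,
                 band_peaks = band_peaks_tbl,
                 aperiodic = aperiodic_tbl,
                 fits = fits),
            class = "eeg_features")
}

#' @export
print.eeg_features <- function(x, ...) {
  cat(sprintf("<eeg_features> %d band-power rows, %d peak rows, %d aperiodic fits\n",
              nrow(x$band_power), nrow(x$band_peaks), nrow(x$aperiodic)))
  invisible(x)
}

#' Wide aperiodic predictor table for group modelling
#'
#' Spreads the per-ROI aperiodic fits into one row per subject with the
#' four predictors of the group logistic model: frontal/posterior offset
#' and exponent.
#'
#' @param features an `eeg_features` object from [extract_features()].
#' @return Tibble: id columns, `frontal_offset`, `frontal_exponent`,
#'   `posterior_offset`, `posterior_exponent`.
#' @export
aperiodic_wide <- function(features) {
  stopifnot(inherits(features, "eeg_features"))
  ap <- features$aperiodic
  id_cols <- setdiff(names(ap), c("roi", "offset", "exponent", "fit_error",
                                  "r_squared", "n_peaks", "flag_poor_fit"))
  tidyr::pivot_wider(ap[, c(id_cols, "roi", "offset", "exponent")],
                     names_from = "roi",
                     values_from = c("offset", "exponent"),
                     names_glue = "{roi}_{.value}")
}
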