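#' Settings for spectral parameterization
#'
#' Defaults mirror the study configuration: fixed-mode (no knee) aperiodic
#' fit from 2 to 55 Hz, at most 7 peaks, peak threshold of 2 SD of the
#' flattened residual, and peak bandwidth limits 0.5-18.0 Hz.
#'
#' @param freq_range aperiodic fit range in Hz.
#' @param max_n_peaks maximum number of Gaussian peaks.
#' @param peak_threshold peak detection threshold, in SD units of the
#'   flattened residual.
#' @param peak_width_limits allowed fitted bandwidths (Hz, 2-SD convention).
#' @param min_peak_height absolute minimum peak height (log10 units).
#' @param robust_percentile percentile of the flattened spectrum used to
#'   select low-residual bins for the robust aperiodic re-fit.
#' @return A list of settings.
#' @export
specparam_settings <- function(freq_range = c(2, 55), max_n_peaks = 7,
                               peak_threshold = 2,
                               peak_width_limits = c(0.5, 18.0),
                               min_peak_height = 0,
                               robust_percentile = 0.025) {
  list(freq_range = freq_range, max_n_peaks = max_n_peaks,
       peak_threshold = peak_threshold,
       peak_width_limits = peak_width_limits,
       min_peak_height = min_peak_height,
       robust_percentile = robust_percentile)
}

gaussian_curve <- function(freqs, cf, height, sdv) {
  height * exp(-(freqs - cf)^2 / (2 * sdv^2))
}

peaks_curve <- function(freqs, peaks) {
  y <- numeric(length(freqs))
  if (NROW(peaks) == 0L) return(y)
  for (k in seq_len(nrow(peaks))) {
    y <- y + gaussian_curve(freqs, peaks$center_freq[k], peaks$amplitude[k],
                            peaks$bandwidth[k] / 2)
  }
  y
}

# Plain straight-line fit of log10 power vs log10 frequency.
simple_ap_fit <- function(freqs, log_power) {
  fit <- lm(log_power ~ log10(freqs))
  c(offset = unname(coef(fit)[1]), exponent = -unname(coef(fit)[2]))
}

# Robust (peak-insensitive) aperiodic fit: ordinary fit, then re-fit using
# only the bins whose flattened (non-negative-clipped) residual lies at or
# below the `robust_percentile` quantile, i.e. the bins hugging the 1/f
# envelope below the oscillatory peaks.
robust_ap_fit <- function(freqs, log_power, robust_percentile = 0.025) {
  init <- simple_ap_fit(freqs, log_power)
  flat <- log_power - (init["offset"] - init["exponent"] * log10(freqs))
  flat[flat < 0] <- 0
  thresh <- quantile(flat, robust_percentile, names = FALSE)
  keep <- flat <= thresh
  if (sum(keep) < 2L) keep <- rank(flat, ties.method = "first") <= 2L
  simple_ap_fit(freqs[keep], log_power[keep])
}

#' Fit the aperiodic (1/f) component of a power spectrum
#'
#' Fits a straight line to log10 power versus log10 frequency over
#' `freq_range` in fixed mode (no spectral knee), using a two-pass robust
#' procedure that re-fits on low-residual bins so oscillatory peaks do not
#' bias the line. The exponent is the negated slope; the offset is the
#' intercept (log10 power at 1 Hz).
#'
#' @param spectrum tibble with columns `freq_hz`, `power_uv2_per_hz`
#'   (strictly positive over the fit range).
#' @param freq_range fit range in Hz (default 2-55).
#' @param robust_percentile see [specparam_settings()].
#' @return A one-row tibble: `offset`, `exponent`, `fit_error` (mean
#'   absolute log10 residual), `freq_lo`, `freq_hi`.
#' @export
fit_aperiodic <- function(spectrum, freq_range = c(2, 55),
                          robust_percentile = 0.025) {
  assert_cols(spectrum, c("freq_hz", "power_uv2_per_hz"), "`spectrum`")
  sel <- spectrum$freq_hz >= freq_range[1] & spectrum$freq_hz <= freq_range[2]
  freqs <- spectrum$freq_hz[sel]
  pow <- spectrum$power_uv2_per_hz[sel]
  if (length(freqs) < 3L) abort("Spectrum does not cover the fit range.")
  if (any(pow <= 0)) abort("Power must be strictly positive over the fit range (log domain).")
  log_power <- log10(pow)
  ap <- robust_ap_fit(freqs, log_power, robust_percentile)
  resid <- log_power - (ap["offset"] - ap["exponent"] * log10(freqs))
  tibble(offset = ap[["offset"]], exponent = ap[["exponent"]],
         fit_error = mean(abs(resid)),
         freq_lo = freq_range[1], freq_hi = freq_range[2])
}

# Guess a Gaussian SD from the half-height width of the residual around bin i.
guess_peak_sd <- function(freqs, resid, i, height, sd_limits) {
  half <- height / 2
  left <- i
  while (left > 1L && resid[left] > half) left <- left - 1L
  right <- i
  n <- length(resid)
  while (right < n && resid[right] > half) right <- right + 1L
  fwhm <- freqs[right] - freqs[left]
  if (fwhm <= 0) fwhm <- 2 * (freqs[2] - freqs[1])
  sdv <- fwhm / 2.355
  min(max(sdv, sd_limits[1]), sd_limits[2])
}

#' Extract Gaussian peaks from a flattened (aperiodic-removed) spectrum
#'
#' Iteratively locates the maximum of the residual curve, stops when the
#' next candidate falls below `peak_threshold` standard deviations of the
#' current residual (or below `min_peak_height`), subtracts a Gaussian
#' guess, and repeats up to `max_n_peaks` times; all Gaussians are then
#' refit jointly by bounded nonlinear least squares. Peaks whose fitted
#' bandwidth leaves `peak_width_limits` are discarded. Ties between equal
#' residual maxima break toward the lower frequency.
#'
#' @param freqs frequency grid (Hz) of the flattened curve.
#' @param flattened log10-power residual after aperiodic removal.
#' @param settings a [specparam_settings()] list.
#' @return A tibble of peaks: `center_freq`, `amplitude`
#'   (log10 power above the aperiodic), `bandwidth` (Hz), sorted by
#'   descending amplitude. Zero rows when no peak clears the threshold.
#' @export
extract_peaks <- function(freqs, flattened, settings = specparam_settings()) {
  stopifnot(length(freqs) == length(flattened))
  sd_limits <- settings$peak_width_limits / 2
  resid <- flattened
  guesses <- list()
  for (k in seq_len(settings$max_n_peaks)) {
    i <- which.max(resid)      # first max = lowest frequency on ties
    height <- resid[i]
    # 1e-6 log10 units is a numerical floor, far below any real oscillation
    if (height <= settings$peak_threshold * sd(resid) ||
        height <= settings$min_peak_height || height <= 1e-6) break
    sdv <- guess_peak_sd(freqs, resid, i, height, sd_limits)
    guesses[[k]] <- c(cf = freqs[i], height = height, sd = sdv)
    resid <- resid - gaussian_curve(freqs, freqs[i], height, sdv)
  }
  if (length(guesses) == 0L) {
    return(tibble(center_freq = double(), amplitude = double(),
                  bandwidth = double()))
  }
  g <- do.call(rbind, guesses)
  fitted <- refit_peaks(freqs, flattened, g, sd_limits)
  fitted <- fitted[fitted$bandwidth >= settings$peak_width_limits[1] &
                     fitted$bandwidth <= settings$peak_width_limits[2] &
                     fitted$amplitude > 0, , drop = FALSE]
  fitted[order(-fitted$amplitude), , drop = FALSE]
}

# Joint bounded nonlinear least-squares refit of all peak Gaussians.
refit_peaks <- function(freqs, flattened, guesses, sd_limits) {
  n_pk <- nrow(guesses)
  par0 <- as.vector(t(guesses))   # cf1, h1, sd1, cf2, ...
  bin <- freqs[2] - freqs[1]
  lower <- as.vector(t(cbind(pmax(min(freqs), guesses[, "cf"] - 2 * guesses[, "sd"]),
                             0,
                             pmax(sd_limits[1] * 0.5, bin / 4))))
  upper <- as.vector(t(cbind(pmin(max(freqs), guesses[, "cf"] + 2 * guesses[, "sd"]),
                             Inf,
                             sd_limits[2] * 1.5)))
  resid_fun <- function(par) {
    m <- matrix(par, ncol = 3, byrow = TRUE)
    y <- numeric(length(freqs))
    for (k in seq_len(n_pk)) {
      y <- y + gaussian_curve(freqs, m[k, 1], m[k, 2], m[k, 3])
    }
    y - flattened
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(par = par0, lower = lower, upper = upper,
                       fn = resid_fun,
                       control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  par <- if (is.null(fit)) par0 else fit$par
  m <- matrix(par, ncol = 3, byrow = TRUE)
  tibble(center_freq = m[, 1], amplitude = m[, 2], bandwidth = 2 * m[, 3])
}

#' Parameterize a power spectrum into aperiodic and periodic components
#'
#' Full decomposition: robust aperiodic fit, flattening, iterative peak
#' extraction with joint Gaussian refit, subtraction of the joint peak
#' model, final aperiodic re-fit on the peak-removed curve, and computation
#' of the periodic residual curve (input log10 spectrum minus the final
#' aperiodic curve). Goodness of fit (R^2 of the full model in log10 space)
#' is reported; fits with R^2 < 0.90 are flagged, not dropped.
#'
#' @inheritParams fit_aperiodic
#' @param settings a [specparam_settings()] list.
#' @return An object of class `parameterized_spectrum` with fields
#'   `aperiodic` (one-row tibble), `peaks` (tibble), `periodic` (tibble:
#'   `freq_hz`, `periodic_log10`), `r_squared`, `fit_error`,
#'   `flag_poor_fit`, `settings` and the fitted curves. Use
#'   [generics::tidy()] for the peak table and [generics::glance()] for the
#'   one-row fit summary.
#' @export
parameterize_spectrum <- function(spectrum, settings = specparam_settings()) {
  assert_cols(spectrum, c("freq_hz", "power_uv2_per_hz"), "`spectrum`")
  fr <- settings$freq_range
  sel <- spectrum$freq_hz >= fr[1] & spectrum$freq_hz <= fr[2]
  freqs <- spectrum$freq_hz[sel]
  pow <- spectrum$power_uv2_per_hz[sel]
  if (length(freqs) < 5L) abort("Spectrum does not cover the fit range.")
  if (any(pow <= 0)) abort("Power must be strictly positive over the fit range (log domain).")
  log_power <- log10(pow)

  ap0 <- robust_ap_fit(freqs, log_power, settings$robust_percentile)
  flat <- log_power - (ap0["offset"] - ap0["exponent"] * log10(freqs))
  peaks <- extract_peaks(freqs, flat, settings)
  peak_model <- peaks_curve(freqs, peaks)

  ap <- simple_ap_fit(freqs, log_power - peak_model)
  ap_curve <- ap["offset"] - ap["exponent"] * log10(freqs)
  model <- ap_curve + peak_model
  resid <- log_power - model
  r2 <- 1 - sum(resid^2) / sum((log_power - mean(log_power))^2)
  periodic <- log_power - ap_curve

  structure(list(
    freq_hz = freqs,
    log_power = log_power,
    aperiodic = tibble(offset = ap[["offset"]], exponent = ap[["exponent"]],
                       fit_error = mean(abs(resid)),
                       freq_lo = fr[1], freq_hi = fr[2]),
    peaks = peaks,
    periodic = tibble(freq_hz = freqs, periodic_log10 = periodic),
    model_log10 = model,
    r_squared = r2,
    fit_error = mean(abs(resid)),
    flag_poor_fit = r2 < 0.90,
    settings = settings
  ), class = "parameterized_spectrum")
}

#' @export
print.parameterized_spectrum <- function(x, ...) {
  cat(sprintf("<parameterized_spectrum> offset=%.3f exponent=%.3f R2=%.4f, %d peak(s)%s\n",
              x$aperiodic$offset, x$aperiodic$exponent, x$r_squared,
              nrow(x$peaks), if (x$flag_poor_fit) " [poor fit]" else ""))
  if (nrow(x$peaks) > 0L) print(x$peaks)
  invisible(x)
}

#' @rdname parameterize_spectrum
#' @param x a `parameterized_spectrum`.
#' @param ... unused.
#' @method tidy parameterized_spectrum
#' @export
tidy.parameterized_spectrum <- function(x, ...) {
  x$peaks
}

#' @rdname parameterize_spectrum
#' @method glance parameterized_spectrum
#' @export
glance.parameterized_spectrum <- function(x, ...) {
  bind_cols(x$aperiodic[, c("offset", "exponent", "fit_error")],
            tibble(r_squared = x$r_squared, n_peaks = nrow(x$peaks),
                   flag_poor_fit = x$flag_poor_fit))
}

#' Parameterize a table of spectra
#'
#' Applies [parameterize_spectrum()] to each group of rows (by default each
#' `subject_id` x `channel` combination) of a long spectra table.
#'
#' @param spectra long tibble with `freq_hz`, `power_uv2_per_hz` and the
#'   grouping columns in `by`.
#' @param by character vector of grouping columns.
#' @param settings a [specparam_settings()] list.
#' @return A tibble with one row per group: the grouping columns, `offset`,
#'   `exponent`, `fit_error`, `r_squared`, `n_peaks`, `flag_poor_fit`, and a
#'   list column `fit` holding each `parameterized_spectrum`.
#' @export
parameterize_spectra <- function(spectra, by = c("subject_id", "channel"),
                                 settings = specparam_settings()) {
  assert_cols(spectra, c(by, "freq_hz", "power_uv2_per_hz"), "`spectra`")
  nested <- tidyr::nest(spectra, data = -dplyr::all_of(by))
  fits <- purrr::map(nested$data, parameterize_spectrum, settings = settings)
  summ <- purrr::map(fits, glance.parameterized_spectrum)
  out <- bind_cols(nested[by], bind_rows(summ))
  out$fit <- fits
  out
}

#' Long table of fitted peaks from [parameterize_spectra()] output
#' @param fits result of [parameterize_spectra()].
#' @return Tibble: grouping columns + `center_freq`, `amplitude`, `bandwidth`.
#' @export
peak_table <- function(fits) {
  by <- setdiff(names(fits),
                c("offset", "exponent", "fit_error", "r_squared", "n_peaks",
                  "flag_poor_fit", "fit"))
  rows <- purrr::map2(seq_len(nrow(fits)), fits$fit, function(i, f) {
    if (nrow(f$peaks) == 0L) return(NULL)
    bind_cols(fits[rep(i, nrow(f$peaks)), by, drop = FALSE], f$peaks)
  })
  bind_rows(rows)
}

#' Long table of periodic residual curves from [parameterize_spectra()] output
#' @inheritParams peak_table
#' @return Tibble: grouping columns + `freq_hz`, `periodic_log10`.
#' @export
periodic_table <- function(fits) {
  by <- setdiff(names(fits),
                c("offset", "exponent", "fit_error", "r_squared", "n_peaks",
                  "flag_poor_fit", "fit"))
  rows <- purrr::map2(seq_len(nrow(fits)), fits$fit, function(i, f) {
    bind_cols(fits[rep(i, nrow(f$periodic)), by, drop = FALSE], f$periodic)
  })
  bind_rows(rows)
}
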