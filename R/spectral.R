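#' Segment a continuous recording into fixed-length epochs
#'
#' Splits each channel into consecutive, non-overlapping epochs of
#' `epoch_length` seconds; a trailing remainder shorter than one epoch is
#' discarded. The pipeline convention is 2-s epochs, which at the native
#' 0.5 Hz spectral resolution of a 2-s window yields the analysis grid.
#'
#' @param recording long tibble with columns `channel`, `sample_index`,
#'   `value_uv` and `fs_hz` (as produced by [simulate_timeseries()]).
#' @param epoch_length epoch length in seconds (default 2).
#' @return An object of class `epoched_recording`: a list with `samples`
#'   (array channel x epoch x time, uV), `fs`, `epoch_length`, `channels`.
#' @export
segment_recording <- function(recording, epoch_length = 2) {
  assert_cols(recording, c("channel", "sample_index", "value_uv", "fs_hz"),
              "`recording`")
  fs <- unique(recording$fs_hz)
  if (length(fs) != 1L) abort("`recording` must have a single sampling rate.")
  channels <- unique(recording$channel)
  n_per_epoch <- round(epoch_length * fs)
  wide <- tidyr::pivot_wider(recording[c("channel", "sample_index", "value_uv")],
                             names_from = "channel", values_from = "value_uv")
  wide <- wide[order(wide$sample_index), , drop = FALSE]
  n_samples <- nrow(wide)
  if (n_samples < n_per_epoch) {
    abort("Recording is shorter than one epoch.")
  }
  n_epochs <- n_samples %/% n_per_epoch
  samples <- array(NA_real_,
                   dim = c(length(channels), n_epochs, n_per_epoch),
                   dimnames = list(channels, NULL, NULL))
  for (ci in seq_along(channels)) {
    x <- wide[[channels[ci]]][seq_len(n_epochs * n_per_epoch)]
    samples[ci, , ] <- matrix(x, nrow = n_epochs, byrow = TRUE)
  }
  structure(list(samples = samples, fs = fs, epoch_length = epoch_length,
                 channels = channels),
            class = "epoched_recording")
}

#' @export
print.epoched_recording <- function(x, ...) {
  d <- dim(x$samples)
  cat(sprintf("<epoched_recording> %d channel(s), %d epoch(s) of %.3g s at %g Hz\n",
              d[1], d[2], x$epoch_length, x$fs))
  invisible(x)
}

#' Reject epochs exceeding an amplitude limit
#'
#' Drops every epoch in which any channel's absolute amplitude exceeds
#' `amp_limit` (default 40 uV, the pipeline's rejection limit for
#' artifact-contaminated segments) and reports retention counts.
#'
#' @param epochs an `epoched_recording` from [segment_recording()].
#' @param amp_limit rejection threshold in uV (> 0).
#' @return A list with `epochs` (the retained `epoched_recording`) and
#'   `report` (a one-row QC tibble: `n_total_segments`, `n_good_segments`,
#'   `pct_good_channels`, `retained_artifact_probability`).
#'   `pct_good_channels` and the artifact probability are not computable
#'   from amplitude-only input and default to pass-through values (100 and
#'   `NA`); supply measured values to [qc_gate()] when available upstream.
#' @export
reject_epochs <- function(epochs, amp_limit = 40) {
  stopifnot(inherits(epochs, "epoched_recording"))
  if (amp_limit <= 0) abort("`amp_limit` must be > 0.")
  peak <- apply(abs(epochs$samples), 2, max)   # max |amplitude| per epoch
  keep <- peak <= amp_limit
  kept <- epochs
  kept$samples <- epochs$samples[, keep, , drop = FALSE]
  report <- tibble(
    n_total_segments = length(keep),
    n_good_segments = sum(keep),
    pct_good_channels = 100,
    retained_artifact_probability = NA_real_
  )
  list(epochs = kept, report = report)
}

#' Apply file-retention quality-control gates
#'
#' Decides whether a recording enters the analysis. A file is included iff
#' it has at least `min_good_segments` good 2-s segments, more than
#' `min_pct_good_channels` percent good channels, and a retained artifact
#' probability strictly below `max_artifact_probability`. Any gate whose
#' input is missing (`NA`) yields an explicit `"ungateable"` decision,
#' never a silent pass.
#'
#' @param report one-row data frame (or list) with `n_good_segments`,
#'   `pct_good_channels`, `retained_artifact_probability`.
#' @param min_good_segments minimum good segments (default 20).
#' @param min_pct_good_channels exclusive lower bound on percent good
#'   channels (default 80).
#' @param max_artifact_probability exclusive upper bound on retained
#'   artifact probability (default 0.3).
#' @return A one-row tibble: `decision` in `{"include","exclude","ungateable"}`
#'   plus a `reason` string.
#' @export
qc_gate <- function(report, min_good_segments = 20,
                    min_pct_good_channels = 80,
                    max_artifact_probability = 0.3) {
  g <- function(x) if (is.null(report[[x]])) NA_real_ else as.numeric(report[[x]])
  seg <- g("n_good_segments")
  pct <- g("pct_good_channels")
  prob <- g("retained_artifact_probability")
  if (any(is.na(c(seg, pct, prob)))) {
    missing <- c("n_good_segments", "pct_good_channels",
                 "retained_artifact_probability")[is.na(c(seg, pct, prob))]
    return(tibble(decision = "ungateable",
                  reason = paste("missing:", paste(missing, collapse = ", "))))
  }
  fails <- c(
    if (seg < min_good_segments)
      sprintf("n_good_segments %g < %g", seg, min_good_segments),
    if (pct <= min_pct_good_channels)
      sprintf("pct_good_channels %g <= %g", pct, min_pct_good_channels),
    if (prob >= max_artifact_probability)
      sprintf("retained_artifact_probability %g >= %g", prob,
              max_artifact_probability)
  )
  if (length(fails) == 0L) {
    tibble(decision = "include", reason = "all gates passed")
  } else {
    tibble(decision = "exclude", reason = paste(fails, collapse = "; "))
  }
}

# ---- Discrete prolate spheroidal (Slepian) tapers --------------------------

# DPSS tapers of length n with half-bandwidth parameter W = nw/n, via the
# standard symmetric tridiagonal eigenproblem; returns an n x k matrix of
# unit-energy tapers. Cached per (n, nw, k).
dpss_cache <- new.env(parent = emptyenv())

dpss_tapers <- function(n, nw = 2, k = 3) {
  key <- paste(n, nw, k, sep = "_")
  if (!is.null(dpss_cache[[key]])) return(dpss_cache[[key]])
  w <- nw / n
  i <- seq_len(n) - 1
  diag_main <- ((n - 1 - 2 * i) / 2)^2 * cos(2 * pi * w)
  off <- i[-1] * (n - i[-1]) / 2
  A <- matrix(0, n, n)
  A[cbind(seq_len(n), seq_len(n))] <- diag_main
  A[cbind(seq_len(n - 1), 2:n)] <- off
  A[cbind(2:n, seq_len(n - 1))] <- off
  e <- eigen(A, symmetric = TRUE)
  tapers <- e$vectors[, seq_len(k), drop = FALSE]
  # unit energy and positive-mean (even) / positive-initial-slope (odd) sign
  for (j in seq_len(k)) {
    tj <- tapers[, j] / sqrt(sum(tapers[, j]^2))
    if (j %% 2 == 1) {
      if (sum(tj) < 0) tj <- -tj
    } else {
      if (sum(tj * seq_len(n)) < 0) tj <- -tj
    }
    tapers[, j] <- tj
  }
  dpss_cache[[key]] <- tapers
  tapers
}

#' Multitaper power spectral density per channel
#'
#' Estimates each channel's PSD by the multitaper method: each epoch is
#' multiplied by `n_tapers` orthogonal discrete prolate spheroidal (Slepian)
#' tapers, the eigenspectra are averaged with equal weight, and the result
#' is averaged across epochs. With 2-s epochs the native grid spacing is
#' 0.5 Hz. The default three tapers correspond to a time-bandwidth product
#' NW = 2 (K = 2NW - 1).
#'
#' @param epochs an `epoched_recording`.
#' @param n_tapers number of tapers (default 3).
#' @param nw time-bandwidth product (default 2).
#' @return A tibble with columns `channel`, `freq_hz`, `power_uv2_per_hz`
#'   (one-sided PSD on the grid 0 .. fs/2).
#' @export
multitaper_psd <- function(epochs, n_tapers = 3, nw = 2) {
  stopifnot(inherits(epochs, "epoched_recording"))
  d <- dim(epochs$samples)
  if (d[2] < 1L) abort("At least one epoch is required.")
  n <- d[3]
  fs <- epochs$fs
  tapers <- dpss_tapers(n, nw = nw, k = n_tapers)
  nyq <- n %/% 2
  freqs <- (0:nyq) * fs / n
  one_sided_scale <- c(1, rep(2, nyq - 1), if (n %% 2 == 0) 1 else 2)

  out <- vector("list", d[1])
  for (ci in seq_len(d[1])) {
    acc <- numeric(nyq + 1)
    for (ei in seq_len(d[2])) {
      x <- epochs$samples[ci, ei, ]
      tapered <- tapers * x           # n x k
      spec <- stats::mvfft(tapered)
      p <- rowMeans(abs(spec[1:(nyq + 1), , drop = FALSE])^2) / fs
      acc <- acc + p * one_sided_scale
    }
    out[[ci]] <- tibble(channel = epochs$channels[ci], freq_hz = freqs,
                        power_uv2_per_hz = acc / d[2])
  }
  bind_rows(out)
}
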