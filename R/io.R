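# Tidy on-disk formats: spectra and periodic curves as TSV, clinical and
# feature tables as CSV, run configuration as YAML.

spectra_cols <- c("subject_id", "channel", "freq_hz", "power_uv2_per_hz")
clinical_cols <- c("subject_id", "group", "age_months", "sex",
                   "seizure_frequency_category", "current_medications",
                   "seizure_types", "infantile_spasms",
                   "mullen_vr_ae", "mullen_fm_ae", "mullen_el_ae",
                   "mullen_rl_ae")

#' Read and write tidy spectra tables
#'
#' Spectra are stored as TSV with columns `subject_id`, `channel`,
#' `freq_hz`, `power_uv2_per_hz` (extra columns such as `group` are
#' preserved).
#'
#' @param spectra spectra tibble.
#' @param path file path.
#' @return `read_spectra()` returns the tibble; `write_spectra()` returns
#'   `path` invisibly.
#' @export
write_spectra <- function(spectra, path) {
  assert_cols(spectra, spectra_cols, "`spectra`")
  readr::write_tsv(spectra, path)
  invisible(path)
}

#' @rdname write_spectra
#' @export
read_spectra <- function(path) {
  sp <- readr::read_tsv(path, show_col_types = FALSE,
                        col_types = readr::cols(
                          channel = readr::col_character(),
                          .default = readr::col_guess()))
  assert_cols(sp, spectra_cols, basename(path))
  sp
}

#' Read and write the clinical table
#'
#' CSV with a strict documented header: `subject_id`, `group`,
#' `age_months`, `sex`, `seizure_frequency_category`,
#' `current_medications` (`;`-separated), `seizure_types` (`;`-separated),
#' `infantile_spasms` (current/past/never), and the four Mullen
#' age-equivalent columns (`mullen_vr_ae`, `mullen_fm_ae`, `mullen_el_ae`,
#' `mullen_rl_ae`, months).
#'
#' @param clinical clinical tibble.
#' @param path file path.
#' @return `read_clinical()` returns the tibble; `write_clinical()` returns
#'   `path` invisibly.
#' @export
write_clinical <- function(clinical, path) {
  assert_cols(clinical, clinical_cols, "`clinical`")
  readr::write_csv(clinical, path)
  invisible(path)
}

#' @rdname write_clinical
#' @export
read_clinical <- function(path) {
  cl <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(
                          subject_id = readr::col_character(),
                          current_medications = readr::col_character(),
                          seizure_types = readr::col_character(),
                          .default = readr::col_guess()))
  missing <- setdiff(clinical_cols, names(cl))
  if (length(missing) > 0L) {
    abort(sprintf("Clinical file %s is missing column(s): %s",
                  basename(path), paste(missing, collapse = ", ")))
  }
  cl$current_medications[is.na(cl$current_medications)] <- ""
  cl$seizure_types[is.na(cl$seizure_types)] <- ""
  cl
}

#' Write feature tables to CSV
#'
#' Writes the three tables of an `eeg_features` object
#' (`<stem>_band_power.csv`, `<stem>_band_peaks.csv`,
#' `<stem>_aperiodic.csv`).
#'
#' @param features an `eeg_features` object.
#' @param stem path stem (directory + prefix).
#' @return The three paths, invisibly.
#' @export
write_features <- function(features, stem) {
  stopifnot(inherits(features, "eeg_features"))
  paths <- paste0(stem, c("_band_power.csv", "_band_peaks.csv",
                          "_aperiodic.csv"))
  readr::write_csv(features$band_power, paths[1])
  readr::write_csv(features$band_peaks, paths[2])
  readr::write_csv(features$aperiodic, paths[3])
  invisible(paths)
}

#' Read and write run configuration
#'
#' YAML round-trip of the [run_config()] list.
#'
#' @param config a run configuration list.
#' @param path file path.
#' @return `read_run_config()` returns the list merged over defaults.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  user <- yaml::read_yaml(path)
  modifyList(run_config(), user)
}
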