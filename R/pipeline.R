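#' Default run configuration
#'
#' Collects every analysis constant in one place. Defaults reproduce the
#' study configuration bit-exactly: 2-55 Hz fixed-mode aperiodic fit, peak
#' width limits 0.5-18.0 Hz, at most 7 peaks, peak threshold 2, 40 uV
#' epoch rejection, 20-good-segment / >80% channel / <0.3 artifact
#' probability retention gates, 2-44 Hz cluster test range, 1000
#' permutations.
#'
#' @param output_dir directory for stage artifacts.
#' @param seed integer seed for every stochastic stage.
#' @param n_per_group cohort size per group for the simulate stage.
#' @param n_perm cluster permutations.
#' @param freq_range aperiodic fit range (Hz).
#' @param peak_width_limits,max_n_peaks,peak_threshold parameterization
#'   settings.
#' @param amp_limit epoch rejection limit (uV).
#' @param min_good_segments,min_pct_good_channels,max_artifact_probability
#'   QC gates.
#' @param cluster_range cluster test range (Hz).
#' @param cluster_alpha cluster-forming alpha.
#' @param bands,rois optional overrides (data frames coercible to the
#'   [band_definitions()] / [roi_definitions()] layouts).
#' @return A named list (class `run_config`).
#' @export
run_config <- function(output_dir = "periospec_run",
                       seed = 1,
                       n_per_group = 49,
                       n_perm = 1000,
                       freq_range = c(2, 55),
                       peak_width_limits = c(0.5, 18.0),
                       max_n_peaks = 7,
                       peak_threshold = 2,
                       amp_limit = 40,
                       min_good_segments = 20,
                       min_pct_good_channels = 80,
                       max_artifact_probability = 0.3,
                       cluster_range = c(2, 44),
                       cluster_alpha = 0.05,
                       bands = NULL,
                       rois = NULL) {
  structure(list(
    output_dir = output_dir, seed = seed, n_per_group = n_per_group,
    n_perm = n_perm, freq_range = freq_range,
    peak_width_limits = peak_width_limits, max_n_peaks = max_n_peaks,
    peak_threshold = peak_threshold, amp_limit = amp_limit,
    min_good_segments = min_good_segments,
    min_pct_good_channels = min_pct_good_channels,
    max_artifact_probability = max_artifact_probability,
    cluster_range = cluster_range, cluster_alpha = cluster_alpha,
    bands = bands, rois = rois
  ), class = c("run_config", "list"))
}

config_bands <- function(config) {
  if (is.null(config$bands)) band_definitions()
  else as_tibble(as.data.frame(config$bands))
}

config_rois <- function(config) {
  if (is.null(config$rois)) return(roi_definitions())
  r <- config$rois
  if (is.data.frame(r)) as_tibble(r)
  else tibble(roi = names(r),
              electrode = lapply(r, as.character))
}

config_settings <- function(config) {
  specparam_settings(freq_range = config$freq_range,
                     max_n_peaks = config$max_n_peaks,
                     peak_threshold = config$peak_threshold,
                     peak_width_limits = config$peak_width_limits)
}

stage_log <- function(dir, stage, settings, inputs, outputs) {
  log <- list(
    stage = stage,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    settings = settings,
    inputs = inputs,
    outputs = lapply(outputs, function(p) {
      list(path = p, md5 = unname(tools::md5sum(p)))
    })
  )
  path <- file.path(dir, sprintf("log_%s.json", stage))
  jsonlite::write_json(log, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

stage_done <- function(dir, stage, outputs) {
  log_path <- file.path(dir, sprintf("log_%s.json", stage))
  if (!file.exists(log_path) || !all(file.exists(outputs))) return(FALSE)
  log <- tryCatch(jsonlite::read_json(log_path), error = function(e) NULL)
  if (is.null(log)) return(FALSE)
  recorded <- vapply(log$outputs, function(o) o$md5 %||% "", character(1))
  paths <- vapply(log$outputs, function(o) o$path %||% "", character(1))
  setequal(paths, outputs) &&
    all(unname(tools::md5sum(paths)) == recorded)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full analysis pipeline
#'
#' Executes the stages `simulate` -> `parameterize` -> `features` ->
#' `clinical` -> `stats` on a synthetic cohort, writing each stage's table
#' plus a machine-readable JSON log (settings, seed, output checksums)
#' under `config$output_dir`. Stages whose recorded outputs already exist
#' with matching checksums are skipped, so partial runs resume. Every
#' artifact is reproducible from the config and seed alone.
#'
#' @param config a [run_config()] (or path to a YAML file readable by
#'   [read_run_config()]).
#' @param stages subset of stages to run (in pipeline order).
#' @param force if `TRUE`, rerun stages even when up to date.
#' @return Invisibly, a list of artifact paths plus the final stats report.
#' @export
run_pipeline <- function(config = run_config(),
                         stages = c("simulate", "parameterize", "features",
                                    "clinical", "stats"),
                         force = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  dir <- config$output_dir
  settings <- config_settings(config)
  bands <- config_bands(config)
  rois <- config_rois(config)

  paths <- list(
    spectra = file.path(dir, "spectra.tsv"),
    clinical_raw = file.path(dir, "clinical.csv"),
    aperiodic = file.path(dir, "parameterization.csv"),
    peaks = file.path(dir, "peaks.csv"),
    periodic = file.path(dir, "periodic.tsv"),
    features_stem = file.path(dir, "features"),
    clinical_scored = file.path(dir, "clinical_scored.csv"),
    stats = file.path(dir, "stats_report.json"),
    stats_txt = file.path(dir, "stats_summary.txt")
  )

  if ("simulate" %in% stages) {
    outs <- c(paths$spectra, paths$clinical_raw)
    if (force || !stage_done(dir, "simulate", outs)) {
      cohort <- simulate_cohort(cohort_config(
        n_per_group = config$n_per_group, seed = config$seed,
        channel_roles = tidyr::unnest(rois, "electrode")))
      write_spectra(cohort$spectra, paths$spectra)
      write_clinical(cohort$clinical, paths$clinical_raw)
      stage_log(dir, "simulate",
                list(seed = config$seed, n_per_group = config$n_per_group),
                list(), outs)
    }
  }

  if ("parameterize" %in% stages) {
    outs <- c(paths$aperiodic, paths$peaks, paths$periodic)
    if (force || !stage_done(dir, "parameterize", outs)) {
      spectra <- read_spectra(paths$spectra)
      roi_avg <- roi_average(spectra, rois)
      id_cols <- setdiff(names(roi_avg),
                         c("channel", "freq_hz", "power_uv2_per_hz",
                           "n_channels", "n_missing"))
      fits <- parameterize_spectra(roi_avg, by = id_cols,
                                   settings = settings)
      readr::write_csv(fits[, setdiff(names(fits), "fit")], paths$aperiodic)
      readr::write_csv(peak_table(fits), paths$peaks)
      readr::write_tsv(periodic_table(fits), paths$periodic)
      stage_log(dir, "parameterize", settings,
                list(spectra = paths$spectra), outs)
    }
  }

  if ("features" %in% stages) {
    outs <- paste0(paths$features_stem,
                   c("_band_power.csv", "_band_peaks.csv", "_aperiodic.csv"))
    if (force || !stage_done(dir, "features", outs)) {
      spectra <- read_spectra(paths$spectra)
      feats <- extract_features(spectra, rois = rois, bands = bands,
                                settings = settings)
      write_features(feats, paths$features_stem)
      stage_log(dir, "features",
                list(bands = as.data.frame(bands),
                     rois = as.data.frame(tidyr::unnest(rois, "electrode")),
                     settings = settings),
                list(spectra = paths$spectra), outs)
    }
  }

  if ("clinical" %in% stages) {
    outs <- paths$clinical_scored
    if (force || !stage_done(dir, "clinical", outs)) {
      clin <- read_clinical(paths$clinical_raw)
      scored <- clin %>%
        score_seizure_severity() %>%
        classify_gaba() %>%
        compute_dq()
      readr::write_csv(scored, paths$clinical_scored)
      stage_log(dir, "clinical", list(), list(clinical = paths$clinical_raw),
                outs)
    }
  }

  report <- NULL
  if ("stats" %in% stages) {
    outs <- c(paths$stats, paths$stats_txt)
    if (force || !stage_done(dir, "stats", outs)) {
      report <- compute_stats_report(paths, config, bands, rois, settings)
      jsonlite::write_json(report, paths$stats, auto_unbox = TRUE,
                           pretty = TRUE, digits = NA, dataframe = "rows")
      writeLines(format_stats_summary(report), paths$stats_txt)
      stage_log(dir, "stats",
                list(n_perm = config$n_perm,
                     cluster_range = config$cluster_range,
                     cluster_alpha = config$cluster_alpha,
                     seed = config$seed),
                list(periodic = paths$periodic,
                     clinical = paths$clinical_scored), outs)
    } else {
      report <- jsonlite::read_json(paths$stats, simplifyVector = TRUE)
    }
  }

  invisible(list(paths = paths, report = report))
}

# The group-level statistical battery run by the `stats` stage.
compute_stats_report <- function(paths, config, bands, rois, settings) {
  periodic <- readr::read_tsv(paths$periodic, show_col_types = FALSE)
  clinical <- readr::read_csv(paths$clinical_scored, show_col_types = FALSE)
  feats_ap <- readr::read_csv(paste0(paths$features_stem, "_aperiodic.csv"),
                              show_col_types = FALSE)
  feats_pk <- readr::read_csv(paste0(paths$features_stem, "_band_peaks.csv"),
                              show_col_types = FALSE)

  frontal <- periodic[periodic$roi == "frontal", ]
  cluster <- cluster_permutation_test(
    frontal, value = "periodic_log10", group = "group",
    subject = "subject_id", freq_range = config$cluster_range,
    n_perm = config$n_perm, cluster_alpha = config$cluster_alpha,
    seed = config$seed)

  ap_wide <- tidyr::pivot_wider(
    feats_ap[, c("subject_id", "group", "roi", "offset", "exponent")],
    names_from = "roi", values_from = c("offset", "exponent"),
    names_glue = "{roi}_{.value}")
  logit <- logistic_group_model(ap_wide, outcome = "group")

  pk <- feats_pk[feats_pk$roi == "frontal" & feats_pk$band == "broad_beta", ]
  pk <- dplyr::left_join(
    pk, clinical[, c("subject_id", "severity_class", "gaba_status")],
    by = "subject_id")
  tsc <- pk[pk$group == "TSC" & pk$gaba_status != "unclassified" &
              pk$severity_class != "unscoreable", ]
  anova_res <- two_way_anova(tsc, outcome = "peak_power_log10",
                             factor1 = "severity_class",
                             factor2 = "gaba_status")
  tukey_sev <- tukey_hsd(tsc, "peak_power_log10", "severity_class")

  list(
    clusters = as.data.frame(tidy.cluster_result(cluster)),
    logistic = as.data.frame(tidy.logistic_group_model(logit)),
    logistic_separation = logit$separation,
    anova = as.data.frame(tidy.anova_result(anova_res)),
    tukey_severity = as.data.frame(tukey_sev),
    n_tsc = sum(clinical$group == "TSC"),
    n_td = sum(clinical$group == "TD")
  )
}

format_stats_summary <- function(report) {
  c(sprintf("Cohort: %d cases, %d controls", report$n_tsc, report$n_td),
    "",
    "Cluster permutation (frontal periodic power):",
    utils::capture.output(print(report$clusters)),
    "",
    "Logistic group model (aperiodic features):",
    utils::capture.output(print(report$logistic)),
    "",
    "Two-way ANOVA (frontal broad-beta peak ~ severity * GABA):",
    utils::capture.output(print(report$anova)))
}
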