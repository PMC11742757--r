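#' Score the seizure-severity composite (E-Chess style)
#'
#' The composite is the sum of three components: seizure frequency over the
#' last two months on an ordinal 0-4 scale (0 = no seizures, 4 = more than
#' daily), the number of current anti-epileptic medications (capped at 6),
#' and the number of distinct seizure types reported (capped at 5). Totals
#' are classified low (0-2), moderate (3-7) or high (>= 8). The printed
#' composite range is 0-12; totals above 12 are allowed, classed high, and
#' flagged in `over_printed_range`. A profile missing any component is
#' explicitly unscoreable (`NA` total, `severity_class = "unscoreable"`).
#'
#' Medication and seizure-type lists may be given as `;`-separated strings
#' or list columns.
#'
#' @param clinical tibble with columns `seizure_frequency_category` (0-4),
#'   `current_medications`, `seizure_types` (plus any id columns, carried).
#' @return The input tibble with added columns `frequency_points`,
#'   `medication_points`, `type_points`, `severity_total`,
#'   `severity_class`, `over_printed_range`.
#' @export
score_seizure_severity <- function(clinical) {
  assert_cols(clinical, c("seizure_frequency_category", "current_medications",
                          "seizure_types"), "`clinical`")
  freq <- clinical$seizure_frequency_category
  if (any(!is.na(freq) & (freq < 0 | freq > 4))) {
    abort("`seizure_frequency_category` must be in 0..4.")
  }
  n_meds <- count_listed(clinical$current_medications)
  n_types <- count_listed(clinical$seizure_types, distinct = TRUE)
  med_pts <- pmin(n_meds, 6L)
  type_pts <- pmin(n_types, 5L)
  total <- freq + med_pts + type_pts
  cls <- ifelse(is.na(total), "unscoreable", classify_severity_chr(total))
  mutate(clinical,
         frequency_points = freq,
         medication_points = med_pts,
         type_points = type_pts,
         severity_total = total,
         severity_class = cls,
         over_printed_range = !is.na(total) & total > 12)
}

# Count entries in a list column or ";"-separated string column.
count_listed <- function(x, distinct = FALSE) {
  if (is.list(x)) {
    vapply(x, function(v) {
      if (length(v) == 0L || all(is.na(v))) return(0L)
      v <- v[nzchar(v)]
      if (distinct) v <- unique(v)
      length(v)
    }, integer(1))
  } else {
    vapply(x, function(s) {
      if (is.na(s)) return(NA_integer_)
      parts <- strsplit(s, ";", fixed = TRUE)[[1]]
      parts <- trimws(parts)
      parts <- parts[nzchar(parts)]
      if (distinct) parts <- unique(parts)
      length(parts)
    }, integer(1), USE.NAMES = FALSE)
  }
}

classify_severity_chr <- function(total) {
  ifelse(total <= 2, "low", ifelse(total <= 7, "moderate", "high"))
}

#' Classify a severity composite total
#'
#' Low for totals 0-2, moderate for 3-7, high for 8 and above.
#'
#' @param total non-negative integer composite total(s).
#' @return Character vector of classes.
#' @export
classify_severity <- function(total) {
  if (any(total < 0, na.rm = TRUE)) abort("`total` must be >= 0.")
  classify_severity_chr(total)
}

#' Read a medication-mechanism ontology
#'
#' Two-column CSV (`medication`, `class`) mapping each anti-epileptic drug
#' name to `GABAergic` or `non-GABAergic`. A small built-in ontology
#' covering the generator's vocabulary ships with the package.
#'
#' @param path CSV path; default is the packaged ontology.
#' @return Tibble with columns `medication`, `class`.
#' @export
read_medication_ontology <- function(path = system.file(
    "extdata", "medication_ontology.csv", package = "periospec")) {
  ont <- readr::read_csv(path, show_col_types = FALSE)
  assert_cols(ont, c("medication", "class"), "medication ontology")
  bad <- setdiff(unique(ont$class), c("GABAergic", "non-GABAergic"))
  if (length(bad) > 0L) {
    abort(sprintf("Unknown ontology class(es): %s", paste(bad, collapse = ", ")))
  }
  ont
}

#' Classify children by GABAergic medication use
#'
#' A child is `on_gaba` if at least one current medication maps to
#' `GABAergic` in the ontology; `unclassified` if any medication name is
#' unknown to the ontology and none is known-GABAergic (never a silent
#' default); otherwise `off_gaba` (including no medications).
#'
#' @param clinical tibble with a `current_medications` column (list or
#'   `;`-separated string).
#' @param ontology tibble from [read_medication_ontology()].
#' @return Input tibble with an added `gaba_status` column.
#' @export
classify_gaba <- function(clinical, ontology = read_medication_ontology()) {
  assert_cols(clinical, "current_medications", "`clinical`")
  meds_list <- split_listed(clinical$current_medications)
  gaba_names <- ontology$medication[ontology$class == "GABAergic"]
  known <- ontology$medication
  status <- vapply(meds_list, function(m) {
    if (length(m) == 0L) return("off_gaba")
    if (any(m %in% gaba_names)) return("on_gaba")
    if (any(!(m %in% known))) return("unclassified")
    "off_gaba"
  }, character(1))
  mutate(clinical, gaba_status = status)
}

split_listed <- function(x) {
  if (is.list(x)) {
    lapply(x, function(v) {
      v <- v[!is.na(v)]
      v[nzchar(v)]
    })
  } else {
    lapply(x, function(s) {
      if (is.na(s)) return(character())
      parts <- trimws(strsplit(s, ";", fixed = TRUE)[[1]])
      parts[nzchar(parts)]
    })
  }
}

#' Compute Mullen developmental quotients
#'
#' Per-subscale DQ = 100 x age-equivalent / chronological age; the
#' nonverbal DQ averages visual reception and fine motor, the verbal DQ
#' averages expressive and receptive language.
#'
#' @param clinical tibble with `age_months`, `mullen_vr_ae`, `mullen_fm_ae`,
#'   `mullen_el_ae`, `mullen_rl_ae` (age equivalents in months).
#' @return Input tibble with added `nonverbal_dq` and `verbal_dq`.
#' @export
compute_dq <- function(clinical) {
  assert_cols(clinical, c("age_months", "mullen_vr_ae", "mullen_fm_ae",
                          "mullen_el_ae", "mullen_rl_ae"), "`clinical`")
  if (any(clinical$age_months <= 0, na.rm = TRUE)) {
    abort("`age_months` must be > 0.")
  }
  mutate(clinical,
         nonverbal_dq = 100 * (.data$mullen_vr_ae + .data$mullen_fm_ae) / 2 /
           .data$age_months,
         verbal_dq = 100 * (.data$mullen_el_ae + .data$mullen_rl_ae) / 2 /
           .data$age_months)
}

#' Greedy 1:1 age- and sex-matched control selection
#'
#' Pairs each case with an unused control of the same sex, assigning in
#' order of increasing best-available age gap (the case whose closest
#' remaining same-sex control is nearest in age is matched first). Ties
#' break by lower subject id. Cases with no same-sex candidate remain in
#' the output with `matched = FALSE`, never silently dropped. Greedy
#' matching is transparent but not guaranteed optimal in total age gap.
#'
#' @param cases,pool tibbles with `subject_id`, `age_months`, `sex`.
#' @return Tibble: `case_id`, `control_id`, `case_age`, `control_age`,
#'   `age_gap`, `sex`, `matched`.
#' @export
match_controls <- function(cases, pool) {
  for (d in list(cases, pool)) {
    assert_cols(d, c("subject_id", "age_months", "sex"), "matching input")
  }
  remaining_cases <- cases[order(cases$subject_id), ]
  remaining_pool <- pool[order(pool$subject_id), ]
  out <- list()
  while (nrow(remaining_cases) > 0L) {
    # best available gap per case
    best <- lapply(seq_len(nrow(remaining_cases)), function(i) {
      ci <- remaining_cases[i, ]
      cand <- remaining_pool[remaining_pool$sex == ci$sex, ]
      if (nrow(cand) == 0L) return(NULL)
      gaps <- abs(cand$age_months - ci$age_months)
      j <- order(gaps, cand$subject_id)[1]
      list(gap = gaps[j], control = cand[j, ])
    })
    has_cand <- !vapply(best, is.null, logical(1))
    if (!any(has_cand)) {
      for (i in seq_len(nrow(remaining_cases))) {
        ci <- remaining_cases[i, ]
        out[[length(out) + 1L]] <- tibble(
          case_id = ci$subject_id, control_id = NA_character_,
          case_age = ci$age_months, control_age = NA_real_,
          age_gap = NA_real_, sex = ci$sex, matched = FALSE)
      }
      break
    }
    gaps <- vapply(best, function(b) if (is.null(b)) Inf else b$gap, numeric(1))
    i <- order(gaps, remaining_cases$subject_id)[1]
    ci <- remaining_cases[i, ]
    ctrl <- best[[i]]$control
    out[[length(out) + 1L]] <- tibble(
      case_id = ci$subject_id, control_id = as.character(ctrl$subject_id),
      case_age = ci$age_months, control_age = ctrl$age_months,
      age_gap = gaps[i], sex = ci$sex, matched = TRUE)
    remaining_cases <- remaining_cases[-i, ]
    remaining_pool <- remaining_pool[remaining_pool$subject_id != ctrl$subject_id, ]
  }
  arrange(bind_rows(out), .data$case_id)
}
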