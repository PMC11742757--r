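profile_row <- function(freq, n_meds, n_types) {
  meds <- if (n_meds == 0) "" else
    paste(sprintf("med%02d", seq_len(n_meds)), collapse = ";")
  types <- if (n_types == 0) "" else
    paste(sprintf("type%d", seq_len(n_types)), collapse = ";")
  tibble::tibble(seizure_frequency_category = freq,
                 current_medications = meds, seizure_types = types)
}

test_that("the severity composite sums its three components with caps", {
  zero <- score_seizure_severity(profile_row(0, 0, 0))
  expect_equal(zero$severity_total, 0)
  expect_equal(zero$severity_class, "low")

  nine <- score_seizure_severity(profile_row(4, 3, 2))
  expect_equal(nine$severity_total, 9)
  expect_equal(nine$severity_class, "high")

  three <- score_seizure_severity(profile_row(1, 1, 1))
  expect_equal(three$severity_total, 3)
  expect_equal(three$severity_class, "moderate")

  # caps: medications at 6, types at 5
  capped <- score_seizure_severity(profile_row(0, 9, 7))
  expect_equal(capped$medication_points, 6)
  expect_equal(capped$type_points, 5)
  expect_true(capped$over_printed_range == (capped$severity_total > 12))

  # duplicate type names count once
  dup <- score_seizure_severity(tibble::tibble(
    seizure_frequency_category = 0,
    current_medications = "",
    seizure_types = "focal;focal;drop"))
  expect_equal(dup$type_points, 2)

  # missing component: explicit unscoreable, never a silent number
  mis <- score_seizure_severity(tibble::tibble(
    seizure_frequency_category = NA_integer_,
    current_medications = "", seizure_types = ""))
  expect_true(is.na(mis$severity_total))
  expect_equal(mis$severity_class, "unscoreable")
})

test_that("severity class boundaries are exact", {
  expect_equal(classify_severity(c(0, 2, 3, 7, 8, 12, 15)),
               c("low", "low", "moderate", "moderate", "high", "high", "high"))
  expect_error(classify_severity(-1), ">= 0")
})

test_that("totals are monotone in each component over the full component grid", {
  grid <- expand.grid(freq = 0:4, meds = 0:6, types = 0:5)
  rows <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    profile_row(grid$freq[i], grid$meds[i], grid$types[i])
  }))
  scored <- score_seizure_severity(rows)
  expect_equal(nrow(scored), 210)
  expect_equal(scored$severity_total,
               grid$freq + grid$meds + grid$types)
  expect_equal(classify_severity(scored$severity_total),
               scored$severity_class)
  # monotone non-decreasing in each component
  for (comp in c("freq", "meds", "types")) {
    others <- setdiff(c("freq", "meds", "types"), comp)
    sp <- split(scored$severity_total,
                interaction(grid[[others[1]]], grid[[others[2]]]))
    ord <- split(grid[[comp]], interaction(grid[[others[1]]], grid[[others[2]]]))
    for (k in seq_along(sp)) {
      expect_true(all(diff(sp[[k]][order(ord[[k]])]) >= 0))
    }
  }
})

test_that("GABA classification follows the ontology with an explicit gap rule", {
  ont <- read_medication_ontology()
  mk <- function(meds) tibble::tibble(current_medications = meds)
  expect_equal(classify_gaba(mk("vigabatrin"), ont)$gaba_status, "on_gaba")
  expect_equal(classify_gaba(mk(""), ont)$gaba_status, "off_gaba")
  expect_equal(classify_gaba(mk("levetiracetam"), ont)$gaba_status, "off_gaba")
  expect_equal(classify_gaba(mk("mystery_drug"), ont)$gaba_status, "unclassified")
  # a known GABAergic drug outranks an unknown co-medication
  expect_equal(classify_gaba(mk("mystery_drug;vigabatrin"), ont)$gaba_status,
               "on_gaba")
})

test_that("developmental quotients follow the age-equivalent ratio", {
  base <- tibble::tibble(age_months = 24, mullen_vr_ae = 24, mullen_fm_ae = 24,
                         mullen_el_ae = 24, mullen_rl_ae = 24)
  dq <- compute_dq(base)
  expect_equal(dq$verbal_dq, 100)
  expect_equal(dq$nonverbal_dq, 100)

  dq2 <- compute_dq(dplyr::mutate(base, mullen_vr_ae = 12, mullen_fm_ae = 12))
  expect_equal(dq2$nonverbal_dq, 50)

  dq3 <- compute_dq(tibble::tibble(age_months = 20, mullen_vr_ae = 20,
                                   mullen_fm_ae = 20, mullen_el_ae = 18,
                                   mullen_rl_ae = 12))
  expect_equal(dq3$verbal_dq, 100 * (18 + 12) / 2 / 20)  # = 75

  expect_error(compute_dq(dplyr::mutate(base, age_months = 0)), "age")
})

test_that("matching is sex-exact, one-to-one, and reports the unmatched", {
  cases <- tibble::tibble(subject_id = c("C1", "C2"),
                          age_months = c(24, 30), sex = c("M", "F"))
  pool <- tibble::tibble(subject_id = c("P1", "P2", "P3"),
                         age_months = c(24, 30, 29), sex = c("M", "F", "F"))
  m <- match_controls(cases, pool)
  expect_equal(sum(m$age_gap), 0)
  expect_true(all(m$matched))

  # sex-exact: nearer-aged opposite-sex candidate is never used
  m2 <- match_controls(
    tibble::tibble(subject_id = "C1", age_months = 24, sex = "M"),
    tibble::tibble(subject_id = c("P1", "P2"), age_months = c(23, 24),
                   sex = c("M", "F")))
  expect_equal(m2$control_id, "P1")

  # no same-sex candidate: reported, not dropped
  m3 <- match_controls(
    tibble::tibble(subject_id = c("C1", "C2"), age_months = c(24, 25),
                   sex = c("M", "M")),
    tibble::tibble(subject_id = "P1", age_months = 24, sex = "M"))
  expect_equal(nrow(m3), 2)
  expect_equal(sum(m3$matched), 1)

  # controls are never reused
  m4 <- match_controls(
    tibble::tibble(subject_id = c("C1", "C2"), age_months = c(24, 24),
                   sex = c("M", "M")),
    tibble::tibble(subject_id = c("P1", "P2"), age_months = c(24, 26),
                   sex = c("M", "M")))
  expect_equal(sort(m4$control_id), c("P1", "P2"))
})

test_that("greedy matching is bounded below by the exhaustive optimum", {
  set.seed(19)
  for (rep in 1:5) {
    cases <- tibble::tibble(subject_id = sprintf("C%d", 1:6),
                            age_months = sample(12:37, 6),
                            sex = sample(c("M", "F"), 6, replace = TRUE))
    pool <- tibble::tibble(subject_id = sprintf("P%d", 1:6),
                           age_months = sample(12:37, 6),
                           sex = cases$sex[sample(6)])
    greedy <- match_controls(cases, pool)
    if (!all(greedy$matched)) next
    optimal <- oracle_optimal_matching_gap(cases, pool)
    expect_gte(sum(greedy$age_gap) + 1e-12, optimal)
  }
})
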