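null_model <- spectrum_model(0.5, 1, gaussian_peak(8, 0.4, 4), noise_sd = 0.05)
grid_2_44 <- seq(2, 44, by = 0.5)

test_that("identical groups yield no clusters; grids must match", {
  base <- simulate_spectrum(null_model, grid_2_44, seed = 3)
  curves <- dplyr::bind_rows(lapply(1:8, function(s) {
    tibble::tibble(subject_id = sprintf("S%d", s),
                   group = ifelse(s <= 4, "A", "B"),
                   freq_hz = base$freq_hz,
                   value = log10(base$power_uv2_per_hz))
  }))
  res <- cluster_permutation_test(curves, "value", "group", "subject_id",
                                  n_perm = 50, seed = 1)
  expect_equal(nrow(tidy(res)), 0)

  off_grid <- curves
  off_grid$freq_hz[off_grid$subject_id == "S1"] <-
    off_grid$freq_hz[off_grid$subject_id == "S1"] + 0.25
  expect_error(cluster_permutation_test(off_grid, "value", "group",
                                        "subject_id", n_perm = 10, seed = 1),
               "grid")
})

test_that("a localized beta increment produces a significant overlapping cluster", {
  m_b <- spectrum_model(0.5, 1,
                        rbind(gaussian_peak(8, 0.4, 4),
                              gaussian_peak(20, 0.3, 3)), noise_sd = 0.05)
  curves <- simulate_group_curves(null_model, m_b, 15, grid_2_44, seed = 6)
  res <- cluster_permutation_test(curves, "value", "group", "subject_id",
                                  n_perm = 300, seed = 6)
  cl <- tidy(res)
  sig <- cl[cl$p_value < 0.05, ]
  expect_gt(nrow(sig), 0)
  expect_true(any(sig$freq_lo <= 29 & sig$freq_hi >= 12))
})

test_that("label exchange negates cluster statistics but keeps p-values", {
  m_b <- spectrum_model(0.5, 1,
                        rbind(gaussian_peak(8, 0.4, 4),
                              gaussian_peak(20, 0.3, 3)), noise_sd = 0.05)
  curves <- simulate_group_curves(null_model, m_b, 10, grid_2_44, seed = 8)
  swapped <- dplyr::mutate(curves, group = ifelse(group == "A", "B", "A"))
  r1 <- cluster_permutation_test(curves, "value", "group", "subject_id",
                                 n_perm = 200, seed = 5)
  r2 <- cluster_permutation_test(swapped, "value", "group", "subject_id",
                                 n_perm = 200, seed = 5)
  expect_equal(tidy(r1)$cluster_stat, -tidy(r2)$cluster_stat)
  expect_equal(tidy(r1)$p_value, tidy(r2)$p_value)

  # reordering subjects within groups does not change the result
  shuffled <- curves[order(rev(curves$subject_id), curves$freq_hz), ]
  r3 <- cluster_permutation_test(shuffled, "value", "group", "subject_id",
                                 n_perm = 200, seed = 5)
  expect_equal(tidy(r1)$cluster_stat, tidy(r3)$cluster_stat)
  expect_equal(tidy(r1)$p_value, tidy(r3)$p_value)
})

test_that("the logistic group model recovers coefficients and flags pathologies", {
  set.seed(101)
  n <- 200
  b1_hat <- replicate(20, {
    x1 <- rnorm(n); x2 <- rnorm(n); x3 <- rnorm(n); x4 <- rnorm(n)
    p <- plogis(0 + 2 * x1)
    df <- tibble::tibble(group = ifelse(runif(n) < p, "g2", "g1"),
                         frontal_offset = x1, frontal_exponent = x2,
                         posterior_offset = x3, posterior_exponent = x4)
    fit <- logistic_group_model(df)
    tidy(fit)$estimate[tidy(fit)$term == "frontal_offset"]
  })
  expect_lt(abs(mean(b1_hat) - 2), 0.4)

  x1 <- rnorm(n); x2 <- rnorm(n); x3 <- rnorm(n); x4 <- rnorm(n)
  p <- plogis(0 + 2 * x1)
  df <- tibble::tibble(group = ifelse(runif(n) < p, "g2", "g1"),
                       frontal_offset = x1, frontal_exponent = x2,
                       posterior_offset = x3, posterior_exponent = x4)
  fit <- logistic_group_model(df)
  expect_false(fit$separation)
  expect_equal(tidy(fit)$odds_ratio, exp(tidy(fit)$estimate))
  expect_true(all(tidy(fit)$ci_low <= tidy(fit)$ci_high))

  # duplicated predictor: rank deficiency is an error
  df_dup <- dplyr::mutate(df, posterior_exponent = frontal_offset)
  expect_error(logistic_group_model(df_dup), "rank")

  # complete separation is flagged, not silently reported
  df_sep <- tibble::tibble(
    group = rep(c("g1", "g2"), each = 12),
    frontal_offset = c(rnorm(12, -4), rnorm(12, 4)),
    frontal_exponent = rnorm(24), posterior_offset = rnorm(24),
    posterior_exponent = rnorm(24))
  fit_sep <- logistic_group_model(df_sep)
  expect_true(fit_sep$separation)
})

test_that("Wald tests are calibrated under the null", {
  set.seed(77)
  n <- 48
  rej <- replicate(400, {
    df <- tibble::tibble(group = sample(rep(c("a", "b"), n / 2)),
                         frontal_offset = rnorm(n),
                         frontal_exponent = rnorm(n),
                         posterior_offset = rnorm(n),
                         posterior_exponent = rnorm(n))
    fit <- logistic_group_model(df)
    tidy(fit)$p_value[tidy(fit)$term == "frontal_offset"] < 0.05
  })
  expect_gte(mean(rej), 0.02)
  expect_lte(mean(rej), 0.09)
})

test_that("two-way ANOVA matches the textbook computation on a balanced toy", {
  toy <- tibble::tibble(
    y = c(3, 4, 5, 6, 7, 8, 2, 3, 4, 9, 10, 11),
    a = rep(c("a1", "a2"), each = 6),
    b = rep(rep(c("b1", "b2"), each = 3), 2))
  res <- two_way_anova(toy, "y", "a", "b")
  oracle <- oracle_two_way_anova(toy, "y", "a", "b")
  tt <- tidy(res)
  expect_equal(tt$statistic[tt$term == "a"], oracle$F_a, tolerance = 1e-10)
  expect_equal(tt$statistic[tt$term == "b"], oracle$F_b, tolerance = 1e-10)
  expect_equal(tt$statistic[tt$term == "a:b"], oracle$F_ab, tolerance = 1e-10)
  # Type I decomposition is exact
  expect_equal(sum(tt$sumsq), oracle$ss[["tot"]], tolerance = 1e-10)

  # empty cell: interaction dropped with a warning
  holey <- toy[!(toy$a == "a2" & toy$b == "b2"), ]
  expect_warning(res2 <- two_way_anova(holey, "y", "a", "b"), "interaction")
  expect_true(res2$interaction_dropped)
})

test_that("ANOVA F p-values are uniform under the global null", {
  set.seed(55)
  pvals <- replicate(500, {
    df <- tibble::tibble(y = rnorm(36),
                         a = rep(c("a1", "a2", "a3"), each = 12),
                         b = rep(rep(c("b1", "b2"), each = 6), 3))
    tt <- tidy(two_way_anova(df, "y", "a", "b"))
    tt$p_value[tt$term == "a"]
  })
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("Tukey HSD agrees with the studentized-range distribution", {
  set.seed(9)
  y <- c(rnorm(8, 0), rnorm(10, 0.8), rnorm(7, 1.6))
  g <- rep(c("g1", "g2", "g3"), c(8, 10, 7))
  res <- tukey_hsd(tibble::tibble(y = y, g = g), "y", "g")
  oracle <- oracle_tukey_p(y, g)
  expect_equal(unname(res$adj_p_value[match(names(oracle), res$contrast)]),
               unname(oracle), tolerance = 1e-8)
  # significance at alpha = 0.05 coincides with the q critical value
  k <- 3; df_err <- length(y) - k
  mse <- sum((y - ave(y, g))^2) / df_err
  ni <- tapply(y, g, length); mi <- tapply(y, g, mean)
  q12 <- abs(mi["g2"] - mi["g1"]) / sqrt(mse / 2 * (1 / ni["g1"] + 1 / ni["g2"]))
  crit <- qtukey(0.95, k, df_err)
  expect_equal(unname(q12 > crit),
               unname(res$adj_p_value[res$contrast == "g2-g1"] < 0.05))

  # identical groups: adjusted p near 1
  y0 <- rep(c(1, 2, 3), 2)
  res0 <- tukey_hsd(tibble::tibble(y = c(y0, y0),
                                   g = rep(c("g1", "g2"), each = 6)), "y", "g")
  expect_gt(res0$adj_p_value, 0.999)

  # k = 2: Tukey p equals the pooled two-sample t-test p
  y2 <- c(rnorm(9, 0), rnorm(9, 0.7))
  g2 <- rep(c("g1", "g2"), each = 9)
  res2 <- tukey_hsd(tibble::tibble(y = y2, g = g2), "y", "g")
  tt <- t.test(y2 ~ g2, var.equal = TRUE)
  expect_equal(res2$adj_p_value, tt$p.value, tolerance = 1e-8)
})

test_that("paired t and Pearson r match independent formula evaluations", {
  set.seed(23)
  x <- rnorm(10, 0.5, 1)
  y <- rnorm(10, 0, 1)
  res <- paired_t(x, y)
  oracle <- oracle_paired_t(x, y)
  expect_equal(res$statistic, oracle$t, tolerance = 1e-10)
  expect_equal(res$df, oracle$df)
  expect_equal(res$p_value, oracle$p, tolerance = 1e-10)

  same <- paired_t(x, x + 0)   # identical pairs
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  cst <- paired_t(x, x - 2)    # constant positive difference
  expect_gt(cst$statistic, 0)
  expect_error(paired_t(x, y[1:5]), "equal lengths")

  r <- pearson_r(x, 2 * x + 3)
  expect_equal(r$r, 1)
  ro <- pearson_r(x, y)
  oro <- oracle_pearson(x, y)
  expect_equal(ro$r, oro$r, tolerance = 1e-10)
  expect_equal(ro$p_value, oro$p, tolerance = 1e-10)
  # orthogonal contrast vectors are uncorrelated
  expect_equal(pearson_r(c(-1, 0, 1, -1, 0, 1),
                         c(1, -2, 1, 1, -2, 1))$r, 0)
  expect_error(pearson_r(x, rep(1, 10)), "Constant")
})
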