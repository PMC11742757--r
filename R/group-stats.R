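# Per-bin pooled-variance two-sample t statistics for a subjects x bins
# matrix split by a logical group indicator (TRUE = group A).
bin_t_stats <- function(X, is_a) {
  n1 <- sum(is_a)
  n2 <- sum(!is_a)
  A <- X[is_a, , drop = FALSE]
  B <- X[!is_a, , drop = FALSE]
  m1 <- colMeans(A)
  m2 <- colMeans(B)
  v1 <- (colSums(A * A) - n1 * m1^2) / (n1 - 1)
  v2 <- (colSums(B * B) - n2 * m2^2) / (n2 - 1)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  tt <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  tt[sp2 == 0 & m1 == m2] <- 0   # identical degenerate bins carry no signal
  tt
}

# Maximal contiguous runs of supra-threshold bins, split by sign; returns a
# data frame of cluster index ranges and summed t.
find_clusters <- function(t_stats, t_crit) {
  supra <- abs(t_stats) > t_crit
  sgn <- sign(t_stats)
  n <- length(t_stats)
  clusters <- list()
  i <- 1L
  while (i <= n) {
    if (supra[i]) {
      j <- i
      while (j < n && supra[j + 1L] && sgn[j + 1L] == sgn[i]) j <- j + 1L
      clusters[[length(clusters) + 1L]] <-
        data.frame(start = i, end = j, cluster_stat = sum(t_stats[i:j]),
                   sign = sgn[i])
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  if (length(clusters) == 0L) {
    data.frame(start = integer(), end = integer(),
               cluster_stat = double(), sign = double())
  } else {
    do.call(rbind, clusters)
  }
}

max_cluster_stat <- function(t_stats, t_crit) {
  cl <- find_clusters(t_stats, t_crit)
  if (nrow(cl) == 0L) 0 else max(abs(cl$cluster_stat))
}

#' Cluster-based permutation test over frequency bins
#'
#' Compares two groups of per-subject spectral curves bin by bin with
#' pooled-variance two-sample t statistics; contiguous runs of bins whose
#' |t| exceeds the two-sided critical value at `cluster_alpha` form
#' candidate clusters (positive and negative signs clustered separately),
#' each summarized by its summed t. Significance is assessed against the
#' permutation null of the maximum |cluster sum| under random relabelling
#' of subjects, with the +1 correction so p-values are never zero.
#'
#' @param data long tibble with one row per subject x frequency bin.
#' @param value name of the value column (e.g. periodic log10 power).
#' @param group name of the two-level group column.
#' @param subject name of the subject id column.
#' @param freq name of the frequency column (Hz).
#' @param freq_range analysis range in Hz (default 2-44).
#' @param n_perm number of label permutations (default 1000).
#' @param cluster_alpha two-sided cluster-forming alpha (default 0.05).
#' @param seed integer seed for the permutation draws.
#' @return An object of class `cluster_result`; [generics::tidy()] returns
#'   the cluster table (`freq_lo`, `freq_hi`, `cluster_stat`, `sign`,
#'   `p_value`).
#' @export
cluster_permutation_test <- function(data, value, group, subject,
                                     freq = "freq_hz",
                                     freq_range = c(2, 44),
                                     n_perm = 1000, cluster_alpha = 0.05,
                                     seed = NULL) {
  assert_cols(data, c(value, group, subject, freq), "`data`")
  data <- data[data[[freq]] >= freq_range[1] & data[[freq]] <= freq_range[2], ]
  wide <- tidyr::pivot_wider(
    data[, c(subject, group, freq, value)],
    names_from = dplyr::all_of(freq), values_from = dplyr::all_of(value))
  # canonical subject order and alphabetical group levels make the result
  # invariant to the row order of the input and to label exchange
  wide <- wide[order(wide[[subject]]), ]
  groups <- wide[[group]]
  lev <- sort(unique(groups))
  if (length(lev) != 2L) abort("`group` must have exactly two levels.")
  X <- as.matrix(wide[, setdiff(names(wide), c(subject, group))])
  if (anyNA(X)) abort("Subjects are not on a common frequency grid.")
  freqs <- as.numeric(colnames(X))
  ord <- order(freqs)
  freqs <- freqs[ord]
  X <- X[, ord, drop = FALSE]
  is_a <- groups == lev[1]
  n1 <- sum(is_a); n2 <- sum(!is_a)
  if (n1 < 2L || n2 < 2L) abort("At least two subjects per group are required.")

  t_crit <- qt(1 - cluster_alpha / 2, df = n1 + n2 - 2)
  t_obs <- bin_t_stats(X, is_a)
  cl <- find_clusters(t_obs, t_crit)

  null_max <- with_seed(seed, {
    vapply(seq_len(n_perm), function(p) {
      perm <- sample(nrow(X))
      max_cluster_stat(bin_t_stats(X, is_a[perm]), t_crit)
    }, numeric(1))
  })

  clusters <- if (nrow(cl) == 0L) {
    tibble(freq_lo = double(), freq_hi = double(), cluster_stat = double(),
           sign = double(), p_value = double())
  } else {
    tibble(
      freq_lo = freqs[cl$start], freq_hi = freqs[cl$end],
      cluster_stat = cl$cluster_stat, sign = cl$sign,
      p_value = vapply(cl$cluster_stat, function(s) {
        (1 + sum(null_max >= abs(s))) / (1 + n_perm)
      }, numeric(1))
    )
  }
  structure(list(
    clusters = clusters,
    t_curve = tibble(freq_hz = freqs, t_stat = t_obs),
    t_crit = t_crit, n_perm = n_perm, cluster_alpha = cluster_alpha,
    tail = "two-sided", analysis_range = freq_range,
    groups = lev, n_per_group = c(n1, n2), null_max = null_max
  ), class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %s vs %s over %g-%g Hz, %d permutation(s)\n",
              x$groups[1], x$groups[2], x$analysis_range[1],
              x$analysis_range[2], x$n_perm))
  if (nrow(x$clusters) == 0L) cat("No supra-threshold clusters.\n")
  else print(x$clusters)
  invisible(x)
}

#' @rdname cluster_permutation_test
#' @param x a `cluster_result`.
#' @param ... unused.
#' @method tidy cluster_result
#' @export
tidy.cluster_result <- function(x, ...) x$clusters

#' @rdname cluster_permutation_test
#' @method glance cluster_result
#' @export
glance.cluster_result <- function(x, ...) {
  tibble(n_clusters = nrow(x$clusters),
         min_p = if (nrow(x$clusters)) min(x$clusters$p_value) else NA_real_,
         n_perm = x$n_perm, cluster_alpha = x$cluster_alpha)
}

#' Logistic regression of group status on aperiodic features
#'
#' Maximum-likelihood binomial fit with intercept predicting the two-level
#' group label from the given predictors (by default the four aperiodic
#' features: frontal/posterior offset and exponent). Reports Wald standard
#' errors, odds ratios and Wald 95% CIs (exp(beta +- 1.96 SE)). Rank
#' deficiency (e.g. a duplicated predictor) is an error; quasi-complete
#' separation is detected and flagged with diagnostics rather than
#' returned as a silently huge odds ratio.
#'
#' @param data tibble with the outcome and predictor columns.
#' @param outcome name of the two-level group column; the second sorted
#'   level is modelled as the event.
#' @param predictors character vector of predictor column names.
#' @return An object of class `logistic_group_model`; `tidy()` returns the
#'   coefficient table with odds ratios and CIs.
#' @export
logistic_group_model <- function(data, outcome = "group",
                                 predictors = c("frontal_offset",
                                                "frontal_exponent",
                                                "posterior_offset",
                                                "posterior_exponent")) {
  assert_cols(data, c(outcome, predictors), "`data`")
  if (nrow(data) <= 10L) abort("N must exceed 10 for the group model.")
  y_lev <- sort(unique(as.character(data[[outcome]])))
  if (length(y_lev) != 2L) abort("`outcome` must have exactly two levels.")
  y <- as.integer(as.character(data[[outcome]]) == y_lev[2])
  Xm <- as.matrix(data[, predictors])
  if (any(apply(Xm, 2, function(c) var(c) == 0))) {
    abort("Constant predictor supplied.")
  }
  mm <- cbind(1, Xm)
  if (qr(mm)$rank < ncol(mm)) abort("Predictors are rank deficient.")
  df <- data.frame(.y = y, Xm)
  fml <- as.formula(paste(".y ~", paste(predictors, collapse = " + ")))
  fit <- suppressWarnings(glm(fml, data = df, family = binomial()))
  probs <- fitted(fit)
  separation <- all(probs[y == 1] > 0.5) && all(probs[y == 0] < 0.5) &&
    all(pmin(probs, 1 - probs) < 1e-6)
  big_se <- any(summary(fit)$coefficients[, "Std. Error"] > 50)
  co <- summary(fit)$coefficients
  tab <- tibble(
    term = rownames(co),
    estimate = co[, "Estimate"],
    std_error = co[, "Std. Error"],
    odds_ratio = exp(co[, "Estimate"]),
    ci_low = exp(co[, "Estimate"] - 1.96 * co[, "Std. Error"]),
    ci_high = exp(co[, "Estimate"] + 1.96 * co[, "Std. Error"]),
    p_value = co[, "Pr(>|z|)"]
  )
  structure(list(
    coefficients = tab, fit = fit,
    event_level = y_lev[2], reference_level = y_lev[1],
    separation = separation || (big_se && !fit$converged),
    separation_diagnostics = list(
      converged = fit$converged,
      max_abs_coef = max(abs(coef(fit))),
      max_se = max(co[, "Std. Error"]),
      min_margin = min(pmin(probs, 1 - probs))
    )
  ), class = "logistic_group_model")
}

#' @export
print.logistic_group_model <- function(x, ...) {
  cat(sprintf("<logistic_group_model> event = %s (ref %s)%s\n",
              x$event_level, x$reference_level,
              if (x$separation) " [SEPARATION DETECTED]" else ""))
  print(x$coefficients)
  invisible(x)
}

#' @rdname logistic_group_model
#' @param x a `logistic_group_model`.
#' @param ... unused.
#' @method tidy logistic_group_model
#' @export
tidy.logistic_group_model <- function(x, ...) x$coefficients

#' @rdname logistic_group_model
#' @method glance logistic_group_model
#' @export
glance.logistic_group_model <- function(x, ...) {
  tibble(separation = x$separation,
         converged = x$separation_diagnostics$converged,
         aic = x$fit$aic, n = length(x$fit$y))
}

#' Fixed-effects ANOVA on beta peak amplitude (one- or two-way)
#'
#' Fits `outcome ~ factor1 * factor2` (or a one-way layout when `factor2`
#' is `NULL`) and reports per-term F tests with sequential (Type I) sums of
#' squares by default; Type II is available for unbalanced sensitivity
#' analysis. If an empty factorial cell makes the interaction inestimable
#' the interaction is dropped with a warning and recorded in the result.
#'
#' @param data tibble holding the outcome and factors.
#' @param outcome outcome column name (numeric).
#' @param factor1,factor2 factor column names (`factor2 = NULL` for one-way).
#' @param type `"I"` (sequential) or `"II"`.
#' @return An object of class `anova_result`; `tidy()` gives the term table.
#' @export
two_way_anova <- function(data, outcome, factor1, factor2 = NULL,
                          type = c("I", "II")) {
  type <- match.arg(type)
  assert_cols(data, c(outcome, factor1, factor2), "`data`")
  data <- as.data.frame(data)
  data[[factor1]] <- factor(data[[factor1]])
  if (nlevels(data[[factor1]]) < 2L) abort("`factor1` needs >= 2 levels.")
  interaction_dropped <- FALSE
  if (is.null(factor2)) {
    fml <- as.formula(paste(outcome, "~", factor1))
  } else {
    data[[factor2]] <- factor(data[[factor2]])
    if (nlevels(data[[factor2]]) < 2L) abort("`factor2` needs >= 2 levels.")
    cells <- table(data[[factor1]], data[[factor2]])
    if (any(cells == 0L)) {
      warn("Empty factorial cell: interaction dropped from the model.")
      interaction_dropped <- TRUE
      fml <- as.formula(paste(outcome, "~", factor1, "+", factor2))
    } else {
      fml <- as.formula(paste(outcome, "~", factor1, "*", factor2))
    }
  }
  fit <- lm(fml, data = data)
  tab <- if (type == "I") anova_type1(fit) else anova_type2(fit, data)
  structure(list(
    terms = tab, fit = fit, formula = fml, type = type,
    interaction_dropped = interaction_dropped,
    residual_df = fit$df.residual,
    coefficients = coef(fit),
    sigma2 = sum(residuals(fit)^2) / fit$df.residual
  ), class = "anova_result")
}

anova_type1 <- function(fit) {
  a <- anova(fit)
  tibble(term = rownames(a), df = a$Df, sumsq = a$`Sum Sq`,
         meansq = a$`Mean Sq`, statistic = a$`F value`,
         p_value = a$`Pr(>F)`)
}

# Type II: each term's SS is the reduction in RSS from adding it last among
# terms of its order (interactions always fitted after both mains).
anova_type2 <- function(fit, data) {
  trms <- attr(terms(fit), "term.labels")
  rss <- function(f) sum(residuals(lm(f, data = data))^2)
  full_rhs <- paste(trms, collapse = " + ")
  out_var <- all.vars(formula(fit))[1]
  full_rss <- sum(residuals(fit)^2)
  res_df <- fit$df.residual
  ms_res <- full_rss / res_df
  rows <- lapply(trms, function(tt) {
    is_inter <- grepl(":", tt, fixed = TRUE)
    others <- setdiff(trms, tt)
    if (!is_inter) others <- others[!grepl(":", others, fixed = TRUE)]
    reduced <- if (length(others) == 0L) paste(out_var, "~ 1")
               else paste(out_var, "~", paste(others, collapse = " + "))
    with_t <- paste(reduced, "+", tt)
    ss <- rss(as.formula(reduced)) - rss(as.formula(with_t))
    df_t <- anova(lm(as.formula(with_t), data = data))[tt, "Df"]
    tibble(term = tt, df = df_t, sumsq = ss, meansq = ss / df_t,
           statistic = (ss / df_t) / ms_res,
           p_value = stats::pf((ss / df_t) / ms_res, df_t, res_df,
                               lower.tail = FALSE))
  })
  bind_rows(rows, tibble(term = "Residuals", df = res_df, sumsq = full_rss,
                         meansq = ms_res, statistic = NA_real_,
                         p_value = NA_real_))
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("<anova_result> %s (Type %s)%s\n",
              deparse(x$formula), x$type,
              if (x$interaction_dropped) " [interaction dropped]" else ""))
  print(x$terms)
  invisible(x)
}

#' @rdname two_way_anova
#' @param x an `anova_result`.
#' @param ... unused.
#' @method tidy anova_result
#' @export
tidy.anova_result <- function(x, ...) x$terms

#' @rdname two_way_anova
#' @method glance anova_result
#' @export
glance.anova_result <- function(x, ...) {
  tibble(residual_df = x$residual_df, sigma2 = x$sigma2, type = x$type,
         interaction_dropped = x$interaction_dropped)
}

#' Tukey HSD pairwise contrasts
#'
#' Studentized-range-adjusted p-values for all pairwise group contrasts of
#' a one-way layout, honoring unbalanced cell sizes (Tukey-Kramer).
#'
#' @param data tibble with the outcome and group columns.
#' @param outcome outcome column name.
#' @param group grouping column name (>= 2 levels).
#' @return Tibble: `contrast`, `estimate`, `conf_low`, `conf_high`,
#'   `adj_p_value`.
#' @export
tukey_hsd <- function(data, outcome, group) {
  assert_cols(data, c(outcome, group), "`data`")
  data <- as.data.frame(data)
  data[[group]] <- factor(data[[group]])
  if (nlevels(data[[group]]) < 2L) abort("Need >= 2 groups for Tukey HSD.")
  fit <- aov(as.formula(paste(outcome, "~", group)), data = data)
  tk <- TukeyHSD(fit)[[group]]
  tibble(contrast = rownames(tk), estimate = unname(tk[, "diff"]),
         conf_low = unname(tk[, "lwr"]), conf_high = unname(tk[, "upr"]),
         adj_p_value = unname(tk[, "p adj"]))
}

#' Paired t-test on matched pairs
#'
#' Standard paired t-test on within-pair differences (df = n - 1).
#'
#' @param x,y numeric vectors of equal length (pair members in order), with
#'   no missing values.
#' @return One-row tibble: `estimate` (mean difference), `statistic`, `df`,
#'   `p_value`, `conf_low`, `conf_high`.
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y)) abort("Paired input requires equal lengths.")
  if (anyNA(x) || anyNA(y)) abort("Paired input must be complete (no NA).")
  if (length(x) < 2L) abort("At least two complete pairs are required.")
  d <- x - y
  if (sd(d) == 0) {
    # degenerate pairs: constant difference has no sampling variance
    tval <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
    return(tibble(estimate = mean(d), statistic = tval,
                  df = length(d) - 1,
                  p_value = if (mean(d) == 0) 1 else 0,
                  conf_low = mean(d), conf_high = mean(d)))
  }
  tt <- t.test(x, y, paired = TRUE)
  tibble(estimate = unname(tt$estimate), statistic = unname(tt$statistic),
         df = unname(tt$parameter), p_value = tt$p.value,
         conf_low = tt$conf.int[1], conf_high = tt$conf.int[2])
}

#' Pearson correlation with two-sided t-based p-value
#'
#' @param x,y numeric vectors (n >= 3, non-constant).
#' @return One-row tibble: `r`, `statistic`, `df`, `p_value`.
#' @export
pearson_r <- function(x, y) {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) abort("Need at least 3 complete observations.")
  if (sd(x) == 0 || sd(y) == 0) abort("Constant vector supplied.")
  ct <- cor.test(x, y, method = "pearson")
  tibble(r = unname(ct$estimate), statistic = unname(ct$statistic),
         df = unname(ct$parameter), p_value = ct$p.value)
}
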