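# Independent formula oracles used to cross-check the statistics layer.
# These are deliberately naive textbook implementations, kept separate from
# the package's code paths.

oracle_paired_t <- function(x, y) {
  d <- x - y
  n <- length(d)
  tval <- mean(d) / (sd(d) / sqrt(n))
  list(t = tval, df = n - 1, p = 2 * pt(-abs(tval), n - 1))
}

oracle_pearson <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  tval <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * pt(-abs(tval), n - 2))
}

# Textbook balanced two-way ANOVA from cell means (a x b design, r reps).
oracle_two_way_anova <- function(df, outcome, fa, fb) {
  y <- df[[outcome]]
  A <- factor(df[[fa]]); B <- factor(df[[fb]])
  gm <- mean(y)
  a <- nlevels(A); b <- nlevels(B)
  r <- nrow(df) / (a * b)
  ss_a <- b * r * sum((tapply(y, A, mean) - gm)^2)
  ss_b <- a * r * sum((tapply(y, B, mean) - gm)^2)
  cell <- tapply(y, list(A, B), mean)
  ss_ab <- r * sum((sweep(sweep(cell, 1, tapply(y, A, mean) - gm),
                          2, tapply(y, B, mean) - gm) - gm)^2)
  ss_tot <- sum((y - gm)^2)
  ss_err <- ss_tot - ss_a - ss_b - ss_ab
  df_err <- a * b * (r - 1)
  list(
    F_a = (ss_a / (a - 1)) / (ss_err / df_err),
    F_b = (ss_b / (b - 1)) / (ss_err / df_err),
    F_ab = (ss_ab / ((a - 1) * (b - 1))) / (ss_err / df_err),
    ss = c(a = ss_a, b = ss_b, ab = ss_ab, err = ss_err, tot = ss_tot)
  )
}

# Tukey-Kramer adjusted p computed directly from the studentized range
# distribution (the tabulated critical values' source).
oracle_tukey_p <- function(y, g) {
  g <- factor(g)
  k <- nlevels(g)
  ni <- tapply(y, g, length)
  mi <- tapply(y, g, mean)
  df_err <- length(y) - k
  mse <- sum((y - ave(y, g))^2) / df_err
  out <- c()
  lev <- levels(g)
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    se <- sqrt(mse / 2 * (1 / ni[i] + 1 / ni[j]))
    q <- abs(mi[j] - mi[i]) / se
    out[paste(lev[j], lev[i], sep = "-")] <-
      ptukey(q, k, df_err, lower.tail = FALSE)
  }
  out
}

# Exact minimum total age gap for 1:1 sex-exact matching by exhaustive
# enumeration over control permutations (small n only).
oracle_optimal_matching_gap <- function(cases, pool) {
  n <- nrow(cases)
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    }
    out
  }
  best <- Inf
  for (assign in perms(seq_len(nrow(pool)))) {
    sel <- assign[seq_len(n)]
    if (any(pool$sex[sel] != cases$sex)) next
    gap <- sum(abs(pool$age_months[sel] - cases$age_months))
    best <- min(best, gap)
  }
  best
}

# Small helper: long curve tibble for two groups of subjects from models.
simulate_group_curves <- function(model_a, model_b, n_per_group, freqs,
                                  seed, value = "log10_power") {
  rows <- lapply(seq_len(2 * n_per_group), function(s) {
    m <- if (s <= n_per_group) model_a else model_b
    sp <- simulate_spectrum(m, freqs, seed = seed * 10000 + s)
    tibble::tibble(
      subject_id = sprintf("S%03d", s),
      group = if (s <= n_per_group) "A" else "B",
      freq_hz = sp$freq_hz,
      value = log10(sp$power_uv2_per_hz))
  })
  dplyr::bind_rows(rows)
}
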