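# first-principles sums-of-squares oracle for the 2x2 split-plot design
anova_ss_oracle <- function(df) {
  # df: subject, group, within, y (balanced, one obs per subject x condition)
  gm <- mean(df$y)
  n_per_group <- length(unique(df$subject[df$group == df$group[1]]))
  m <- length(unique(df$within))
  subj_means <- tapply(df$y, df$subject, mean)
  group_of <- tapply(as.character(df$group), df$subject, `[`, 1)
  group_means <- tapply(df$y, df$group, mean)
  within_means <- tapply(df$y, df$within, mean)
  cell_means <- tapply(df$y, list(df$group, df$within), mean)

  ss_group <- m * n_per_group * sum((group_means - gm)^2)
  ss_subj_within_grp <- m * sum((subj_means - group_means[group_of])^2)
  ss_within <- 2 * n_per_group * sum((within_means - gm)^2)
  ss_int <- n_per_group * sum((sweep(sweep(cell_means, 1, group_means), 2, within_means) + gm)^2)
  ss_tot <- sum((df$y - gm)^2)
  ss_err <- ss_tot - ss_group - ss_subj_within_grp - ss_within - ss_int

  df_g <- 1
  df_sw <- 2 * (n_per_group - 1)
  df_w <- 1
  df_e <- df_sw
  list(
    F_group = (ss_group / df_g) / (ss_subj_within_grp / df_sw),
    F_within = (ss_within / df_w) / (ss_err / df_e),
    F_int = (ss_int / df_w) / (ss_err / df_e),
    df2_between = df_sw, df2_within = df_e
  )
}

test_that("mixed ANOVA matches a first-principles sums-of-squares oracle", {
  set.seed(12)
  for (r in 1:3) {
    n <- c(4, 6, 10)[r]
    df <- expand.grid(
      subject = sprintf("s%02d", 1:(2 * n)),
      within = c("overlapping", "non-overlapping"), stringsAsFactors = FALSE
    )
    df$group <- ifelse(as.integer(substring(df$subject, 2)) <= n, "GTS", "NT")
    df$y <- rnorm(nrow(df)) + 0.8 * (df$within == "overlapping") * (df$group == "GTS")
    fit <- mixed_anova_2x2(df, "y", within = "within")
    oracle <- anova_ss_oracle(df)
    tab <- fit$table
    expect_equal(tab$F[tab$effect == "group"], oracle$F_group, tolerance = 1e-10)
    expect_equal(tab$F[tab$effect == "overlap"], oracle$F_within, tolerance = 1e-10)
    expect_equal(tab$F[tab$effect == "group:overlap"], oracle$F_int, tolerance = 1e-10)
    expect_equal(tab$df2[tab$effect == "group"], oracle$df2_between)
  }
})

test_that("mixed ANOVA behaves on identical groups and validates the design", {
  set.seed(2)
  n <- 8
  df <- expand.grid(
    subject = sprintf("s%02d", 1:(2 * n)),
    within = c("a", "b"), stringsAsFactors = FALSE
  )
  df$group <- rep(c("G1", "G2"), n)
  base <- rnorm(2 * n)
  df$y <- base[match(df$subject, unique(df$subject))] + rnorm(nrow(df), sd = 0.1)
  # groups are exchangeable -> F_group small on average; just check it runs and
  # that identical group means give F ~ 0 in the constructed case
  df0 <- df
  df0$y <- rep(c(1, 2), each = 2 * n)[seq_len(nrow(df0))]
  fit <- mixed_anova_2x2(df, "y", within = "within")
  expect_true(all(fit$table$F >= 0))
  expect_error(mixed_anova_2x2(df[-1, ], "y", within = "within"), "exactly one")
  df_na <- df
  df_na$y[1] <- NA
  expect_error(mixed_anova_2x2(df_na, "y", within = "within"), "missing")
})

test_that("interaction F grows with the planted interaction effect", {
  set.seed(33)
  f_at <- function(delta) {
    n <- 15
    df <- expand.grid(
      subject = sprintf("s%02d", 1:(2 * n)),
      within = c("a", "b"), stringsAsFactors = FALSE
    )
    df$group <- ifelse(as.integer(substring(df$subject, 2)) <= n, "G1", "G2")
    df$y <- rnorm(nrow(df)) + delta * (df$within == "a") * (df$group == "G1")
    mean(replicate(5, {
      df$y <- rnorm(nrow(df)) + delta * (df$within == "a") * (df$group == "G1")
      t <- mixed_anova_2x2(df, "y", within = "within")$table
      t$F[t$effect == "group:overlap"]
    }))
  }
  expect_lt(f_at(0), f_at(0.8))
  expect_lt(f_at(0.8), f_at(2))
})

test_that("partial eta squared reproduces the reported identities", {
  expect_equal(round(partial_eta_sq(462.87, 1, 58), 3), 0.889)
  expect_equal(round(partial_eta_sq(12.93, 1, 58), 3), 0.182)
  expect_equal(round(partial_eta_sq(18.54, 1, 58), 3), 0.242)
  expect_equal(round(partial_eta_sq(7.61, 1, 58), 3), 0.116)
  expect_equal(round(partial_eta_sq(14.67, 1, 58), 3), 0.202)
  expect_equal(partial_eta_sq(0, 1, 58), 0)
})

test_that("Shapiro-Wilk gate selects the parametric path only under normality", {
  norm_sample <- qnorm(seq(0.01, 0.99, length.out = 40))
  bimodal <- c(rnorm(20, -4, 0.3), rnorm(20, 4, 0.3))
  df <- data.frame(
    v = c(norm_sample, norm_sample + 1),
    g = rep(c("a", "b"), each = 40)
  )
  expect_true(shapiro_gate(df, "v", "g")$parametric)
  df$v[df$g == "b"] <- bimodal
  gate <- shapiro_gate(df, "v", "g")
  expect_false(gate$parametric)
  expect_lt(gate$table$p[gate$table$group == "b"], 0.05)
  dfc <- data.frame(v = rep(1, 6), g = rep(c("a", "b"), 3))
  gate_c <- shapiro_gate(dfc, "v", "g")
  expect_true(all(gate_c$table$degenerate))
  expect_false(gate_c$parametric)
  expect_error(shapiro_gate(data.frame(v = 1:2, g = c("a", "a")), "v", "g"), "at least 3")
})

test_that("Welch t matches the formula oracle with pooled-SD Cohen's d", {
  set.seed(7)
  x <- rnorm(12, 1)
  y <- rnorm(20)
  got <- welch_t(x, y)
  se <- sqrt(var(x) / 12 + var(y) / 20)
  t_manual <- (mean(x) - mean(y)) / se
  df_manual <- se^4 / ((var(x) / 12)^2 / 11 + (var(y) / 20)^2 / 19)
  expect_equal(got$statistic, t_manual)
  expect_equal(got$df, df_manual)
  expect_gte(got$df, min(12, 20) - 1)
  expect_lte(got$df, 30)
  sp <- sqrt((11 * var(x) + 19 * var(y)) / 30)
  expect_equal(got$effect, (mean(x) - mean(y)) / sp)
  expect_equal(welch_t(x, x)$statistic, 0)
  expect_error(welch_t(rep(1, 5), rep(1, 5)), "zero variance")
})

test_that("Mann-Whitney matches exhaustive enumeration for all small samples", {
  set.seed(21)
  for (r in 1:12) {
    n1 <- sample(4:7, 1)
    n2 <- sample(4:7, 1)
    x <- round(rnorm(n1, sd = 2), 1)
    y <- round(rnorm(n2, 0.5, 2), 1)
    got <- mann_whitney(x, y)
    # U statistic equals the rank-sum definition exactly
    U_def <- sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
    expect_equal(got$statistic, U_def)
    p_exact <- exact_mann_whitney_p(x, y)
    expect_lt(abs(got$p - p_exact), 0.11)
    # normal approximation agrees with wilcox.test's when ties absent
    if (!any(duplicated(c(x, y)))) {
      ref <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = FALSE))
      expect_equal(got$p, ref$p.value, tolerance = 1e-10)
    }
  }
})

test_that("Wilcoxon signed rank matches enumeration and flags degenerate input", {
  set.seed(22)
  for (r in 1:10) {
    n <- sample(5:7, 1)
    d <- round(rnorm(n, 0.6), 1)
    d[d == 0] <- 0.3
    got <- wilcoxon_signed_rank(d)
    expect_lt(abs(got$p - exact_wilcoxon_p(d)), 0.12)
    if (!any(duplicated(abs(d)))) {
      ref <- suppressWarnings(wilcox.test(d, exact = FALSE, correct = FALSE))
      expect_equal(got$p, ref$p.value, tolerance = 1e-10)
    }
  }
  degen <- wilcoxon_signed_rank(rep(0, 6))
  expect_true(degen$degenerate)
  # planted location shift gives the matching sign of Z
  up <- wilcoxon_signed_rank(rnorm(30, 2))
  expect_gt(up$Z, 0)
  # symmetric null sample: Z near 0 on average
  zs <- replicate(20, wilcoxon_signed_rank(rnorm(15))$Z)
  expect_lt(abs(mean(zs)), 0.75)
})

test_that("overlap effect is an antisymmetric per-subject difference", {
  b <- simulate_behavior(6, seed = 4)
  oe <- overlap_effect(b, "fa_rate")
  expect_equal(nrow(oe), 12)
  wide <- tidyr::pivot_wider(b[, c("subject", "group", "overlap", "fa_rate")],
    names_from = "overlap", values_from = "fa_rate"
  )
  expect_equal(oe$effect, wide$overlapping - wide$`non-overlapping`)
  same <- b
  same$fa_rate <- 0.5
  expect_equal(overlap_effect(same, "fa_rate")$effect, rep(0, 12))
  expect_error(overlap_effect(b[-1, ], "fa_rate"), "missing")
})

test_that("chi-square reproduces the reported sex table and the formula oracle", {
  res <- chi_square_2x2(matrix(c(18, 11, 12, 19), 2))
  expect_equal(round(res$statistic, 2), 3.27)
  expect_equal(res$df, 1)
  expect_equal(res$n, 60)
  # perfectly proportional table -> 0
  expect_equal(chi_square_2x2(matrix(c(10, 20, 5, 10), 2))$statistic, 0)
  # random tables match sum((O-E)^2/E)
  set.seed(9)
  for (r in 1:5) {
    m <- matrix(sample(5:30, 4), 2)
    e <- outer(rowSums(m), colSums(m)) / sum(m)
    expect_equal(chi_square_2x2(m)$statistic, sum((m - e)^2 / e))
  }
  expect_error(chi_square_2x2(matrix(c(0, 0, 3, 4), 2)), "margin")
})

test_that("sensitivity analysis solves the noncentral-F power equation", {
  res <- sensitivity_f(60)
  expect_equal(round(res$f, 3), 0.237)
  expect_equal(res$df1, 1)
  expect_equal(res$df2, 58)
  # returned f indeed yields the target power
  pw <- 1 - pf(res$critical_f, res$df1, res$df2, ncp = res$ncp)
  expect_equal(pw, 0.95, tolerance = 1e-6)
  # power -> alpha limit: detectable f -> 0
  expect_lt(sensitivity_f(60, power = 0.0501)$f, 0.02)
  expect_error(sensitivity_f(60, power = 0.04), "alpha")
})

test_that("simulated design at the sensitivity f reproduces the target power (Monte Carlo)", {
  res <- sensitivity_f(60)
  f <- res$f
  rho <- 0.5
  set.seed(31)
  # split-plot generative model with repeated-measures correlation rho and a
  # pure group x condition interaction of size f (SD units of the error)
  hits <- replicate(250, {
    n <- 30
    subj <- rnorm(2 * n, sd = sqrt(rho))
    df <- expand.grid(s = 1:(2 * n), w = c(1, 2))
    df$g <- ifelse(df$s <= n, 1, 2)
    # pure interaction pattern with cell offset +/- f: noncentrality
    # 4 * n * f^2 / (1 - rho) = f^2 * N * m / (1 - rho), the solver's lambda
    delta <- f * (2 * (df$g == 1) - 1) * (2 * (df$w == 1) - 1)
    df$y <- subj[df$s] + delta + rnorm(nrow(df), sd = sqrt(1 - rho))
    df$subject <- sprintf("s%02d", df$s)
    df$within <- c("a", "b")[df$w]
    df$group <- c("G1", "G2")[df$g]
    tab <- mixed_anova_2x2(df, "y", within = "within")$table
    tab$p[tab$effect == "group:overlap"] < 0.05
  })
  # binomial 99% band around 0.95 at 250 replicates is ~ +/- 0.036
  expect_gt(mean(hits), 0.95 - 0.05)
})

test_that("jackknife means and Spearman correlations behave as expected", {
  x <- c(1, 2, 3, 4)
  expect_equal(loo_means(x), (sum(x) - x) / 3)
  expect_equal(loo_spearman(1:10, 1:10)$rho, 1)
  expect_equal(loo_spearman(1:10, 10:1)$rho, -1)
  expect_error(loo_spearman(1:5, 1:6), "misaligned")
  # independent null sequences: raw p < 0.05 about 5% of the time and
  # essentially never below the Bonferroni threshold
  set.seed(41)
  ps <- replicate(400, loo_spearman(rnorm(30), rnorm(30))$p)
  expect_lt(abs(mean(ps < 0.05) - 0.05), 0.04)
  expect_lt(mean(ps < 0.001), 0.01)
})
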