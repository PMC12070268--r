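# Behavioural and demographic statistics of the 2 (group) x 2 (overlap)
# mixed design: split-plot ANOVA with partial eta squared, Shapiro-Wilk-gated
# post hocs, rank tests with effect size r, chi-square, sensitivity power
# analysis, and jackknifed Spearman correlations.

#' 2x2 mixed (split-plot) ANOVA
#'
#' Classical sums-of-squares F tests for the between-subjects factor, the
#' within-subjects factor and their interaction, on a balanced two-group,
#' two-condition design with one observation per subject and condition.
#' Implemented via `stats::aov` with a subject error stratum; partial eta
#' squared is reported per effect.
#'
#' @param data A long tibble (e.g. a [simulate_behavior()] table).
#' @param dv Name of the dependent-variable column.
#' @param subject,group,within Names of the id, between- and within-factor
#'   columns (defaults `subject`, `group`, `overlap`).
#' @return An object of class `mixed_anova`: list with `table` (tibble:
#'   `effect`, `df1`, `df2`, `F`, `p`, `eta_sq_p`) and the design sizes.
#' @export
#' @examples
#' behav <- simulate_behavior(12, seed = 1)
#' mixed_anova_2x2(behav, "fa_rate")
mixed_anova_2x2 <- function(data, dv, subject = "subject", group = "group",
                            within = "overlap") {
  df <- data.frame(
    y = data[[dv]],
    subject = factor(data[[subject]]),
    group = factor(data[[group]]),
    within = factor(data[[within]])
  )
  if (anyNA(df$y)) abort("missing values in the dependent variable.")
  if (nlevels(df$group) != 2 || nlevels(df$within) != 2) {
    abort("design must have exactly 2 groups and 2 within-subject conditions.")
  }
  counts <- table(df$subject, df$within)
  if (any(counts != 1)) abort("each subject needs exactly one observation per condition.")
  fit <- stats::aov(y ~ group * within + Error(subject), data = df)
  s <- summary(fit)
  between <- as.data.frame(s[["Error: subject"]][[1]])
  within_tab <- as.data.frame(s[["Error: Within"]][[1]])
  pick <- function(tab, row) {
    i <- grep(row, trimws(rownames(tab)), fixed = TRUE)[1]
    tab[i, c("Df", "F value", "Pr(>F)")]
  }
  g <- pick(between, "group")
  w <- pick(within_tab, "within")
  i <- pick(within_tab, "group:within")
  df2_b <- between[grep("Residuals", rownames(between)), "Df"]
  df2_w <- within_tab[grep("Residuals", rownames(within_tab)), "Df"]
  tab <- tibble(
    effect = c("group", "overlap", "group:overlap"),
    df1 = c(g$Df, w$Df, i$Df),
    df2 = c(df2_b, df2_w, df2_w),
    F = c(g$`F value`, w$`F value`, i$`F value`),
    p = c(g$`Pr(>F)`, w$`Pr(>F)`, i$`Pr(>F)`)
  )
  tab$eta_sq_p <- partial_eta_sq(tab$F, tab$df1, tab$df2)
  structure(
    list(table = tab, dv = dv, n_subjects = nlevels(df$subject)),
    class = "mixed_anova"
  )
}

#' @export
print.mixed_anova <- function(x, ...) {
  cat(sprintf("<mixed_anova> dv = %s, n = %d subjects\n", x$dv, x$n_subjects))
  print(as.data.frame(x$table), row.names = FALSE)
  invisible(x)
}

#' Partial eta squared from F and degrees of freedom
#'
#' `F * df1 / (F * df1 + df2)`.
#'
#' @param f F statistic(s).
#' @param df1,df2 Numerator and denominator degrees of freedom.
#' @return Partial eta squared.
#' @export
#' @examples
#' partial_eta_sq(462.87, 1, 58) # ~ 0.889
partial_eta_sq <- function(f, df1, df2) {
  if (any(f < 0) || any(df1 <= 0) || any(df2 <= 0)) abort("inputs must be non-negative (df positive).")
  f * df1 / (f * df1 + df2)
}

#' Shapiro-Wilk normality gate for post hoc test selection
#'
#' Runs Shapiro-Wilk tests per group and gates the post hoc path: parametric
#' t-tests only when every group retains normality (p > 0.05), otherwise the
#' rank-based tests. Constant samples are flagged degenerate and force the
#' nonparametric path.
#'
#' @param data A data frame.
#' @param value Name of the value column.
#' @param by Name of the grouping column.
#' @return A list: `parametric` (logical), `table` (tibble `group`, `n`, `W`,
#'   `p`, `degenerate`).
#' @export
shapiro_gate <- function(data, value, by = "group") {
  groups <- split(data[[value]], data[[by]])
  rows <- purrr::imap_dfr(groups, function(v, g) {
    v <- v[!is.na(v)]
    if (length(v) < 3) abort("Shapiro-Wilk requires at least 3 observations per group.")
    if (stats::sd(v) == 0) {
      return(tibble(group = g, n = length(v), W = NA_real_, p = NA_real_, degenerate = TRUE))
    }
    sw <- stats::shapiro.test(v)
    tibble(group = g, n = length(v), W = unname(sw$statistic), p = sw$p.value, degenerate = FALSE)
  })
  list(parametric = all(!rows$degenerate) && all(rows$p > 0.05), table = rows)
}

posthoc_result <- function(test, statistic, df = NA_real_, Z = NA_real_, p,
                           effect = NA_real_, effect_type = NA_character_,
                           degenerate = FALSE, r = NULL) {
  structure(
    list(
      test = test, statistic = statistic, df = df, Z = Z, p = p,
      effect = effect, effect_type = effect_type, degenerate = degenerate,
      r = r %||% effect
    ),
    class = "posthoc_test"
  )
}

#' @export
print.posthoc_test <- function(x, ...) {
  cat(sprintf(
    "<posthoc_test> %s: statistic = %.4g%s, p = %.4g, %s = %.3f\n",
    x$test, x$statistic,
    if (is.finite(x$df)) sprintf(" (df = %.2f)", x$df) else "",
    x$p, x$effect_type, x$effect
  ))
  invisible(x)
}

#' Welch two-sample t-test with Cohen's d
#'
#' Welch t statistic with Welch-Satterthwaite degrees of freedom; Cohen's d
#' from the pooled standard deviation.
#'
#' @param x,y Numeric vectors (two groups).
#' @return A `posthoc_test` with fields `statistic` (t), `df`, `p`, `effect`
#'   (d).
#' @export
welch_t <- function(x, y) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2) abort("need at least 2 observations per group.")
  if (sd(x) == 0 && sd(y) == 0) abort("both groups have zero variance.")
  tt <- stats::t.test(x, y, var.equal = FALSE)
  sp <- sqrt(((length(x) - 1) * var(x) + (length(y) - 1) * var(y)) /
    (length(x) + length(y) - 2))
  d <- (mean(x) - mean(y)) / sp
  posthoc_result("welch_t",
    statistic = unname(tt$statistic), df = unname(tt$parameter),
    p = tt$p.value, effect = d, effect_type = "d"
  )
}

# tie-corrected normal-approximation machinery shared by both rank tests
rank_sigma_mw <- function(n1, n2, ties) {
  n <- n1 + n2
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sqrt(n1 * n2 / 12 * ((n + 1) - tie_term))
}

#' Mann-Whitney U test (normal approximation, tie-corrected)
#'
#' U statistic of the first sample, standardized Z with tie correction and no
#' continuity correction, two-sided p from the normal approximation, and
#' effect size `r = Z / sqrt(r_n)` (per-group n by convention).
#'
#' @param x,y Numeric vectors (two groups).
#' @param r_n Sample size for the effect size denominator (default: the
#'   per-group size `max(length(x), length(y))`).
#' @return A `posthoc_test` with fields `statistic` (U), `Z`, `p`, `effect`
#'   (r).
#' @export
mann_whitney <- function(x, y, r_n = NULL) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  n1 <- length(x)
  n2 <- length(y)
  if (n1 < 2 || n2 < 2) abort("need at least 2 observations per group.")
  rk <- rank(c(x, y))
  U1 <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  sigma <- rank_sigma_mw(n1, n2, table(c(x, y)))
  if (sigma == 0) {
    return(posthoc_result("mann_whitney",
      statistic = U1, Z = NA_real_,
      p = NA_real_, degenerate = TRUE, effect_type = "r"
    ))
  }
  Z <- (U1 - mu) / sigma
  p <- 2 * pnorm(-abs(Z))
  r_n <- r_n %||% max(n1, n2)
  posthoc_result("mann_whitney",
    statistic = U1, Z = Z, p = p,
    effect = effect_size_r(Z, r_n), effect_type = "r"
  )
}

#' Wilcoxon signed-rank test (normal approximation, tie-corrected)
#'
#' Paired signed-rank test: zero differences are discarded, V is the sum of
#' positive ranks, Z uses the tie-corrected variance without continuity
#' correction, and the effect size is `r = Z / sqrt(r_n)` (per-group n by
#' convention).
#'
#' @param x,y Paired numeric vectors (or `y = NULL` and `x` the differences).
#' @param r_n Sample size for the effect size denominator (default: the
#'   number of pairs).
#' @return A `posthoc_test` with fields `statistic` (V), `Z`, `p`, `effect`
#'   (r); `degenerate = TRUE` when all differences are zero.
#' @export
wilcoxon_signed_rank <- function(x, y = NULL, r_n = NULL) {
  d <- if (is.null(y)) x else x - y
  n_pairs <- length(d)
  d <- d[!is.na(d) & d != 0]
  n <- length(d)
  if (n == 0) {
    return(posthoc_result("wilcoxon_signed_rank",
      statistic = 0, Z = NA_real_,
      p = NA_real_, degenerate = TRUE, effect_type = "r"
    ))
  }
  rk <- rank(abs(d))
  V <- sum(rk[d > 0])
  mu <- n * (n + 1) / 4
  ties <- table(abs(d))
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  if (sigma2 <= 0) {
    return(posthoc_result("wilcoxon_signed_rank",
      statistic = V, Z = NA_real_,
      p = NA_real_, degenerate = TRUE, effect_type = "r"
    ))
  }
  Z <- (V - mu) / sqrt(sigma2)
  p <- 2 * pnorm(-abs(Z))
  r_n <- r_n %||% n_pairs
  posthoc_result("wilcoxon_signed_rank",
    statistic = V, Z = Z, p = p,
    effect = effect_size_r(Z, r_n), effect_type = "r"
  )
}

#' Per-subject overlap effect
#'
#' The within-subject difference overlapping minus non-overlapping of a
#' behavioural measure.
#'
#' @param data A long behavioural table with `subject`, `group` and an
#'   overlap-condition column.
#' @param value Name of the measure column (default `"fa_rate"`).
#' @param within Name of the condition column (default `"overlap"`), with
#'   levels `"overlapping"` and `"non-overlapping"`.
#' @return A tibble `subject`, `group`, `effect`.
#' @export
overlap_effect <- function(data, value = "fa_rate", within = "overlap") {
  wide <- tidyr::pivot_wider(
    data[, c("subject", "group", within, value)],
    names_from = dplyr::all_of(within), values_from = dplyr::all_of(value)
  )
  if (!all(c("overlapping", "non-overlapping") %in% names(wide))) {
    abort("both overlap conditions must be present for every subject.")
  }
  if (anyNA(wide$overlapping) || anyNA(wide$`non-overlapping`)) {
    abort("a subject is missing one of the conditions.")
  }
  tibble(
    subject = wide$subject, group = wide$group,
    effect = wide$overlapping - wide$`non-overlapping`
  )
}

#' Pearson chi-square test for a 2x2 table
#'
#' Pearson chi-square without continuity correction, df = 1.
#'
#' @param counts A 2x2 matrix of non-negative integer counts.
#' @return A list: `statistic`, `df`, `p`, `n`.
#' @export
#' @examples
#' chi_square_2x2(matrix(c(18, 11, 12, 19), 2)) # ~ 3.27
chi_square_2x2 <- function(counts) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == 2) || any(counts < 0)) abort("`counts` must be a non-negative 2x2 table.")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) abort("a table margin is zero.")
  ct <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  list(
    statistic = unname(ct$statistic), df = unname(ct$parameter),
    p = ct$p.value, n = sum(counts)
  )
}

#' Sensitivity power analysis for the 2x2 mixed-design interaction
#'
#' Smallest Cohen's f detectable for the within-between interaction of a
#' mixed ANOVA with `groups` groups and `measurements` repeated measures,
#' given total N, alpha and target power. Uses the noncentral-F formulation
#' with noncentrality `f^2 * N * m * epsilon / (1 - rho)` and
#' `df1 = (groups-1)(m-1)`, `df2 = (N-groups)(m-1) * epsilon`.
#'
#' @param n_total Total sample size.
#' @param groups Number of groups (default 2).
#' @param measurements Repeated measurements per subject (default 2).
#' @param alpha Significance level (default 0.05).
#' @param power Target power (default 0.95).
#' @param rho Correlation among repeated measures (default 0.5).
#' @param epsilon Nonsphericity correction (default 1).
#' @return A list: `f` (detectable effect size), `ncp`, `df1`, `df2`,
#'   `critical_f`.
#' @export
#' @examples
#' sensitivity_f(60)$f # ~ 0.237
sensitivity_f <- function(n_total = 60, groups = 2, measurements = 2,
                          alpha = 0.05, power = 0.95, rho = 0.5, epsilon = 1) {
  if (n_total <= groups || groups < 2 || measurements < 2) abort("infeasible design sizes.")
  if (alpha <= 0 || alpha >= 1 || power <= alpha || power >= 1) abort("need alpha < power < 1.")
  if (rho < 0 || rho >= 1) abort("`rho` must lie in [0, 1).")
  df1 <- (groups - 1) * (measurements - 1)
  df2 <- (n_total - groups) * (measurements - 1) * epsilon
  crit <- qf(1 - alpha, df1, df2)
  pw <- function(f) {
    ncp <- f^2 * n_total * measurements * epsilon / (1 - rho)
    1 - pf(crit, df1, df2, ncp = ncp)
  }
  sol <- stats::uniroot(function(f) pw(f) - power, c(1e-8, 10), tol = 1e-10)
  f <- sol$root
  list(
    f = f, ncp = f^2 * n_total * measurements * epsilon / (1 - rho),
    df1 = df1, df2 = df2, critical_f = crit
  )
}

#' Leave-one-out (jackknife) means
#'
#' The n jackknife averages of a vector: element i is the mean with
#' observation i excluded. Used to put behavioural and clinical variables on
#' the same leave-one-out footing as the cluster statistics before
#' correlating them.
#'
#' @param x Numeric vector.
#' @return Numeric vector of the same length.
#' @export
loo_means <- function(x) {
  n <- length(x)
  if (n < 2) abort("need at least 2 observations.")
  (sum(x) - x) / (n - 1)
}

#' Spearman correlation of two leave-one-out series
#'
#' Spearman's rho between two aligned per-iteration series, with a
#' significance flag at a Bonferroni-corrected alpha (default 0.001, i.e. a
#' 48-comparison family at familywise 0.05).
#'
#' @param x,y Aligned numeric vectors (same leave-one-out iterations).
#' @param alpha Corrected significance threshold (default 0.001).
#' @return A tibble: `rho`, `p`, `significant`, `n`.
#' @export
loo_spearman <- function(x, y, alpha = 0.001) {
  if (length(x) != length(y)) abort("leave-one-out series are misaligned.")
  ok <- stats::complete.cases(x, y)
  ct <- suppressWarnings(stats::cor.test(x[ok], y[ok], method = "spearman"))
  tibble(
    rho = unname(ct$estimate), p = ct$p.value,
    significant = ct$p.value < alpha, n = sum(ok)
  )
}
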