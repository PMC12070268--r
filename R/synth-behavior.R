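# Behavioural-outcome generator: per-subject rates and reaction times for a
# 2 (group) x 2 (feature overlap) design.

#' Default behavioural cell parameters
#'
#' Cell means and standard deviations of Nogo false-alarm rate, Go hit rate
#' and Go reaction time for the GTS and neurotypical (NT) groups in the
#' overlapping and non-overlapping conditions. False-alarm cells differ by
#' group and condition (carrying the group x overlap interaction); hit rates
#' and reaction times differ by condition only.
#'
#' @return A tibble with columns `group`, `overlap`, `fa_mean`, `fa_sd`,
#'   `hit_mean`, `hit_sd`, `rt_mean`, `rt_sd`.
#' @export
behavior_cells <- function() {
  tibble(
    group = rep(c("GTS", "NT"), each = 2),
    overlap = rep(c("overlapping", "non-overlapping"), 2),
    fa_mean = c(0.35, 0.02, 0.24, 0.01),
    fa_sd = c(0.13, 0.03, 0.08, 0.01),
    hit_mean = c(0.97, 0.98, 0.97, 0.98),
    hit_sd = c(0.04, 0.03, 0.04, 0.03),
    rt_mean = c(498, 490, 498, 490),
    rt_sd = c(49, 46, 49, 46)
  )
}

# bounded-rate sampler: Beta matched to (mean, sd) by moments; falls back to
# a clipped normal only when moment matching is infeasible (sd^2 >= m(1-m))
draw_rate <- function(n, mean, sd) {
  if (mean < 0 || mean > 1) abort("rate means must lie in [0, 1].")
  if (sd < 0) abort("rate SDs must be non-negative.")
  if (sd == 0) return(rep(mean, n))
  v <- sd^2
  if (v < mean * (1 - mean)) {
    nu <- mean * (1 - mean) / v - 1
    rbeta(n, mean * nu, (1 - mean) * nu)
  } else {
    pmin(1, pmax(0, rnorm(n, mean, sd)))
  }
}

#' Simulate a behavioural outcome table
#'
#' Draws one row per subject and overlap condition. Rates (hit rate,
#' false-alarm rate) come from Beta distributions moment-matched to the cell
#' mean/SD so their `[0, 1]` support is respected even for near-floor cells;
#' reaction times are normal, truncated at zero. Within-subject correlation
#' across conditions is induced by a shared subject-level normal quantile.
#' Optionally appends tic-severity covariates (independent noise) for the
#' GTS group, for use by the jackknifed correlation stage.
#'
#' @param n_per_group Subjects per group (default 30).
#' @param cells Cell specification as from [behavior_cells()].
#' @param subject_cor Rank correlation of a subject's outcomes across
#'   conditions, induced via a Gaussian copula (default 0.5).
#' @param clinical If `TRUE`, add `ygtss_motor`, `ygtss_vocal`, `ygtss_total`
#'   scores for GTS subjects (NA for NT).
#' @param seed Integer seed.
#' @return A tibble of class `behavioral_table` with columns `subject`,
#'   `group`, `overlap`, `hit_rate`, `rt_ms`, `fa_rate` (plus clinical
#'   columns if requested); one row per subject x condition.
#' @export
#' @examples
#' behav <- simulate_behavior(n_per_group = 30, seed = 1)
#' dplyr::count(behav, group, overlap)
simulate_behavior <- function(n_per_group = 30, cells = behavior_cells(),
                              subject_cor = 0.5, clinical = FALSE, seed = NULL) {
  need <- c("group", "overlap", "fa_mean", "fa_sd", "hit_mean", "hit_sd", "rt_mean", "rt_sd")
  if (!all(need %in% names(cells))) abort("`cells` is missing required columns.")
  if (any(cells$fa_mean < 0 | cells$fa_mean > 1 | cells$hit_mean < 0 | cells$hit_mean > 1)) {
    abort("rate means must lie in [0, 1].")
  }
  if (any(cells[, c("fa_sd", "hit_sd", "rt_sd")] < 0)) abort("SDs must be non-negative.")

  with_seed_if(seed, {
    groups <- unique(cells$group)
    rows <- list()
    for (g in groups) {
      subj_q <- rnorm(n_per_group) # shared subject quantile (copula)
      ids <- sprintf("%s%02d", tolower(g), seq_len(n_per_group))
      for (ov in unique(cells$overlap)) {
        cl <- cells[cells$group == g & cells$overlap == ov, ]
        if (nrow(cl) != 1) abort("each group x overlap cell must appear exactly once.")
        # mix subject quantile with fresh noise, then map through the cell's
        # marginal sampler by rank to keep the cell mean/SD calibrated
        zi <- sqrt(subject_cor) * subj_q +
          sqrt(1 - subject_cor) * rnorm(n_per_group)
        fa <- sort(draw_rate(n_per_group, cl$fa_mean, cl$fa_sd))[rank(zi, ties.method = "first")]
        hit <- sort(draw_rate(n_per_group, cl$hit_mean, cl$hit_sd))[rank(zi, ties.method = "first")]
        rt <- pmax(1, rnorm(n_per_group, cl$rt_mean, cl$rt_sd))
        rows[[length(rows) + 1L]] <- tibble(
          subject = ids, group = g, overlap = ov,
          hit_rate = hit, rt_ms = rt, fa_rate = fa
        )
      }
    }
    out <- dplyr::bind_rows(rows)
    if (clinical) {
      gts_ids <- unique(out$subject[out$group == "GTS"])
      clin <- tibble(
        subject = gts_ids,
        ygtss_motor = pmax(0, rnorm(length(gts_ids), 14.5, 3.8)),
        ygtss_vocal = pmax(0, rnorm(length(gts_ids), 8.1, 6.3)),
        ygtss_total = pmax(0, rnorm(length(gts_ids), 41.9, 15.9))
      )
      out <- dplyr::left_join(out, clin, by = "subject")
    }
    out <- dplyr::arrange(out, .data$group, .data$subject, .data$overlap)
    class(out) <- c("behavioral_table", class(out))
    out
  })
}
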