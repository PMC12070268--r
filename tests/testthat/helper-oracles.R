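# Shared fixtures and independent oracles used across test files.

small_array <- function(n = 16) make_sensor_array(n)

# exact Mann-Whitney p-value by exhaustive enumeration of group assignments:
# two-sided p of |U - mu| under the permutation null
exact_mann_whitney_p <- function(x, y) {
  n1 <- length(x)
  pool <- c(x, y)
  n <- length(pool)
  rk <- rank(pool)
  mu <- n1 * (n - n1) / 2
  obs <- abs(sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2 - mu)
  combs <- utils::combn(n, n1)
  stats <- apply(combs, 2, function(idx) {
    abs(sum(rk[idx]) - n1 * (n1 + 1) / 2 - mu)
  })
  mean(stats >= obs - 1e-12)
}

# exact Wilcoxon signed-rank p by enumeration of all sign assignments
exact_wilcoxon_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  rk <- rank(abs(d))
  mu <- n * (n + 1) / 4
  obs <- abs(sum(rk[d > 0]) - mu)
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  stats <- abs(as.vector(signs %*% rk) - mu)
  mean(stats >= obs - 1e-12)
}

# brute-force connected components via igraph, for validating cluster forming
# and DBSCAN reachability
igraph_components <- function(members, adj) {
  sub <- adj[members, members, drop = FALSE]
  g <- igraph::graph_from_adjacency_matrix(sub, mode = "undirected")
  split(members, igraph::components(g)$membership)
}

# exact sign-flip null distribution of the maximal positive / minimal
# negative cluster T_sum for a paired design (independent reimplementation:
# t by formula, components via igraph)
exact_signflip_cluster_p <- function(a, b, adj, threshold) {
  d <- a - b
  n <- nrow(d)
  tstat <- function(dd) {
    mu <- colMeans(dd)
    s <- apply(dd, 2, sd)
    t <- mu / (s / sqrt(n))
    t[s == 0] <- sign(mu[s == 0]) * 1e6
    t
  }
  max_tsum <- function(t) {
    best_pos <- 0
    best_neg <- 0
    for (sgn in c(1, -1)) {
      sup <- which(if (sgn > 0) t > threshold else t < -threshold)
      if (!length(sup)) next
      for (comp in igraph_components(sup, adj)) {
        ts <- sum(t[comp])
        if (sgn > 0) best_pos <- max(best_pos, ts) else best_neg <- min(best_neg, ts)
      }
    }
    c(best_pos, best_neg)
  }
  t_obs <- tstat(d)
  obs <- max_tsum(t_obs)
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  null_mat <- t(apply(signs, 1, function(s) max_tsum(tstat(d * s))))
  list(
    t_obs = t_obs,
    p_pos = mean(null_mat[, 1] >= obs[1] - 1e-12),
    p_neg = mean(null_mat[, 2] <= obs[2] + 1e-12),
    obs = obs
  )
}

# quick paired band-power matrices from a simulated study
study_band_matrices <- function(sim, band = "theta") {
  bp <- band_power_table(sim, band)
  list(
    over = power_matrix(bp, "overlapping"),
    non = power_matrix(bp, "non-overlapping")
  )
}

# single-group effect spec at the desk scale used by the heavier suites
desk_spec <- function(seed, amp_over = 0, amp_non = 0, n_trials = 12,
                      groups = c(GTS = 12), sfreq = 64,
                      channels = c("Cz", "FCz", "FC1", "FC2")) {
  amp <- matrix(rep(c(amp_over, amp_non), each = length(groups)),
    length(groups), 2,
    dimnames = list(names(groups), c("overlapping", "non-overlapping"))
  )
  effect_spec(
    n_subjects = groups, n_trials = n_trials, sfreq = sfreq,
    epoch_win = c(-1, 1),
    effects = list(list(
      name = "theta", freq = 5.5, channels = channels,
      center_s = 0.45, sd_s = 0.15, amp = amp
    )),
    seed = seed
  )
}
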