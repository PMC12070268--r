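# Cluster-based permutation inference over arbitrary adjacency structures
# (sensor neighbour graphs and 3-d voxel grids), for dependent (paired,
# within-group) and independent (between-group) designs. The cluster-level
# statistic is T_sum, the sum of member t-values; family-wise error is
# controlled by referencing each observed cluster to the Monte-Carlo
# distribution of the maximal cluster statistic of its sign.

T_CAP <- 1e6 # cap for zero-variance paired differences

#' Elementwise t statistics per node
#'
#' Classical t statistic at every node (channel or voxel): a paired t on the
#' within-subject condition difference for the dependent design, a pooled
#' two-sample t for the independent design. Zero-variance paired differences
#' produce a deterministic capped value (+/-1e6) instead of +/-Inf.
#'
#' @param a,b Numeric matrices, subjects x nodes. Dependent design: paired by
#'   row (same subjects). Independent design: the two groups (row counts may
#'   differ).
#' @param design `"dependent"` or `"independent"`.
#' @return Numeric vector of t values with attributes `df` and `design`.
#' @export
elementwise_t <- function(a, b, design = c("dependent", "independent")) {
  design <- match.arg(design)
  a <- as.matrix(a)
  b <- as.matrix(b)
  if (ncol(a) != ncol(b)) abort("node dimensions differ.")
  if (design == "dependent") {
    if (nrow(a) != nrow(b)) abort("dependent design requires paired rows.")
    n <- nrow(a)
    if (n < 2) abort("need at least 2 subjects per cell.")
    d <- a - b
    mu <- colMeans(d)
    s <- sqrt(colSums((d - rep(mu, each = n))^2) / (n - 1))
    t <- mu / (s / sqrt(n))
    zero <- s == 0
    t[zero] <- sign(mu[zero]) * T_CAP
    t[zero & mu == 0] <- 0
    df <- n - 1
  } else {
    n1 <- nrow(a)
    n2 <- nrow(b)
    if (n1 < 2 || n2 < 2) abort("need at least 2 subjects per group.")
    m1 <- colMeans(a)
    m2 <- colMeans(b)
    ss1 <- colSums((a - rep(m1, each = n1))^2)
    ss2 <- colSums((b - rep(m2, each = n2))^2)
    sp <- sqrt((ss1 + ss2) / (n1 + n2 - 2))
    se <- sp * sqrt(1 / n1 + 1 / n2)
    t <- (m1 - m2) / se
    zero <- se == 0
    t[zero] <- sign(m1[zero] - m2[zero]) * T_CAP
    t[zero & m1 == m2] <- 0
    df <- n1 + n2 - 2
  }
  attr(t, "df") <- df
  attr(t, "design") <- design
  t
}

# connected components of suprathreshold same-sign nodes; returns a list of
# clusters (integer member vectors + t_sum) and the extreme T_sums.
# min_neighbors: a node is admitted only if at least that many of its
# neighbours are suprathreshold with the same sign (0 disables the rule).
cluster_stats <- function(t_map, threshold, nb, min_neighbors = 0) {
  clusters <- list()
  max_pos <- 0
  min_neg <- 0
  for (sgn in c(1, -1)) {
    supra <- if (sgn > 0) t_map > threshold else t_map < -threshold
    idx <- which(supra)
    if (min_neighbors > 0 && length(idx)) {
      keep <- vapply(idx, function(i) sum(supra[nb[[i]]]) >= min_neighbors, logical(1))
      idx <- idx[keep]
      supra[] <- FALSE
      supra[idx] <- TRUE
    }
    if (!length(idx)) next
    seen <- logical(length(t_map))
    for (s0 in idx) {
      if (seen[s0]) next
      comp <- integer(0)
      stack <- s0
      seen[s0] <- TRUE
      while (length(stack)) {
        v <- stack[length(stack)]
        stack <- stack[-length(stack)]
        comp <- c(comp, v)
        for (u in nb[[v]]) {
          if (supra[u] && !seen[u]) {
            seen[u] <- TRUE
            stack <- c(stack, u)
          }
        }
      }
      ts <- sum(t_map[comp])
      clusters[[length(clusters) + 1L]] <- list(members = comp, t_sum = ts, sign = sgn)
      if (sgn > 0) max_pos <- max(max_pos, ts) else min_neg <- min(min_neg, ts)
    }
  }
  list(clusters = clusters, max_pos = max_pos, min_neg = min_neg)
}

clusters_to_tibble <- function(cl, nodes) {
  if (!length(cl)) {
    return(tibble(
      cluster = integer(0), sign = integer(0), n_nodes = integer(0),
      members = list(), t_sum = numeric(0)
    ))
  }
  tibble(
    cluster = seq_along(cl),
    sign = vapply(cl, function(c) as.integer(c$sign), integer(1)),
    n_nodes = vapply(cl, function(c) length(c$members), integer(1)),
    members = lapply(cl, function(c) nodes[c$members]),
    t_sum = vapply(cl, function(c) c$t_sum, numeric(1))
  )
}

#' Form clusters from a t-map
#'
#' Groups suprathreshold nodes of equal sign into connected components under
#' the adjacency structure and sums their t-values. With `min_neighbors > 0`
#' a node is admitted only if at least that many of its neighbours are also
#' suprathreshold with the same sign (the conventional sensor-level rule that
#' suppresses singleton clusters).
#'
#' @param t_map Numeric vector of node statistics (named, or names taken from
#'   the adjacency matrix).
#' @param threshold Positive cluster-forming threshold.
#' @param adjacency Logical adjacency matrix (see [sensor_adjacency()],
#'   [grid_adjacency()]).
#' @param min_neighbors Minimum suprathreshold neighbours per node (default 0
#'   = rule disabled).
#' @return A `cluster_set` tibble: `cluster`, `sign`, `n_nodes`, `members`
#'   (list of node names), `t_sum`. Empty (zero rows) when nothing survives.
#' @export
form_clusters <- function(t_map, threshold, adjacency, min_neighbors = 0) {
  if (threshold <= 0) abort("`threshold` must be positive.")
  nodes <- colnames(adjacency) %||% names(t_map) %||% as.character(seq_along(t_map))
  nb <- adjacency_list(adjacency)
  cs <- cluster_stats(as.numeric(t_map), threshold, nb, min_neighbors)
  out <- clusters_to_tibble(cs$clusters, nodes)
  class(out) <- c("cluster_set", class(out))
  attr(out, "threshold") <- threshold
  attr(out, "nodes") <- nodes
  out
}

#' Cluster-based permutation test
#'
#' Monte-Carlo cluster inference: the observed t-map is thresholded (default:
#' two-sided critical t at `alpha` for the design's degrees of freedom) and
#' clustered; the same is done for `R` randomizations - sign flips of the
#' within-subject difference for the dependent design, group-label
#' permutations preserving group sizes for the independent design - and each
#' observed cluster's T_sum is referenced to the null distribution of the
#' maximal cluster statistic of its sign. Each tail is tested at `alpha/2`
#' (two-tailed correction): cluster p-values are
#' `(1 + #(null >= observed)) / (R + 1)` and flagged significant when
#' `p <= alpha/2`.
#'
#' @param a,b Subjects x nodes matrices (see [elementwise_t()]).
#' @param design `"dependent"` or `"independent"`.
#' @param adjacency Logical adjacency matrix over nodes.
#' @param R Number of randomizations (default 1000).
#' @param alpha Two-tailed family-wise alpha (default 0.05).
#' @param threshold Cluster-forming threshold; default the two-sided critical
#'   t at `alpha` for the design's df.
#' @param min_neighbors Minimum suprathreshold neighbours per node (default 2
#'   for sensor-style graphs; set 0 for voxel grids).
#' @param seed Integer seed for the permutation schedule.
#' @return A `cluster_set` tibble with columns `cluster`, `sign`, `n_nodes`,
#'   `members`, `t_sum`, `p`, `significant`; attributes carry the threshold,
#'   design, `R`, `alpha`, observed t-map and null extrema.
#' @export
#' @examples
#' arr <- make_sensor_array(16)
#' adj <- sensor_adjacency(arr)
#' a <- matrix(rnorm(8 * 16), 8)
#' b <- matrix(rnorm(8 * 16), 8)
#' permutation_test(a, b, "dependent", adj, R = 99, seed = 1)
permutation_test <- function(a, b, design = c("dependent", "independent"),
                             adjacency, R = 1000, alpha = 0.05,
                             threshold = NULL, min_neighbors = 2, seed = NULL) {
  design <- match.arg(design)
  if (R < 1) abort("`R` must be at least 1.")
  a <- as.matrix(a)
  b <- as.matrix(b)
  t_obs <- elementwise_t(a, b, design)
  df <- attr(t_obs, "df")
  threshold <- threshold %||% qt(1 - alpha / 2, df)
  nodes <- colnames(adjacency) %||% colnames(a) %||% as.character(seq_len(ncol(a)))
  nb <- adjacency_list(adjacency)
  obs <- cluster_stats(as.numeric(t_obs), threshold, nb, min_neighbors)

  null_max <- numeric(R)
  null_min <- numeric(R)
  with_seed_if(seed, {
    if (design == "dependent") {
      d <- a - b
      n <- nrow(d)
      ss <- colSums(d^2)
      S <- matrix(sample(c(-1, 1), R * n, replace = TRUE), R, n)
      M <- (S %*% d) / n
      v <- pmax((rep(ss, each = R) - n * M^2) / (n - 1), 0)
      Tm <- M / sqrt(v / n)
      zero <- v <= 0
      Tm[zero] <- sign(M[zero]) * T_CAP
      for (r in seq_len(R)) {
        cs <- cluster_stats(Tm[r, ], threshold, nb, min_neighbors)
        null_max[r] <- cs$max_pos
        null_min[r] <- cs$min_neg
      }
    } else {
      X <- rbind(a, b)
      n1 <- nrow(a)
      n <- nrow(X)
      sum_x <- colSums(X)
      sum_x2 <- colSums(X^2)
      G <- matrix(0, R, n)
      for (r in seq_len(R)) G[r, sample.int(n, n1)] <- 1
      sA <- G %*% X
      sA2 <- G %*% (X^2)
      n2 <- n - n1
      mA <- sA / n1
      mB <- (rep(sum_x, each = R) - sA) / n2
      ssA <- pmax(sA2 - n1 * mA^2, 0)
      ssB <- pmax((rep(sum_x2, each = R) - sA2) - n2 * mB^2, 0)
      se <- sqrt((ssA + ssB) / (n - 2) * (1 / n1 + 1 / n2))
      Tm <- (mA - mB) / se
      zero <- se <= 0
      Tm[zero] <- sign(mA[zero] - mB[zero]) * T_CAP
      for (r in seq_len(R)) {
        cs <- cluster_stats(Tm[r, ], threshold, nb, min_neighbors)
        null_max[r] <- cs$max_pos
        null_min[r] <- cs$min_neg
      }
    }
  })

  out <- clusters_to_tibble(obs$clusters, nodes)
  p <- vapply(seq_len(nrow(out)), function(i) {
    if (out$sign[i] > 0) {
      (sum(null_max >= out$t_sum[i]) + 1) / (R + 1)
    } else {
      (sum(null_min <= out$t_sum[i]) + 1) / (R + 1)
    }
  }, numeric(1))
  out$p <- p
  out$significant <- if (nrow(out)) p <= alpha / 2 else logical(0)
  class(out) <- c("cluster_set", class(out))
  attr(out, "threshold") <- threshold
  attr(out, "design") <- design
  attr(out, "R") <- R
  attr(out, "alpha") <- alpha
  attr(out, "t_map") <- stats::setNames(as.numeric(t_obs), nodes)
  attr(out, "nodes") <- nodes
  attr(out, "null_max") <- null_max
  attr(out, "null_min") <- null_min
  out
}

#' Between-group test on per-subject contrast maps
#'
#' Independent-design cluster permutation test on per-subject overlap-effect
#' (condition-contrast) maps from two groups.
#'
#' @param contrasts_a,contrasts_b Subjects x nodes contrast matrices for the
#'   two groups.
#' @inheritParams permutation_test
#' @return A `cluster_set` tibble as from [permutation_test()].
#' @export
between_group_contrast_test <- function(contrasts_a, contrasts_b, adjacency,
                                        R = 1000, alpha = 0.05, threshold = NULL,
                                        min_neighbors = 2, seed = NULL) {
  permutation_test(contrasts_a, contrasts_b,
    design = "independent",
    adjacency = adjacency, R = R, alpha = alpha, threshold = threshold,
    min_neighbors = min_neighbors, seed = seed
  )
}

#' Voxel-grid adjacency (26-neighbourhood)
#'
#' Neighbour relation of a regular voxel grid: voxels are adjacent when their
#' Euclidean distance is at most `sqrt(3)` grid steps (26-connectivity).
#'
#' @param model A `source_model`, or a tibble with `x`, `y`, `z` columns plus
#'   a `spacing` argument.
#' @param spacing Grid spacing in mm (taken from the model if omitted).
#' @return Logical adjacency matrix with voxel ids as dimnames.
#' @export
grid_adjacency <- function(model, spacing = NULL) {
  if (inherits(model, "source_model")) {
    vox <- model$voxels
    spacing <- spacing %||% model$spacing
  } else {
    vox <- model
    if (is.null(spacing)) abort("`spacing` required when `model` is a plain table.")
  }
  pos <- as.matrix(vox[, c("x", "y", "z")])
  d <- as.matrix(stats::dist(pos))
  adj <- d <= spacing * sqrt(3) * 1.001 & d > 0
  dimnames(adj) <- list(vox$voxel, vox$voxel)
  adj
}

#' Reshape a long band-power table into a subjects x channels matrix
#'
#' @param tbl A long table with `subject`, `channel` and a value column.
#' @param condition Optional condition filter.
#' @param value Name of the value column (default `"power"`).
#' @return Numeric matrix, one row per subject (sorted), one column per
#'   channel (input order preserved).
#' @export
power_matrix <- function(tbl, condition = NULL, value = "power") {
  if (!is.null(condition)) tbl <- tbl[tbl$condition == condition, ]
  wide <- tidyr::pivot_wider(
    tbl[, c("subject", "channel", value)],
    names_from = "channel", values_from = dplyr::all_of(value)
  )
  wide <- dplyr::arrange(wide, .data$subject)
  m <- as.matrix(wide[, -1])
  rownames(m) <- wide$subject
  m
}
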