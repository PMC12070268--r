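chain_adjacency <- function(n, labels = letters[seq_len(n)]) {
  adj <- matrix(FALSE, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1)) adj[i, i + 1] <- adj[i + 1, i] <- TRUE
  adj
}

test_that("elementwise t matches the classical formulas and guards zero variance", {
  set.seed(4)
  a <- matrix(rnorm(6 * 3), 6, 3)
  b <- matrix(rnorm(6 * 3), 6, 3)
  t_dep <- elementwise_t(a, b, "dependent")
  for (j in 1:3) {
    expect_equal(t_dep[j], unname(t.test(a[, j], b[, j], paired = TRUE)$statistic))
  }
  expect_equal(attr(t_dep, "df"), 5)
  t_ind <- elementwise_t(a, b, "independent")
  for (j in 1:3) {
    expect_equal(t_ind[j], unname(t.test(a[, j], b[, j], var.equal = TRUE)$statistic))
  }
  expect_equal(attr(t_ind, "df"), 10)
  # identical conditions -> 0; constant nonzero difference -> capped value
  expect_equal(as.numeric(elementwise_t(a, a, "dependent")), rep(0, 3))
  paired <- elementwise_t(matrix(c(1, 2, 3)), matrix(c(0, 1, 2)), "dependent")
  expect_equal(as.numeric(paired), 1e6)
  expect_error(elementwise_t(a[1, , drop = FALSE], b[1, , drop = FALSE], "dependent"), "2 subjects")
})

test_that("cluster forming groups suprathreshold same-sign components with exact T_sum", {
  adj <- chain_adjacency(3)
  cs <- form_clusters(c(a = 3, b = 3, c = -3), threshold = 2, adjacency = adj)
  cs <- cs[order(cs$sign, decreasing = TRUE), ]
  expect_equal(nrow(cs), 2)
  expect_equal(sort(cs$members[[1]]), c("a", "b"))
  expect_equal(cs$t_sum[1], 6)
  expect_equal(cs$members[[2]], "c")
  expect_equal(cs$t_sum[2], -3)
  # zero map -> empty set; non-adjacent suprathreshold nodes -> singletons
  expect_equal(nrow(form_clusters(c(a = 0, b = 0, c = 0), 2, adj)), 0)
  cs2 <- form_clusters(c(a = 3, b = 0, c = 3), 2, adj)
  expect_equal(nrow(cs2), 2)
  expect_true(all(cs2$n_nodes == 1))
  # min-neighbor rule removes the singletons
  expect_equal(nrow(form_clusters(c(a = 3, b = 0, c = 3), 2, adj, min_neighbors = 2)), 0)
  expect_error(form_clusters(c(a = 1), threshold = -1, adjacency = adj[1, 1, drop = FALSE]), "positive")
})

test_that("cluster components agree with an igraph oracle on random maps", {
  set.seed(11)
  arr <- small_array(20)
  adj <- sensor_adjacency(arr)
  for (r in 1:10) {
    tmap <- stats::setNames(rnorm(20, sd = 2), arr$channel)
    cs <- form_clusters(tmap, threshold = 1.5, adjacency = adj)
    got <- lapply(cs$members, sort)
    want <- list()
    for (sgn in c(1, -1)) {
      sup <- which(if (sgn > 0) tmap > 1.5 else tmap < -1.5)
      if (length(sup)) {
        want <- c(want, lapply(igraph_components(sup, adj), function(ix) sort(arr$channel[ix])))
      }
    }
    expect_setequal(got, want)
    expect_equal(
      sort(cs$t_sum),
      sort(unname(vapply(want[match(got, want)], function(m) sum(tmap[m]), numeric(1))))
    )
  }
})

test_that("permutation p-values match exact sign-flip enumeration for n=5", {
  set.seed(7)
  arr <- small_array(12)
  adj <- sensor_adjacency(arr)
  a <- matrix(rnorm(5 * 12, mean = 0.8), 5, 12, dimnames = list(NULL, arr$channel))
  b <- matrix(rnorm(5 * 12), 5, 12, dimnames = list(NULL, arr$channel))
  thr <- qt(0.975, 4)
  oracle <- exact_signflip_cluster_p(a, b, adj, thr)
  cs <- permutation_test(a, b, "dependent", adj,
    R = 2000, threshold = thr,
    min_neighbors = 0, seed = 99
  )
  pos <- cs[cs$sign > 0, ]
  expect_gt(nrow(pos), 0)
  biggest <- pos[which.max(pos$t_sum), ]
  # Monte-Carlo p vs exact enumeration within ~4 binomial SEs
  se <- sqrt(oracle$p_pos * (1 - oracle$p_pos) / 2000) + 1e-3
  expect_lt(abs(biggest$p - oracle$p_pos), 4 * se + 1 / 2000)
})

test_that("permutation test is reproducible, bounded below by 1/(R+1), and relabeling-invariant", {
  set.seed(2)
  arr <- small_array(12)
  adj <- sensor_adjacency(arr)
  a <- matrix(rnorm(8 * 12, mean = 1.5), 8, 12, dimnames = list(NULL, arr$channel))
  b <- matrix(rnorm(8 * 12), 8, 12, dimnames = list(NULL, arr$channel))
  cs1 <- permutation_test(a, b, "dependent", adj, R = 200, seed = 5)
  cs2 <- permutation_test(a, b, "dependent", adj, R = 200, seed = 5)
  expect_identical(tidy(cs1), tidy(cs2))
  expect_true(all(cs1$p >= 1 / 201))
  # relabel nodes by a permutation: p-values invariant
  perm <- sample(12)
  adj_p <- adj[perm, perm]
  cs3 <- permutation_test(a[, perm], b[, perm], "dependent", adj_p, R = 200, seed = 5)
  expect_equal(sort(cs3$p), sort(cs1$p))
  expect_equal(sort(cs3$t_sum), sort(cs1$t_sum))
  expect_error(permutation_test(a, b, "dependent", adj, R = 0), "R")
})

test_that("independent-design permutation detects a planted group shift and not a null", {
  set.seed(3)
  arr <- small_array(16)
  adj <- sensor_adjacency(arr)
  seeded <- which(arr$channel %in% c("Cz", "FCz", "FC1", "FC2"))
  a <- matrix(rnorm(12 * 16), 12, 16, dimnames = list(NULL, arr$channel))
  b <- matrix(rnorm(12 * 16), 12, 16, dimnames = list(NULL, arr$channel))
  a[, seeded] <- a[, seeded] + 2
  cs <- between_group_contrast_test(a, b, adj, R = 300, seed = 8)
  hit <- cs[cs$significant & cs$sign > 0, ]
  expect_gt(nrow(hit), 0)
  expect_true(any(arr$channel[seeded] %in% unlist(hit$members)))
  # identical groups: no cluster beats chance
  cs0 <- between_group_contrast_test(a, a, adj, R = 300, seed = 8)
  expect_false(any(cs0$significant))
})

test_that("grid adjacency is 26-connected and symmetric", {
  arr <- small_array(16)
  m <- make_source_model(10, arr)
  adj <- grid_adjacency(m)
  expect_true(isSymmetric(unname(adj)))
  expect_false(any(diag(adj)))
  # an interior voxel has 26 neighbours
  pos <- as.matrix(m$voxels[, c("x", "y", "z")])
  interior <- which.min(rowSums(pos^2))
  expect_equal(sum(adj[interior, ]), 26)
})

test_that("power_matrix reshapes long tables with subjects sorted and channels preserved", {
  tbl <- tibble::tibble(
    subject = rep(c("s2", "s1"), each = 2), condition = "c",
    channel = rep(c("A", "B"), 2), power = c(3, 4, 1, 2)
  )
  m <- power_matrix(tbl, "c")
  expect_equal(rownames(m), c("s1", "s2"))
  expect_equal(colnames(m), c("A", "B"))
  expect_equal(m["s1", "B"], 2)
})
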