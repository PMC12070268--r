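toy_map <- function(n = 1000, seed = 1) {
  set.seed(seed)
  k <- ceiling(n^(1 / 3))
  g <- expand.grid(x = seq_len(k), y = seq_len(k), z = seq_len(k))[seq_len(n), ] * 5
  tibble::tibble(
    voxel = seq_len(n), x = g$x, y = g$y, z = g$z,
    label = sample(c("parcelA", "parcelB"), n, replace = TRUE),
    contrast = rnorm(n)
  )
}

test_that("atlas masking removes exactly the reserved labels", {
  m <- toy_map(200)
  m$label[1:20] <- "non-labelled"
  m$label[21:30] <- "cerebellum"
  out <- mask_by_atlas(m)
  expect_equal(nrow(out), 170)
  expect_false(any(out$label %in% c("non-labelled", "cerebellum")))
  expect_identical(mask_by_atlas(m[31:40, ]), m[31:40, ])
  all_res <- m[1:20, ]
  expect_warning(empty <- mask_by_atlas(all_res), "empty")
  expect_equal(nrow(empty), 0)
})

test_that("top-percent threshold keeps ceil(q/100*N) voxels with deterministic ties", {
  m <- toy_map(1000)
  top <- top_percent_threshold(m, q = 1)
  expect_equal(nrow(top), 10)
  expect_equal(sort(top$contrast), sort(m$contrast, decreasing = TRUE)[10:1])
  # planted hotspot is exactly recovered
  m2 <- m
  m2$contrast[101:110] <- 100
  expect_equal(top_percent_threshold(m2, 1)$voxel, 101:110)
  # all-equal values: ties broken by voxel index
  m3 <- m
  m3$contrast <- 1
  expect_equal(top_percent_threshold(m3, 1)$voxel, 1:10)
  # negative direction picks the most negative values
  expect_equal(
    sort(top_percent_threshold(m2, 1, direction = "negative")$contrast),
    sort(m2$contrast)[1:10]
  )
  expect_error(top_percent_threshold(m[0, ], 1), "empty")
})

test_that("DBSCAN separates blobs, discards sparse noise, and keeps touching lines", {
  # two 8-voxel blobs 50 mm apart on a 5 mm grid
  blob <- expand.grid(x = c(0, 5), y = c(0, 5), z = c(0, 5))
  blob2 <- blob
  blob2$x <- blob2$x + 50
  vox <- rbind(blob, blob2)
  tb <- tibble::tibble(voxel = seq_len(nrow(vox)), x = vox$x, y = vox$y, z = vox$z)
  cl <- dbscan_voxels(tb, spacing = 5)
  expect_equal(length(unique(cl$cluster)), 2)
  expect_equal(nrow(cl), 16)
  expect_equal(length(unique(cl$cluster[cl$voxel <= 8])), 1)
  # 4 isolated voxels -> all noise
  iso <- tibble::tibble(voxel = 1:4, x = c(0, 100, 200, 300), y = 0, z = 0)
  expect_equal(nrow(dbscan_voxels(iso, spacing = 5)), 0)
  # a touching line of 12 voxels is one cluster (reachability chain)
  line <- tibble::tibble(voxel = 1:12, x = 5 * (1:12), y = 0, z = 0)
  cll <- dbscan_voxels(line, spacing = 5, min_pts = 3)
  expect_equal(unique(cll$cluster), 1)
  expect_equal(nrow(cll), 12)
})

test_that("DBSCAN is order-invariant and matches a brute-force reachability oracle", {
  set.seed(8)
  for (r in 1:5) {
    n <- 60
    tb <- tibble::tibble(
      voxel = seq_len(n),
      x = 5 * sample.int(12, n, replace = TRUE),
      y = 5 * sample.int(12, n, replace = TRUE),
      z = 5 * sample.int(4, n, replace = TRUE)
    )
    tb <- dplyr::distinct(tb, x, y, z, .keep_all = TRUE)
    eps <- 7.5
    min_pts <- 4
    got <- dbscan_voxels(tb, eps = eps, min_pts = min_pts)
    # oracle: core points via distance counts, clusters via igraph components
    # over core-core edges, then attach borders
    d <- as.matrix(dist(as.matrix(tb[, c("x", "y", "z")])))
    core <- rowSums(d <= eps) >= min_pts
    want_members <- c()
    if (any(core)) {
      sub <- d[core, core, drop = FALSE] <= eps
      diag(sub) <- FALSE
      g <- igraph::graph_from_adjacency_matrix(sub, mode = "undirected")
      comp <- igraph::components(g)$membership
      core_idx <- which(core)
      member <- rep(NA_integer_, nrow(tb))
      member[core_idx] <- comp
      for (i in which(!core)) {
        near_core <- core_idx[d[i, core_idx] <= eps]
        if (length(near_core)) {
          # border points attach to the nearest core (ties by voxel index)
          best <- near_core[order(d[i, near_core], tb$voxel[near_core])][1]
          member[i] <- member[best]
        }
      }
      want_members <- which(!is.na(member))
      # same voxel partition (up to cluster relabeling)
      expect_setequal(got$voxel, tb$voxel[want_members])
      split_got <- unname(split(got$voxel, got$cluster))
      split_want <- unname(split(tb$voxel[want_members], member[want_members]))
      expect_setequal(lapply(split_got, sort), lapply(split_want, sort))
    } else {
      expect_equal(nrow(got), 0)
    }
    # permuting the row order does not change the partition
    perm <- sample(nrow(tb))
    got_p <- dbscan_voxels(tb[perm, ], eps = eps, min_pts = min_pts)
    expect_setequal(
      unname(lapply(split(got$voxel, got$cluster), sort)),
      unname(lapply(split(got_p$voxel, got_p$cluster), sort))
    )
  }
})

test_that("cluster labelling reports histograms and dominant labels", {
  tb <- tibble::tibble(
    voxel = 1:10, x = 5 * (1:10), y = 0, z = 0,
    label = c(rep("parcelA", 7), rep("parcelB", 3)),
    cluster = c(rep(1L, 7), rep(2L, 3))
  )
  lab <- label_clusters(tb)
  expect_equal(lab$dominant_label, c("parcelA", "parcelB"))
  expect_equal(lab$n_voxels, c(7L, 3L))
  # straddling cluster lists both labels with counts
  tb2 <- dplyr::mutate(tb, cluster = 1L)
  lab2 <- label_clusters(tb2)
  expect_equal(as.integer(lab2$labels[[1]][c("parcelA", "parcelB")]), c(7L, 3L))
  # atlas relabeling permutes the histogram consistently
  atlas <- tibble::tibble(voxel = 1:10, label = rev(tb$label))
  lab3 <- label_clusters(tb2, atlas = atlas)
  expect_equal(as.integer(lab3$labels[[1]][c("parcelA", "parcelB")]), c(7L, 3L))
})

test_that("masking precedes thresholding in the localization chain", {
  m <- toy_map(500, seed = 3)
  # put the most extreme values on reserved voxels: they must not survive
  m$label[1:5] <- "cerebellum"
  m$contrast[1:5] <- 100
  top <- top_percent_threshold(mask_by_atlas(m), q = 1)
  expect_false(any(top$voxel %in% 1:5))
  # thresholding before masking would have kept them (asserts order matters)
  top_wrong <- suppressWarnings(mask_by_atlas(top_percent_threshold(m, q = 1)))
  expect_false(identical(sort(top$voxel), sort(top_wrong$voxel)))
})

test_that("the full localization chain finds a planted hotspot and labels it", {
  arr <- small_array(16)
  model <- make_source_model(10, arr, seed = 2)
  rc <- dplyr::mutate(model$voxels, contrast = 0.01 * rnorm(nrow(model$voxels)))
  hot <- which(rc$label == rc$label[which(rc$x > 15 & rc$z > 15)[1]])[1:12]
  rc$contrast[hot] <- 0.9
  peaks <- localize_peaks(rc, spacing = 10, q = 1)
  expect_gte(nrow(peaks), 1)
  expect_equal(peaks$dominant_label[1], rc$label[hot[1]])
})
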