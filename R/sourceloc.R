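# Peak localization of source contrasts: atlas masking, top-percentile
# thresholding, and DBSCAN density clustering with atlas labelling.

#' Exclude reserved atlas regions from a source map
#'
#' Removes voxels whose atlas label is in the reserved set (by default the
#' non-labelled and cerebellar voxels). Applied before thresholding.
#'
#' @param map A tibble with a `label` column (e.g. a `source_contrast_map`).
#' @param reserved Labels to exclude.
#' @return The map without the reserved voxels (empty, with a warning, if
#'   everything was reserved).
#' @export
mask_by_atlas <- function(map, reserved = c("non-labelled", "cerebellum")) {
  if (!"label" %in% names(map)) abort("`map` has no `label` column.")
  out <- map[!(map$label %in% reserved), , drop = FALSE]
  if (nrow(out) == 0) warn("all voxels carry reserved labels; the masked map is empty.")
  out
}

#' Retain the top percentile of a source map
#'
#' Keeps the `ceiling(q/100 * N)` voxels with the most extreme values:
#' largest values for `direction = "positive"`, smallest for `"negative"`,
#' largest magnitudes for `"absolute"`. Ties are broken deterministically by
#' voxel index. `NA` values are dropped first.
#'
#' @param map A tibble with a value column (default `contrast`).
#' @param q Percentage to retain (default 1).
#' @param direction `"positive"`, `"negative"` or `"absolute"`.
#' @param value Name of the value column.
#' @return The retained rows of `map`.
#' @export
top_percent_threshold <- function(map, q = 1, direction = c("positive", "negative", "absolute"),
                                  value = "contrast") {
  direction <- match.arg(direction)
  v <- map[[value]]
  map <- map[!is.na(v), , drop = FALSE]
  v <- map[[value]]
  if (nrow(map) == 0) abort("cannot threshold an empty map.")
  n_keep <- ceiling(q / 100 * nrow(map))
  key <- switch(direction, positive = -v, negative = v, absolute = -abs(v))
  ord <- order(key, map$voxel)
  map[sort(ord[seq_len(n_keep)]), , drop = FALSE]
}

#' DBSCAN clustering of voxels in millimetre space
#'
#' Standard core/border/noise DBSCAN over Euclidean distances of the voxel
#' coordinates: a voxel is a core point if at least `min_pts` voxels
#' (including itself) lie within `eps`; clusters are the connected components
#' of core points plus their border points; noise is discarded. The defaults
#' follow the convention of a search radius of 1.5 grid steps and a minimum
#' cluster size of 5 voxels.
#'
#' @param voxels A tibble with `voxel`, `x`, `y`, `z` (mm).
#' @param eps Search radius in mm (default `1.5 * spacing`).
#' @param min_pts Minimum points within `eps` for a core voxel (default 5).
#' @param spacing Grid spacing in mm, used for the default `eps`.
#' @return A `voxel_clusters` tibble: the clustered voxels with an integer
#'   `cluster` column (noise removed). Cluster ids are ordered by size.
#' @export
dbscan_voxels <- function(voxels, eps = NULL, min_pts = 5, spacing = 5) {
  eps <- eps %||% (1.5 * spacing)
  if (eps <= 0 || min_pts < 1) abort("`eps` must be positive and `min_pts` at least 1.")
  n <- nrow(voxels)
  out <- dplyr::mutate(voxels, cluster = NA_integer_)
  if (n == 0) {
    class(out) <- c("voxel_clusters", class(out))
    return(out)
  }
  pos <- as.matrix(voxels[, c("x", "y", "z")])
  d <- as.matrix(stats::dist(pos))
  nbrs <- lapply(seq_len(n), function(i) which(d[i, ] <= eps)) # includes self
  core <- vapply(nbrs, length, integer(1)) >= min_pts

  # cluster the core points (connected components of the core graph), then
  # attach each border point to its nearest core neighbour (ties broken by
  # voxel index) so the partition is independent of row order
  cl <- rep(NA_integer_, n)
  next_id <- 0L
  for (i in seq_len(n)) {
    if (!core[i] || !is.na(cl[i])) next
    next_id <- next_id + 1L
    cl[i] <- next_id
    queue <- i
    while (length(queue)) {
      v <- queue[1]
      queue <- queue[-1]
      for (u in nbrs[[v]]) {
        if (core[u] && is.na(cl[u])) {
          cl[u] <- next_id
          queue <- c(queue, u)
        }
      }
    }
  }
  for (i in which(!core)) {
    cand <- nbrs[[i]][core[nbrs[[i]]]]
    if (length(cand)) {
      ord <- order(d[i, cand], voxels$voxel[cand])
      cl[i] <- cl[cand[ord[1]]]
    }
  }
  out$cluster <- cl
  out <- out[!is.na(out$cluster), , drop = FALSE]
  if (nrow(out)) {
    sizes <- sort(table(out$cluster), decreasing = TRUE)
    remap <- stats::setNames(seq_along(sizes), names(sizes))
    out$cluster <- as.integer(remap[as.character(out$cluster)])
    out <- out[order(out$cluster, out$voxel), , drop = FALSE]
  }
  class(out) <- c("voxel_clusters", class(out))
  attr(out, "eps") <- eps
  attr(out, "min_pts") <- min_pts
  out
}

#' Summarize and label voxel clusters with an atlas
#'
#' Per cluster: size, centroid (mm) and the histogram of atlas labels with
#' the dominant label.
#'
#' @param clusters A `voxel_clusters` tibble (must carry a `label` column, or
#'   supply `atlas`).
#' @param atlas Optional tibble `voxel`, `label` to (re)label from.
#' @return A tibble: `cluster`, `n_voxels`, `x`, `y`, `z` (centroid),
#'   `dominant_label`, `labels` (list-column of per-label counts).
#' @export
label_clusters <- function(clusters, atlas = NULL) {
  if (!is.null(atlas)) {
    clusters$label <- atlas$label[match(clusters$voxel, atlas$voxel)]
  }
  if (!"label" %in% names(clusters)) abort("no labels available; supply `atlas`.")
  dplyr::summarise(
    dplyr::group_by(clusters, .data$cluster),
    n_voxels = dplyr::n(),
    x = mean(.data$x), y = mean(.data$y), z = mean(.data$z),
    dominant_label = names(sort(table(.data$label), decreasing = TRUE))[1],
    labels = list(sort(table(.data$label), decreasing = TRUE)),
    .groups = "drop"
  )
}

#' Localize the peak regions of a source contrast
#'
#' The full localization chain in the stated order: atlas masking, then
#' top-percentile thresholding, then DBSCAN, then labelling.
#'
#' @param contrast_map A `source_contrast_map`.
#' @param spacing Grid spacing in mm.
#' @param q Top percentage retained (default 1).
#' @param direction Threshold direction (see [top_percent_threshold()]).
#' @param eps,min_pts DBSCAN parameters (defaults `1.5 * spacing` and 5).
#' @param reserved Reserved atlas labels to exclude.
#' @return As [label_clusters()].
#' @export
localize_peaks <- function(contrast_map, spacing, q = 1,
                           direction = "positive", eps = NULL, min_pts = 5,
                           reserved = c("non-labelled", "cerebellum")) {
  masked <- mask_by_atlas(contrast_map, reserved)
  top <- top_percent_threshold(masked, q = q, direction = direction)
  cl <- dbscan_voxels(top, eps = eps, min_pts = min_pts, spacing = spacing)
  label_clusters(cl)
}
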