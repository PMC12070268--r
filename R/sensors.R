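# Sensor geometry: equidistant spherical layouts and neighbourhood graphs.

# canonical unit-sphere positions for the midfrontal/centroparietal channels
# that sensor-level theta clusters are typically seeded at
named_channel_positions <- function() {
  pos <- rbind(
    Cz  = c(0.00, 0.00, 1.00),
    FCz = c(0.00, 0.35, 0.94),
    FC1 = c(-0.25, 0.33, 0.91),
    FC2 = c(0.25, 0.33, 0.91),
    CP1 = c(-0.25, -0.33, 0.91),
    CP2 = c(0.25, -0.33, 0.91),
    F2  = c(0.18, 0.63, 0.76),
    FC4 = c(0.52, 0.35, 0.78)
  )
  pos / sqrt(rowSums(pos^2))
}

#' Construct an equidistant spherical sensor array
#'
#' Places `n_channels` electrodes quasi-uniformly on the upper part of a unit
#' head sphere (Fibonacci lattice) and pins the eight canonical midfrontal /
#' centroparietal labels (Cz, FCz, FC1, FC2, CP1, CP2, F2, FC4) to their
#' standard positions so simulated effects can be seeded at named electrodes.
#'
#' @param n_channels Number of electrodes (default 61, a standard montage
#'   size; at least 12).
#' @param z_min Lowest z coordinate of the electrode cap (default -0.25).
#' @return A tibble of class `sensor_array` with columns `channel`, `x`, `y`,
#'   `z`; positions have unit norm and labels are unique.
#' @export
#' @examples
#' arr <- make_sensor_array(32)
#' nrow(arr)
make_sensor_array <- function(n_channels = 61, z_min = -0.25) {
  stopifnot_scalar_num(n_channels, "n_channels", positive = TRUE)
  if (n_channels < 12) abort("`n_channels` must be at least 12.")
  n <- as.integer(n_channels)
  i <- seq_len(n)
  z <- z_min + (i - 0.5) / n * (1 - z_min)
  phi <- i * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  pos <- cbind(x = r * cos(phi), y = r * sin(phi), z = z)
  labels <- sprintf("E%02d", i)

  named <- named_channel_positions()
  taken <- integer(0)
  for (k in seq_len(nrow(named))) {
    d2 <- colSums((t(pos) - named[k, ])^2)
    d2[taken] <- Inf
    j <- which.min(d2)
    pos[j, ] <- named[k, ]
    labels[j] <- rownames(named)[k]
    taken <- c(taken, j)
  }

  out <- tibble(channel = labels, x = pos[, 1], y = pos[, 2], z = pos[, 3])
  class(out) <- c("sensor_array", class(out))
  out
}

#' Sensor neighbourhood from an inter-electrode distance threshold
#'
#' Builds the symmetric, irreflexive neighbour relation used for spatial
#' clustering. The chordal distance threshold is chosen automatically as the
#' smallest value at which the median electrode has at least `target_degree`
#' neighbours, which yields the conventional 6-8 neighbours per electrode on
#' quasi-uniform layouts.
#'
#' @param array A [make_sensor_array()] tibble.
#' @param threshold Optional fixed distance threshold; overrides the
#'   automatic choice.
#' @param target_degree Median neighbour count targeted by the automatic
#'   threshold (default 6).
#' @return A logical adjacency matrix with channel dimnames; the chosen
#'   threshold is stored in `attr(, "threshold")`.
#' @export
#' @examples
#' adj <- sensor_adjacency(make_sensor_array(32))
#' isSymmetric(adj)
sensor_adjacency <- function(array, threshold = NULL, target_degree = 6) {
  pos <- as.matrix(array[, c("x", "y", "z")])
  d <- as.matrix(stats::dist(pos))
  if (is.null(threshold)) {
    cand <- sort(unique(as.vector(d[upper.tri(d)])))
    for (th in cand) {
      deg <- rowSums(d <= th) - 1L
      if (stats::median(deg) >= target_degree) {
        threshold <- th
        break
      }
    }
    threshold <- threshold %||% max(cand)
  }
  adj <- d <= threshold
  diag(adj) <- FALSE
  dimnames(adj) <- list(array$channel, array$channel)
  attr(adj, "threshold") <- threshold
  adj
}

# adjacency matrix -> list of integer neighbour vectors (internal fast form)
adjacency_list <- function(adj) {
  lapply(seq_len(nrow(adj)), function(i) which(adj[i, ]))
}
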