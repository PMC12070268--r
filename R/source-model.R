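# Toy volumetric source space: regular grid inside a spherical head, dipole
# leadfields, and a geometric atlas with reserved labels for masking tests.

#' Construct a toy volumetric source model
#'
#' Builds a regular grid of voxels inside a spherical head, an analytic
#' dipole leadfield per inside voxel (homogeneous-medium potential at the
#' scalp electrodes, average-referenced, with small seeded per-electrode gain
#' variability), and a geometric atlas: octant x depth-shell parcels, plus
#' two reserved labels - `"non-labelled"` for the deepest central voxels and
#' `"cerebellum"` for a posterior-inferior wedge - so that atlas-based
#' exclusion can be exercised without a real anatomical atlas.
#'
#' @param grid_spacing_mm Grid spacing in mm (default 5).
#' @param array A [make_sensor_array()] tibble; electrode positions are
#'   scaled to the scalp radius.
#' @param head_radius_mm Scalp sphere radius (default 60 mm); sources are
#'   restricted to `head_radius_mm - 8` mm.
#' @param gain_sd SD of the multiplicative electrode gain perturbation
#'   (default 0.05).
#' @param seed Integer seed for the gain perturbation.
#' @return A list of class `source_model` with elements `voxels` (tibble:
#'   `voxel`, `x`, `y`, `z` in mm, `label`), `leadfield` (list of channels x 3
#'   matrices), `spacing`, `channels`, `array`.
#' @export
#' @examples
#' model <- make_source_model(grid_spacing_mm = 10, array = make_sensor_array(32))
#' nrow(model$voxels)
make_source_model <- function(grid_spacing_mm = 5, array = make_sensor_array(),
                              head_radius_mm = 60, gain_sd = 0.05, seed = 1) {
  stopifnot_scalar_num(grid_spacing_mm, "grid_spacing_mm", positive = TRUE)
  r_in <- head_radius_mm - 8
  ax <- seq(-r_in, r_in, by = grid_spacing_mm)
  grid <- as.matrix(expand.grid(x = ax, y = ax, z = ax))
  inside <- sqrt(rowSums(grid^2)) <= r_in
  grid <- grid[inside, , drop = FALSE]
  nv <- nrow(grid)

  r <- sqrt(rowSums(grid^2))
  lbl <- character(nv)
  shell <- ifelse(r > r_in / 2, "sup", "deep")
  oct <- paste0(
    ifelse(grid[, 1] >= 0, "R", "L"),
    ifelse(grid[, 2] >= 0, "ant", "post"),
    ifelse(grid[, 3] >= 0, "up", "low")
  )
  lbl <- paste(oct, shell, sep = "_")
  lbl[r < 0.25 * r_in] <- "non-labelled"
  lbl[grid[, 2] < -0.35 * r_in & grid[, 3] < -0.2 * r_in] <- "cerebellum"

  elec <- as.matrix(array[, c("x", "y", "z")]) * head_radius_mm
  gains <- with_seed_if(seed, {
    1 + rnorm(nrow(elec), 0, gain_sd)
  })

  # homogeneous-medium dipole potential: V = (r_e - r_v) . q / (4 pi |r_e - r_v|^3)
  leadfield <- vector("list", nv)
  for (v in seq_len(nv)) {
    dvec <- t(t(elec) - grid[v, ])
    d3 <- (sqrt(rowSums(dvec^2)))^3
    L <- dvec / d3 / (4 * pi) * gains
    L <- sweep(L, 2, colMeans(L)) # average reference
    leadfield[[v]] <- L * 1e5 # scale to a convenient uV-per-unit-moment range
  }

  structure(
    list(
      voxels = tibble(
        voxel = seq_len(nv), x = grid[, 1], y = grid[, 2], z = grid[, 3],
        label = lbl
      ),
      leadfield = leadfield, spacing = grid_spacing_mm,
      channels = array$channel, array = array,
      head_radius_mm = head_radius_mm
    ),
    class = "source_model"
  )
}

#' @export
print.source_model <- function(x, ...) {
  cat(sprintf(
    "<source_model> %d inside voxels, %g mm grid, %d channels, %d parcels\n",
    nrow(x$voxels), x$spacing, length(x$channels), length(unique(x$voxels$label))
  ))
  invisible(x)
}

#' Simulate sensor epochs containing a single oscillating dipole
#'
#' Projects a band-limited burst at one voxel of a [make_source_model()]
#' through its leadfield and adds sensor white noise, producing an "active"
#' and a "baseline" (noise-only) condition for source-localization checks.
#' The signal-to-noise ratio is defined as the ratio of the RMS of the
#' projected source signal to the noise RMS, averaged over channels, within
#' the burst window.
#'
#' @param model A `source_model`.
#' @param voxel Index of the active voxel.
#' @param freq Burst frequency in Hz.
#' @param snr Sensor-level signal-to-noise ratio (RMS ratio in the burst
#'   window).
#' @param n_trials Trials per condition.
#' @param sfreq Sampling rate in Hz.
#' @param epoch_win Epoch window in seconds.
#' @param burst_win Window containing the oscillation, in seconds.
#' @param seed Integer seed.
#' @return A tibble with `condition` (`"active"`/`"baseline"`) and an
#'   `epochs` list-column.
#' @export
simulate_dipole_epochs <- function(model, voxel, freq, snr = 5, n_trials = 40,
                                   sfreq = 256, epoch_win = c(-2, 2),
                                   burst_win = c(0, 1), seed = 1) {
  stopifnot(inherits(model, "source_model"))
  times <- seq(epoch_win[1], epoch_win[2], by = 1 / sfreq)
  ns <- length(times)
  nch <- length(model$channels)
  L <- model$leadfield[[voxel]]

  with_seed_if(seed, {
    ori <- rnorm(3)
    ori <- ori / sqrt(sum(ori^2))
    gain <- as.numeric(L %*% ori) # channels
    in_burst <- times >= burst_win[1] & times <= burst_win[2]
    ramp <- rep(0, ns)
    ramp[in_burst] <- sin(pi * seq(0, 1, length.out = sum(in_burst)))^2 # smooth on/off
    noise_sd <- 1
    # scale source amplitude for the requested sensor-level SNR in the window
    amp <- snr * noise_sd / sqrt(mean(gain^2) * mean((ramp[in_burst])^2) / 2)

    make_cond <- function(active) {
      arr <- array(rnorm(n_trials * nch * ns, 0, noise_sd), dim = c(n_trials, nch, ns))
      if (active) {
        for (tr in seq_len(n_trials)) {
          s <- amp * ramp * cos(2 * pi * freq * times + runif(1, 0, 2 * pi))
          arr[tr, , ] <- arr[tr, , ] + outer(gain, s)
        }
      }
      eeg_epochs(arr, sfreq, times, model$array,
        subject = "sim01", condition = if (active) "active" else "baseline"
      )
    }
    tibble(
      condition = c("active", "baseline"),
      epochs = list(make_cond(TRUE), make_cond(FALSE))
    )
  })
}
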