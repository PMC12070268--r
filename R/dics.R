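# Frequency-domain source analysis: multitaper cross-spectral densities and
# DICS (Dynamic Imaging of Coherent Sources) beamforming.

#' Multitaper (Hanning) cross-spectral density of a frequency band
#'
#' Estimates the channels x channels cross-spectral density over a time
#' window (default 0-1 s post-stimulus): each trial's window is demeaned,
#' Hanning-tapered and Fourier-transformed, and the outer products of the
#' spectra are averaged over trials and over the Fourier bins falling inside
#' the band.
#'
#' @param x An `eeg_epochs` object.
#' @param band Band name or `c(lo, hi)` Hz.
#' @param window Analysis window in seconds (default `c(0, 1)`).
#' @return An object of class `eeg_csd`: list with `C` (complex Hermitian
#'   matrix), `band`, `freqs` (bins used), `window`, `n_trials`, `channels`,
#'   `condition`.
#' @export
csd_multitaper <- function(x, band = "theta", window = c(0, 1)) {
  stopifnot(inherits(x, "eeg_epochs"))
  lim <- band_limits(band)
  check_window(window, "window")
  sel <- which(x$times >= window[1] & x$times <= window[2])
  if (length(sel) < 8) abort("analysis window lies outside the epoch (or is too short).")
  nw <- length(sel)
  taper <- 0.5 - 0.5 * cos(2 * pi * seq(0, 1, length.out = nw)) # Hanning
  fax <- (seq_len(nw) - 1) * x$sfreq / nw
  fbin <- which(fax >= lim[1] & fax <= lim[2])
  if (!length(fbin)) abort("no Fourier bins inside the requested band for this window length.")

  d <- dim(x$data)
  C <- matrix(0 + 0i, d[2], d[2])
  for (tr in seq_len(d[1])) {
    seg <- x$data[tr, , sel, drop = TRUE]
    if (d[2] == 1) seg <- matrix(seg, nrow = 1)
    seg <- (seg - rowMeans(seg)) * rep(taper, each = d[2])
    X <- mvfft(t(seg))[fbin, , drop = FALSE] # bins x channels
    for (k in seq_along(fbin)) {
      C <- C + tcrossprod(X[k, ], Conj(X[k, ]))
    }
  }
  C <- C / (d[1] * length(fbin))
  C <- (C + Conj(t(C))) / 2 # enforce exact Hermitian symmetry
  dimnames(C) <- list(x$channels$channel, x$channels$channel)
  structure(
    list(
      C = C, band = lim, freqs = fax[fbin], window = window,
      n_trials = d[1], channels = x$channels$channel, condition = x$condition
    ),
    class = "eeg_csd"
  )
}

#' @export
print.eeg_csd <- function(x, ...) {
  cat(sprintf(
    "<eeg_csd> condition=%s: %d channels, band %g-%g Hz (%d bins), %d trials\n",
    x$condition, length(x$channels), x$band[1], x$band[2],
    length(x$freqs), x$n_trials
  ))
  invisible(x)
}

#' Pool two CSDs (trial-weighted average)
#'
#' Combines the condition-wise CSDs into the CSD of the pooled trials, for
#' constructing a common spatial filter.
#'
#' @param x,y `eeg_csd` objects on the same channels and band.
#' @return An `eeg_csd` with condition `"combined"`.
#' @export
csd_combine <- function(x, y) {
  if (!identical(x$channels, y$channels)) abort("channel sets differ.")
  x$C <- (x$C * x$n_trials + y$C * y$n_trials) / (x$n_trials + y$n_trials)
  x$n_trials <- x$n_trials + y$n_trials
  x$condition <- "combined"
  x
}

#' Common DICS spatial filters
#'
#' Computes, per inside voxel, the beamformer weights
#' `W = (L' Cinv L)^{-1} L' Cinv` from the real part of the (combined) CSD,
#' regularized as `C + lambda * mean(diag(C)) * I`. `rank` controls how many
#' leadfield orientations are retained (3 = all, the standard choice for
#' EEG; lower values truncate the leadfield by SVD). The filters satisfy the
#' unit-gain constraint `W L = I` on the retained orientation subspace.
#'
#' @param csd An `eeg_csd` (normally of the pooled conditions).
#' @param model A `source_model` supplying the leadfields.
#' @param lambda Regularization as a fraction of mean sensor power
#'   (default 0.05).
#' @param rank Retained leadfield orientations (default 3).
#' @return An object of class `dics_filters`: list with `weights` (list of
#'   orientations x channels matrices), `model`, `lambda`, `rank`.
#' @export
dics_common_filter <- function(csd, model, lambda = 0.05, rank = 3) {
  stopifnot(inherits(csd, "eeg_csd"), inherits(model, "source_model"))
  if (!identical(csd$channels, model$channels)) abort("CSD and model channel bases differ.")
  C <- Re(csd$C)
  Creg <- C + lambda * mean(diag(C)) * diag(nrow(C))
  Ci <- tryCatch(solve(Creg), error = function(e) {
    abort("sensor CSD is singular even after regularization.")
  })
  weights <- lapply(model$leadfield, function(L) {
    if (rank < ncol(L)) {
      sv <- svd(L)
      L <- sv$u[, seq_len(rank), drop = FALSE] %*% diag(sv$d[seq_len(rank)], rank)
    }
    M <- t(L) %*% Ci %*% L
    Mi <- tryCatch(solve(M), error = function(e) {
      # near-singular source covariance: fall back to a pseudoinverse
      sv <- svd(M)
      keep <- sv$d > max(sv$d) * 1e-10
      sv$v[, keep, drop = FALSE] %*% diag(1 / sv$d[keep], sum(keep)) %*% t(sv$u[, keep, drop = FALSE])
    })
    Mi %*% t(L) %*% Ci
  })
  structure(
    list(weights = weights, model = model, lambda = lambda, rank = rank),
    class = "dics_filters"
  )
}

#' Source power map from a spatial filter set and a condition CSD
#'
#' Projects the (real part of the) condition CSD through every voxel's filter
#' and reduces the orientations to a scalar as the dominant eigenvalue of the
#' projected source CSD (dominant-orientation beamformer output).
#'
#' @param filters A `dics_filters` object.
#' @param csd The condition's `eeg_csd` (same channel basis).
#' @return A `source_power_map` tibble: `voxel`, `x`, `y`, `z`, `label`,
#'   `power`, with the band/condition as attributes.
#' @export
source_power <- function(filters, csd) {
  stopifnot(inherits(filters, "dics_filters"), inherits(csd, "eeg_csd"))
  if (!identical(csd$channels, filters$model$channels)) abort("CSD and filter channel bases differ.")
  C <- Re(csd$C)
  pw <- vapply(filters$weights, function(W) {
    S <- W %*% C %*% t(W)
    max(eigen((S + t(S)) / 2, symmetric = TRUE, only.values = TRUE)$values)
  }, numeric(1))
  out <- dplyr::mutate(filters$model$voxels, power = pmax(pw, 0))
  attr(out, "band") <- csd$band
  attr(out, "condition") <- csd$condition
  class(out) <- c("source_power_map", class(out))
  out
}

#' Relative source-power contrast between two conditions
#'
#' Per voxel, `(P_a - P_b) / (P_a + P_b)`, bounded in `[-1, 1]`; voxels where
#' both powers are zero get `NA` (flagged undefined).
#'
#' @param p_a,p_b `source_power_map` tibbles on identical voxel sets (e.g.
#'   overlapping and non-overlapping condition).
#' @return A `source_contrast_map` tibble: `voxel`, `x`, `y`, `z`, `label`,
#'   `contrast`.
#' @export
relative_contrast <- function(p_a, p_b) {
  if (!identical(p_a$voxel, p_b$voxel)) abort("voxel sets differ.")
  denom <- p_a$power + p_b$power
  r <- ifelse(denom > 0, (p_a$power - p_b$power) / denom, NA_real_)
  out <- dplyr::mutate(p_a[, c("voxel", "x", "y", "z", "label")], contrast = r)
  attr(out, "spacing") <- attr(p_a, "spacing")
  class(out) <- c("source_contrast_map", class(out))
  out
}
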