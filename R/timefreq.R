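# Morlet wavelet time-frequency decomposition and band averaging.

#' Morlet wavelet time-frequency decomposition
#'
#' Convolves every trial and channel with L2-normalized complex Morlet
#' wavelets (default width 7 cycles at every frequency) and averages the
#' squared magnitude over trials, yielding total (non-phase-locked plus
#' phase-locked) power per channel, frequency and time point. Data are
#' zero-padded to the ceiling of the trial length in seconds before the FFT
#' convolution, which fixes the spectral sampling grid independently of the
#' exact trial length.
#'
#' @param x A single `eeg_epochs` object or a tibble with an `epochs`
#'   list-column (then a `tfr` list-column is returned).
#' @param freqs Frequencies of interest in Hz (default `3:30`).
#' @param width Wavelet width in cycles (default 7).
#' @return An object of class `eeg_tfr`: list with `power` (channels x
#'   frequencies x times array), `freqs`, `times`, `channels`, `sfreq`,
#'   `subject`, `group`, `condition`, `n_trials`.
#' @export
#' @examples
#' spec <- effect_spec(n_subjects = c(GTS = 1), n_trials = 4, sfreq = 128,
#'                     epoch_win = c(-1, 1), seed = 2)
#' sim <- simulate_epochs(spec, make_sensor_array(16))
#' tfr <- morlet_tfr(sim$epochs[[1]], freqs = 4:8)
morlet_tfr <- function(x, freqs = 3:30, width = 7) {
  if (is.data.frame(x) && "epochs" %in% names(x)) {
    x$tfr <- purrr::map(x$epochs, morlet_tfr, freqs = freqs, width = width)
    return(x)
  }
  stopifnot(inherits(x, "eeg_epochs"))
  d <- dim(x$data)
  fs <- x$sfreq
  n <- d[3]
  np <- as.integer(ceiling(n / fs) * fs) # zero-pad to whole seconds
  # the +/-2 sigma core of the lowest-frequency wavelet must fit the padded
  # length (tails beyond 3 sigma are truncated anyway)
  sigma_max <- width / (2 * pi * min(freqs))
  if (2 * floor(2 * sigma_max * fs) + 1 > np) {
    abort("epoch too short for the lowest-frequency wavelet.")
  }

  m <- matrix(aperm(x$data, c(3, 1, 2)), nrow = n) # samples x (trials*channels)
  mp <- rbind(m, matrix(0, np - n, ncol(m)))
  MF <- mvfft(mp)

  power <- array(0, dim = c(d[2], length(freqs), n))
  for (fi in seq_along(freqs)) {
    f <- freqs[fi]
    sigma_t <- width / (2 * pi * f)
    half <- min(floor(3 * sigma_t * fs), floor((np - 1) / 2))
    tt <- (-half:half) / fs
    w <- exp(2i * pi * f * tt) * exp(-tt^2 / (2 * sigma_t^2))
    w <- w / sqrt(sum(Mod(w)^2)) # unit energy
    wv <- complex(length.out = np)
    wv[((-half:half) %% np) + 1] <- w # centered at lag 0, wrapped
    conv <- mvfft(MF * as.vector(fft(wv)), inverse = TRUE) / np
    p <- Mod(conv[seq_len(n), , drop = FALSE])^2 # samples x (trials*channels)
    pa <- array(p, dim = c(n, d[1], d[2]))
    power[, fi, ] <- t(colMeans(aperm(pa, c(2, 1, 3)))) # mean over trials
  }

  structure(
    list(
      power = power, freqs = as.numeric(freqs), times = x$times,
      channels = x$channels, sfreq = fs, subject = x$subject,
      group = x$group, condition = x$condition, n_trials = d[1]
    ),
    class = "eeg_tfr"
  )
}

#' @export
print.eeg_tfr <- function(x, ...) {
  cat(sprintf(
    "<eeg_tfr> subject=%s condition=%s: %d channels x %d freqs (%g-%g Hz) x %d times\n",
    x$subject, x$condition, dim(x$power)[1], dim(x$power)[2],
    min(x$freqs), max(x$freqs), dim(x$power)[3]
  ))
  invisible(x)
}

#' Average a TFR over a frequency band and time window
#'
#' Arithmetic mean of power over the frequency bins inside the band and the
#' samples inside the window, per channel.
#'
#' @param tfr An `eeg_tfr` object.
#' @param band Band name (`"theta"`, `"alpha"`, `"beta"`) or `c(lo, hi)` Hz.
#' @param time_window Analysis window in seconds (default `c(0, 1)`,
#'   post-stimulus).
#' @return A tibble of class `band_power` with columns `subject`, `group`,
#'   `condition`, `channel`, `power`; the band and window are attributes.
#' @export
band_average <- function(tfr, band = "theta", time_window = c(0, 1)) {
  stopifnot(inherits(tfr, "eeg_tfr"))
  lim <- band_limits(band)
  check_window(time_window, "time_window")
  fsel <- tfr$freqs >= lim[1] & tfr$freqs <= lim[2]
  tsel <- tfr$times >= time_window[1] & tfr$times <= time_window[2]
  if (!any(fsel)) abort("no TFR frequencies inside the requested band.")
  if (!any(tsel)) abort("no TFR samples inside the requested time window.")
  vals <- apply(tfr$power[, fsel, tsel, drop = FALSE], 1, mean)
  out <- tibble(
    subject = tfr$subject, group = tfr$group, condition = tfr$condition,
    channel = tfr$channels$channel, power = vals
  )
  attr(out, "band") <- lim
  attr(out, "time_window") <- time_window
  class(out) <- c("band_power", class(out))
  out
}

#' Band power for a whole set of subjects and conditions
#'
#' Convenience wrapper: maps [morlet_tfr()] (restricted to the band's
#' frequencies) and [band_average()] over an epochs-set tibble and binds the
#' per-channel results into one long table.
#'
#' @param sim A tibble with `subject`, `group`, `condition` and an `epochs`
#'   list-column, as returned by [simulate_epochs()].
#' @param band Band name or `c(lo, hi)` Hz.
#' @param time_window Analysis window in seconds.
#' @param width Wavelet width in cycles.
#' @return A long tibble: `subject`, `group`, `condition`, `channel`, `power`.
#' @export
band_power_table <- function(sim, band = "theta", time_window = c(0, 1), width = 7) {
  lim <- band_limits(band)
  freqs <- seq(ceiling(lim[1]), floor(lim[2]))
  purrr::map_dfr(sim$epochs, function(ep) {
    band_average(morlet_tfr(ep, freqs = freqs, width = width), lim, time_window)
  })
}

#' Per-channel condition contrast of band power
#'
#' Elementwise difference overlap minus non-overlap (first argument minus
#' second), matched by channel.
#'
#' @param bp_overlap,bp_nonoverlap `band_power` tibbles from the same subject
#'   with identical channel sets.
#' @return A tibble `subject`, `group`, `channel`, `contrast`.
#' @export
condition_contrast <- function(bp_overlap, bp_nonoverlap) {
  if (!identical(bp_overlap$channel, bp_nonoverlap$channel)) {
    abort("channel sets differ between conditions.")
  }
  tibble(
    subject = bp_overlap$subject, group = bp_overlap$group,
    channel = bp_overlap$channel,
    contrast = bp_overlap$power - bp_nonoverlap$power
  )
}

#' Grand average of TFRs or band-power tables
#'
#' Unweighted mean across subjects. For `eeg_tfr` inputs the power arrays are
#' averaged; for `band_power` tibbles the per-channel values are averaged.
#'
#' @param x A list of `eeg_tfr` objects, or a long band-power tibble with a
#'   `channel` and `power` column.
#' @return Same type as the input, averaged, with subject set to
#'   `"grand_average"`.
#' @export
grand_average <- function(x) {
  if (is.list(x) && length(x) && inherits(x[[1]], "eeg_tfr")) {
    if (length(x) == 0) abort("empty group.")
    ref <- x[[1]]
    acc <- ref$power
    for (t in x[-1]) {
      if (!identical(dim(t$power), dim(acc))) abort("TFR dimensions differ.")
      acc <- acc + t$power
    }
    ref$power <- acc / length(x)
    ref$subject <- "grand_average"
    return(ref)
  }
  if (is.data.frame(x) && all(c("channel", "power") %in% names(x))) {
    if (nrow(x) == 0) abort("empty group.")
    return(dplyr::summarise(
      dplyr::group_by(x, dplyr::across(dplyr::any_of(c("group", "condition", "channel")))),
      power = mean(.data$power), .groups = "drop"
    ))
  }
  abort("`x` must be a list of eeg_tfr objects or a band-power table.")
}
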