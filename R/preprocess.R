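# Deterministic signal conditioning: resampling, zero-phase IIR filtering,
# average reference, artifact rejection, spherical-spline interpolation,
# baseline correction. All functions accept a single `eeg_epochs` object or a
# tibble with an `epochs` list-column and preserve whichever they were given.

#' Preprocessing configuration
#'
#' Default parameters of the preprocessing chain: resampling to 256 Hz, an
#' 8th-order (effective, zero-phase) Butterworth band-pass of 0.5-40 Hz, a
#' 48-52 Hz band-stop notch, a +/-200 microvolt amplitude rejection
#' criterion, a flatline criterion of peak-to-peak < 0.5 microvolts over more
#' than 100 ms, and a -200..0 ms baseline window.
#'
#' @param target_rate_hz Resampling target in Hz.
#' @param bandpass_hz Band-pass edges in Hz.
#' @param filter_order Effective band-pass order after forward-backward
#'   application.
#' @param notch_hz Band-stop edges in Hz.
#' @param amp_crit_uv Absolute amplitude criterion in microvolts.
#' @param flat_crit_uv,flat_dur_s Flatline peak-to-peak criterion and minimum
#'   duration.
#' @param baseline_win Baseline window in seconds.
#' @return A list of class `preproc_config`.
#' @export
preproc_config <- function(target_rate_hz = 256, bandpass_hz = c(0.5, 40),
                           filter_order = 8, notch_hz = c(48, 52),
                           amp_crit_uv = 200, flat_crit_uv = 0.5,
                           flat_dur_s = 0.1, baseline_win = c(-0.2, 0)) {
  check_window(bandpass_hz, "bandpass_hz")
  check_window(notch_hz, "notch_hz")
  check_window(baseline_win, "baseline_win")
  if (amp_crit_uv <= 0 || flat_crit_uv <= 0 || flat_dur_s <= 0) {
    abort("rejection criteria must be positive.")
  }
  structure(
    list(
      target_rate_hz = target_rate_hz, bandpass_hz = bandpass_hz,
      filter_order = filter_order, notch_hz = notch_hz,
      amp_crit_uv = amp_crit_uv, flat_crit_uv = flat_crit_uv,
      flat_dur_s = flat_dur_s, baseline_win = baseline_win
    ),
    class = "preproc_config"
  )
}

#' Resample epochs to a lower rate
#'
#' Fourier-domain resampling by the rational factor `target_rate / sfreq`:
#' the spectrum is cropped at the new Nyquist frequency and inverse
#' transformed, which is band-limited-exact (flat passband, no FIR ripple).
#' The new sample count is `ceiling(n * target / original)`. Only
#' downsampling (or the identity) is allowed.
#'
#' @param x An `eeg_epochs` object or a tibble with an `epochs` list-column.
#' @param target_rate Target sampling rate in Hz.
#' @return Same shape as `x`, resampled.
#' @export
resample_epochs <- function(x, target_rate = 256) {
  fmap_epochs(x, function(ep) {
    if (target_rate > ep$sfreq) abort("upsampling is not supported; target rate exceeds the data rate.")
    if (target_rate == ep$sfreq) return(ep)
    g <- gcd_int(round(target_rate), round(ep$sfreq))
    p <- round(target_rate) / g
    q <- round(ep$sfreq) / g
    n <- dim(ep$data)[3]
    n_new <- ceiling(n * p / q)
    # pad (edge value) to a multiple of q so the resampled length is integer
    n_pad <- ceiling(n / q) * q
    m_out <- n_pad * p / q
    out <- reshape_apply(ep, function(m) {
      if (n_pad > n) m <- rbind(m, m[rep(n, n_pad - n), , drop = FALSE])
      X <- mvfft(m)
      keep <- floor(m_out / 2)
      Y <- matrix(0 + 0i, m_out, ncol(m))
      Y[1, ] <- X[1, ]
      Y[1 + seq_len(keep - 1), ] <- X[1 + seq_len(keep - 1), , drop = FALSE]
      Y[m_out + 1 - seq_len(keep - 1), ] <- X[n_pad + 1 - seq_len(keep - 1), , drop = FALSE]
      if (m_out %% 2 == 0) Y[keep + 1, ] <- Re(X[keep + 1, ]) # fold Nyquist bin
      y <- Re(mvfft(Y, inverse = TRUE)) / n_pad
      y[seq_len(n_new), , drop = FALSE]
    },
    new_times = ep$times[1] + (seq_len(n_new) - 1) / target_rate,
    new_sfreq = target_rate
    )
    out
  })
}

gcd_int <- function(a, b) if (b == 0) a else gcd_int(b, a %% b)

#' Band-pass and notch filter epochs
#'
#' Applies a Butterworth band-pass (default 0.5-40 Hz, effective order 8
#' after zero-phase forward-backward filtering) followed by a band-stop notch
#' around the 50 Hz line frequency (default 48-52 Hz), per trial and channel.
#'
#' @param x An `eeg_epochs` object or a tibble with an `epochs` list-column.
#' @param cfg A [preproc_config()].
#' @return Same shape as `x`, filtered.
#' @export
filter_band_notch <- function(x, cfg = preproc_config()) {
  fmap_epochs(x, function(ep) {
    nyq <- ep$sfreq / 2
    if (nyq <= cfg$bandpass_hz[2]) abort("sampling rate too low for the requested band-pass.")
    # forward-backward doubles the order, so design at half the target order
    bp <- signal::butter(cfg$filter_order / 4, cfg$bandpass_hz / nyq, type = "pass")
    notch <- if (cfg$notch_hz[2] < nyq) {
      signal::butter(2, cfg$notch_hz / nyq, type = "stop")
    } else {
      NULL
    }
    reshape_apply(ep, function(m) {
      n <- nrow(m)
      out <- apply(m, 2, function(col) {
        col <- col - mean(col)
        # mirror-pad to suppress filtfilt edge transients near the 0.5 Hz edge
        padded <- c(rev(col), col, rev(col))
        y <- signal::filtfilt(bp, padded)
        if (!is.null(notch)) y <- signal::filtfilt(notch, y)
        y[n + seq_len(n)]
      })
      matrix(out, nrow = n)
    })
  })
}

#' Re-reference epochs to the average reference
#'
#' Subtracts the instantaneous mean over channels from every channel, so the
#' channel mean is zero at every sample. Idempotent.
#'
#' @param x An `eeg_epochs` object or a tibble with an `epochs` list-column.
#' @return Same shape as `x`, average-referenced.
#' @export
rereference_average <- function(x) {
  fmap_epochs(x, function(ep) {
    if (dim(ep$data)[2] < 2) abort("average reference needs at least 2 channels.")
    for (tr in seq_len(dim(ep$data)[1])) {
      sl <- ep$data[tr, , ]
      ep$data[tr, , ] <- sweep(sl, 2, colMeans(sl))
    }
    ep
  })
}

#' Automatic artifact rejection
#'
#' Drops every epoch in which any channel exceeds the absolute amplitude
#' criterion (default +/-200 microvolts) or is flat - peak-to-peak below 0.5
#' microvolts over a sliding window longer than 100 ms. A channel-level
#' violation rejects the whole epoch. Manual inspection and ICA-based
#' artifact removal are outside the scope of this chain; the log notes this.
#'
#' @param x A single `eeg_epochs` object.
#' @param cfg A [preproc_config()].
#' @return A list with `epochs` (the kept trials; possibly zero trials, with
#'   a warning) and `log`, a tibble with one row per input trial: `trial`,
#'   `kept`, `reason` (`"amplitude"`, `"flatline"` or NA), `channel`.
#' @export
reject_artifacts <- function(x, cfg = preproc_config()) {
  stopifnot(inherits(x, "eeg_epochs"))
  d <- dim(x$data)
  w <- floor(cfg$flat_dur_s * x$sfreq) + 2 # window spanning > flat_dur_s
  reason <- rep(NA_character_, d[1])
  channel <- rep(NA_character_, d[1])
  for (tr in seq_len(d[1])) {
    sl <- x$data[tr, , , drop = TRUE]
    if (d[2] == 1) sl <- matrix(sl, nrow = 1)
    amp_bad <- which(apply(abs(sl), 1, max) > cfg$amp_crit_uv)
    if (length(amp_bad)) {
      reason[tr] <- "amplitude"
      channel[tr] <- x$channels$channel[amp_bad[1]]
      next
    }
    if (w <= d[3]) {
      for (ch in seq_len(d[2])) {
        v <- sl[ch, ]
        ptp <- zoo::rollmax(v, w) + zoo::rollmax(-v, w)
        if (any(ptp < cfg$flat_crit_uv)) {
          reason[tr] <- "flatline"
          channel[tr] <- x$channels$channel[ch]
          break
        }
      }
    }
  }
  keep <- is.na(reason)
  if (!any(keep)) warn("all epochs were rejected.")
  log <- tibble(
    trial = seq_len(d[1]), kept = keep, reason = reason, channel = channel
  )
  attr(log, "note") <- "automatic criteria only; no manual inspection or ICA stage"
  x$data <- x$data[keep, , , drop = FALSE]
  list(epochs = x, log = log)
}

# spherical-spline interpolation matrices (Perrin-style, stiffness m, up to
# `terms` Legendre terms)
spline_g <- function(cosang, stiffness = 4, terms = 20) {
  n <- seq_len(terms)
  coef <- (2 * n + 1) / (n^stiffness * (n + 1)^stiffness)
  out <- array(0, dim = dim(as.matrix(cosang)))
  x <- as.matrix(cosang)
  p_prev <- matrix(1, nrow(x), ncol(x)) # P_0
  p_cur <- x # P_1
  for (k in n) {
    out <- out + coef[k] * p_cur
    p_next <- ((2 * k + 1) * x * p_cur - k * p_prev) / (k + 1)
    p_prev <- p_cur
    p_cur <- p_next
  }
  out / (4 * pi)
}

#' Topographic (spherical-spline) channel interpolation
#'
#' Replaces the listed bad channels with a spherical-spline estimate from the
#' remaining channels on the unit head sphere; good channels are untouched.
#'
#' @param x An `eeg_epochs` object or a tibble with an `epochs` list-column.
#' @param bad_channels Character vector of channel labels (strict subset).
#' @param stiffness Spline stiffness exponent (default 4).
#' @return Same shape as `x`, with bad channels replaced.
#' @export
interpolate_channels <- function(x, bad_channels, stiffness = 4) {
  if (length(bad_channels) == 0) return(x)
  fmap_epochs(x, function(ep) {
    labels <- ep$channels$channel
    bad <- match(bad_channels, labels)
    if (anyNA(bad)) abort("unknown channel in `bad_channels`.")
    if (length(bad) >= length(labels)) abort("cannot interpolate: no good channels left.")
    good <- setdiff(seq_along(labels), bad)
    pos <- as.matrix(ep$channels[, c("x", "y", "z")])
    pos <- pos / sqrt(rowSums(pos^2))
    cos_gg <- pmin(pmax(tcrossprod(pos[good, , drop = FALSE]), -1), 1)
    cos_bg <- pmin(pmax(pos[bad, , drop = FALSE] %*% t(pos[good, , drop = FALSE]), -1), 1)
    G <- spline_g(cos_gg, stiffness)
    Gb <- spline_g(cos_bg, stiffness)
    ng <- length(good)
    A <- rbind(cbind(G + diag(1e-8, ng), 1), c(rep(1, ng), 0))
    for (tr in seq_len(dim(ep$data)[1])) {
      V <- ep$data[tr, good, , drop = TRUE]
      if (ng == 1) V <- matrix(V, nrow = 1)
      sol <- solve(A, rbind(V, 0)) # weights (ng x t) and constant (1 x t)
      est <- Gb %*% sol[seq_len(ng), , drop = FALSE] +
        matrix(sol[ng + 1, ], length(bad), dim(ep$data)[3], byrow = TRUE)
      ep$data[tr, bad, ] <- est
    }
    ep
  })
}

#' Baseline-correct epochs
#'
#' Subtracts, per trial and channel, the mean over the baseline window
#' (default -200..0 ms). Idempotent.
#'
#' @param x An `eeg_epochs` object or a tibble with an `epochs` list-column.
#' @param window Baseline window in seconds.
#' @return Same shape as `x`, baseline-corrected.
#' @export
baseline_correct <- function(x, window = c(-0.2, 0)) {
  check_window(window)
  fmap_epochs(x, function(ep) {
    sel <- ep$times >= window[1] & ep$times <= window[2]
    if (!any(sel)) abort("baseline window lies outside the epoch.")
    for (tr in seq_len(dim(ep$data)[1])) {
      sl <- ep$data[tr, , , drop = TRUE]
      if (dim(ep$data)[2] == 1) sl <- matrix(sl, nrow = 1)
      ep$data[tr, , ] <- sl - rowMeans(sl[, sel, drop = FALSE])
    }
    ep
  })
}
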