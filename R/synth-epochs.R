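# Sensor-level EEG generator: 1/f background plus band-limited oscillatory
# bursts whose amplitude depends on group and overlap condition.

#' Specify the oscillatory effect structure of simulated EEG
#'
#' Collects everything the epoch generator needs: subject and trial counts,
#' sampling rate, epoch window, 1/f background parameters, and a list of
#' band-limited burst effects. Each effect plants a Gaussian-windowed
#' sinusoid (non-phase-locked: uniform random phase per trial) on a set of
#' channels, with an amplitude that may differ by group and condition.
#'
#' @param n_subjects Named integer vector of subjects per group,
#'   e.g. `c(GTS = 30, NT = 30)`.
#' @param n_trials Trials per subject and condition (default 84, the number
#'   of Nogo trials per overlap condition in the task).
#' @param sfreq Sampling rate in Hz (default 256).
#' @param epoch_win Epoch window in seconds around the stimulus (default
#'   `c(-2, 2)`); must be symmetric around 0.
#' @param noise_exponent Spectral exponent of the 1/f background (default 1).
#' @param noise_scale_uv Per-channel background RMS in microvolts (default 10).
#' @param amp_subject_sd SD of a per-subject log-normal amplitude multiplier
#'   (between-subject effect variability; default 0.2).
#' @param effects List of effects, each a list with elements `name`, `freq`
#'   (Hz, within 3-30), `channels` (label vector, or `"all"`), `center_s`,
#'   `sd_s` (Gaussian burst envelope, seconds), and `amp`: a groups x
#'   conditions matrix of burst amplitudes in microvolts (dimnames required).
#' @param conditions Condition labels (default overlapping / non-overlapping).
#' @param seed Integer seed.
#' @return A list of class `effect_spec`.
#' @export
effect_spec <- function(n_subjects = c(GTS = 30, NT = 30), n_trials = 84,
                        sfreq = 256, epoch_win = c(-2, 2),
                        noise_exponent = 1, noise_scale_uv = 10,
                        amp_subject_sd = 0.2,
                        effects = default_effects(names(n_subjects)),
                        conditions = c("overlapping", "non-overlapping"),
                        seed = 1) {
  check_window(epoch_win, "epoch_win")
  if (abs(epoch_win[1] + epoch_win[2]) > 1e-9) abort("`epoch_win` must be symmetric around 0.")
  if (is.null(names(n_subjects)) || any(names(n_subjects) == "")) {
    abort("`n_subjects` must be a named vector (one entry per group).")
  }
  for (ef in effects) {
    if (ef$freq < 3 || ef$freq > 30) abort("effect frequencies must lie within 3-30 Hz.")
    amp <- ef$amp
    if (!is.matrix(amp) || is.null(rownames(amp)) || is.null(colnames(amp))) {
      abort("effect `amp` must be a groups x conditions matrix with dimnames.")
    }
    if (any(amp < 0)) abort("effect amplitudes must be non-negative.")
    if (!all(names(n_subjects) %in% rownames(amp))) abort("`amp` rows must cover all groups.")
    if (!all(conditions %in% colnames(amp))) abort("`amp` columns must cover all conditions.")
  }
  structure(
    list(
      n_subjects = n_subjects, n_trials = n_trials, sfreq = sfreq,
      epoch_win = epoch_win, noise_exponent = noise_exponent,
      noise_scale_uv = noise_scale_uv, amp_subject_sd = amp_subject_sd,
      effects = effects, conditions = conditions, seed = seed
    ),
    class = "effect_spec"
  )
}

#' Default oscillatory effects of the simulated study
#'
#' Midfrontal theta is stronger in the overlapping than the non-overlapping
#' condition (more so in the GTS group); alpha and beta power over a broad
#' channel set are weaker in the overlapping condition.
#'
#' @param groups Group labels (default `c("GTS", "NT")`).
#' @return A list of effect descriptions for [effect_spec()].
#' @export
default_effects <- function(groups = c("GTS", "NT")) {
  amp <- function(over, non) {
    m <- cbind(rep_len(over, length(groups)), rep_len(non, length(groups)))
    dimnames(m) <- list(groups, c("overlapping", "non-overlapping"))
    m
  }
  list(
    list(
      name = "theta", freq = 5.5, channels = c("Cz", "FCz", "FC1", "FC2"),
      center_s = 0.45, sd_s = 0.15, amp = amp(over = c(7, 5.5), non = c(2.5, 2.5))
    ),
    list(
      name = "alpha", freq = 10, channels = "all",
      center_s = 0.55, sd_s = 0.2, amp = amp(over = c(2, 2), non = c(5, 5))
    ),
    list(
      name = "beta", freq = 22, channels = "all",
      center_s = 0.5, sd_s = 0.18, amp = amp(over = c(1.5, 1.5), non = c(3.5, 3.5))
    )
  )
}

# vectorized 1/f^exponent noise: columns are independent signals, each scaled
# to the requested RMS
one_over_f_noise <- function(n_samples, n_signals, sfreq, exponent = 1, scale = 10) {
  w <- matrix(rnorm(n_samples * n_signals), n_samples, n_signals)
  if (exponent == 0) {
    return(w * scale / rep(sqrt(colMeans(w^2)), each = n_samples))
  }
  f <- c(0, seq_len(n_samples - 1)) * sfreq / n_samples
  f[f > sfreq / 2] <- sfreq - f[f > sfreq / 2] # mirror to physical frequency
  h <- c(0, 1 / f[-1]^(exponent / 2))
  x <- Re(mvfft(mvfft(w) * h, inverse = TRUE)) / n_samples
  x * scale / rep(sqrt(colMeans(x^2)), each = n_samples)
}

#' Simulate multichannel EEG epochs for all subjects and conditions
#'
#' Generates, per subject and condition, `n_trials` epochs of 1/f background
#' noise (independent across channels) with the burst effects of the spec
#' added on their seeded channels. Burst phase is uniform per trial, so the
#' planted power is non-phase-locked (it survives trial-averaged total-power
#' analysis but not evoked averaging). The result is bit-reproducible from
#' the spec's seed.
#'
#' @param spec An [effect_spec()].
#' @param array A [make_sensor_array()] tibble.
#' @return A tibble with columns `subject`, `group`, `condition` and an
#'   `epochs` list-column of [eeg_epochs()] objects.
#' @export
#' @examples
#' spec <- effect_spec(n_subjects = c(GTS = 2, NT = 2), n_trials = 8, seed = 3)
#' sim <- simulate_epochs(spec, make_sensor_array(32))
#' sim$epochs[[1]]
simulate_epochs <- function(spec, array = make_sensor_array()) {
  stopifnot(inherits(spec, "effect_spec"))
  fs <- spec$sfreq
  times <- seq(spec$epoch_win[1], spec$epoch_win[2], by = 1 / fs)
  ns <- length(times)
  nch <- nrow(array)
  labels <- array$channel

  with_seed_if(spec$seed, {
    rows <- list()
    for (g in names(spec$n_subjects)) {
      for (i in seq_len(spec$n_subjects[[g]])) {
        subj <- sprintf("%s%02d", tolower(g), i)
        # per-subject effect-strength multiplier (shared across conditions)
        mult <- if (spec$amp_subject_sd > 0) {
          stats::rlnorm(length(spec$effects), -spec$amp_subject_sd^2 / 2, spec$amp_subject_sd)
        } else {
          rep(1, length(spec$effects))
        }
        for (cond in spec$conditions) {
          noise <- one_over_f_noise(
            ns, spec$n_trials * nch, fs,
            spec$noise_exponent, spec$noise_scale_uv
          )
          arr <- aperm(array(noise, dim = c(ns, spec$n_trials, nch)), c(2, 3, 1))
          for (k in seq_along(spec$effects)) {
            ef <- spec$effects[[k]]
            a <- ef$amp[g, cond] * mult[k]
            if (a == 0) next
            chans <- if (identical(ef$channels, "all")) labels else ef$channels
            idx <- match(chans, labels)
            if (anyNA(idx)) abort("effect channels missing from the sensor array.")
            env <- exp(-(times - ef$center_s)^2 / (2 * ef$sd_s^2))
            phase <- runif(spec$n_trials, 0, 2 * pi)
            # trials x samples burst matrix, same waveform on every seeded channel
            burst <- a * outer(phase, times, function(p, t) cos(2 * pi * ef$freq * t + p)) *
              rep(env, each = spec$n_trials)
            for (ci in idx) arr[, ci, ] <- arr[, ci, ] + burst
          }
          rows[[length(rows) + 1L]] <- tibble(
            subject = subj, group = g, condition = cond,
            epochs = list(eeg_epochs(arr, fs, times, array,
              subject = subj, group = g, condition = cond
            ))
          )
        }
      }
    }
    dplyr::bind_rows(rows)
  })
}

#' Simulate null EEG epochs (no condition or group effects)
#'
#' Returns epochs from the same generator with every burst amplitude set to
#' zero, so condition labels are statistically exchangeable. Used for
#' type-I-error calibration of the downstream statistics.
#'
#' @inheritParams simulate_epochs
#' @return As [simulate_epochs()].
#' @export
simulate_null_epochs <- function(spec, array = make_sensor_array()) {
  spec$effects <- lapply(spec$effects, function(ef) {
    ef$amp[] <- 0
    ef
  })
  simulate_epochs(spec, array)
}
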