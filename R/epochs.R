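# The epoched-EEG container used throughout the pipeline.

#' Create an epoched EEG object
#'
#' Bundles a trials x channels x samples voltage array (in microvolts) with
#' its time axis, sampling rate, channel geometry and condition metadata.
#'
#' @param data Numeric array `trials x channels x samples` (microvolts).
#' @param sfreq Sampling rate in Hz.
#' @param times Time axis in seconds (length = n samples), stimulus at 0.
#' @param channels A [make_sensor_array()] tibble (or any tibble with
#'   `channel`, `x`, `y`, `z`) matching the second array dimension.
#' @param subject,group,condition Metadata scalars.
#' @return An object of class `eeg_epochs`.
#' @export
eeg_epochs <- function(data, sfreq, times, channels,
                       subject = NA_character_, group = NA_character_,
                       condition = NA_character_) {
  if (length(dim(data)) != 3L) abort("`data` must be a 3-d array (trials x channels x samples).")
  if (dim(data)[2] != nrow(channels)) abort("channel dimension does not match `channels`.")
  if (dim(data)[3] != length(times)) abort("sample dimension does not match `times`.")
  structure(
    list(
      data = data, sfreq = sfreq, times = as.numeric(times),
      channels = channels, subject = subject, group = group,
      condition = condition
    ),
    class = "eeg_epochs"
  )
}

#' @export
print.eeg_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<eeg_epochs> subject=%s group=%s condition=%s\n  %d trials x %d channels x %d samples @ %g Hz, t = [%.3f, %.3f] s\n",
    x$subject, x$group, x$condition, d[1], d[2], d[3], x$sfreq,
    min(x$times), max(x$times)
  ))
  invisible(x)
}

#' Number of trials in an epochs object
#' @param x An `eeg_epochs` object.
#' @return Integer trial count.
#' @export
n_trials <- function(x) dim(x$data)[1]

# apply f to the samples x (trials*channels) matrix view and rebuild;
# f may change the number of samples (new_times then required)
reshape_apply <- function(x, f, new_times = NULL, new_sfreq = NULL) {
  d <- dim(x$data)
  m <- matrix(aperm(x$data, c(3, 1, 2)), nrow = d[3])
  out <- f(m)
  ns <- nrow(out)
  arr <- aperm(array(out, dim = c(ns, d[1], d[2])), c(2, 3, 1))
  x$data <- arr
  if (!is.null(new_times)) x$times <- new_times
  if (!is.null(new_sfreq)) x$sfreq <- new_sfreq
  x
}

# map a function over the `epochs` list-column of an epochs-set tibble,
# or apply it directly to a bare eeg_epochs object
fmap_epochs <- function(x, f) {
  if (inherits(x, "eeg_epochs")) return(f(x))
  if (is.data.frame(x) && "epochs" %in% names(x)) {
    x$epochs <- purrr::map(x$epochs, f)
    return(x)
  }
  abort("expected an `eeg_epochs` object or a tibble with an `epochs` list-column.")
}

#' Concatenate the trials of two epochs objects
#'
#' Used to pool both Nogo conditions before estimating the combined
#' cross-spectral density for a common DICS filter.
#'
#' @param x,y `eeg_epochs` sharing channels, sampling rate and time axis.
#' @return An `eeg_epochs` object with condition `"combined"`.
#' @export
append_epochs <- function(x, y) {
  if (!identical(x$channels$channel, y$channels$channel)) abort("channel sets differ.")
  if (!isTRUE(all.equal(x$times, y$times)) || x$sfreq != y$sfreq) abort("time axes differ.")
  d <- dim(x$data)
  arr <- array(NA_real_, dim = c(d[1] + dim(y$data)[1], d[2], d[3]))
  arr[seq_len(d[1]), , ] <- x$data
  arr[d[1] + seq_len(dim(y$data)[1]), , ] <- y$data
  eeg_epochs(arr, x$sfreq, x$times, x$channels,
    subject = x$subject, group = x$group, condition = "combined"
  )
}
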