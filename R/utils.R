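#' @importFrom rlang %||% abort warn
#' @importFrom stats qt pt pf qf pnorm sd var fft mvfft rnorm runif rbeta
#' @importFrom tibble tibble as_tibble
#' @keywords internal
"_PACKAGE"

# run expr under a local RNG state when seed is given
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  withr::with_seed(as.integer(seed), expr)
}

stopifnot_scalar_num <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a finite numeric scalar.", name))
  }
  if (positive && x <= 0) abort(sprintf("`%s` must be positive.", name))
  invisible(x)
}

check_window <- function(window, name = "window") {
  if (!is.numeric(window) || length(window) != 2L || window[1] >= window[2]) {
    abort(sprintf("`%s` must be c(start, end) with start < end.", name))
  }
  invisible(window)
}

#' Canonical frequency-band limits
#'
#' Returns the band limits used throughout the package: theta 4-7 Hz,
#' alpha 8-12 Hz, beta 15-30 Hz.
#'
#' @param band Band name (`"theta"`, `"alpha"`, `"beta"`) or a numeric
#'   `c(lo, hi)` pair, which is returned unchanged.
#' @return Numeric vector `c(lo, hi)` in Hz.
#' @export
#' @examples
#' band_limits("theta")
band_limits <- function(band) {
  if (is.numeric(band)) {
    if (length(band) != 2L || band[1] > band[2]) {
      abort("numeric `band` must be c(lo, hi) with lo <= hi.")
    }
    return(band)
  }
  switch(match.arg(band, c("theta", "alpha", "beta")),
    theta = c(4, 7),
    alpha = c(8, 12),
    beta = c(15, 30)
  )
}
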