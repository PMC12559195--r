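# shared helpers: angles, seeds, smoothing kernels, input checks

#' Wrap angles into (-180, 180]
#'
#' @param x angles in degrees.
#' @return Angles wrapped to the interval (-180, 180].
#' @examples
#' wrap_angle(c(350, -190, 180, 540))
#' @export
wrap_angle <- function(x) {
  w <- x - 360 * floor(x / 360)   # [0, 360)
  ifelse(w > 180, w - 360, w)
}

# derive a reproducible 32-bit sub-seed from a root seed and a stream id
sub_seed <- function(seed, stream) {
  (as.double(seed) * 48271 + 7919 * stream) %% 2147483647
}

# central difference with one-sided ends; rate converts to per-second units
central_diff <- function(x, rate_hz) {
  n <- length(x)
  if (n < 2) return(rep(0, n))
  d <- numeric(n)
  d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / 2
  d[1] <- x[2] - x[1]
  d[n] <- x[n] - x[n - 1]
  d * rate_hz
}

check_positive <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x <= 0) {
    abort(paste0("`", what, "` must be a single positive number."),
          class = "courtsig_config_error")
  }
  invisible(x)
}

check_range <- function(x, what) {
  if (!is.numeric(x) || length(x) != 2 || any(!is.finite(x)) || x[1] >= x[2]) {
    abort(paste0("`", what, "` must be a length-2 numeric (low, high) with low < high."),
          class = "courtsig_config_error")
  }
  invisible(x)
}

#' Gaussian smoothing with reflective boundaries
#'
#' Convolves a uniformly sampled series with a unit-mass Gaussian kernel.
#' The series is padded by reflection at both ends, so a constant series
#' is returned unchanged and no mass is lost at the boundaries. This is the
#' smoother used for signal-probability traces (sigma 0.1 s) and velocity
#' traces (sigma 1 s).
#'
#' @param x numeric series, uniformly sampled.
#' @param sigma_s kernel standard deviation in seconds.
#' @param rate_hz sampling rate of `x` in Hz.
#' @return Smoothed numeric series, same length as `x`.
#' @examples
#' smooth_series(rnorm(500), sigma_s = 0.1, rate_hz = 50)
#' @export
smooth_series <- function(x, sigma_s, rate_hz) {
  check_positive(sigma_s, "sigma_s")
  check_positive(rate_hz, "rate_hz")
  n <- length(x)
  if (n == 0) return(x)
  sigma <- sigma_s * rate_hz
  r <- max(1L, ceiling(4 * sigma))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  r <- min(r, n - 1L)
  k_full <- stats::dnorm(seq(-r, r), sd = sigma)
  k_full <- k_full / sum(k_full)
  if (r == 0) return(x)
  padded <- c(x[(r + 1):2], x, x[(n - 1):(n - r)])
  out <- stats::filter(padded, k_full, sides = 2)
  as.numeric(out[(r + 1):(r + n)])
}

# map seg_type/event_type names to the canonical signal labels
canonical_signal <- function(x) {
  dplyr::case_match(
    x,
    c("pulse_train", "pulse_song", "pulse") ~ "pulse",
    c("vibration_train", "vibration") ~ "vibration",
    "sine" ~ "sine",
    "none" ~ "none",
    .default = NA_character_
  )
}

signal_levels <- function() c("none", "vibration", "pulse", "sine")
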