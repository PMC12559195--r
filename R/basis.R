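#' Raised-cosine temporal basis with logarithmic spacing
#'
#' Builds `n_basis` raised-cosine bumps on a log-warped lag axis covering
#' `(0, window_s]`. Each bump is `(cos(u) + 1)/2` for `u` in `[-pi, pi]` and
#' zero outside, where `u` is the distance to the bump centre measured in
#' warped time `x = log(lag + log_offset_s)`. Centres are equally spaced in
#' warped time, so peak lags are log-spaced: the basis has fine resolution
#' at short lags and coarse resolution near the window end, compressing a
#' 1 s cue history into few coefficients.
#'
#' @param n_basis number of basis functions (default 4).
#' @param window_s lag window length in seconds (default 1).
#' @param rate_hz sampling rate of the lag grid in Hz.
#' @param first_peak_s lag of the first peak in seconds.
#' @param last_peak_s lag of the last peak; defaults to one sample short of
#'   the window end so all peaks are strictly inside the window.
#' @param log_offset_s warp offset `c` in `x = log(lag + c)`; smaller values
#'   stretch short lags more.
#' @return An object of class `cosine_basis`: list with `B` (`lag x basis`
#'   matrix, columns normalized to unit peak), `lags_s`, `peaks_s`, and the
#'   construction parameters.
#' @examples
#' b <- cosine_basis()
#' dim(b$B)
#' b$peaks_s
#' @export
cosine_basis <- function(n_basis = 4, window_s = 1, rate_hz = 50,
                         first_peak_s = 0.04, last_peak_s = NULL,
                         log_offset_s = 0.02) {
  if (n_basis < 1) abort("`n_basis` must be >= 1.", class = "courtsig_config_error")
  check_positive(window_s, "window_s")
  check_positive(rate_hz, "rate_hz")
  L <- round(window_s * rate_hz)
  if (L < 2) {
    abort("window shorter than 2 lag samples at this rate.",
          class = "courtsig_config_error")
  }
  lags <- seq_len(L) / rate_hz
  if (is.null(last_peak_s)) last_peak_s <- window_s - 1 / rate_hz
  warp <- function(t) log(t + log_offset_s)
  if (n_basis == 1) {
    ctrs <- warp((first_peak_s + last_peak_s) / 2)
    dphi <- (warp(last_peak_s) - warp(first_peak_s) + 1) / 2
  } else {
    ctrs <- seq(warp(first_peak_s), warp(last_peak_s), length.out = n_basis)
    dphi <- diff(ctrs)[1]
  }
  x <- warp(lags)
  B <- vapply(ctrs, function(ci) {
    u <- (x - ci) * pi / (2 * dphi)
    u <- pmin(pi, pmax(-pi, u))
    (cos(u) + 1) / 2
  }, numeric(L))
  B <- sweep(B, 2, apply(B, 2, max), "/")
  peaks <- lags[apply(B, 2, which.max)]
  structure(
    list(B = B, lags_s = lags, peaks_s = peaks, n_basis = n_basis,
         window_s = window_s, rate_hz = rate_hz, n_lags = L,
         first_peak_s = first_peak_s, last_peak_s = last_peak_s,
         log_offset_s = log_offset_s),
    class = "cosine_basis"
  )
}

#' Project a lag-domain filter onto the basis
#'
#' Least-squares projection: returns coefficients `w` minimizing
#' `||f - B w||`. For filters in the span of `B`, back-projection
#' `B %*% w` reproduces `f` to machine precision.
#'
#' @param basis a [cosine_basis()].
#' @param f numeric filter on the basis lag grid.
#' @return Numeric coefficient vector of length `n_basis`.
#' @export
project_filter <- function(basis, f) {
  stopifnot(length(f) == basis$n_lags)
  qr.solve(basis$B, f)
}

#' @method autoplot cosine_basis
#' @export
autoplot.cosine_basis <- function(object, ...) {
  df <- tibble(
    lag_s = rep(object$lags_s, object$n_basis),
    basis = factor(rep(seq_len(object$n_basis), each = object$n_lags)),
    value = as.numeric(object$B)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$lag_s, .data$value, colour = .data$basis)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "lag (s)", y = "basis value",
                  title = "Raised-cosine basis (log-spaced peaks)")
}
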