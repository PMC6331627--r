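#' STFT specification
#'
#' @param window_len Window length N in samples (default 1024).
#' @param hop Frame advance in samples (default 512).
#' @param window `"blackmanharris"` (default; 4-term minimum-sidelobe taper)
#'   or `"rectangular"` (debug/analysis mode).
#' @export
stft_spec <- function(window_len = 1024L, hop = 512L,
                      window = c("blackmanharris", "rectangular")) {
  window <- match.arg(window)
  stopifnot(window_len > 0, hop > 0, hop <= window_len)
  structure(list(window_len = as.integer(window_len), hop = as.integer(hop),
                 window = window), class = "stft_spec")
}

#' 4-term Blackman-Harris window
#'
#' Symmetric minimum-sidelobe taper with fixed coefficients
#' (0.35875, 0.48829, 0.14128, 0.01168).
#'
#' @param n Window length.
#' @export
blackman_harris <- function(n) {
  if (n == 1L) return(1)
  a <- c(0.35875, 0.48829, 0.14128, 0.01168)
  m <- seq(0, n - 1) / (n - 1)
  a[1] - a[2] * cos(2 * pi * m) + a[3] * cos(4 * pi * m) -
    a[4] * cos(6 * pi * m)
}

window_values <- function(spec) {
  switch(spec$window,
         blackmanharris = blackman_harris(spec$window_len),
         rectangular = rep(1, spec$window_len))
}

#' Short-time Fourier transform
#'
#' Column k of the result holds the N-point DFT (convention
#' `X(k) = sum_m x(m) e^{-j 2 pi k m / N}`) of the windowed frame starting at
#' `(k-1) * hop` samples. By default only the one-sided spectrum
#' (rows 1..N/2+1, frequencies 0..Nyquist) is kept.
#'
#' @param x Numeric vector, length at least `window_len`.
#' @param spec An [stft_spec].
#' @param onesided Keep only non-negative frequencies (default `TRUE`).
#' @return Complex matrix, one column per frame.
#' @export
stft <- function(x, spec = stft_spec(), onesided = TRUE) {
  N <- spec$window_len
  if (length(x) < N)
    stop("segment shorter than one analysis window (", N, " samples)")
  n_frames <- (length(x) - N) %/% spec$hop + 1L
  idx <- outer(seq_len(N), (seq_len(n_frames) - 1L) * spec$hop, `+`)
  frames <- matrix(x[idx], nrow = N) * window_values(spec)
  X <- stats::mvfft(frames)
  if (onesided) X[seq_len(N %/% 2L + 1L), , drop = FALSE] else X
}

#' Power spectrum in decibels
#'
#' `E = |X|^2`, floored at `eps` before the log so silent frames stay finite:
#' `10 * log10(max(E, eps))`.
#'
#' @param X Complex STFT matrix.
#' @param eps Power floor (default 1e-12 of full scale).
#' @return Numeric matrix of dB values, same shape.
#' @export
power_db <- function(X, eps = 1e-12) {
  stopifnot(eps > 0)
  E <- Mod(X)^2
  10 * log10(pmax(E, eps))
}

#' Spectrogram image of one breath segment
#'
#' The dB-scaled one-sided power spectrogram treated as an intensity image:
#' rows are frequency bins ascending from 0 Hz (row 1), columns are time
#' frames, so vertical structure in the image is broadband (short transient)
#' energy.
#'
#' @param x Numeric sample vector or an [audio_signal].
#' @param spec An [stft_spec].
#' @param rate Sampling rate in Hz (taken from `x` when it is an
#'   [audio_signal]).
#' @param eps dB floor passed to [power_db()].
#' @return A `breath_spectrogram`: list with `values` (dB matrix),
#'   `freq_axis` (Hz per row), `time_axis` (seconds at each frame centre),
#'   `rate`, `spec`.
#' @export
spectrogram <- function(x, spec = stft_spec(), rate = NULL, eps = 1e-12) {
  if (inherits(x, "audio_signal")) { rate <- x$rate; x <- x$samples }
  if (is.null(rate)) stop("rate is required when x is a plain vector")
  X <- stft(x, spec, onesided = TRUE)
  vals <- power_db(X, eps)
  N <- spec$window_len
  structure(list(values = vals,
                 freq_axis = (seq_len(nrow(vals)) - 1) * rate / N,
                 time_axis = ((seq_len(ncol(vals)) - 1) * spec$hop + N / 2) /
                   rate,
                 rate = rate, spec = spec),
            class = "breath_spectrogram")
}

#' @export
print.breath_spectrogram <- function(x, ...) {
  cat(sprintf(
    "<breath_spectrogram> %d freq bins x %d frames, 0-%.0f Hz, %.2f s\n",
    nrow(x$values), ncol(x$values), max(x$freq_axis),
    utils::tail(x$time_axis, 1)))
  invisible(x)
}

#' @export
plot.breath_spectrogram <- function(x, ...) {
  graphics::image(x$time_axis, x$freq_axis, t(x$values),
                  xlab = "time (s)", ylab = "frequency (Hz)",
                  col = grDevices::gray.colors(64, 0, 1), ...)
  invisible(x)
}
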