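#' Texture enhancement specification
#'
#' Parameters of the vertical-texture strengthening stage: the edge mask and
#' Laplacian-of-Gaussian (LoG) filtering, then the triple-threshold
#' (zero-crossing rate, short-band energy, total energy) detector that turns
#' discontinuous vertical line segments into continuous lines.
#'
#' @param sigma LoG scale in pixels.
#' @param kernel_size Odd LoG kernel size.
#' @param zcr_th Max sign-transition count for a "continuous" column, as a
#'   fraction of the number of rows.
#' @param sbe_window Short-band energy window length in rows.
#' @param sbe_th,te_th Per-image quantiles of the column SBE/TE above which a
#'   column is energetic enough to carry a line (gain-invariant thresholds).
#' @param sbe_absolute,te_absolute Optional absolute thresholds overriding the
#'   quantiles (useful when comparing images on a common scale).
#' @param zero_band Magnitudes below this fraction of the column maximum are
#'   treated as zero by the sign function in the ZCR.
#' @param fill_threshold Fraction of the column maximum a pixel must exceed
#'   to count as part of the detected line when the fill run is delimited.
#'   Stricter than `zero_band`: the run should span the energetic dashes,
#'   not every pixel that merely registers against the ZCR zero-band.
#' @param fill_value Grey level written into extended lines; default
#'   (`NULL`) extends each line at its own intensity (the mean of the
#'   column's supra-threshold pixels), which preserves the image histogram
#'   that the grey-level quantization depends on.
#' @param fill_full_column If `TRUE`, extend detected lines over the full
#'   image height instead of the first-to-last detected pixel run.
#' @export
enhance_spec <- function(sigma = 1.0, kernel_size = 7L, zcr_th = 0.25,
                         sbe_window = 32L, sbe_th = 0.75, te_th = 0.75,
                         sbe_absolute = NULL, te_absolute = NULL,
                         zero_band = 0.05, fill_threshold = 0.25,
                         fill_value = NULL, fill_full_column = FALSE) {
  stopifnot(sigma > 0, kernel_size %% 2 == 1, zcr_th > 0, zcr_th <= 1,
            sbe_window >= 1, sbe_th >= 0, sbe_th <= 1, te_th >= 0, te_th <= 1,
            zero_band >= 0, zero_band < 1, fill_threshold >= 0,
            fill_threshold < 1)
  structure(list(sigma = sigma, kernel_size = as.integer(kernel_size),
                 zcr_th = zcr_th, sbe_window = as.integer(sbe_window),
                 sbe_th = sbe_th, te_th = te_th,
                 sbe_absolute = sbe_absolute, te_absolute = te_absolute,
                 zero_band = zero_band, fill_threshold = fill_threshold,
                 fill_value = fill_value,
                 fill_full_column = isTRUE(fill_full_column)),
            class = "enhance_spec")
}

# 2-D convolution (kernel flipped), zero padding, output same size as image.
# Shifted-accumulate form: one dense add per kernel element.
conv2d_same <- function(image, kernel) {
  nr <- nrow(image); nc <- ncol(image)
  kr <- nrow(kernel); kc <- ncol(kernel)
  acc <- matrix(0, nr + kr - 1L, nc + kc - 1L)
  for (u in seq_len(kr)) for (v in seq_len(kc)) {
    k <- kernel[u, v]
    if (k != 0)
      acc[u:(u + nr - 1L), v:(v + nc - 1L)] <-
        acc[u:(u + nr - 1L), v:(v + nc - 1L)] + k * image
  }
  r0 <- (kr - 1L) %/% 2L; c0 <- (kc - 1L) %/% 2L
  acc[(r0 + 1L):(r0 + nr), (c0 + 1L):(c0 + nc), drop = FALSE]
}

#' The 6x6 vertical-edge mask M
#'
#' Six identical rows of `(-1, 2, -1, 2, -1, -1)`. Each row sums to zero, so
#' structures constant along time (horizontal stripes, e.g. sustained tones)
#' cancel, while single-column vertical lines are amplified.
#'
#' @export
mask_M <- function() {
  matrix(rep(c(-1, 2, -1, 2, -1, -1), each = 6), nrow = 6)
}

#' Convolve a spectrogram image with the vertical-edge mask
#'
#' @param image Numeric matrix, at least 6x6 (rows = frequency, columns =
#'   time).
#' @return Matrix of the same size (zero-padded convolution).
#' @export
convolve_mask_M <- function(image) {
  if (nrow(image) < 6L || ncol(image) < 6L)
    stop("image must be at least 6x6 for the edge mask")
  conv2d_same(image, mask_M())
}

#' Laplacian-of-Gaussian kernel
#'
#' Samples of `-(x^2 + y^2 - 2 sigma^2) / sigma^4 * exp(-(x^2 + y^2) /
#' (2 sigma^2))` on the centred integer grid. With `mean_subtract = TRUE`
#' (default) the mean is removed so the entries sum to zero and constant
#' images give exactly zero response. The centre value before subtraction is
#' `2 / sigma^2`.
#'
#' @param sigma Scale in pixels.
#' @param kernel_size Odd size.
#' @param mean_subtract Subtract the kernel mean (default `TRUE`).
#' @export
log_kernel <- function(sigma, kernel_size = 7L, mean_subtract = TRUE) {
  stopifnot(sigma > 0)
  if (kernel_size %% 2 == 0) stop("kernel_size must be odd")
  h <- (kernel_size - 1L) / 2L
  g <- seq(-h, h)
  r2 <- outer(g^2, g^2, `+`)
  k <- -(r2 - 2 * sigma^2) / sigma^4 * exp(-r2 / (2 * sigma^2))
  if (mean_subtract) k - mean(k) else k
}

#' Apply LoG filtering to an image
#'
#' @param image Numeric matrix larger than the kernel.
#' @param spec An [enhance_spec].
#' @return Filtered matrix, same size.
#' @export
apply_log <- function(image, spec = enhance_spec()) {
  if (nrow(image) < spec$kernel_size || ncol(image) < spec$kernel_size)
    stop("image smaller than the LoG kernel")
  conv2d_same(image, log_kernel(spec$sigma, spec$kernel_size))
}

col_sgn <- function(x, zero_band) {
  th <- zero_band * max(abs(x), 0)
  s <- sign(x)
  s[abs(x) <= th] <- 0
  s
}

#' Column zero-crossing (sign-transition) count
#'
#' Counts the positions where the sign state of the column changes, with
#' sign mapped to \{-1, 0, +1\} after a zero-band: magnitudes below
#' `zero_band` of the column maximum count as zero. A continuous vertical
#' line yields a low count; a dashed one a high count.
#'
#' @param column Numeric vector (one time column along frequency).
#' @param zero_band Zero-band fraction.
#' @export
column_zcr <- function(column, zero_band = 0.05) {
  n <- length(column)
  if (n < 2L) return(0L)
  s <- col_sgn(column, zero_band)
  sum(s[-1] != s[-n])
}

#' Column short-band energy
#'
#' Maximum over sliding windows of `window` rows of the sum of squares —
#' whether any band of the column holds enough energy to form a line.
#'
#' @param column Numeric vector.
#' @param window Window length in rows.
#' @export
column_sbe <- function(column, window = 32L) {
  n <- length(column)
  if (n == 0L) return(0)
  w <- min(as.integer(window), n)
  cs <- cumsum(c(0, column^2))
  max(cs[(w + 1L):(n + 1L)] - cs[1:(n - w + 1L)])
}

#' Column total energy
#'
#' @param column Numeric vector.
#' @export
column_te <- function(column) sum(column^2)

#' Strengthen discontinuous vertical texture into continuous lines
#'
#' For each time column of the edge-enhanced image, the triple test is
#' applied: sign-transition count below `zcr_th * nrow`, short-band energy
#' above its threshold and total energy above its threshold. Columns passing
#' all three are flagged, and the vertical run between the first and last
#' pixel above `fill_threshold` of the column maximum is filled with
#' `fill_value`, extending the dashed line into a continuous one. Unflagged
#' columns pass through unchanged.
#'
#' @param image Numeric matrix, normally `apply_log(convolve_mask_M(...))`.
#' @param spec An [enhance_spec].
#' @return An `enhanced_image`: list with `values` (same shape) and
#'   `flagged_columns` (integer vector of column indices).
#' @export
strengthen_texture <- function(image, spec = enhance_spec()) {
  nr <- nrow(image); nc <- ncol(image)
  zcr <- apply(image, 2, column_zcr, zero_band = spec$zero_band)
  sbe <- apply(image, 2, column_sbe, window = spec$sbe_window)
  te <- apply(image, 2, column_te)
  sbe_thr <- if (!is.null(spec$sbe_absolute)) spec$sbe_absolute
             else stats::quantile(sbe, spec$sbe_th, names = FALSE)
  te_thr <- if (!is.null(spec$te_absolute)) spec$te_absolute
            else stats::quantile(te, spec$te_th, names = FALSE)
  flagged <- which(zcr < spec$zcr_th * nr & sbe > sbe_thr & te > te_thr)
  out <- image
  for (j in flagged) {
    col <- image[, j]
    supra <- which(abs(col) > spec$fill_threshold * max(abs(col), 0))
    if (length(supra) == 0L) next
    run <- if (spec$fill_full_column) seq_len(nr)
           else supra[1]:supra[length(supra)]
    fill <- if (is.null(spec$fill_value)) mean(col[supra]) else spec$fill_value
    out[run, j] <- fill
  }
  structure(list(values = out, flagged_columns = flagged),
            class = "enhanced_image")
}

#' Full texture-enhancement stage for one spectrogram
#'
#' Edge mask, then LoG filtering, then triple-threshold line strengthening —
#' the fixed processing order of the enhancement stage.
#'
#' @param spg A `breath_spectrogram` (or plain matrix).
#' @param spec An [enhance_spec].
#' @return An `enhanced_image` (see [strengthen_texture()]).
#' @export
enhance_spectrogram <- function(spg, spec = enhance_spec()) {
  img <- if (inherits(spg, "breath_spectrogram")) spg$values else spg
  strengthen_texture(apply_log(convolve_mask_M(img), spec), spec)
}
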