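#' Quantize an image to g grey levels
#'
#' Linear min--max binning into levels `0 .. g-1`; the bin boundaries are
#' affine in the pixel values, so the quantized image is invariant to any
#' positive affine rescaling and the histogram shape is preserved. A constant
#' image maps to level 0.
#'
#' @param image Finite numeric matrix.
#' @param g Number of grey levels (default 16).
#' @return Integer matrix with values in `0 .. g-1`.
#' @export
quantize_grey <- function(image, g = 16L) {
  stopifnot(all(is.finite(image)), g >= 2)
  rng <- range(image)
  if (rng[1] == rng[2])
    return(matrix(0L, nrow(image), ncol(image)))
  q <- floor((image - rng[1]) / (rng[2] - rng[1]) * g)
  mode(q) <- "integer"
  q[q > g - 1L] <- g - 1L
  matrix(q, nrow(image), ncol(image))
}

glcm_offsets <- function(d, theta) {
  switch(as.character(theta),
         "0"   = c(0L, d),    # along time (columns)
         "45"  = c(d, d),
         "90"  = c(d, 0L),    # along frequency (rows)
         "135" = c(d, -d),
         stop("theta must be one of 0, 45, 90, 135"))
}

#' Grey-level co-occurrence matrix
#'
#' Counts ordered pixel pairs separated by distance `d` in direction `theta`
#' (0 degrees along time/columns, 90 along frequency/rows), accumulated
#' symmetrically (both orientations of each pair) and normalised to
#' probabilities.
#'
#' @param image Integer matrix with values in `0 .. g-1` (see
#'   [quantize_grey()]).
#' @param d Pixel distance (>= 1).
#' @param theta Direction in degrees: 0, 45, 90 or 135.
#' @param g Number of grey levels.
#' @return A `glcm` object: list with `P` (g x g probability matrix), `d`,
#'   `theta`, `g`.
#' @export
glcm <- function(image, d = 1L, theta = 0, g = 16L) {
  stopifnot(d >= 1)
  off <- glcm_offsets(as.integer(d), theta)
  nr <- nrow(image); nc <- ncol(image)
  dr <- off[1]; dc <- off[2]
  rows <- seq_len(nr - dr)
  cols <- if (dc >= 0) seq_len(nc - dc) else seq(1 - dc, nc)
  if (length(rows) == 0L || length(cols) == 0L)
    stop("image smaller than the (d, theta) displacement")
  i <- image[rows, cols, drop = FALSE]
  j <- image[rows + dr, cols + dc, drop = FALSE]
  counts <- tabulate(as.integer(i) * g + as.integer(j) + 1L, nbins = g * g)
  P <- matrix(counts, g, g, byrow = TRUE)   # row = level of first pixel
  P <- P + t(P)                             # symmetric accumulation
  structure(list(P = P / sum(P), d = as.integer(d), theta = theta,
                 g = as.integer(g)), class = "glcm")
}

get_P <- function(P) {
  if (inherits(P, "glcm")) P <- P$P
  if (!is.matrix(P) || nrow(P) != ncol(P)) stop("need a square GLCM matrix")
  s <- sum(P)
  if (s <= 0) stop("GLCM has zero mass; cannot normalise")
  P / s
}

#' GLCM texture statistics
#'
#' The four Haralick-style statistics used as texture features, computed from
#' one normalised GLCM with levels indexed `1 .. g`:
#' \describe{
#'   \item{energy}{angular second moment, `sum P(i,j)^2`}
#'   \item{inertia}{`sum (i-j)^2 P(i,j)^2`; with `classic = TRUE` the
#'     standard contrast `sum (i-j)^2 P(i,j)`}
#'   \item{correlation}{`(sum i j P(i,j) - u1 u2) / (d1 d2)` with marginal
#'     means `u1, u2` and standard deviations `d1, d2`; defined as 0 when a
#'     marginal is degenerate (constant image)}
#'   \item{entropy}{`-sum P log10 P`, with `0 log 0 = 0`}
#' }
#'
#' @param P A `glcm` object or square probability matrix.
#' @param classic Use the standard contrast form in [glcm_inertia()].
#' @name glcm_features
NULL

#' @rdname glcm_features
#' @export
glcm_energy <- function(P) sum(get_P(P)^2)

#' @rdname glcm_features
#' @export
glcm_inertia <- function(P, classic = FALSE) {
  P <- get_P(P)
  g <- nrow(P)
  ij <- outer(seq_len(g), seq_len(g), `-`)^2
  if (classic) sum(ij * P) else sum(ij * P^2)
}

#' @rdname glcm_features
#' @export
glcm_correlation <- function(P) {
  P <- get_P(P)
  g <- nrow(P)
  lev <- seq_len(g)
  pi_ <- rowSums(P); pj <- colSums(P)
  u1 <- sum(lev * pi_); u2 <- sum(lev * pj)
  d1 <- sqrt(sum((lev - u1)^2 * pi_)); d2 <- sqrt(sum((lev - u2)^2 * pj))
  if (d1 * d2 == 0) return(0)
  (sum(outer(lev, lev) * P) - u1 * u2) / (d1 * d2)
}

#' @rdname glcm_features
#' @export
glcm_entropy <- function(P) {
  P <- get_P(P)
  nz <- P[P > 0]
  -sum(nz * log10(nz))
}

glcm_angles <- c(0, 45, 90, 135)
glcm_stats <- c("energy", "inertia", "correlation", "entropy")

#' Canonical texture feature names
#'
#' The 16 features in canonical order: statistic-major, angle-minor —
#' `energy_0, energy_45, energy_90, energy_135, inertia_0, ...,
#' entropy_135`.
#'
#' @export
feature_names <- function() {
  as.vector(t(outer(glcm_stats, glcm_angles, paste, sep = "_")))
}

#' Extract the 16-feature texture vector of one breath image
#'
#' Quantizes to `g` grey levels, builds one symmetric GLCM per angle
#' (0, 45, 90, 135 degrees) at distance `d`, and computes energy, inertia,
#' correlation and entropy for each, assembled in the canonical order of
#' [feature_names()]. With rows = frequency, the 90-degree features read the
#' along-frequency (vertical-texture) structure.
#'
#' @param image Numeric matrix, `enhanced_image` or `breath_spectrogram`.
#' @param d GLCM pixel distance (default 1).
#' @param g Grey levels (default 16).
#' @param classic_contrast Use standard contrast for the inertia features.
#' @return Named numeric vector of length 16.
#' @export
extract_features <- function(image, d = 1L, g = 16L, classic_contrast = FALSE) {
  if (inherits(image, "enhanced_image")) image <- image$values
  if (inherits(image, "breath_spectrogram")) image <- image$values
  q <- quantize_grey(image, g)
  mats <- lapply(glcm_angles, function(th) glcm(q, d = d, theta = th, g = g))
  names(mats) <- glcm_angles
  out <- unlist(lapply(glcm_stats, function(s) {
    vapply(mats, function(m) switch(s,
      energy = glcm_energy(m),
      inertia = glcm_inertia(m, classic = classic_contrast),
      correlation = glcm_correlation(m),
      entropy = glcm_entropy(m)), numeric(1))
  }))
  names(out) <- feature_names()
  out
}
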