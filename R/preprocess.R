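#' Bandpass filter specification
#'
#' Defaults follow the acquisition chain being modelled: a third-order
#' Butterworth IIR bandpass from 20 to 6000 Hz, which keeps the band where
#' respiratory-tract and sputum energy live and removes DC drift and
#' out-of-band noise.
#'
#' @param order Filter order.
#' @param low_hz,high_hz Band edges in Hz.
#' @param zero_phase If `TRUE`, apply forward-backward filtering
#'   (zero-phase); default is causal forward-only filtering as a real-time
#'   system would run.
#' @export
filter_spec <- function(order = 3L, low_hz = 20, high_hz = 6000,
                        zero_phase = FALSE) {
  stopifnot(order >= 1, low_hz > 0, high_hz > low_hz)
  structure(list(order = as.integer(order), low_hz = low_hz, high_hz = high_hz,
                 zero_phase = isTRUE(zero_phase)), class = "filter_spec")
}

#' Bandpass-filter a recording
#'
#' @param signal An [audio_signal] with `rate > 2 * high_hz`.
#' @param spec A [filter_spec].
#' @return Filtered [audio_signal], same length and rate.
#' @export
bandpass_filter <- function(signal, spec = filter_spec()) {
  stopifnot(inherits(signal, "audio_signal"), inherits(spec, "filter_spec"))
  if (signal$rate <= 2 * spec$high_hz)
    stop("sampling rate ", signal$rate, " Hz cannot represent the ",
         spec$high_hz, " Hz band edge; resample the input first")
  if (length(signal$samples) == 0L) return(signal)
  b <- signal::butter(spec$order,
                      c(spec$low_hz, spec$high_hz) / (signal$rate / 2),
                      type = "pass")
  y <- if (spec$zero_phase) signal::filtfilt(b, signal$samples)
       else as.numeric(signal::filter(b, signal$samples))
  audio_signal(y, signal$rate)
}

#' Segmentation specification
#'
#' Parameters of the short-time autocorrelation two-threshold breath
#' segmenter. Frame scores are the maximum of the frame's raw
#' autocorrelation over lags `k_min .. L-1`; the noise floor `max(R)` is the
#' maximum score over the leading voiceless frames, and the two working
#' thresholds are `T1 = a * max(R)` (start/end judgement and hysteresis
#' release) and `T2 = b * max(R)` (segment opening).
#'
#' @param frame_len Frame length L in samples (~46 ms at 44.1 kHz).
#' @param hop Hop between frame starts in samples.
#' @param a,b Threshold multipliers, `0 < a < b` (defaults 1 and 10).
#' @param k_min Smallest lag used in the frame score; excludes the near-zero
#'   lags that would otherwise be dominated by the frame's energy term.
#' @param noise_floor_frames Number of leading voiceless frames used to
#'   estimate `max(R)`. The default (40 frames, ~0.95 s at the default frame
#'   geometry and 44.1 kHz) uses most of the voiceless lead the recordings
#'   are assumed to start with; too few frames underestimate the maximum and
#'   leave T1 inside the bulk of the background-score distribution.
#' @param min_breath_s Segments shorter than this are discarded.
#' @param min_gap_s A segment closes only after scores stay below T1 this long.
#' @export
segmentation_spec <- function(frame_len = 2048L, hop = 1024L, a = 1, b = 10,
                              k_min = 20L, noise_floor_frames = 40L,
                              min_breath_s = 0.5, min_gap_s = 0.3) {
  stopifnot(frame_len > 0, hop > 0, a > 0, b > a, k_min >= 1,
            k_min < frame_len, noise_floor_frames >= 1,
            min_breath_s > 0, min_gap_s > 0)
  structure(list(frame_len = as.integer(frame_len), hop = as.integer(hop),
                 a = a, b = b, k_min = as.integer(k_min),
                 noise_floor_frames = as.integer(noise_floor_frames),
                 min_breath_s = min_breath_s, min_gap_s = min_gap_s),
            class = "segmentation_spec")
}

#' Raw short-time autocorrelation of one frame at one lag
#'
#' `R(k) = sum_{m=1}^{L-k} x(m) x(m+k)` for a frame of length L. Unnormalised,
#' so it scales quadratically with amplitude.
#'
#' @param frame Numeric vector (one analysis frame).
#' @param k Lag in samples, `0 <= k < length(frame)`.
#' @export
frame_autocorrelation <- function(frame, k) {
  L <- length(frame)
  if (k < 0 || k >= L) stop("lag k must satisfy 0 <= k < frame length")
  sum(frame[seq_len(L - k)] * frame[seq_len(L - k) + k])
}

# linear autocorrelation of every column of a frame matrix, lags 0..L-1,
# via zero-padded FFT (exact up to roundoff)
frame_autocorr_matrix <- function(frames) {
  L <- nrow(frames)
  nfft <- 2^ceiling(log2(2L * L))
  padded <- rbind(frames, matrix(0, nfft - L, ncol(frames)))
  spec <- stats::mvfft(padded)
  r <- Re(stats::mvfft(spec * Conj(spec), inverse = TRUE)) / nfft
  r[seq_len(L), , drop = FALSE]
}

#' Frame score: maximum autocorrelation over informative lags
#'
#' @param frame Numeric vector.
#' @param k_min Smallest lag considered (default 20 samples).
#' @return `max_k R(k)` over `k_min <= k < L`.
#' @export
frame_score <- function(frame, k_min = 20L) {
  L <- length(frame)
  stopifnot(k_min >= 1, k_min < L)
  r <- frame_autocorr_matrix(matrix(frame, ncol = 1))
  max(r[(k_min + 1L):L, 1])
}

# frame the signal (columns = frames) and score all frames at once.
# Two real frames are packed into one complex FFT (and the two real power
# spectra into one inverse FFT), which halves the transform count; the
# result is the same linear autocorrelation as frame_autocorr_matrix().
frame_scores <- function(samples, spec) {
  L <- spec$frame_len
  n <- length(samples)
  n_frames <- if (n < L) 0L else (n - L) %/% spec$hop + 1L
  if (n_frames == 0L) return(numeric(0))
  idx <- outer(seq_len(L), (seq_len(n_frames) - 1L) * spec$hop, `+`)
  frames <- matrix(samples[idx], nrow = L)
  n_pairs <- (n_frames + 1L) %/% 2L
  if (n_frames %% 2L == 1L) frames <- cbind(frames, 0)
  nfft <- 2^ceiling(log2(2L * L))
  odd <- 2L * seq_len(n_pairs) - 1L
  packed <- rbind(frames[, odd, drop = FALSE] +
                    1i * frames[, odd + 1L, drop = FALSE],
                  matrix(0, nfft - L, n_pairs))
  Z <- stats::mvfft(packed)
  rev_idx <- c(1L, nfft:2L)
  Zc <- Conj(Z[rev_idx, , drop = FALSE])
  P1 <- Mod((Z + Zc) / 2)^2                  # power spectrum of odd frames
  P2 <- Mod((Z - Zc) / 2)^2                  # ... of even frames
  q <- stats::mvfft(P1 + 1i * P2, inverse = TRUE) / nfft
  lags <- (spec$k_min + 1L):L
  scores <- numeric(2L * n_pairs)
  scores[odd] <- apply(Re(q[lags, , drop = FALSE]), 2, max)
  scores[odd + 1L] <- apply(Im(q[lags, , drop = FALSE]), 2, max)
  scores[seq_len(n_frames)]
}

#' Estimate the voiceless noise floor max(R)
#'
#' The maximum frame score over the leading `noise_floor_frames` frames,
#' which are assumed to contain no breathing (recordings start with a
#' ventilator-only gap).
#'
#' @param signal An [audio_signal].
#' @param spec A [segmentation_spec].
#' @export
estimate_noise_floor <- function(signal, spec = segmentation_spec()) {
  stopifnot(inherits(signal, "audio_signal"))
  need <- spec$frame_len + (spec$noise_floor_frames - 1L) * spec$hop
  if (length(signal$samples) < need)
    stop("recording too short for ", spec$noise_floor_frames,
         " noise-floor frames (need ", need, " samples)")
  head_samples <- signal$samples[seq_len(need)]
  max(frame_scores(head_samples, spec))
}

#' Segment a recording into breath cycles
#'
#' Hysteresis state machine over frame scores: a segment opens when a score
#' reaches `T2 = b * max(R)` (the start is refined backward to just after the
#' last frame scoring below `T1 = a * max(R)`), and closes when scores stay
#' below T1 for at least `min_gap_s`. Segments shorter than `min_breath_s`
#' are discarded.
#'
#' @param signal An [audio_signal] (normally already bandpass-filtered).
#' @param spec A [segmentation_spec].
#' @return data.frame with columns `start`, `end`: 0-based half-open sample
#'   intervals, sorted and non-overlapping. Empty when no frame reaches T2.
#' @export
segment_breaths <- function(signal, spec = segmentation_spec()) {
  stopifnot(inherits(signal, "audio_signal"))
  n <- length(signal$samples)
  scores <- frame_scores(signal$samples, spec)
  if (length(scores) == 0L)
    return(data.frame(start = integer(0), end = integer(0)))
  floor_r <- estimate_noise_floor(signal, spec)
  t1 <- spec$a * floor_r
  t2 <- max(spec$b * floor_r, .Machine$double.xmin)  # silence floor guard
  rate <- signal$rate
  gap_frames <- max(1L, ceiling(spec$min_gap_s * rate / spec$hop))
  segs_start <- integer(0); segs_end <- integer(0)
  in_seg <- FALSE; below <- 0L; start_f <- 1L; last_above <- 1L
  prev_end_f <- 0L
  for (f in seq_along(scores)) {
    s <- scores[f]
    if (!in_seg) {
      if (s >= t2) {
        g <- f
        while (g - 1L > prev_end_f && scores[g - 1L] >= t1) g <- g - 1L
        start_f <- g; last_above <- f; below <- 0L; in_seg <- TRUE
      }
    } else {
      if (s >= t1) { last_above <- f; below <- 0L }
      else {
        below <- below + 1L
        if (below >= gap_frames) {
          segs_start <- c(segs_start, start_f)
          segs_end <- c(segs_end, last_above)
          prev_end_f <- last_above
          in_seg <- FALSE
        }
      }
    }
  }
  if (in_seg) { segs_start <- c(segs_start, start_f)
                segs_end <- c(segs_end, last_above) }
  if (length(segs_start) == 0L)
    return(data.frame(start = integer(0), end = integer(0)))
  start_sample <- (segs_start - 1L) * spec$hop                 # 0-based
  end_sample <- pmin((segs_end - 1L) * spec$hop + spec$frame_len, n)
  keep <- (end_sample - start_sample) >= spec$min_breath_s * rate
  data.frame(start = start_sample[keep], end = end_sample[keep])
}

#' Extract the samples of one segment
#'
#' @param signal An [audio_signal].
#' @param start,end 0-based half-open sample interval.
#' @return Numeric vector of `end - start` samples.
#' @export
segment_samples <- function(signal, start, end) {
  stopifnot(start >= 0, end > start, end <= length(signal$samples))
  signal$samples[(start + 1L):end]
}
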