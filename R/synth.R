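#' Synthetic-recording specification
#'
#' Parameters of one simulated intubated-patient recording: breathing epochs
#' of band-limited airflow noise shaped by an inhale/pause/exhale envelope,
#' separated by gaps that hold only ventilator background noise, with
#' optional short broadband bursts (the sputum signature) inside the epochs.
#'
#' The layout is gap, cycle, gap, cycle, ..., cycle, gap: `n_cycles` breath
#' cycles and `n_cycles + 1` gaps, so the total duration is
#' `n_cycles * cycle_s + (n_cycles + 1) * gap_s`.
#'
#' @param n_cycles Number of breath cycles (>= 0).
#' @param cycle_s Seconds per inhale--exhale cycle.
#' @param gap_s Seconds of ventilator-only gap before, between and after cycles.
#' @param burst_rate Expected bursts per second during breathing epochs; 0
#'   gives the "without sputum" class.
#' @param burst_bandwidth_hz Upper spectral extent of a burst (Hz).
#' @param snr_db Breath-signal-to-ventilator-noise ratio in dB (peak breath
#'   envelope RMS over background RMS).
#' @param breath_low_hz,breath_high_hz Band of the airflow noise (Hz).
#' @param inhale_frac,pause_frac Fractions of the cycle spent in the inhale
#'   phase and the inter-phase pause; the exhale takes the remainder.
#' @param pause_floor Residual envelope amplitude during the pause (fraction
#'   of peak); models the continuing airflow between phases.
#' @param amplitude Peak envelope amplitude of the breath noise (full scale 1).
#' @param seed Integer seed; the whole recording is a deterministic function
#'   of the spec.
#' @param rate Sampling rate (Hz).
#' @return A `synth_spec` list.
#' @export
synth_spec <- function(n_cycles = 4L, cycle_s = 3, gap_s = 1.5,
                       burst_rate = 4, burst_bandwidth_hz = 6000,
                       snr_db = 12, breath_low_hz = 100, breath_high_hz = 1500,
                       inhale_frac = 0.40, pause_frac = 0.07,
                       pause_floor = 0.15, amplitude = 0.3,
                       seed = 1L, rate = 44100L) {
  stopifnot(n_cycles >= 0, cycle_s > 0, gap_s > 0, burst_rate >= 0,
            burst_bandwidth_hz > 0, amplitude > 0,
            inhale_frac > 0, pause_frac >= 0, inhale_frac + pause_frac < 1,
            rate > 0)
  structure(list(n_cycles = as.integer(n_cycles), cycle_s = cycle_s,
                 gap_s = gap_s, burst_rate = burst_rate,
                 burst_bandwidth_hz = burst_bandwidth_hz, snr_db = snr_db,
                 breath_low_hz = breath_low_hz, breath_high_hz = breath_high_hz,
                 inhale_frac = inhale_frac, pause_frac = pause_frac,
                 pause_floor = pause_floor, amplitude = amplitude,
                 seed = as.integer(seed), rate = as.integer(rate)),
            class = "synth_spec")
}

# run expr with a private RNG stream; global .Random.seed untouched
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", globalenv())
  on.exit(if (has) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

# band-limited Gaussian noise via a 4th-order Butterworth bandpass
bandlimited_noise <- function(n, low_hz, high_hz, rate) {
  if (n == 0L) return(numeric(0))
  w <- c(low_hz, min(high_hz, rate / 2 * 0.99)) / (rate / 2)
  b <- signal::butter(4, w, type = "pass")
  x <- as.numeric(signal::filter(b, stats::rnorm(n)))
  x / max(stats::sd(x), .Machine$double.eps)
}

# inhale / pause / exhale raised-cosine envelope for one cycle of n samples
breath_envelope <- function(n, inhale_frac, pause_frac, pause_floor) {
  n_in <- max(1L, round(n * inhale_frac))
  n_pause <- max(0L, round(n * pause_frac))
  n_ex <- n - n_in - n_pause
  if (n_ex < 1L) { n_ex <- 1L; n_in <- n - n_pause - 1L }
  hann_lobe <- function(m) sin(pi * (seq_len(m) - 0.5) / m)^2
  env <- c(hann_lobe(n_in), rep(0, n_pause), hann_lobe(n_ex))
  pmax(env, pause_floor)
}

#' Generate one labelled synthetic respiratory recording
#'
#' Deterministic given the spec (including its seed). The generated truth —
#' cycle boundaries and burst onset times — is returned alongside the audio so
#' segmentation and enhancement can be scored against ground truth.
#'
#' @param spec A [synth_spec].
#' @return A `labelled_recording` list with elements `audio` ([audio_signal]),
#'   `label` (`"with_sputum"` if `burst_rate > 0` else `"without_sputum"`),
#'   `truth_segments` (data.frame of 0-based half-open sample intervals
#'   `start`, `end`, one row per cycle) and `truth_burst_times` (seconds).
#' @export
synthesize_recording <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  rate <- spec$rate
  n_cyc <- round(spec$cycle_s * rate)
  n_gap <- round(spec$gap_s * rate)
  n_total <- spec$n_cycles * n_cyc + (spec$n_cycles + 1L) * n_gap
  with_seed(spec$seed, {
    noise_sd <- spec$amplitude * 10^(-spec$snr_db / 20)
    x <- stats::rnorm(n_total, sd = noise_sd)          # ventilator background
    env1 <- breath_envelope(n_cyc, spec$inhale_frac, spec$pause_frac,
                            spec$pause_floor)
    starts <- n_gap + (seq_len(spec$n_cycles) - 1L) * (n_cyc + n_gap)  # 0-based
    burst_times <- numeric(0)
    for (s in starts) {
      breath <- bandlimited_noise(n_cyc, spec$breath_low_hz,
                                  spec$breath_high_hz, rate)
      x[(s + 1L):(s + n_cyc)] <- x[(s + 1L):(s + n_cyc)] +
        spec$amplitude * env1 * breath
      if (spec$burst_rate > 0) {
        k <- stats::rpois(1, spec$burst_rate * spec$cycle_s)
        if (k > 0) {
          t0 <- sort(stats::runif(k, 0, spec$cycle_s))
          for (tb in t0) {
            dur <- stats::runif(1, 0.005, 0.020)
            m <- max(8L, round(dur * rate))
            i0 <- s + round(tb * rate)
            if (i0 + m > s + n_cyc) m <- s + n_cyc - i0
            if (m < 8L) next
            amp <- spec$amplitude * 1.5 * min(stats::rexp(1), 3)
            burst <- bandlimited_noise(m, spec$breath_low_hz,
                                       spec$burst_bandwidth_hz, rate)
            taper <- sin(pi * (seq_len(m) - 0.5) / m)^2
            x[(i0 + 1L):(i0 + m)] <- x[(i0 + 1L):(i0 + m)] + amp * taper * burst
            burst_times <- c(burst_times, (i0) / rate)
          }
        }
      }
    }
    segs <- data.frame(start = starts, end = starts + n_cyc)
    structure(list(audio = audio_signal(pmin(1, pmax(-1, x)), rate),
                   label = if (spec$burst_rate > 0) "with_sputum"
                           else "without_sputum",
                   truth_segments = segs,
                   truth_burst_times = burst_times,
                   spec = spec),
              class = "labelled_recording")
  })
}

#' @export
print.labelled_recording <- function(x, ...) {
  cat(sprintf("<labelled_recording> %s: %d cycles, %d bursts, %.1f s @ %d Hz\n",
              x$label, nrow(x$truth_segments), length(x$truth_burst_times),
              length(x$audio$samples) / x$audio$rate, x$audio$rate))
  invisible(x)
}

#' Generate a balanced labelled corpus
#'
#' Produces `n_per_class` recordings per class. Each recording gets its own
#' seed derived from `seed`, and nuisance parameters (SNR, cycle length,
#' envelope shape, burst rate) are jittered per recording so the corpus is not
#' 220 copies of one waveform.
#'
#' @param n_per_class Recordings per class (>= 1).
#' @param spec_template A [synth_spec] giving the central parameter values;
#'   its `burst_rate` is used for the with-sputum class and forced to 0 for
#'   the without-sputum class.
#' @param seed Master seed for per-recording substreams.
#' @return List of `labelled_recording`s, with-sputum first.
#' @export
synthesize_corpus <- function(n_per_class, spec_template = synth_spec(),
                              seed = 1L) {
  stopifnot(n_per_class >= 1)
  n <- 2L * n_per_class
  draws <- with_seed(seed, list(
    seeds = sample.int(.Machine$integer.max - 1L, n),
    snr = stats::runif(n, -3, 3),
    cyc = stats::runif(n, 0.85, 1.15),
    inh = stats::runif(n, -0.05, 0.05),
    br  = stats::runif(n, 0.7, 1.3)
  ))
  labels <- rep(c("with_sputum", "without_sputum"), each = n_per_class)
  lapply(seq_len(n), function(i) {
    sp <- spec_template
    sp$seed <- draws$seeds[i]
    sp$snr_db <- sp$snr_db + draws$snr[i]
    sp$cycle_s <- sp$cycle_s * draws$cyc[i]
    sp$inhale_frac <- sp$inhale_frac + draws$inh[i]
    sp$burst_rate <- if (labels[i] == "with_sputum")
      sp$burst_rate * draws$br[i] else 0
    synthesize_recording(sp)
  })
}
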