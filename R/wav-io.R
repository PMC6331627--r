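#' Audio signal container
#'
#' A mono waveform: a numeric sample vector plus its sampling rate. Amplitudes
#' are dimensionless with nominal range \[-1, 1\] (full scale of the 16-bit
#' converter they model).
#'
#' @param samples Numeric vector of finite amplitudes.
#' @param rate Sampling rate in samples/second (positive scalar, default 44100,
#'   the rate of the bedside acquisition hardware being modelled).
#' @return An object of class `audio_signal` with elements `samples` and `rate`.
#' @export
audio_signal <- function(samples = numeric(0), rate = 44100L) {
  samples <- as.numeric(samples)
  if (length(samples) && !all(is.finite(samples)))
    stop("audio samples must be finite")
  rate <- as.integer(rate)
  if (length(rate) != 1L || is.na(rate) || rate <= 0L)
    stop("rate must be a positive scalar")
  structure(list(samples = samples, rate = rate), class = "audio_signal")
}

#' @export
print.audio_signal <- function(x, ...) {
  cat(sprintf("<audio_signal> %d samples @ %d Hz (%.3f s)\n",
              length(x$samples), x$rate, length(x$samples) / x$rate))
  invisible(x)
}

#' @export
length.audio_signal <- function(x) length(x$samples)

#' Read a mono 16-bit PCM WAV file
#'
#' Minimal RIFF/WAVE reader for the canonical uncompressed format the
#' acquisition hardware produces (PCM, 16-bit, one channel). Samples are
#' rescaled to \[-1, 1\] by dividing by 32768.
#'
#' @param path Path to an existing WAV file.
#' @return An [audio_signal].
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  readBin(con, "integer", 1, 4, endian = "little")   # chunk size
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)
  rate <- NULL; bits <- NULL; channels <- NULL; fmt_code <- NULL
  samples <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    sz <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, "integer", sz %/% 2L, 2, signed = FALSE,
                     endian = "little")
      fmt_code <- fmt[1]
      channels <- fmt[2]
      rate <- fmt[3] + 65536 * fmt[4]
      bits <- fmt[8]
    } else if (identical(id, "data")) {
      n <- sz %/% 2L
      samples <- if (n > 0L)
        readBin(con, "integer", n, 2, signed = TRUE, endian = "little")
      else integer(0)
      if (sz %% 2L == 1L) readBin(con, "raw", 1)
    } else {
      readBin(con, "raw", sz + sz %% 2L)  # skip unknown chunk (word-aligned)
    }
    if (!is.null(samples) && !is.null(rate)) break
  }
  if (is.null(rate) || is.null(samples)) stop("malformed WAV (missing chunk): ", path)
  if (!identical(as.integer(fmt_code), 1L))
    stop("unsupported WAV encoding (need PCM): format code ", fmt_code)
  if (!identical(as.integer(channels), 1L))
    stop("expected mono WAV, got ", channels, " channels")
  if (!identical(as.integer(bits), 16L))
    stop("expected 16-bit PCM, got ", bits, " bits")
  audio_signal(samples / 32768, rate)
}

#' Write a mono 16-bit PCM WAV file
#'
#' @param path Output path.
#' @param signal An [audio_signal] with samples in \[-1, 1\].
#' @param clip If `TRUE`, out-of-range samples are clipped to full scale;
#'   if `FALSE` (default) they raise an error.
#' @return `path`, invisibly.
#' @export
write_wav <- function(path, signal, clip = FALSE) {
  stopifnot(inherits(signal, "audio_signal"))
  x <- signal$samples
  if (length(x) && (any(x > 1) || any(x < -1))) {
    if (!clip) stop("samples outside [-1, 1]; set clip = TRUE to clip")
    x <- pmin(1, pmax(-1, x))
  }
  pcm <- as.integer(pmin(32767, pmax(-32768, round(x * 32768))))
  n_bytes <- 2L * length(pcm)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(c(1L, 1L), con, 2, endian = "little")            # PCM, mono
  writeBin(as.integer(signal$rate), con, 4, endian = "little")
  writeBin(as.integer(signal$rate * 2L), con, 4, endian = "little")  # byte rate
  writeBin(c(2L, 16L), con, 2, endian = "little")           # block align, bits
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, 4, endian = "little")
  if (length(pcm)) writeBin(pcm, con, 2, endian = "little")
  invisible(path)
}
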