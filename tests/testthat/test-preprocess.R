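test_that("frame autocorrelation matches the double-loop oracle", {
  set.seed(11)
  for (i in 1:100) {
    frame <- rnorm(32)
    k <- sample(0:31, 1)
    expect_equal(frame_autocorrelation(frame, k), oracle_autocorr(frame, k),
                 tolerance = 1e-9)
  }
  expect_identical(frame_autocorrelation(numeric(16) , 5), 0)
  expect_equal(frame_autocorrelation(rep(1, 20), 6), 14)  # L - k unit products
  expect_error(frame_autocorrelation(rnorm(8), 8), "lag")
})

test_that("frame score picks periodic structure over noise", {
  expect_identical(frame_score(numeric(64), 5), 0)
  # periodic frame: maximizing lag is a multiple of the period
  p <- 16
  frame <- rep(sin(2 * pi * (1:p) / p), 16)
  L <- length(frame)
  r <- vapply(20:(L - 1), function(k) frame_autocorrelation(frame, k), 1)
  best <- (20:(L - 1))[which.max(r)]
  expect_equal(best %% p, 0)
  expect_equal(frame_score(frame, 20), max(r), tolerance = 1e-9)
  # same-power white noise scores lower
  set.seed(21)
  for (i in 1:10) {
    noise <- rnorm(L)
    noise <- noise * sqrt(sum(frame^2) / sum(noise^2))
    expect_gt(frame_score(frame, 20), frame_score(noise, 20))
  }
})

test_that("noise floor estimate behaves under silence, scaling and shortness", {
  sp <- segmentation_spec()
  silent <- audio_signal(numeric(sp$frame_len +
                                   (sp$noise_floor_frames - 1) * sp$hop),
                         44100)
  expect_identical(estimate_noise_floor(silent, sp), 0)
  set.seed(31)
  noise <- audio_signal(rnorm(60000, sd = 0.05), 44100)
  f1 <- estimate_noise_floor(noise, sp)
  noise2 <- audio_signal(2 * noise$samples, 44100)
  expect_equal(estimate_noise_floor(noise2, sp), 4 * f1, tolerance = 1e-9)
  # matches the per-frame oracle over the leading frames
  oracle <- max(vapply(seq_len(sp$noise_floor_frames), function(f) {
    fr <- noise$samples[((f - 1) * sp$hop + 1):((f - 1) * sp$hop + sp$frame_len)]
    max(vapply(sp$k_min:(sp$frame_len - 1), function(k)
      oracle_autocorr(fr, k), 1))
  }, 1))
  expect_equal(f1, oracle, tolerance = 1e-6)
  expect_error(estimate_noise_floor(audio_signal(rnorm(100), 44100), sp),
               "too short")
})

test_that("bandpass filter passes mid-band and rejects out-of-band energy", {
  rate <- 44100
  t <- seq_len(rate) / rate
  tail_rms <- function(x) sqrt(mean(x[(rate / 2):rate]^2))
  tone1k <- audio_signal(sin(2 * pi * 1000 * t), rate)
  out1k <- bandpass_filter(tone1k)
  expect_equal(tail_rms(out1k$samples), tail_rms(tone1k$samples),
               tolerance = 0.01)
  dc <- audio_signal(rep(0.5, rate), rate)
  expect_lt(tail_rms(bandpass_filter(dc)$samples), 0.005)
  tone5 <- audio_signal(sin(2 * pi * 5 * t), rate)
  atten_db <- 20 * log10(tail_rms(bandpass_filter(tone5)$samples) /
                           tail_rms(out1k$samples))
  expect_lt(atten_db, -18)
  expect_error(bandpass_filter(audio_signal(rnorm(100), 8000)), "resample")
  # no energy gain for band-limited input
  set.seed(41)
  bl <- bandpass_filter(audio_signal(rnorm(rate, sd = 0.1), rate))
  expect_lt(sqrt(mean(bl$samples^2)), 1.05 * 0.1 * 1.01)
})

test_that("segmentation recovers the generated cycles", {
  rec <- synthesize_recording(synth_spec(seed = 7))
  filt <- bandpass_filter(rec$audio)
  segs <- segment_breaths(filt)
  expect_equal(nrow(segs), 4)
  for (i in 1:4)
    expect_gte(jaccard_interval(c(segs$start[i], segs$end[i]),
                                c(rec$truth_segments$start[i],
                                  rec$truth_segments$end[i])), 0.7)
  # disjoint, sorted, in bounds
  expect_true(all(diff(segs$start) > 0))
  expect_true(all(segs$start < segs$end))
  expect_true(all(segs$start[-1] >= segs$end[-nrow(segs)]))
  expect_true(all(segs$end <= length(filt$samples)))
})

test_that("segmentation is scale invariant and empty on pure background", {
  rec <- synthesize_recording(toy_synth_spec(13))
  filt <- bandpass_filter(rec$audio)
  segs <- segment_breaths(filt)
  scaled <- audio_signal(0.25 * filt$samples, filt$rate)
  expect_identical(segment_breaths(scaled), segs)
  set.seed(51)
  bg <- audio_signal(rnorm(5 * 44100, sd = 0.05), 44100)
  expect_equal(nrow(segment_breaths(bg)), 0)
  silent <- audio_signal(numeric(3 * 44100), 44100)
  expect_equal(nrow(segment_breaths(silent)), 0)
})

test_that("sub-min_gap pauses merge and concatenated recordings segment independently", {
  # constructed: lead gap + breath, 0.15 s dip, breath + trailing gap
  rate <- 44100
  sp <- segmentation_spec()
  set.seed(61)
  mk_band <- function(n) {
    b <- signal::butter(4, c(100, 1500) / (rate / 2), "pass")
    x <- as.numeric(signal::filter(b, rnorm(n)))
    x / sd(x)
  }
  gap <- function(n) rnorm(n, sd = 0.024)           # 12 dB below breath RMS
  breath <- function(n) 0.3 * mk_band(n) * sin(pi * (1:n) / n)
  one <- c(gap(1.3 * rate), breath(0.8 * rate), gap(0.15 * rate),
           breath(0.8 * rate), gap(1.3 * rate))
  sig <- audio_signal(one, rate)
  segs <- segment_breaths(sig, sp)
  expect_equal(nrow(segs), 1)   # 0.15 s < min_gap_s: one merged breath
  # concatenation = union of individual segmentations (offset-adjusted)
  rec_a <- synthesize_recording(toy_synth_spec(71))
  rec_b <- synthesize_recording(toy_synth_spec(72, burst_rate = 0))
  seg_a <- segment_breaths(rec_a$audio, sp)
  seg_b <- segment_breaths(rec_b$audio, sp)
  cat_sig <- audio_signal(c(rec_a$audio$samples, rec_b$audio$samples), rate)
  seg_cat <- segment_breaths(cat_sig, sp)
  offset <- length(rec_a$audio$samples)
  expect_equal(nrow(seg_cat), nrow(seg_a) + nrow(seg_b))
  got_b <- seg_cat[(nrow(seg_a) + 1):nrow(seg_cat), ]
  for (i in seq_len(nrow(seg_b)))
    expect_gte(jaccard_interval(c(got_b$start[i] - offset, got_b$end[i] - offset),
                                c(seg_b$start[i], seg_b$end[i])), 0.9)
})
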