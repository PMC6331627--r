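test_that("edge mask cancels row-constant structure and matches the oracle", {
  const <- matrix(5, 10, 10)
  expect_true(all(abs(convolve_mask_M(const)[4:7, 4:7]) < 1e-12))
  # horizontal stripes (pure-tone rows): zero interior response
  stripes <- matrix(rep(sin(1:12), 12), 12, 12)   # constant along time
  out <- convolve_mask_M(stripes)
  expect_true(all(abs(out[4:9, 4:9]) < 1e-10))
  set.seed(201)
  img <- matrix(rnorm(100), 10, 10)
  expect_equal(convolve_mask_M(img), oracle_conv2d(img, mask_M()),
               tolerance = 1e-12)
  expect_error(convolve_mask_M(matrix(1, 4, 4)), "6x6")
})

test_that("LoG kernel matches its formula, symmetry and centre value", {
  k_raw <- log_kernel(1, 7, mean_subtract = FALSE)
  expect_equal(k_raw[4, 4], 2)                      # 2 / sigma^2 at origin
  k9 <- log_kernel(1.5, 9, mean_subtract = FALSE)
  g <- seq(-4, 4)
  for (x in 1:9) for (y in 1:9) {
    r2 <- g[x]^2 + g[y]^2
    expect_equal(k9[y, x], -(r2 - 2 * 1.5^2) / 1.5^4 * exp(-r2 / (2 * 1.5^2)),
                 tolerance = 1e-12)
  }
  k <- log_kernel(1.2, 7)
  expect_equal(sum(k), 0, tolerance = 1e-12)
  expect_equal(k, k[7:1, ]); expect_equal(k, t(k))  # radial symmetry
  expect_error(log_kernel(1, 8), "odd")
})

test_that("LoG filtering suppresses constants, highlights columns, smooths noise", {
  interior <- apply_log(matrix(3, 20, 20))[5:16, 5:16]   # away from padding
  expect_true(all(abs(interior) < 1e-10))
  img <- matrix(0, 40, 40); img[5:35, 20] <- 10
  out <- apply_log(img, enhance_spec())
  col_mag <- mean(abs(out[10:30, 20]))
  bg_mag <- mean(abs(out[10:30, c(1:14, 26:40)]))
  expect_gt(col_mag, 10 * bg_mag)
  set.seed(202)
  noise <- matrix(rnorm(3600), 60, 60)
  v1 <- var(as.vector(apply_log(noise, enhance_spec(sigma = 1))))
  v2 <- var(as.vector(apply_log(noise, enhance_spec(sigma = 2))))
  expect_lt(v2, v1)
})

test_that("column statistics follow their definitions", {
  expect_identical(column_zcr(numeric(20)), 0L)
  expect_identical(column_zcr(rep(2, 20)), 0L)
  expect_identical(column_zcr(c(1, 0, 1, 0, 1)), 4L)  # each on/off step
  expect_identical(column_sbe(numeric(16)), 0)
  expect_identical(column_te(numeric(16)), 0)
  expect_equal(column_sbe(rep(1, 32), 32), 32)
  expect_equal(column_te(rep(1, 32)), 32)
  set.seed(203)
  x <- rnorm(64)
  expect_equal(column_te(x), sum(x^2), tolerance = 1e-12)
  w <- 16
  oracle_sbe <- max(vapply(1:(64 - w + 1), function(i)
    sum(x[i:(i + w - 1)]^2), 1))
  expect_equal(column_sbe(x, w), oracle_sbe, tolerance = 1e-12)
})

# a dashed vertical line (three energetic dash blocks, few sign transitions)
# on a quiet background, as the LoG stage emits it for a sputum burst
dashed_line_image <- function(seed, n = 64, col = 30, gain = 8) {
  set.seed(seed)
  img <- matrix(rnorm(n * n, sd = 0.15), n, n)
  o <- sample(-3:3, 1)
  for (blk in list(10:18, 28:36, 46:54)) img[blk + o, col] <- gain
  img
}

test_that("triple-threshold strengthening fills dashed lines and is idempotent", {
  img <- dashed_line_image(204)
  sp <- enhance_spec()
  out <- strengthen_texture(img, sp)
  expect_true(30 %in% out$flagged_columns)
  # flagged column becomes one continuous run at the fill value
  col <- out$values[, 30]
  run <- range(which(col == max(abs(img))))
  expect_true(all(col[run[1]:run[2]] == max(abs(img))))
  # unflagged columns untouched
  untouched <- setdiff(1:64, out$flagged_columns)
  expect_identical(out$values[, untouched], img[, untouched])
  # idempotence on 5 seeded cases
  for (s in 205:209) {
    im <- dashed_line_image(s)
    once <- strengthen_texture(im, sp)
    twice <- strengthen_texture(once$values, sp)
    expect_identical(twice$values, once$values)
    expect_identical(twice$flagged_columns, once$flagged_columns)
  }
})

test_that("strengthening leaves featureless images alone", {
  zero <- matrix(0, 32, 32)
  out <- strengthen_texture(zero, enhance_spec())
  expect_identical(out$values, zero)
  expect_length(out$flagged_columns, 0)
  # white noise: few columns flagged across seeds
  fracs <- vapply(1:20, function(s) {
    set.seed(s)
    img <- matrix(rnorm(64 * 64), 64, 64)
    length(strengthen_texture(img, enhance_spec())$flagged_columns) / 64
  }, 1)
  expect_lt(mean(fracs), 0.10)
})

test_that("adding a burst never removes flags at fixed absolute thresholds", {
  sp0 <- enhance_spec()
  for (s in 210:214) {
    img <- dashed_line_image(s)
    sbe <- apply(img, 2, column_sbe, window = sp0$sbe_window)
    te <- apply(img, 2, column_te)
    sp_abs <- enhance_spec(sbe_absolute = quantile(sbe, 0.75, names = FALSE),
                           te_absolute = quantile(te, 0.75, names = FALSE))
    before <- strengthen_texture(img, sp_abs)$flagged_columns
    img2 <- img
    img2[10:50, 45] <- 9                      # extra burst column
    after <- strengthen_texture(img2, sp_abs)$flagged_columns
    expect_true(all(before %in% after))
  }
})

test_that("sputum breaths yield more flagged columns than clean breaths", {
  flags_of <- function(seed, burst_rate) {
    rec <- synthesize_recording(toy_synth_spec(seed, burst_rate,
                                               n_cycles = 1))
    tr <- rec$truth_segments[1, ]
    x <- segment_samples(rec$audio, tr$start, tr$end)
    spg <- spectrogram(x, stft_spec(), rate = rec$audio$rate)
    length(enhance_spectrogram(spg)$flagged_columns)
  }
  with_f <- vapply(1:50, flags_of, 1, burst_rate = 4)
  without_f <- vapply(51:100, flags_of, 1, burst_rate = 0)
  p <- wilcox.test(with_f, without_f, alternative = "greater")$p.value
  expect_lt(p, 0.01)
})
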