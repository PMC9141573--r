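test_that("resampling yields exactly 1920 samples with spectra preserved", {
  expect_length(resample_to_64(rnorm(3000), 100), 1920)
  expect_length(resample_to_64(rnorm(3750), 125), 1920)
  expect_identical(resample_to_64(1:1920 * 1.0, 64), 1:1920 * 1.0)
  expect_error(resample_to_64(rnorm(30 * 50), 50), class = "somnet_rate_error")
  expect_error(resample_to_64(rnorm(100), 100), class = "somnet_shape_error")

  # a pure 10 Hz tone keeps its dominant frequency through decimation
  x <- sin(2 * pi * 10 * (0:2999) / 100)
  y <- resample_to_64(x, 100)
  p <- stats::spec.pgram(stats::ts(y, frequency = 64), plot = FALSE,
                         taper = 0)
  expect_lt(abs(p$freq[which.max(p$spec)] - 10), 0.25)
})

test_that("the short-time power grid is 129 x 14 over 0-32 Hz", {
  g <- stft_power(rnorm(1920))
  expect_equal(dim(unclass(g)), c(129, 14))
  expect_equal(attr(g, "bin_hz"), 0.25)
  expect_error(stft_power(rnorm(1000)), class = "somnet_shape_error")

  # zero signal sits at the dB floor
  g0 <- stft_power(numeric(1920))
  expect_true(all(g0 == -120))

  # a 13 Hz tone peaks at bin 52 (0-based): 13 / 0.25 Hz
  g13 <- stft_power(sin(2 * pi * 13 * (0:1919) / 64))
  expect_true(all(apply(unclass(g13), 2, which.max) - 1 == 52))
})

test_that("stft_power agrees with a naive direct DFT", {
  set.seed(99)
  for (i in 1:3) {
    x <- rnorm(1920)
    ours <- unclass(stft_power(x))
    ref <- naive_stft_db(x)
    keep <- ref > -100            # compare above the floor region
    expect_lt(max(abs(ours[keep] - ref[keep])), 1e-6)
  }
})

test_that("rasterization produces the 100 x 80 dot colormapped image", {
  g <- stft_power(rnorm(1920))
  img <- rasterize(g)
  expect_equal(dim(img), c(100, 80, 3))
  expect_true(all(img >= 0 & img <= 1))

  # degenerate all-equal grid maps every pixel to colormap entry 0
  flat <- rasterize(matrix(5, 129, 14))
  lut <- viridis_lut()
  expect_true(all(abs(sweep(matrix(flat, ncol = 3), 2, lut[1, ])) < 1e-12))
})

test_that("cropping keeps rows [14, 90) and columns [11, 71)", {
  img <- array(runif(100 * 80 * 3), c(100, 80, 3))
  out <- crop_spectrogram(img)
  expect_equal(dim(out), c(76, 60, 3))
  # corner identity: input pixel (row 14, col 11), 0-based, is output (0, 0)
  expect_identical(out[1, 1, ], img[15, 12, ])
  expect_error(crop_spectrogram(array(0, c(80, 100, 3))),
               class = "somnet_shape_error")
})

test_that("epoch images are 76 x 60 x 3 for all supported source rates", {
  set.seed(5)
  for (rate in c(100, 125, 64)) {
    img <- epoch_to_image(rnorm(30 * rate), rate)
    expect_equal(dim(img), c(76, 60, 3))
    expect_true(all(img >= 0 & img <= 1))
  }
})

test_that("the pipeline is deterministic and amplitude-invariant", {
  set.seed(11)
  x <- rnorm(3000)
  expect_identical(epoch_to_image(x, 100), epoch_to_image(x, 100))
  for (a in c(0.1, 10, 1000)) {
    expect_lt(max(abs(epoch_to_image(a * x, 100) - epoch_to_image(x, 100))),
              1e-9)
  }
})

test_that("pure tones localize to the expected image rows within 1 Hz", {
  for (f in c(5, 13, 25)) {
    x <- sin(2 * pi * f * (0:2999) / 100)
    img <- epoch_to_image(x, 100, grayscale = TRUE)
    peak_row <- which.max(rowMeans(img[, , 1]))
    # invert the resize + crop geometry: row -> frequency
    freq_at <- function(r) 32 * (1 - (r - 1 + 14) / 99)
    expect_lt(abs(freq_at(peak_row) - f), 1)
  }
})

test_that("N2 spindle bursts light up the 12-14 Hz rows at burst times", {
  x <- synth_epoch("N2", 100, seed = 21)
  bursts <- attr(x, "bursts")
  img <- epoch_to_image(as.numeric(x), 100, grayscale = TRUE)
  rows <- floor(image_row_for_freq(14)):ceiling(image_row_for_freq(12))
  cols_of <- function(t0, t1) {
    cl <- floor(image_col_for_time(t0)):ceiling(image_col_for_time(t1))
    cl[cl >= 1 & cl <= 60]
  }
  burst_cols <- unique(unlist(lapply(seq_len(nrow(bursts)), function(i) {
    cols_of(bursts[i, "start"], bursts[i, "end"])
  })))
  other_cols <- setdiff(seq_len(60), burst_cols)
  expect_gt(length(burst_cols), 0)   # this seed's bursts survive the crop
  expect_gt(mean(img[rows, burst_cols, 1]), mean(img[rows, other_cols, 1]))
})

test_that("epoch batches convert to aligned image tensors", {
  ib <- small_images()
  expect_equal(dim(ib$images), c(76, 60, 3, nrow(small_epochs())))
  expect_equal(nrow(ib$meta), nrow(small_epochs()))
  expect_equal(as.character(ib$meta$stage),
               as.character(small_epochs()$stage))
})
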