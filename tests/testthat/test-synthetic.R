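test_that("hypnogram sampling is a reproducible Markov chain", {
  tm <- default_transition_model()
  expect_true(all(abs(rowSums(tm$P) - 1) < 1e-9))

  h1 <- sample_hypnogram(200, tm, seed = 5)
  h2 <- sample_hypnogram(200, tm, seed = 5)
  expect_identical(h1, h2)
  expect_false(identical(h1, sample_hypnogram(200, tm, seed = 6)))

  # absorbing chain: identity rows never leave the initial state
  absorbing <- list(P = diag(5), init = c(1, 0, 0, 0, 0))
  expect_true(all(sample_hypnogram(50, absorbing, seed = 1) == "W"))

  bad <- tm
  bad$P[1, 1] <- 2
  expect_error(sample_hypnogram(10, bad), class = "somnet_value_error")
})

test_that("empirical transition frequencies match the configured matrix", {
  tm <- default_transition_model()
  h <- as.integer(sample_hypnogram(100000, tm, seed = 42))
  from <- h[-length(h)]
  to <- h[-1]
  for (i in 1:5) {
    n_i <- sum(from == i)
    for (j in 1:5) {
      p <- tm$P[i, j]
      se <- sqrt(p * (1 - p) / n_i)
      expect_lt(abs(mean(to[from == i] == j) - p), 3 * se + 1e-12,
                label = sprintf("transition %d->%d", i, j))
    }
  }
})

psd_band_fraction <- function(x, lo, hi, rate = 100) {
  p <- stats::spec.pgram(stats::ts(as.numeric(x), frequency = rate),
                         plot = FALSE, taper = 0, spans = 5)
  sum(p$spec[p$freq >= lo & p$freq <= hi]) / sum(p$spec)
}

test_that("each stage's recipe places its power in the hallmark band", {
  # N3: slow 0.5-2 Hz activity dominates every other recipe band
  x3 <- synth_epoch("N3", 100, seed = 1)
  f_slow <- psd_band_fraction(x3, 0.5, 2)
  for (band in list(c(4, 7), c(8, 13), c(12, 14), c(4, 8))) {
    expect_gt(f_slow, psd_band_fraction(x3, band[1], band[2]))
  }
  # N1 and REM center on theta; W on alpha
  expect_gt(psd_band_fraction(synth_epoch("N1", 100, seed = 2), 4, 7),
            psd_band_fraction(synth_epoch("N1", 100, seed = 2), 8, 13))
  xw <- synth_epoch("W", 100, seed = 3)
  expect_gt(psd_band_fraction(xw, 8, 13), psd_band_fraction(xw, 4, 7))
  expect_gt(psd_band_fraction(xw, 8, 13), psd_band_fraction(xw, 0.5, 2))
  # N2 spindle band outshines slow and alpha-adjacent bands
  x2 <- synth_epoch("N2", 100, seed = 4)
  expect_gt(psd_band_fraction(x2, 12, 14), psd_band_fraction(x2, 8, 11))
  expect_gt(psd_band_fraction(x2, 12, 14), psd_band_fraction(x2, 0.5, 2))

  expect_error(synth_epoch("S9"), class = "somnet_label_error")
})

test_that("Wake alpha is active for more than half the epoch", {
  for (seed in 1:5) {
    x <- synth_epoch("W", 100, seed = seed)
    # envelope of the 8-13 Hz band via the analytic spectrogram grid
    g <- unclass(stft_power(resample_to_64(as.numeric(x), 100)))
    alpha_rows <- which(seq(0, 32, by = 0.25) >= 8 &
                          seq(0, 32, by = 0.25) <= 13)
    band_db <- apply(g[alpha_rows, ], 2, max)
    active <- band_db > (max(band_db) - 10)
    expect_gt(mean(active), 0.5)
  }
})

test_that("epochs are deterministic given a seed", {
  expect_identical(synth_epoch("N2", 100, seed = 9),
                   synth_epoch("N2", 100, seed = 9))
  expect_identical(generate_dataset(2, 5, seed = 3),
                   generate_dataset(2, 5, seed = 3))
})

test_that("generated datasets have consistent sizes and labels", {
  ds <- generate_dataset(4, 20, rate = 100, seed = 8)
  expect_equal(nrow(ds), 4)
  for (i in 1:4) {
    expect_length(ds$hypnogram[[i]], 20)
    expect_length(ds$recording[[i]]$samples, 20 * 3000)
  }
  ep <- dataset_to_epochs(ds)
  expect_equal(nrow(ep), 80)
  expect_equal(attr(ep, "sample_rate"), 100)
  expect_true(all(vapply(ep$samples, length, numeric(1)) == 3000))
})

test_that("simulated fixtures survive the EDF round trip into images", {
  ds <- generate_dataset(2, 10, seed = 12)
  dir <- withr::local_tempdir()
  paths <- simulate_dataset(ds, dir)
  ep_all <- purrr::pmap_dfr(paths, function(subject_id, edf, hypnogram) {
    rec <- load_recording(edf, "EEG Fpz-Cz")
    segment_epochs(rec, read_hypnogram_csv(hypnogram))
  })
  expect_equal(nrow(ep_all), 20)
  expect_equal(as.character(ep_all$stage),
               as.character(dataset_to_epochs(ds)$stage))
  attr(ep_all, "sample_rate") <- 100
  ib <- epochs_to_images(ep_all)
  expect_equal(dim(ib$images), c(76, 60, 3, 20))
  # EDF 16-bit quantization perturbs pixels only marginally
  ib0 <- epochs_to_images(dataset_to_epochs(ds))
  expect_lt(mean(abs(ib$images - ib0$images)), 0.02)
  expect_gt(stats::cor(as.numeric(ib$images), as.numeric(ib0$images)), 0.99)
})
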