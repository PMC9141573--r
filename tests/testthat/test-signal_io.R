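test_that("stage mapping follows the R&K to AASM rules", {
  m <- map_stage(c("W", "S1", "S2", "S3", "S4", "R"))
  expect_equal(as.character(m$stage), c("W", "N1", "N2", "N3", "N3", "REM"))
  expect_false(any(m$excluded))

  # EDF+ annotation spellings map identically
  m2 <- map_stage(c("Sleep stage W", "Sleep stage 4", "Sleep stage R"))
  expect_equal(as.character(m2$stage), c("W", "N3", "REM"))

  excl <- map_stage(c("Movement time", "Sleep stage ?"))
  expect_true(all(excl$excluded))
  expect_true(all(is.na(excl$stage)))

  expect_error(map_stage("S9"), class = "somnet_label_error",
               regexp = "S9")
})

test_that("EDF write/read round-trips samples within 16-bit quantization", {
  rate <- 100
  x <- 50 * sin(2 * pi * 1.3 * (0:(60 * rate - 1)) / rate) + rnorm(60 * rate)
  path <- withr::local_tempfile(fileext = ".edf")
  write_edf(path, list("EEG Fpz-Cz" = list(samples = x, sample_rate = rate)),
            physical_range = 200)
  edf <- read_edf(path)
  expect_equal(edf$signals$label, "EEG Fpz-Cz")
  expect_equal(edf$signals$sample_rate, rate)
  expect_equal(edf$signals$n_samples, 6000)
  quant <- 2 * 200 / 65535
  expect_lt(max(abs(edf$data[["EEG Fpz-Cz"]] - x)), quant)
})

test_that("load_recording returns the named channel and errors helpfully", {
  path <- withr::local_tempfile(fileext = ".edf")
  x <- rnorm(60 * 100)
  write_edf(path, list("EEG Fpz-Cz" = list(samples = x, sample_rate = 100)),
            subject_id = "SY01")
  rec <- load_recording(path, "EEG Fpz-Cz")
  expect_s3_class(rec, "somnet_recording")
  expect_length(rec$samples, 6000)
  expect_equal(rec$sample_rate, 100)
  expect_equal(rec$subject_id, "SY01")

  err <- expect_error(load_recording(path, "EEG Pz-Oz"),
                      class = "somnet_channel_error")
  expect_match(conditionMessage(err), "EEG Fpz-Cz")

  # SHHS-style sampling rate
  p2 <- withr::local_tempfile(fileext = ".edf")
  write_edf(p2, list("EEG C4-A1" = list(samples = rnorm(300 * 125),
                                        sample_rate = 125)))
  expect_length(load_recording(p2, "EEG C4-A1")$samples, 37500)
})

test_that("EDF+ annotations round-trip through the TAL channel", {
  path <- withr::local_tempfile(fileext = ".edf")
  ann <- tibble::tibble(onset_s = c(0, 60, 90), duration_s = c(60, 30, 30),
                        stage = c("W", "Movement time", "S1"))
  write_edf(path, list("EEG Fpz-Cz" = list(samples = rnorm(120 * 100),
                                           sample_rate = 100)),
            annotations = ann)
  edf <- read_edf(path)
  expect_equal(edf$annotations$onset_s, c(0, 60, 90))
  expect_equal(edf$annotations$duration_s, c(60, 30, 30))
  expect_equal(edf$annotations$text, c("W", "Movement time", "S1"))
})

test_that("segment_epochs expands annotations into labelled 30-s epochs", {
  rate <- 100
  rec <- new_recording("A", "EEG Fpz-Cz", rate, rnorm(600 * rate))
  ann <- tibble::tibble(onset_s = 0, duration_s = 600, stage = "S2")
  ep <- segment_epochs(rec, ann)
  expect_equal(nrow(ep), 20)
  expect_true(all(vapply(ep$samples, length, numeric(1)) == 3000))
  expect_true(all(ep$stage == "N2"))
  expect_equal(ep$epoch_index, 0:19)
})

test_that("segment_epochs drops excluded labels and flags bad durations", {
  rec <- new_recording("A", "EEG Fpz-Cz", 100, rnorm(120 * 100))
  ann <- tibble::tibble(onset_s = c(0, 60, 90), duration_s = c(60, 30, 30),
                        stage = c("W", "Movement time", "S1"))
  ep <- segment_epochs(rec, ann)
  expect_equal(nrow(ep), 3)
  expect_equal(as.character(ep$stage), c("W", "W", "N1"))
  counts <- attr(ep, "slot_counts")
  expect_equal(unname(counts["excluded"]), 1)
  # conservation: emitted + excluded + truncated == annotated slots
  expect_equal(sum(counts), 4)

  expect_error(
    segment_epochs(rec, tibble::tibble(onset_s = 0, duration_s = 45,
                                       stage = "W")),
    class = "somnet_annotation_error"
  )
})

test_that("annotations past the signal end are truncated with a warning", {
  rec <- new_recording("A", "EEG Fpz-Cz", 100, rnorm(60 * 100))
  ann <- tibble::tibble(onset_s = 0, duration_s = 90, stage = "W")
  expect_warning(ep <- segment_epochs(rec, ann), "past the end")
  expect_equal(nrow(ep), 2)
  counts <- attr(ep, "slot_counts")
  expect_equal(unname(counts["truncated"]), 1)
  expect_equal(sum(counts), 3)
})

test_that("hypnogram CSV dialect round-trips", {
  ann <- tibble::tibble(onset_s = c(0, 30), duration_s = c(30, 30),
                        stage = c("W", "N2"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_hypnogram_csv(ann, path)
  expect_equal(read_hypnogram_csv(path), ann)
})
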