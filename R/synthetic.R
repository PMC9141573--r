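# Synthetic sleep-EEG generator. Each stage has an oscillatory recipe
# reflecting its scoring hallmarks: dominant alpha (8-13 Hz) for Wake,
# low-amplitude mixed-frequency 4-7 Hz activity for N1, a theta background
# with 12-14 Hz spindle bursts for N2, high-amplitude 0.5-2 Hz slow waves
# for N3, and mixed 4-8 Hz low-amplitude activity for REM. N1 and REM are
# deliberately spectrally adjacent — disambiguating them requires the
# hypnogram context, which is what the sequence model exploits. Hypnograms
# are sampled from a first-order Markov chain whose default transition
# matrix is ordinally constrained by the transition regularities of real
# sleep (Wake moves to N1 far more often than to REM; N1 feeds N2 while
# REM rarely does).

# base amplitude unit in microvolts; recipe amplitudes are relative to it
.amp_uV <- 20

#' Stage-conditioned spectral recipes
#'
#' Each recipe lists oscillatory components (frequency band, relative
#' amplitude, duty = fraction of the epoch the component is active) plus a
#' relative broadband-noise level. N2 additionally carries a spindle
#' component realized as 2-4 discrete 0.5-1.5 s bursts at 12-14 Hz.
#'
#' @return Named list of recipes, one per stage.
#' @export
stage_recipes <- function() {
  list(
    W = list(components = list(c(lo = 8, hi = 13, amp = 1.0, duty = 0.85)),
             noise_sd = 0.40),
    N1 = list(components = list(c(lo = 4, hi = 7, amp = 0.8, duty = 0.85)),
              noise_sd = 0.45),
    N2 = list(components = list(c(lo = 4, hi = 7, amp = 0.5, duty = 0.9)),
              spindles = c(lo = 12, hi = 14, amp = 1.3),
              noise_sd = 0.40),
    N3 = list(components = list(c(lo = 0.5, hi = 2, amp = 2.5, duty = 0.9)),
              noise_sd = 0.40),
    REM = list(components = list(c(lo = 4, hi = 8, amp = 0.75, duty = 0.85)),
               noise_sd = 0.45)
  )
}

#' Default hypnogram transition model
#'
#' A row-stochastic 5 x 5 matrix over (W, N1, N2, N3, REM) plus an initial
#' distribution (nights start awake). The entries are generator defaults,
#' not estimates; their ordering encodes the empirical regularities the
#' sequence model can exploit: `P(W->REM) << P(W->N1)` and
#' `P(N1->N2) >> P(REM->N2)`.
#'
#' @return List with `P` (transition matrix) and `init` (initial
#'   distribution).
#' @export
default_transition_model <- function() {
  P <- matrix(c(
    # W     N1     N2     N3     REM
    0.880, 0.105, 0.005, 0.000, 0.010,   # from W
    0.100, 0.550, 0.320, 0.005, 0.025,   # from N1
    0.020, 0.030, 0.850, 0.060, 0.040,   # from N2
    0.010, 0.005, 0.095, 0.880, 0.010,   # from N3
    0.050, 0.050, 0.020, 0.005, 0.875    # from REM
  ), 5, 5, byrow = TRUE,
  dimnames = list(stage_levels(), stage_levels()))
  list(P = P, init = c(W = 1, N1 = 0, N2 = 0, N3 = 0, REM = 0))
}

#' Sample a Markov hypnogram
#'
#' @param n_epochs number of 30-s epochs (>= 1).
#' @param tm transition model from [default_transition_model()] (list with
#'   `P` and `init`).
#' @param seed RNG seed; the sequence is a deterministic function of it.
#' @return Factor vector of length `n_epochs` over [stage_levels()].
#' @export
sample_hypnogram <- function(n_epochs, tm = default_transition_model(),
                             seed = 42) {
  stopifnot(n_epochs >= 1)
  P <- tm$P
  if (any(P < 0) || any(abs(rowSums(P) - 1) > 1e-9)) {
    abort("Transition matrix must be row-stochastic (rows sum to 1, entries >= 0).",
          class = "somnet_value_error")
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  draw <- function(p) sample.int(5L, 1L, prob = p)
  s <- integer(n_epochs)
  s[1] <- draw(tm$init)
  for (t in seq_len(n_epochs - 1L)) s[t + 1L] <- draw(P[s[t], ])
  stage_factor(stage_levels()[s])
}

# one band-limited component: a sparse sum of sinusoids restricted to the
# band, gated by a smooth contiguous duty window at a random position
.band_component <- function(n, rate, lo, hi, amp, duty) {
  t <- (seq_len(n) - 1) / rate
  freqs <- runif(3, lo, hi)
  phases <- runif(3, 0, 2 * pi)
  x <- rowSums(vapply(seq_len(3), function(i) {
    sin(2 * pi * freqs[i] * t + phases[i])
  }, numeric(n))) / sqrt(3)
  if (duty < 1) {
    span <- 30 * duty
    start <- runif(1, 0, 30 - span)
    env <- .smooth_window(t, start, start + span, ramp = 0.25)
    x <- x * env
  }
  amp * x
}

.smooth_window <- function(t, a, b, ramp = 0.25) {
  up <- pmin(pmax((t - a) / ramp, 0), 1)
  down <- pmin(pmax((b - t) / ramp, 0), 1)
  0.5 * (1 - cos(pi * up)) * 0.5 * (1 - cos(pi * down))
}

#' Synthesize one 30-s epoch of a given stage
#'
#' Sums the stage recipe's band-limited oscillations (with, for N2, 2-4
#' spindle bursts of 0.5-1.5 s at 12-14 Hz) and adds Gaussian broadband
#' noise. Deterministic given `seed`.
#'
#' @param stage one of [stage_levels()].
#' @param rate sampling rate in Hz (default 100).
#' @param seed RNG seed; if `NULL`, draws from the current RNG stream.
#' @param amplitude overall scale factor (emulating inter-subject
#'   amplitude variability).
#' @return Numeric vector of `30 * rate` microvolt samples. For N2, the
#'   burst intervals are attached as attribute `"bursts"` (matrix with
#'   columns `start`, `end`, seconds).
#' @export
synth_epoch <- function(stage, rate = 100, seed = NULL, amplitude = 1) {
  stage <- as.character(stage)
  rec <- stage_recipes()[[stage]]
  if (is.null(rec)) {
    abort(sprintf("No recipe for stage %s.", sQuote(stage)),
          class = "somnet_label_error")
  }
  if (!is.null(seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
  }
  n <- as.integer(30 * rate)
  t <- (seq_len(n) - 1) / rate
  x <- numeric(n)
  for (cp in rec$components) {
    x <- x + .band_component(n, rate, cp["lo"], cp["hi"], cp["amp"], cp["duty"])
  }
  bursts <- NULL
  if (!is.null(rec$spindles)) {
    sp <- rec$spindles
    k <- sample(2:4, 1)
    starts <- sort(runif(k, 0.5, 29.5 - 1.5))
    # nudge bursts apart so they stay distinct events
    for (i in seq_len(k - 1)) {
      if (starts[i + 1] - starts[i] < 2) starts[i + 1] <- starts[i] + 2
    }
    durs <- runif(k, 0.5, 1.5)
    ends <- pmin(starts + durs, 29.9)
    for (i in seq_len(k)) {
      f <- runif(1, sp["lo"], sp["hi"])
      ph <- runif(1, 0, 2 * pi)
      x <- x + sp["amp"] * sin(2 * pi * f * t + ph) *
        .smooth_window(t, starts[i], ends[i], ramp = 0.15)
    }
    bursts <- cbind(start = starts, end = ends)
  }
  x <- .amp_uV * amplitude * (x + rnorm(n, sd = rec$noise_sd))
  if (!is.null(bursts)) attr(x, "bursts") <- bursts
  x
}

#' Generate a labelled synthetic dataset
#'
#' Samples one Markov hypnogram per subject, synthesizes the matching
#' 30-s epochs, and concatenates them into a continuous recording. A
#' per-subject amplitude factor drawn from `amp_range` emulates
#' inter-subject variability. Fully reproducible given `seed`.
#'
#' @param n_subjects number of subjects.
#' @param epochs_per_subject epochs (30 s each) per subject.
#' @param rate sampling rate in Hz.
#' @param seed master seed.
#' @param tm transition model (see [default_transition_model()]).
#' @param amp_range range of per-subject amplitude factors.
#' @return A tibble with one row per subject: `subject_id`, `amplitude`,
#'   `hypnogram` (list of stage factors), `recording` (list of
#'   `somnet_recording`).
#' @export
#' @examples
#' ds <- generate_dataset(2, 10, seed = 1)
#' dataset_to_epochs(ds)
generate_dataset <- function(n_subjects, epochs_per_subject, rate = 100,
                             seed = 42, tm = default_transition_model(),
                             amp_range = c(0.8, 1.25)) {
  stopifnot(n_subjects >= 1, epochs_per_subject >= 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  subjects <- sprintf("S%02d", seq_len(n_subjects))
  rows <- lapply(seq_len(n_subjects), function(s) {
    hyp <- sample_hypnogram(epochs_per_subject, tm,
                            seed = sample.int(.Machine$integer.max, 1))
    amp <- runif(1, amp_range[1], amp_range[2])
    sig <- unlist(lapply(as.character(hyp), function(st) {
      as.numeric(synth_epoch(st, rate, seed = NULL, amplitude = amp))
    }))
    tibble::tibble(
      subject_id = subjects[s], amplitude = amp,
      hypnogram = list(hyp),
      recording = list(new_recording(subjects[s], "EEG Fpz-Cz", rate, sig))
    )
  })
  dplyr::bind_rows(rows)
}

#' Flatten a synthetic dataset to an epoch table
#'
#' Produces the same shape as [segment_epochs()]: one row per epoch with
#' `subject_id`, `epoch_index`, `stage` and `samples`, plus the
#' `sample_rate` attribute, ready for [epochs_to_images()].
#'
#' @param dataset output of [generate_dataset()].
#' @return Epoch tibble.
#' @export
dataset_to_epochs <- function(dataset) {
  rate <- dataset$recording[[1]]$sample_rate
  spp <- as.integer(30 * rate)
  out <- purrr::pmap_dfr(dataset, function(subject_id, hypnogram, recording,
                                           ...) {
    n <- length(hypnogram)
    tibble::tibble(
      subject_id = subject_id,
      epoch_index = seq_len(n) - 1L,
      onset_s = 30 * (seq_len(n) - 1),
      stage = stage_factor(hypnogram),
      samples = lapply(seq_len(n) - 1L, function(e) {
        recording$samples[e * spp + seq_len(spp)]
      })
    )
  })
  attr(out, "sample_rate") <- rate
  out
}

#' Write a synthetic dataset as EDF + hypnogram-CSV fixtures
#'
#' One EDF file (channel `"EEG Fpz-Cz"`) and one `*_hypnogram.csv`
#' per subject, consumable by [load_recording()] and
#' [read_hypnogram_csv()].
#'
#' @param dataset output of [generate_dataset()].
#' @param dir output directory (created if missing).
#' @return Tibble of written paths, invisibly.
#' @export
simulate_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- purrr::pmap_dfr(dataset, function(subject_id, hypnogram, recording,
                                             ...) {
    edf <- file.path(dir, paste0(subject_id, ".edf"))
    csv <- file.path(dir, paste0(subject_id, "_hypnogram.csv"))
    ann <- tibble::tibble(
      onset_s = 30 * (seq_along(hypnogram) - 1),
      duration_s = 30,
      stage = as.character(hypnogram)
    )
    write_edf(edf, setNames(list(list(samples = recording$samples,
                                      sample_rate = recording$sample_rate)),
                            recording$channel),
              annotations = ann, subject_id = subject_id)
    write_hypnogram_csv(ann, csv)
    tibble::tibble(subject_id = subject_id, edf = edf, hypnogram = csv)
  })
  invisible(paths)
}
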