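# Shared fixtures built in code. Heavy objects are cached per test run so
# several test files can reuse them without regenerating.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}

# small labelled synthetic dataset (2 subjects x 12 epochs at 100 Hz)
small_epochs <- function() {
  cached("small_epochs", dataset_to_epochs(generate_dataset(2, 12, seed = 7)))
}

small_images <- function() {
  cached("small_images", epochs_to_images(small_epochs()))
}

# fixture confusion matrices from the published single-channel EEG
# sleep-staging benchmarks (Sleep-EDFX-8/-20/-78, SHHS)
benchmark_cm <- function(name) {
  read_confusion_csv(system.file("extdata",
                                 paste0("confusion_", name, ".csv"),
                                 package = "somnet"))
}

# independent naive discrete Fourier transform power (dB, no floor) for the
# STFT oracle tests
naive_stft_db <- function(x, nfft = 256, hop = 128) {
  w <- 0.5 * (1 - cos(2 * pi * (0:(nfft - 1)) / (nfft - 1)))
  n_frames <- (length(x) - nfft) %/% hop + 1
  k <- 0:(nfft / 2)
  out <- matrix(0, length(k), n_frames)
  for (fr in seq_len(n_frames)) {
    seg <- x[(fr - 1) * hop + seq_len(nfft)] * w
    for (ki in seq_along(k)) {
      ph <- -2 * pi * k[ki] * (0:(nfft - 1)) / nfft
      out[ki, fr] <- Mod(sum(seg * complex(argument = ph)))^2
    }
  }
  10 * log10(out)
}

# acceptance-scale synthetic study: 20 subjects x 100 epochs, subjects
# S01-S16 train / S17-S20 test
acceptance_split <- function() {
  cached("acceptance_split", {
    ds <- generate_dataset(20, 100, seed = 42)
    ib <- epochs_to_images(dataset_to_epochs(ds))
    subj <- sprintf("S%02d", 1:20)
    tr <- which(ib$meta$subject_id %in% subj[1:16])
    te <- which(ib$meta$subject_id %in% subj[17:20])
    list(
      train = list(images = ib$images[, , , tr, drop = FALSE],
                   meta = ib$meta[tr, ]),
      test = list(images = ib$images[, , , te, drop = FALSE],
                  meta = ib$meta[te, ])
    )
  })
}

# trained fits on the acceptance split, cached by (lstm layers, seed, passes)
acceptance_fit <- function(lstm_layers, seed, passes) {
  key <- sprintf("fit_%d_%d_%d", lstm_layers, seed, passes)
  cached(key, {
    sp <- acceptance_split()
    suppressWarnings(train_fold(
      sp$train, sp$test,
      train_config(passes = passes, eval_every = 3, lr = 1e-3, seed = seed),
      model_config(lstm_layers = lstm_layers)
    ))
  })
}
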