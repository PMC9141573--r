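# Recording and epoch handling: load a named channel from an EDF file,
# expand stage annotations to 30-s slots, and segment the signal into
# labelled epochs ready for spectrogram conversion.

#' Load one EEG channel from an EDF/EDF+ recording
#'
#' @param path an EDF or EDF+ file.
#' @param channel signal label to extract (e.g. `"EEG Fpz-Cz"`); all other
#'   channels are ignored.
#' @return A `somnet_recording`: list with `subject_id`, `channel`,
#'   `sample_rate` (Hz), `samples` (microvolts) and `start_time` (seconds,
#'   0 for continuous files).
#' @export
load_recording <- function(path, channel) {
  edf <- read_edf(path)
  if (!channel %in% edf$signals$label) {
    abort(sprintf(
      "Channel %s not found in %s. Available channels: %s",
      sQuote(channel), path,
      paste(sQuote(edf$signals$label), collapse = ", ")
    ), class = "somnet_channel_error")
  }
  rate <- edf$signals$sample_rate[edf$signals$label == channel]
  new_recording(edf$subject_id, channel, rate, edf$data[[channel]])
}

#' @rdname load_recording
#' @param subject_id,sample_rate,samples,start_time recording fields; used to
#'   build a recording directly (e.g. from the synthetic generator).
#' @export
new_recording <- function(subject_id, channel, sample_rate, samples,
                          start_time = 0) {
  stopifnot(sample_rate > 0)
  structure(
    list(subject_id = subject_id, channel = channel,
         sample_rate = sample_rate, samples = as.numeric(samples),
         start_time = start_time),
    class = "somnet_recording"
  )
}

#' @export
print.somnet_recording <- function(x, ...) {
  cat(sprintf("<somnet_recording> subject %s, channel %s: %d samples @ %g Hz (%.1f s)\n",
              x$subject_id, x$channel, length(x$samples), x$sample_rate,
              length(x$samples) / x$sample_rate))
  invisible(x)
}

#' Read or write the plain-text hypnogram dialect
#'
#' A three-column CSV (`onset_s,duration_s,stage`) used for fixtures and for
#' the outputs of [simulate_dataset()]. Durations must be multiples of 30 s.
#'
#' @param path CSV file path.
#' @return A tibble with columns `onset_s`, `duration_s`, `stage`.
#' @export
read_hypnogram_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("onset_s", "duration_s", "stage") %in% names(df)))
  tibble::as_tibble(df[, c("onset_s", "duration_s", "stage")])
}

#' @rdname read_hypnogram_csv
#' @param annotations tibble with `onset_s`, `duration_s`, `stage`.
#' @export
write_hypnogram_csv <- function(annotations, path) {
  utils::write.csv(
    as.data.frame(annotations)[, c("onset_s", "duration_s", "stage")],
    path, row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' Segment a recording into labelled 30-s epochs
#'
#' Expands stage annotations (which may span several 30-s slots) into
#' per-epoch labels, maps them to the AASM scheme via [map_stage()], drops
#' movement/unknown slots, and cuts the signal into epochs of exactly
#' `30 * sample_rate` samples. Epoch indices are 0-based slot positions, so
#' `onset_s = 30 * epoch_index`; indices of excluded slots are absent.
#'
#' @param rec a `somnet_recording` (see [load_recording()]).
#' @param annotations tibble with `onset_s`, `duration_s`, `stage`
#'   (non-overlapping, time-ordered; durations multiples of 30 s).
#' @param trim_wake_minutes if positive, leading/trailing Wake beyond this
#'   many minutes around the sleep period is discarded. Default 0: all
#'   annotated epochs are kept.
#' @return A tibble with columns `subject_id`, `epoch_index`, `onset_s`,
#'   `stage` (factor) and `samples` (list of numeric vectors), with
#'   attributes `sample_rate` and `slot_counts`
#'   (`emitted`/`excluded`/`truncated`, which sum to the annotated slots).
#' @export
segment_epochs <- function(rec, annotations, trim_wake_minutes = 0) {
  ann <- tibble::as_tibble(annotations)
  stopifnot(all(c("onset_s", "duration_s", "stage") %in% names(ann)))
  if (any(ann$duration_s %% 30 != 0 | ann$duration_s <= 0)) {
    abort("Annotation durations must be positive multiples of 30 s.",
          class = "somnet_annotation_error")
  }
  if (is.unsorted(ann$onset_s, strictly = TRUE) && nrow(ann) > 1) {
    abort("Annotations must be ordered by onset.",
          class = "somnet_annotation_error")
  }
  ends <- ann$onset_s + ann$duration_s
  if (nrow(ann) > 1 && any(ann$onset_s[-1] < ends[-nrow(ann)])) {
    abort("Annotations must not overlap.", class = "somnet_annotation_error")
  }

  # expand to 30-s slots, half-open [onset, onset + 30)
  slots <- tidyr::uncount(ann, .data$duration_s / 30, .id = "slot") |>
    dplyr::mutate(onset_s = .data$onset_s + 30 * (.data$slot - 1)) |>
    dplyr::select("onset_s", "stage")
  mapped <- map_stage(slots$stage)
  slots$stage <- mapped$stage
  slots$excluded <- mapped$excluded

  rate <- rec$sample_rate
  spp <- 30 * rate
  n_total <- length(rec$samples)
  fits <- (slots$onset_s * rate + spp) <= n_total
  if (any(!fits)) {
    warn(sprintf("%d annotated slot(s) extend past the end of the signal; dropped.",
                 sum(!fits)))
  }

  counts <- c(
    emitted = sum(!slots$excluded & fits),
    excluded = sum(slots$excluded),
    truncated = sum(!slots$excluded & !fits)
  )
  keep <- slots[!slots$excluded & fits, ]
  out <- tibble::tibble(
    subject_id = rec$subject_id,
    epoch_index = as.integer(keep$onset_s %/% 30),
    onset_s = keep$onset_s,
    stage = stage_factor(keep$stage),
    samples = lapply(keep$onset_s, function(o) {
      rec$samples[o * rate + seq_len(spp)]
    })
  )

  if (trim_wake_minutes > 0 && any(out$stage != "W")) {
    sleep_idx <- range(which(out$stage != "W"))
    pad <- trim_wake_minutes * 2  # epochs of 30 s
    keep_rows <- seq(max(1, sleep_idx[1] - pad),
                     min(nrow(out), sleep_idx[2] + pad))
    out <- out[keep_rows, ]
  }

  attr(out, "sample_rate") <- rate
  attr(out, "slot_counts") <- counts
  out
}

#' Save or load an epoch/image container
#'
#' Batch containers (epoch tables, image tensors plus labels) are stored as
#' single-object RDS files — the package's array-container format.
#'
#' @param object any R object (epoch tibble, image batch list, ...).
#' @param path container path (conventionally `.rds`).
#' @return `read_container` returns the stored object.
#' @export
write_container <- function(object, path) {
  saveRDS(object, path)
  invisible(path)
}

#' @rdname write_container
#' @export
read_container <- function(path) readRDS(path)
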