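# Minimal EDF / EDF+ container support: 16-bit signals, ASCII headers, and
# the EDF+ "EDF Annotations" time-stamped annotation (TAL) channel. Covers
# what polysomnography sleep-staging needs: continuous single/multi-channel
# records with integer sampling rates and per-epoch stage annotations.

.edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = width, flag = "-")
}

.edf_num <- function(x, width) {
  s <- formatC(x, format = "fg", width = 1, digits = 8)
  s <- trimws(s)
  if (nchar(s) > width) s <- substr(s, 1, width)
  .edf_pad(s, width)
}

#' Write an EDF or EDF+ file
#'
#' Writes one or more continuous signals to a 16-bit EDF container with a
#' 1-second data-record size. When `annotations` are supplied the file is
#' written as EDF+C with an `"EDF Annotations"` channel holding one
#' time-stamped annotation per entry (all placed in the first data record).
#'
#' @param path output file path.
#' @param signals a named list; each element is a list with `samples`
#'   (numeric, microvolts) and `sample_rate` (integer Hz). All signals must
#'   span the same whole number of seconds.
#' @param annotations optional tibble/data.frame with columns `onset_s`,
#'   `duration_s`, `stage` (or `text`).
#' @param subject_id recorded in the patient-identification header field.
#' @param physical_range half-range in microvolts mapped onto the 16-bit
#'   digital span; defaults to the smallest power of ten covering the data.
#'   Round-tripping is exact up to this quantization step.
#' @return `path`, invisibly.
#' @export
write_edf <- function(path, signals, annotations = NULL,
                      subject_id = "X", physical_range = NULL) {
  stopifnot(is.list(signals), length(signals) > 0, !is.null(names(signals)))
  rates <- vapply(signals, function(s) s$sample_rate, numeric(1))
  lens <- vapply(signals, function(s) length(s$samples), numeric(1))
  if (any(rates <= 0 | rates != round(rates))) {
    abort("EDF writer requires positive integer sample rates.")
  }
  secs <- lens / rates
  if (length(unique(secs)) != 1 || secs[1] != round(secs[1])) {
    abort("All signals must span the same whole number of seconds.")
  }
  n_rec <- as.integer(secs[1])

  ann_bytes <- NULL
  if (!is.null(annotations)) {
    ann <- as.data.frame(annotations)
    txt_col <- if ("stage" %in% names(ann)) "stage" else "text"
    tal <- function(onset, dur = NULL, text = "") {
      c(charToRaw(sprintf("%+g", onset)),
        if (!is.null(dur)) c(as.raw(0x15), charToRaw(sprintf("%g", dur))),
        as.raw(0x14), charToRaw(text), as.raw(0x14), as.raw(0x00))
    }
    # per-record byte payloads: a record-start timestamp TAL, plus (record 0
    # only) every annotation TAL
    ann_bytes <- lapply(seq_len(n_rec) - 1L, function(r) {
      b <- tal(r)
      if (r == 0L && nrow(ann) > 0) {
        for (i in seq_len(nrow(ann))) {
          b <- c(b, tal(ann$onset_s[i], ann$duration_s[i],
                        as.character(ann[[txt_col]][i])))
        }
      }
      b
    })
    ann_spr <- ceiling(max(lengths(ann_bytes)) / 2) + 1L  # int16 "samples"
    ann_bytes <- lapply(ann_bytes, function(b) {
      c(b, raw(2L * ann_spr - length(b)))
    })
  }

  ns <- length(signals) + as.integer(!is.null(annotations))
  header_bytes <- 256L * (1L + ns)

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s) writeBin(charToRaw(s), con)
  wr(.edf_pad("0", 8))
  wr(.edf_pad(subject_id, 80))
  wr(.edf_pad("somnet", 80))
  wr(.edf_pad("01.01.00", 8))
  wr(.edf_pad("00.00.00", 8))
  wr(.edf_num(header_bytes, 8))
  wr(.edf_pad(if (is.null(annotations)) "" else "EDF+C", 44))
  wr(.edf_num(n_rec, 8))
  wr(.edf_num(1, 8))
  wr(.edf_num(ns, 4))

  pr <- physical_range %||%
    max(10^ceiling(log10(max(abs(unlist(lapply(signals, `[[`, "samples"))),
                             1e-6))), 100)
  labels <- c(names(signals), if (!is.null(annotations)) "EDF Annotations")
  sprs <- c(rates, if (!is.null(annotations)) ann_spr)
  pmins <- c(rep(-pr, length(signals)), if (!is.null(annotations)) -1)
  pmaxs <- c(rep(pr, length(signals)), if (!is.null(annotations)) 1)
  for (l in labels) wr(.edf_pad(l, 16))
  for (l in labels) wr(.edf_pad("", 80))
  for (i in seq_len(ns)) wr(.edf_pad(if (i <= length(signals)) "uV" else "", 8))
  for (v in pmins) wr(.edf_num(v, 8))
  for (v in pmaxs) wr(.edf_num(v, 8))
  for (i in seq_len(ns)) wr(.edf_num(-32768, 8))
  for (i in seq_len(ns)) wr(.edf_num(32767, 8))
  for (l in labels) wr(.edf_pad("", 80))
  for (v in sprs) wr(.edf_num(v, 8))
  for (l in labels) wr(.edf_pad("", 32))

  gain <- pr * 2 / 65535
  for (r in seq_len(n_rec) - 1L) {
    for (i in seq_along(signals)) {
      x <- signals[[i]]$samples[r * rates[i] + seq_len(rates[i])]
      d <- as.integer(pmin(pmax(round(x / gain), -32768L), 32767L))
      writeBin(d, con, size = 2L, endian = "little")
    }
    if (!is.null(annotations)) writeBin(ann_bytes[[r + 1L]], con)
  }
  invisible(path)
}

#' Read an EDF or EDF+ file
#'
#' Parses the ASCII header, decodes every ordinary signal to physical units
#' (applying the per-signal digital-to-physical calibration), and, for EDF+
#' files, extracts time-stamped annotations from any `"EDF Annotations"`
#' channel.
#'
#' @param path an EDF/EDF+ file.
#' @return A list with `subject_id`, `n_records`, `record_duration_s`,
#'   `signals` (tibble: `label`, `sample_rate`, `n_samples`), `data` (named
#'   list of numeric vectors, one per ordinary signal) and `annotations`
#'   (tibble `onset_s`, `duration_s`, `text`; zero rows when absent).
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Cannot read EDF file: %s", path), class = "somnet_io_error")
  }
  bytes <- readBin(path, "raw", n = file.size(path))
  if (length(bytes) < 256) {
    abort(sprintf("Not an EDF file (truncated header): %s", path),
          class = "somnet_io_error")
  }
  asc <- function(from, len) {
    trimws(rawToChar(bytes[from + seq_len(len) - 1L]))
  }
  subject_id <- asc(9, 80)
  header_bytes <- as.integer(asc(185, 8))
  n_rec <- as.integer(asc(237, 8))
  rec_dur <- as.numeric(asc(245, 8))
  ns <- as.integer(asc(253, 4))

  idx <- seq_len(ns)
  # byte offsets of per-signal header fields (each field stored for all ns
  # signals consecutively): label 16, transducer 80, dim 8, phys min 8,
  # phys max 8, dig min 8, dig max 8, prefilter 80, samples/record 8
  off <- c(label = 0, transducer = 16, dim = 96, pmin = 104, pmax = 112,
           dmin = 120, dmax = 128, prefilter = 136, spr = 216)
  getf <- function(name, width) {
    base <- 256L + off[[name]] * ns
    vapply(idx, function(i) asc(base + (i - 1L) * width + 1L, width), "")
  }
  labels <- getf("label", 16L)
  pmin_ <- as.numeric(getf("pmin", 8L))
  pmax_ <- as.numeric(getf("pmax", 8L))
  dmin_ <- as.numeric(getf("dmin", 8L))
  dmax_ <- as.numeric(getf("dmax", 8L))
  spr <- as.integer(getf("spr", 8L))

  rec_words <- sum(spr)
  is_ann <- labels == "EDF Annotations"
  payload <- bytes[-seq_len(header_bytes)]
  if (n_rec < 0) n_rec <- length(payload) %/% (2L * rec_words)
  ints <- readBin(payload, "integer", n = n_rec * rec_words,
                  size = 2L, signed = TRUE, endian = "little")

  data <- vector("list", ns)
  ann_raw <- raw(0)
  starts <- cumsum(c(0L, spr))[seq_len(ns)]
  for (i in idx) {
    pos <- as.vector(outer(seq_len(spr[i]) + starts[i],
                           (seq_len(n_rec) - 1L) * rec_words, `+`))
    if (is_ann[i]) {
      seg <- ints[pos]
      ann_raw <- c(ann_raw, writeBin(seg, raw(), size = 2L,
                                     endian = "little"))
    } else {
      gain <- (pmax_[i] - pmin_[i]) / (dmax_[i] - dmin_[i])
      data[[i]] <- (ints[pos] - dmin_[i]) * gain + pmin_[i]
    }
  }
  names(data) <- labels

  annotations <- .parse_tals(ann_raw)
  tibble::lst(
    subject_id = if (nzchar(subject_id)) subject_id else
      sub("\\.edf$", "", basename(path), ignore.case = TRUE),
    n_records = n_rec,
    record_duration_s = rec_dur,
    signals = tibble::tibble(
      label = labels[!is_ann],
      sample_rate = spr[!is_ann] / rec_dur,
      n_samples = spr[!is_ann] * n_rec
    ),
    data = data[!is_ann],
    annotations = annotations
  )
}

# Parse EDF+ time-stamped annotation lists. Record-keeping TALs (empty
# annotation text) are dropped.
.parse_tals <- function(ann_raw) {
  out <- tibble::tibble(onset_s = numeric(), duration_s = numeric(),
                        text = character())
  if (length(ann_raw) == 0) return(out)
  # split the byte stream on NUL separators
  nul <- which(ann_raw == as.raw(0x00))
  bounds <- c(0L, nul)
  recs <- list()
  for (j in seq_len(length(bounds) - 1L)) {
    seg <- ann_raw[(bounds[j] + 1L):(bounds[j + 1L] - 1L)]
    if (length(seg) == 0) next
    recs[[length(recs) + 1L]] <- seg
  }
  parse_one <- function(seg) {
    parts <- strsplit(rawToChar(seg), "\x14", fixed = TRUE)[[1]]
    if (length(parts) < 2 || !nzchar(parts[2])) return(NULL)
    head_part <- strsplit(parts[1], "\x15", fixed = TRUE)[[1]]
    tibble::tibble(
      onset_s = as.numeric(head_part[1]),
      duration_s = if (length(head_part) > 1) as.numeric(head_part[2]) else NA_real_,
      text = parts[2]
    )
  }
  rows <- purrr::compact(lapply(recs, parse_one))
  if (length(rows)) out <- dplyr::bind_rows(rows)
  out
}
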