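# Deterministic epoch -> spectrogram-image pipeline. A 30-s epoch is
# resampled to 64 Hz (1920 samples), transformed to a 129 x 14 short-time
# power grid (Hann window 256, hop 128, 0-32 Hz), rasterized to a
# colormapped 100 x 80-dot image, and cropped to the fixed 76 x 60 x 3
# model input. All steps are pure functions of the input signal.

SPEC_FS <- 64L          # analysis rate, Hz
SPEC_NSAMP <- 1920L     # 30 s at 64 Hz
SPEC_NFFT <- 256L       # window length -> 0.25 Hz bins
SPEC_HOP <- 128L        # frame hop -> 14 frames per epoch
SPEC_DB_FLOOR <- -120   # dB floor for zero-power bins

#' Resample a 30-s epoch to the 64 Hz analysis rate
#'
#' Sleep-relevant EEG activity lies below 32 Hz, so epochs are decimated to
#' 64 Hz before spectral analysis. Anti-aliasing is applied by the polyphase
#' filter of [signal::resample()]. Upsampling is not supported: source rates
#' below 64 Hz are rejected.
#'
#' @param samples numeric vector, exactly `30 * src_rate` samples.
#' @param src_rate source sampling rate in Hz (>= 64).
#' @return Numeric vector of exactly 1920 samples.
#' @export
resample_to_64 <- function(samples, src_rate) {
  if (src_rate < SPEC_FS) {
    abort(sprintf("Unsupported source rate %g Hz: must be >= 64 Hz.", src_rate),
          class = "somnet_rate_error")
  }
  if (length(samples) != 30 * src_rate) {
    abort(sprintf("Expected %g samples (30 s at %g Hz), got %d.",
                  30 * src_rate, src_rate, length(samples)),
          class = "somnet_shape_error")
  }
  if (src_rate == SPEC_FS) return(as.numeric(samples))
  g <- .gcd(SPEC_FS, round(src_rate))
  y <- signal::resample(as.numeric(samples), SPEC_FS / g, round(src_rate) / g)
  y <- as.numeric(y)
  length(y) <- SPEC_NSAMP  # defensive: resample returns exactly n*p/q here
  y[is.na(y)] <- 0
  y
}

.gcd <- function(a, b) if (b == 0) a else .gcd(b, a %% b)

#' Short-time power spectrum of a 64 Hz epoch
#'
#' Windowed FFT with a 256-sample Hann window and 128-sample hop; the
#' squared magnitude is converted to decibels with a floor at -120 dB. For
#' the 1920-sample epoch this yields 14 frames of 129 one-sided frequency
#' bins spanning 0-32 Hz in 0.25 Hz steps.
#'
#' @param samples_64 numeric vector of exactly 1920 samples at 64 Hz.
#' @return A `somnet_stft`: 129 x 14 matrix of dB power (rows = frequency,
#'   ascending from 0 Hz) with attributes `bin_hz` and `frame_hop_s`.
#' @export
stft_power <- function(samples_64) {
  if (length(samples_64) != SPEC_NSAMP) {
    abort(sprintf("Expected %d samples at 64 Hz, got %d.",
                  SPEC_NSAMP, length(samples_64)),
          class = "somnet_shape_error")
  }
  n_frames <- (SPEC_NSAMP - SPEC_NFFT) %/% SPEC_HOP + 1L
  w <- 0.5 * (1 - cos(2 * pi * (0:(SPEC_NFFT - 1)) / (SPEC_NFFT - 1)))
  frames <- vapply(seq_len(n_frames), function(k) {
    samples_64[(k - 1L) * SPEC_HOP + seq_len(SPEC_NFFT)] * w
  }, numeric(SPEC_NFFT))
  spec <- stats::mvfft(frames)[seq_len(SPEC_NFFT / 2 + 1L), , drop = FALSE]
  p <- Mod(spec)^2
  db <- 10 * log10(p)
  db[!is.finite(db)] <- SPEC_DB_FLOOR
  db <- pmax(db, SPEC_DB_FLOOR)
  structure(db, class = "somnet_stft",
            bin_hz = SPEC_FS / SPEC_NFFT, frame_hop_s = SPEC_HOP / SPEC_FS)
}

# Bilinear interpolation matrix mapping n_src samples onto n_dst positions
# (align-corners grid: endpoint maps to endpoint).
.interp_matrix <- function(n_dst, n_src) {
  pos <- (seq_len(n_dst) - 1) * (n_src - 1) / (n_dst - 1)
  lo <- pmin(floor(pos), n_src - 2)
  frac <- pos - lo
  m <- matrix(0, n_dst, n_src)
  m[cbind(seq_len(n_dst), lo + 1)] <- 1 - frac
  m[cbind(seq_len(n_dst), lo + 2)] <- frac
  m
}

#' The bundled 256-entry colormap lookup table
#'
#' The perceptually-uniform viridis colormap (public-domain), stored with
#' the package as a static CSV so that rasterization does not depend on any
#' plotting library at run time.
#'
#' @return A 256 x 3 matrix of RGB values in `[0, 1]`.
#' @export
viridis_lut <- function() {
  if (is.null(.somnet_env$lut)) {
    path <- system.file("extdata", "viridis256.csv", package = "somnet")
    .somnet_env$lut <- as.matrix(utils::read.csv(path))
  }
  .somnet_env$lut
}

#' Rasterize a power grid to a 100 x 80-dot colormapped image
#'
#' The dB grid is min-max normalized to `[0, 1]` per image (making the
#' pipeline invariant to signal amplitude), bilinearly resized to a
#' 100-dot frequency axis (vertical, decreasing down the image: row 0 =
#' 32 Hz, as in a rendered spectrogram figure) by an 80-dot time axis
#' (horizontal), and mapped through the 256-entry colormap. A degenerate
#' all-equal grid maps every pixel to colormap entry 0.
#'
#' @param grid a `somnet_stft` (or any 129 x 14 matrix of dB values).
#' @param grayscale if `TRUE`, the normalized value is replicated across the
#'   three channels instead of using the colormap.
#' @return A 100 x 80 x 3 array (rows x columns x RGB) of values in
#'   `[0, 1]`.
#' @export
rasterize <- function(grid, grayscale = FALSE) {
  g <- unclass(grid)
  stopifnot(is.matrix(g))
  rng <- range(g)
  v <- if (rng[1] == rng[2]) matrix(0, nrow(g), ncol(g)) else
    (g - rng[1]) / (rng[2] - rng[1])
  a <- .interp_matrix(100L, nrow(g))[, rev(seq_len(nrow(g))), drop = FALSE]
  b <- t(.interp_matrix(80L, ncol(g)))
  vi <- a %*% v %*% b                      # 100 x 80, row 0 = top = 32 Hz
  vi <- pmin(pmax(vi, 0), 1)
  if (grayscale) {
    return(array(vi, dim = c(100L, 80L, 3L)))
  }
  lut <- viridis_lut()
  idx <- pmin(floor(vi * 256), 255) + 1L
  array(lut[idx, ], dim = c(100L, 80L, 3L))
}

#' Crop the rasterized spectrogram to the model input
#'
#' Retains rows 14-89 and columns 11-70 (0-based, half-open ranges
#' `[14, 90)` and `[11, 71)`) of the 100 x 80 dot image — discarding the
#' figure margins — yielding the fixed 76 x 60 x 3 input tensor
#' (frequency x time x RGB).
#'
#' @param image a 100 x 80 x 3 array from [rasterize()].
#' @return A 76 x 60 x 3 array.
#' @export
crop_spectrogram <- function(image) {
  d <- dim(image)
  if (length(d) != 3 || d[1] != 100 || d[2] != 80 || d[3] != 3) {
    abort(sprintf("Expected a 100 x 80 x 3 image, got %s.",
                  paste(d, collapse = " x ")),
          class = "somnet_shape_error")
  }
  image[15:90, 12:71, , drop = FALSE]
}

#' Convert one 30-s epoch to its spectrogram image
#'
#' The composition resample -> STFT -> rasterize -> crop. Deterministic:
#' identical input gives identical output, and scaling the input amplitude
#' leaves the image unchanged (log power followed by per-image min-max
#' normalization).
#'
#' @inheritParams resample_to_64
#' @inheritParams rasterize
#' @return A `somnet_image`: 76 x 60 x 3 array of values in `[0, 1]`.
#' @export
#' @examples
#' x <- sin(2 * pi * 13 * seq(0, 30, length.out = 3001)[-1])
#' img <- epoch_to_image(x, 100)
#' dim(img)
epoch_to_image <- function(samples, src_rate, grayscale = FALSE) {
  img <- crop_spectrogram(rasterize(stft_power(resample_to_64(samples, src_rate)),
                                    grayscale = grayscale))
  structure(img, class = c("somnet_image", class(img)))
}

#' Convert a segmented epoch table to an image batch
#'
#' @param epochs tibble from [segment_epochs()] (or the synthetic
#'   generator): columns `subject_id`, `epoch_index`, `stage`, `samples`,
#'   with a `sample_rate` attribute (or supply `src_rate`).
#' @param src_rate sampling rate; defaults to the table's attribute.
#' @inheritParams rasterize
#' @return A list with `images` (76 x 60 x 3 x n array), `meta` (tibble
#'   `subject_id`, `epoch_index`, `stage`).
#' @export
epochs_to_images <- function(epochs, src_rate = NULL, grayscale = FALSE) {
  rate <- src_rate %||% attr(epochs, "sample_rate")
  stopifnot(!is.null(rate))
  n <- nrow(epochs)
  images <- array(0, dim = c(76L, 60L, 3L, n))
  for (i in seq_len(n)) {
    images[, , , i] <- epoch_to_image(epochs$samples[[i]], rate,
                                      grayscale = grayscale)
  }
  list(
    images = images,
    meta = tibble::tibble(
      subject_id = epochs$subject_id,
      epoch_index = epochs$epoch_index,
      stage = stage_factor(epochs$stage)
    )
  )
}

#' Geometry of the cropped spectrogram image
#'
#' Maps physical coordinates to pixel positions of the final 76 x 60 image:
#' which row a frequency lands on and which column a time within the epoch
#' lands on, inverting the resize-and-crop transforms. Useful for locating
#' e.g. the 12-14 Hz spindle band in a rendered image.
#'
#' @param freq_hz frequencies in `[0, 32]` Hz.
#' @param time_s times in `[0, 30]` s.
#' @return `image_row_for_freq`: fractional 1-based row index (may fall
#'   outside `[1, 76]` for frequencies cropped away); `image_col_for_time`:
#'   fractional 1-based column index.
#' @export
image_row_for_freq <- function(freq_hz) {
  bin <- freq_hz / (SPEC_FS / SPEC_NFFT)          # source bin, 0-based
  full <- 99 * (1 - bin / (SPEC_NFFT / 2))        # 100-row raster, 0-based
  full - 14 + 1
}

#' @rdname image_row_for_freq
#' @export
image_col_for_time <- function(time_s) {
  centers <- ((seq_len(14) - 1) * SPEC_HOP + (SPEC_NFFT - 1) / 2) / SPEC_FS
  frame <- stats::approx(centers, seq_len(14) - 1, xout = time_s,
                         rule = 2)$y               # fractional frame, 0-based
  full <- frame * 79 / 13                          # 80-col raster, 0-based
  full - 11 + 1
}
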