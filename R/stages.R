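#' AASM sleep-stage levels
#'
#' The five-class AASM scoring scheme in the canonical order used throughout
#' the package: Wake, N1, N2, N3 and REM. All confusion matrices, transition
#' matrices and model outputs index classes in this order.
#'
#' @return Character vector `c("W", "N1", "N2", "N3", "REM")`.
#' @export
#' @examples
#' stage_levels()
stage_levels <- function() c("W", "N1", "N2", "N3", "REM")

#' @rdname stage_levels
#' @param x character or factor of stage labels.
#' @export
stage_factor <- function(x) factor(as.character(x), levels = stage_levels())

# Normalized R&K / annotation vocabulary -> AASM value (NA = excluded).
# Keys are upper-cased, whitespace-collapsed source strings.
.stage_map <- c(
  "W" = "W", "WAKE" = "W", "SLEEP STAGE W" = "W",
  "S1" = "N1", "1" = "N1", "SLEEP STAGE 1" = "N1", "N1" = "N1",
  "S2" = "N2", "2" = "N2", "SLEEP STAGE 2" = "N2", "N2" = "N2",
  "S3" = "N3", "3" = "N3", "SLEEP STAGE 3" = "N3", "N3" = "N3",
  "S4" = "N3", "4" = "N3", "SLEEP STAGE 4" = "N3",
  "R" = "REM", "REM" = "REM", "SLEEP STAGE R" = "REM",
  "MOVEMENT" = NA, "MOVEMENT TIME" = NA, "M" = NA,
  "UNKNOWN" = NA, "?" = NA, "SLEEP STAGE ?" = NA
)

#' Map legacy sleep-stage labels to the 5-class AASM scheme
#'
#' Applies the standard R&K-to-AASM conversion: S1 and S2 become N1 and N2,
#' S3 and S4 are merged into N3, R becomes REM, and W stays W. Movement time
#' and unscored ("?") epochs carry no AASM value and are flagged excluded.
#' Already-AASM labels pass through unchanged. Matching ignores case and the
#' `"Sleep stage "` prefix used by EDF+ hypnogram annotations.
#'
#' @param source_label character vector of stage labels from an annotation
#'   file (e.g. `"S4"`, `"Sleep stage 2"`, `"Movement time"`).
#' @return A tibble with columns `source` (the input), `stage` (factor over
#'   [stage_levels()], `NA` for excluded epochs) and `excluded` (logical).
#' @export
#' @examples
#' map_stage(c("S4", "W", "Movement time"))
map_stage <- function(source_label) {
  src <- as.character(source_label)
  key <- toupper(trimws(gsub("[[:space:]]+", " ", src)))
  unknown <- !(key %in% names(.stage_map))
  if (any(unknown)) {
    abort(sprintf(
      "Unrecognized stage label(s): %s",
      paste(sQuote(unique(src[unknown])), collapse = ", ")
    ), class = "somnet_label_error")
  }
  val <- unname(.stage_map[key])
  tibble::tibble(
    source = src,
    stage = stage_factor(val),
    excluded = is.na(val)
  )
}
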