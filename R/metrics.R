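# Evaluation suite: 5x5 confusion matrices (rows = reference scoring,
# columns = model prediction), per-class precision/recall/F1, overall
# accuracy, macro-F1 and Cohen's kappa, plus hypnogram transition counts.

#' Confusion matrix of reference vs predicted stages
#'
#' @param reference,predicted equal-length stage vectors (characters or
#'   factors over [stage_levels()]). Rows of the result are the reference
#'   (specialist) stages, columns the predictions.
#' @return A `somnet_confusion`: 5 x 5 integer matrix with dimnames.
#' @export
#' @examples
#' confusion(c("W", "W", "N1"), c("W", "N1", "N1"))
confusion <- function(reference, predicted) {
  if (length(reference) != length(predicted)) {
    abort("reference and predicted must have the same length.",
          class = "somnet_shape_error")
  }
  cm <- table(factor(as.character(reference), levels = stage_levels()),
              factor(as.character(predicted), levels = stage_levels()))
  cm <- matrix(as.integer(cm), 5, 5,
               dimnames = list(reference = stage_levels(),
                               predicted = stage_levels()))
  structure(cm, class = c("somnet_confusion", "matrix"))
}

#' @rdname confusion
#' @param x a 5 x 5 matrix of counts (e.g. read from CSV).
#' @export
as_confusion <- function(x) {
  x <- as.matrix(x)
  stopifnot(all(dim(x) == 5), all(x >= 0))
  x <- matrix(as.integer(round(x)), 5, 5,
              dimnames = list(reference = stage_levels(),
                              predicted = stage_levels()))
  structure(x, class = c("somnet_confusion", "matrix"))
}

#' Read or write the confusion-matrix CSV dialect
#'
#' A header row of the five class labels followed by five rows of integer
#' counts (reference stages in row order W, N1, N2, N3, REM).
#'
#' @param path CSV path.
#' @return `read_confusion_csv` returns a `somnet_confusion`.
#' @export
read_confusion_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  as_confusion(df[, stage_levels()])
}

#' @rdname read_confusion_csv
#' @param cm a confusion matrix.
#' @export
write_confusion_csv <- function(cm, path) {
  utils::write.csv(as.data.frame(unclass(cm))[stage_levels()], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Classification metrics from a confusion matrix
#'
#' Per-class precision `PR_k = TP_k / colsum_k`, recall
#' `RE_k = TP_k / rowsum_k` and `F1_k = 2 PR RE / (PR + RE)` (all in
#' percent); overall accuracy `ACC = 100 * trace / total`; macro-F1 `MF1` =
#' unweighted mean of the five unrounded F1 values; Cohen's kappa
#' `(p_o - p_e) / (1 - p_e)` with `p_e` the marginal chance agreement.
#' Classes with a zero denominator get PR/RE/F1 of 0 with a warning.
#'
#' @param cm a `somnet_confusion` (or any 5 x 5 count matrix).
#' @return A `somnet_metrics` list: `per_class` tibble (`stage`, `PR`,
#'   `RE`, `F1`), `ACC`, `MF1`, `kappa`, `n`.
#' @export
#' @examples
#' cm <- confusion(rep(stage_levels(), 10), rep(stage_levels(), 10))
#' metrics(cm)$ACC
metrics <- function(cm) {
  m <- unclass(as_confusion(cm))
  total <- sum(m)
  if (total == 0) {
    abort("Confusion matrix has no observations.", class = "somnet_value_error")
  }
  tp <- diag(m)
  cs <- colSums(m)
  rs <- rowSums(m)
  pr <- unname(ifelse(cs > 0, tp / cs, 0))
  re <- unname(ifelse(rs > 0, tp / rs, 0))
  f1 <- unname(ifelse(pr + re > 0, 2 * pr * re / (pr + re), 0))
  if (any(cs == 0 | rs == 0)) {
    warn("Zero row/column sums: affected per-class metrics set to 0.")
  }
  po <- sum(tp) / total
  pe <- sum(rs * cs) / total^2
  structure(
    list(
      per_class = tibble::tibble(stage = stage_levels(),
                                 PR = 100 * pr, RE = 100 * re, F1 = 100 * f1),
      ACC = 100 * po,
      MF1 = 100 * mean(f1),
      kappa = (po - pe) / (1 - pe),
      n = total
    ),
    class = "somnet_metrics"
  )
}

#' @export
print.somnet_metrics <- function(x, digits = 2, ...) {
  cat(sprintf("<somnet_metrics> n = %d epochs\n", x$n))
  cat(sprintf("  ACC %.2f%%  MF1 %.2f%%  kappa %.2f\n", x$ACC, x$MF1, x$kappa))
  pc <- x$per_class
  for (i in seq_len(nrow(pc))) {
    cat(sprintf("  %-3s PR %6.2f  RE %6.2f  F1 %6.2f\n",
                pc$stage[i], pc$PR[i], pc$RE[i], pc$F1[i]))
  }
  invisible(x)
}

#' @export
tidy.somnet_metrics <- function(x, ...) x$per_class

#' @export
glance.somnet_metrics <- function(x, ...) {
  tibble::tibble(ACC = x$ACC, MF1 = x$MF1, kappa = x$kappa, n = x$n)
}

#' @export
tidy.somnet_confusion <- function(x, ...) {
  tibble::as_tibble(as.data.frame.table(unclass(x), responseName = "count"))
}

#' Count specific stage transitions in a hypnogram
#'
#' Counts adjacent ordered pairs `(s_t, s_t+1)` matching each requested
#' pair. When `subject` is given, pairs never straddle a subject boundary.
#'
#' @param stages stage sequence (character/factor over [stage_levels()]).
#' @param pairs list of `c(from, to)` pairs, or a two-column matrix.
#' @param subject optional vector of subject ids aligned with `stages`.
#' @return A tibble with columns `from`, `to`, `count`.
#' @export
#' @examples
#' count_transitions(c("W", "W", "N1", "N2", "N2", "REM"),
#'                   list(c("W", "N1"), c("W", "REM")))
count_transitions <- function(stages, pairs, subject = NULL) {
  if (is.matrix(pairs)) pairs <- asplit(pairs, 1)
  bad <- !vapply(pairs, function(p) all(p %in% stage_levels()), logical(1))
  if (any(bad)) {
    abort(sprintf("Unknown stage in transition pair(s): %s",
                  paste(vapply(pairs[bad], paste, "", collapse = "->"),
                        collapse = ", ")),
          class = "somnet_label_error")
  }
  s <- as.character(stages)
  if (length(s) == 0) abort("Empty hypnogram.", class = "somnet_value_error")
  from <- s[-length(s)]
  to <- s[-1]
  keep <- if (is.null(subject)) rep(TRUE, length(from)) else {
    subject[-length(subject)] == subject[-1]
  }
  purrr::map_dfr(pairs, function(p) {
    n <- sum(keep & from == p[1] & to == p[2])
    tibble::tibble(from = p[1], to = p[2], count = n)
  })
}
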