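# ggplot2 views of the package's result types.

#' @export
autoplot.somnet_image <- function(object, ...) {
  d <- dim(object)
  df <- expand.grid(row = seq_len(d[1]), col = seq_len(d[2]))
  df$fill <- grDevices::rgb(object[, , 1][as.matrix(df)],
                            object[, , 2][as.matrix(df)],
                            object[, , 3][as.matrix(df)])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$fill)) +
    ggplot2::scale_fill_identity() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "time (columns)", y = "frequency (rows, 32 Hz at top)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.somnet_confusion <- function(object, ...) {
  df <- tidy.somnet_confusion(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$reference,
                                   fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$count), size = 3) +
    ggplot2::scale_y_discrete(limits = rev(stage_levels())) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(x = "predicted", y = "reference") +
    ggplot2::theme_minimal()
}

#' Plot a hypnogram
#'
#' Classic step plot of stage against time with deep sleep at the bottom.
#'
#' @param stages stage sequence (factor/character over [stage_levels()]).
#' @return A ggplot object.
#' @export
plot_hypnogram <- function(stages) {
  depth <- c(W = 5, REM = 4, N1 = 3, N2 = 2, N3 = 1)
  df <- tibble::tibble(
    time_h = (seq_along(stages) - 1) * 30 / 3600,
    depth = depth[as.character(stages)]
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_h, y = .data$depth)) +
    ggplot2::geom_step() +
    ggplot2::scale_y_continuous(breaks = unname(depth),
                                labels = names(depth), limits = c(0.5, 5.5)) +
    ggplot2::labs(x = "time (h)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.somnet_fit <- function(object, ...) {
  h <- object$history
  df <- tidyr::pivot_longer(
    h[, c("pass", "loss_total", "test_ACC")],
    c("loss_total", "test_ACC"), names_to = "metric", values_to = "value"
  ) |> tidyr::drop_na()
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pass, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~metric, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "training pass", y = NULL) +
    ggplot2::theme_minimal()
}
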