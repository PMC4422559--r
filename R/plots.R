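#' Plot a time-course matrix
#'
#' One panel per feature, replicates as thin lines.  Intended for quick
#' inspection of a handful of features; subset first for large matrices.
#'
#' @param tc A [tc_matrix()].
#' @param features Optional character vector of feature ids to show.
#' @return A ggplot object.
#' @export
plot_timecourse <- function(tc, features = NULL) {
  df <- as_tibble(tc)
  if (!is.null(features)) df <- filter(df, .data$feature_id %in% features)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$value,
                                   group = .data$replicate)) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~feature_id, scales = "free_y") +
    ggplot2::labs(x = "time (min)", y = "level",
                  title = sprintf("%s, %s", attr(tc, "kind"), attr(tc, "condition")))
}

#' Heat map of motif assignment frequencies
#'
#' Mirrors the frequency heat-map view of the inference output: metabolites
#' by motif, tile fill = percent of method variants supporting the
#' assignment with posterior above threshold.
#'
#' @param object A `motif_assignment` from [assign_motifs()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.motif_assignment <- function(object, ...) {
  df <- object$frequencies |>
    mutate(pct = 100 * .data$frequency,
           motif = factor(.data$motif, levels = MOTIFS))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$motif, y = .data$metabolite,
                                   fill = .data$pct)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.0f", .data$pct)),
                       size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick",
                                 limits = c(0, 100),
                                 name = "frequency (%)") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Motif assignment frequency over method variants")
}

#' Binned error rates of a robustness analysis
#'
#' @param object A `robustness_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.robustness_report <- function(object, ...) {
  df <- object$binned |>
    pivot_longer(c("total_error_rate", "fn_rate", "fp_rate"),
                 names_to = "rate", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin, y = .data$value,
                                   group = .data$rate, colour = .data$rate)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "maximal assignment frequency bin (%)",
                  y = "error rate") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Impulse fit against the data
#'
#' @param object An `impulse_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.impulse_fit <- function(object, ...) {
  grid <- seq(min(object$times), max(object$times), length.out = 200)
  fitted <- tibble(time = grid,
                   value = impulse_value(object$params, grid))
  obs <- tibble(time = object$times, value = object$levels)
  p <- ggplot2::ggplot(fitted, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point(data = obs) +
    ggplot2::labs(x = "time (min)", y = "level",
                  title = sprintf("impulse fit (sse = %.3g)", object$sse))
  if (!is.na(object$t_half)) {
    p <- p + ggplot2::geom_vline(xintercept = object$t_half,
                                 linetype = "dashed", colour = "grey40")
  }
  p
}
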