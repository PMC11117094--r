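#' Plot information atoms
#'
#' Bar chart of the four atoms of a PID or variance-partitioning result.
#'
#' @param object A `pid_atoms` or `vp_fit` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @method autoplot pid_atoms
autoplot.pid_atoms <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$atom, y = .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(
      y = "information (bits)", x = NULL,
      title = sprintf("PID atoms (%s)", object$estimator)
    ) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.pid_atoms
#' @export
#' @method autoplot vp_fit
autoplot.vp_fit <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$atom, y = .data$value)) +
    ggplot2::geom_col(fill = "darkorange") +
    ggplot2::labs(
      y = "explained variance fraction", x = NULL,
      title = "Variance partitioning atoms"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a sweep: significant fractions against noise fraction or data size
#'
#' @param object A `triplet_sweep` table.
#' @param x `"nu"` (noise sweep) or `"n"` (size sweep).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @method autoplot triplet_sweep
autoplot.triplet_sweep <- function(object, x = c("nu", "n"), ...) {
  x <- match.arg(x)
  df <- tidyr::pivot_longer(
    object[!is.na(object$atom), ],
    cols = dplyr::any_of(c("fraction_sig_perm", "fraction_sig_adj")),
    names_to = "test", values_to = "fraction"
  )
  df <- df[!is.na(df$fraction), ]
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data[[x]], y = .data$fraction,
    colour = .data$atom, linetype = .data$test
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_x_log10() +
    ggplot2::facet_grid(measure ~ model + strategy) +
    ggplot2::labs(
      x = if (x == "nu") "noise fraction" else "data size",
      y = "fraction significant"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a significance sketch matrix
#'
#' Tile plot of the measure-by-model significance fractions produced by
#' [summarize_sketch()].
#'
#' @param sketch Output of [summarize_sketch()].
#' @param column `"fraction_sig_perm"` or `"fraction_sig_adj"`.
#' @return A ggplot object.
#' @export
plot_sketch <- function(sketch, column = "fraction_sig_perm") {
  ggplot2::ggplot(sketch, ggplot2::aes(
    x = .data$model, y = .data$atom, fill = .data[[column]]
  )) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data[[column]])), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick", limits = c(0, 1)) +
    ggplot2::facet_wrap(~measure) +
    ggplot2::labs(x = "ground-truth model", y = "atom", fill = "fraction\nsignificant") +
    ggplot2::theme_minimal()
}
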