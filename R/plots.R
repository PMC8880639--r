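# ggplot2 displays for the main result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_vline geom_raster
#'   geom_col geom_point labs scale_fill_gradient theme_minimal facet_wrap
NULL

#' @export
ggplot2::autoplot

#' Plot a scan as a raster
#'
#' @param object A [gray_image()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.last_image <- function(object, ...) {
  px <- object$pixels
  df <- tidyr::expand_grid(row = seq_len(nrow(px)), col = seq_len(ncol(px)))
  df$intensity <- as.vector(t(px))
  ggplot(df, aes(x = .data$col, y = -.data$row, fill = .data$intensity)) +
    geom_raster() +
    scale_fill_gradient(low = "black", high = "white", limits = c(0, 255)) +
    labs(x = "column (px)", y = "row (px)", fill = "intensity") +
    theme_minimal()
}

#' Plot a signal form
#'
#' @param object A `last_signal` tibble from [to_signal_form()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.last_signal <- function(object, ...) {
  ggplot(object, aes(x = .data$x, y = .data$y)) +
    geom_line(colour = "grey20") +
    geom_point(data = object[object$gap, ], colour = "orange", size = 0.4) +
    labs(x = "column (px)", y = "height (px)",
         title = "Signal form (orange = interpolated gaps)") +
    theme_minimal()
}

#' Plot a baseline decomposition
#'
#' Raw signal, estimated baseline and aligned signal from
#' [adaptive_baseline()].
#'
#' @param object A `last_aligned` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.last_aligned <- function(object, ...) {
  long <- tidyr::pivot_longer(object[, c("x", "raw", "baseline", "aligned")],
                              -"x", names_to = "component")
  ggplot(long, aes(x = .data$x, y = .data$value, colour = .data$component)) +
    geom_line() +
    labs(x = "column (px)", y = "height (px)", colour = NULL,
         title = "BEADS baseline decomposition") +
    theme_minimal()
}

#' Plot cross-validation fold accuracies
#'
#' @param object A `last_cv` from [cross_validate()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.last_cv <- function(object, ...) {
  df <- tibble(fold = factor(seq_along(object$per_fold)),
               accuracy = object$per_fold)
  ggplot(df, aes(x = .data$fold, y = .data$accuracy)) +
    geom_col(fill = "steelblue") +
    labs(x = "fold", y = "accuracy (%)",
         title = sprintf("%d-fold CV, overall %.1f%%", object$k,
                         object$accuracy)) +
    theme_minimal()
}

#' Plot feature significance
#'
#' @param object A `last_significance` from [kruskal_dunn()].
#' @param top Show at most this many features, ranked by p-value.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.last_significance <- function(object, top = 30L, ...) {
  df <- dplyr::arrange(as_tibble(unclass2(object)), .data$p_kw)
  df <- utils::head(df, top)
  df$feature <- factor(df$feature, levels = rev(df$feature))
  ggplot(df, aes(x = -log10(.data$p_kw), y = .data$feature,
                 fill = .data$significant)) +
    geom_col() +
    labs(x = expression(-log[10](p)), y = NULL,
         title = "Kruskal-Wallis group differences") +
    theme_minimal()
}
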