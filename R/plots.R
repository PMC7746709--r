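#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a closed contour
#'
#' @param object A [closed_contour()]. @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.closed_contour <- function(object, ...) {
  df <- tibble::tibble(x = object$x, y = object$y)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_polygon(fill = NA, colour = "grey20") +
    ggplot2::coord_fixed() +
    ggplot2::scale_y_reverse() +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = NULL, y = NULL)
}

#' Plot a surprisal profile
#'
#' @param object A [surprisal_profile()].
#' @param which Which columns to draw.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.surprisal_profile <- function(object,
                                       which = c("u_norm", "u_signed"), ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object)[, c("s", which)],
    -"s", names_to = "measure", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$s, y = .data$value,
                                     colour = .data$measure)) +
    ggplot2::geom_line() +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = "arc position (fraction of perimeter)",
                  y = "surprisal")
}

#' Side-by-side correspondence plot for a shape pair
#'
#' Draws the base contour with its probes and the test contour (offset to
#' the right) with predicted or responded positions, colored by probe
#' order.
#'
#' @param base,test [closed_contour()]s.
#' @param predictions Prediction tibble (`probe_s`, `predicted_s`,
#'   `valid`).
#' @param gap Horizontal gap between the shapes, as a fraction of the
#'   base width.
#' @return A ggplot.
#' @export
plot_correspondence <- function(base, test, predictions, gap = 0.2) {
  test <- normalize_pair_scale(base, test)
  dx <- (max(base$x) - min(base$x)) * (1 + gap) + (min(base$x) - min(test$x))
  pr <- predictions[predictions$valid, ]
  pb <- arc_point(base, pr$probe_s)
  pt <- arc_point(test, pr$predicted_s)
  shapes <- dplyr::bind_rows(
    tibble::tibble(x = base$x, y = base$y, shape = "base"),
    tibble::tibble(x = test$x + dx, y = test$y, shape = "test"))
  dots <- dplyr::bind_rows(
    tibble::tibble(x = pb$x, y = pb$y, order = pr$probe_s, shape = "base"),
    tibble::tibble(x = pt$x + dx, y = pt$y, order = pr$probe_s, shape = "test"))
  ggplot2::ggplot(shapes, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_polygon(ggplot2::aes(group = .data$shape),
                          fill = NA, colour = "grey50") +
    ggplot2::geom_point(data = dots, ggplot2::aes(colour = .data$order),
                        size = 1.6) +
    ggplot2::scale_colour_viridis_c(name = "probe arc") +
    ggplot2::coord_fixed() +
    ggplot2::scale_y_reverse() +
    ggplot2::theme_void()
}

#' Congruity bar plot
#'
#' @param congruity_tbl Output of [congruity()] (optionally several rows
#'   per pair).
#' @return A ggplot.
#' @export
plot_congruity <- function(congruity_tbl) {
  df <- congruity_tbl
  if (!"pair_id" %in% names(df)) df$pair_id <- "pair"
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pair_id, y = .data$congruity)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = c(0, 1), linetype = "dashed") +
    ggplot2::coord_cartesian(ylim = c(min(0, min(df$congruity)), 1)) +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = NULL, y = "congruity (0 = random, 1 = perfect)")
}

#' Plot a morph sequence
#'
#' @param object A [morph_sequence()]. @param ... Unused.
#' @return A ggplot faceted by morph level.
#' @export
autoplot.morph_sequence <- function(object, ...) {
  df <- purrr::map2_dfr(object$levels, object$contours, function(a, ct) {
    tibble::tibble(alpha = sprintf("alpha = %.2f", a), x = ct$x, y = ct$y)
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_polygon(fill = "grey85", colour = "grey20") +
    ggplot2::facet_wrap(~alpha, nrow = 1) +
    ggplot2::coord_fixed() +
    ggplot2::scale_y_reverse() +
    ggplot2::theme_void()
}
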