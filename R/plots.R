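circle_layout <- function(labels) {
  p <- length(labels)
  theta <- seq(0, 2 * pi, length.out = p + 1)[seq_len(p)]
  tibble::tibble(node = labels, x = cos(theta), y = sin(theta))
}

#' @export
autoplot.ggm_network <- function(object, min_weight = 0, ...) {
  lay <- circle_layout(object$node_labels)
  edges <- tidy(object) |>
    dplyr::filter(abs(.data$weight) > min_weight) |>
    dplyr::left_join(dplyr::rename(lay, xa = "x", ya = "y"),
                     by = c(node_a = "node")) |>
    dplyr::left_join(dplyr::rename(lay, xb = "x", yb = "y"),
                     by = c(node_b = "node"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$xa, y = .data$ya, xend = .data$xb,
                   yend = .data$yb, linewidth = abs(.data$weight),
                   colour = .data$weight > 0),
      show.legend = c(linewidth = FALSE, colour = TRUE)) +
    ggplot2::scale_colour_manual(
      values = c(`TRUE` = "#2166ac", `FALSE` = "#b2182b"),
      labels = c(`TRUE` = "positive", `FALSE` = "negative"),
      name = "partial correlation") +
    ggplot2::scale_linewidth(range = c(0.2, 2.5)) +
    ggplot2::geom_point(data = lay, ggplot2::aes(.data$x, .data$y),
                        size = 10, shape = 21, fill = "white") +
    ggplot2::geom_text(data = lay,
                       ggplot2::aes(.data$x, .data$y, label = .data$node),
                       size = 3) +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
}

#' @export
autoplot.clpn_network <- function(object, threshold = NULL, ...) {
  thr <- threshold %||% object$report_threshold
  lay <- circle_layout(object$node_labels)
  edges <- reported_edges(object, threshold = thr) |>
    dplyr::filter(.data$type == "cross_lagged") |>
    dplyr::left_join(dplyr::rename(lay, xa = "x", ya = "y"),
                     by = c(from = "node")) |>
    dplyr::left_join(dplyr::rename(lay, xb = "x", yb = "y"),
                     by = c(to = "node"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$xa, y = .data$ya, xend = .data$xb,
                   yend = .data$yb, linewidth = abs(.data$weight),
                   colour = .data$weight > 0),
      arrow = ggplot2::arrow(length = ggplot2::unit(0.18, "inches"),
                             type = "closed"),
      show.legend = c(linewidth = FALSE, colour = TRUE)) +
    ggplot2::scale_colour_manual(
      values = c(`TRUE` = "#2166ac", `FALSE` = "#b2182b"),
      labels = c(`TRUE` = "positive", `FALSE` = "negative"),
      name = "lagged effect") +
    ggplot2::scale_linewidth(range = c(0.3, 2)) +
    ggplot2::geom_point(data = lay, ggplot2::aes(.data$x, .data$y),
                        size = 10, shape = 21, fill = "white") +
    ggplot2::geom_text(data = lay,
                       ggplot2::aes(.data$x, .data$y, label = .data$node),
                       size = 3) +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
}

#' Standardized centrality line plot
#'
#' Mirrors the standardized centrality display convention: z-scored
#' strength and expected influence per node, one line per wave.
#'
#' @param ... Named [centrality_table()] outputs, e.g.
#'   `plot_centrality(T0 = ct0, T1 = ct1)`.
#' @return A ggplot object.
#' @export
plot_centrality <- function(...) {
  tabs <- list(...)
  stopifnot(length(tabs) >= 1, !is.null(names(tabs)))
  df <- purrr::imap_dfr(tabs, ~ dplyr::mutate(.x, wave = .y)) |>
    tidyr::pivot_longer(c("z_strength", "z_expected_influence"),
                        names_to = "index", values_to = "z") |>
    dplyr::mutate(index = dplyr::recode(.data$index,
                                        z_strength = "strength",
                                        z_expected_influence = "expected influence"))
  ggplot2::ggplot(df, ggplot2::aes(.data$z, .data$node, colour = .data$wave,
                                   group = .data$wave)) +
    ggplot2::geom_path() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~index) +
    ggplot2::labs(x = "z score", y = NULL, colour = "wave") +
    ggplot2::theme_minimal()
}

#' Bootstrap edge-accuracy plot
#'
#' Edges sorted by sample estimate with their bootstrap quantile intervals.
#'
#' @param boot An `edge_bootstrap` table from [bootstrap_edges()].
#' @return A ggplot object.
#' @export
plot_edge_ci <- function(boot) {
  df <- dplyr::mutate(boot,
                      edge = paste(.data$node_a, .data$node_b, sep = "--"))
  df <- dplyr::mutate(df,
                      edge = factor(.data$edge,
                                    levels = df$edge[order(df$estimate)]))
  ggplot2::ggplot(df, ggplot2::aes(.data$estimate, .data$edge)) +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_lower,
                                         xmax = .data$ci_upper),
                            height = 0, colour = "grey60") +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_point(ggplot2::aes(x = .data$boot_mean), size = 1,
                        colour = "#b2182b", shape = 1) +
    ggplot2::labs(x = "edge weight", y = NULL) +
    ggplot2::theme_minimal()
}

#' Case-dropping stability plot
#'
#' Mean subsample-to-full-sample centrality correlation against the drop
#' proportion, with an empirical quantile band.
#'
#' @param stability A `stability_result` from [cs_coefficient()] (or a
#'   list of them, named by wave/index).
#' @param band Quantile band width (default central 95%).
#' @return A ggplot object.
#' @export
plot_stability <- function(stability, band = 0.95) {
  if (inherits(stability, "stability_result")) {
    stability <- list(stability = stability)
  }
  df <- purrr::imap_dfr(stability, function(st, nm) {
    dplyr::mutate(st$correlations, series = paste(nm, st$index))
  })
  a <- (1 - band) / 2
  summ <- df |>
    dplyr::group_by(.data$series, .data$drop) |>
    dplyr::summarise(
      mid = mean(.data$correlation, na.rm = TRUE),
      lo = quantile(.data$correlation, a, na.rm = TRUE),
      hi = quantile(.data$correlation, 1 - a, na.rm = TRUE),
      .groups = "drop")
  ggplot2::ggplot(summ, ggplot2::aes(.data$drop, .data$mid,
                                     colour = .data$series,
                                     fill = .data$series)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0.7, linetype = 2) +
    ggplot2::labs(x = "proportion of cases dropped",
                  y = "correlation with full-sample centrality",
                  colour = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}
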