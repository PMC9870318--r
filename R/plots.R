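#' Plot sweeps of one neuron
#'
#' Stacked voltage (or clamp-current) traces, one facet strip per step.
#'
#' @param sweeps Sweep-set tibble (`step`, `time_ms`, `response`).
#' @param steps Optional subset of step amplitudes to draw.
#' @return A ggplot.
#' @export
plot_sweeps <- function(sweeps, steps = NULL) {
  if (!is.null(steps)) sweeps <- filter(sweeps, .data$step %in% steps)
  ggplot2::ggplot(sweeps,
                  ggplot2::aes(.data$time_ms, .data$response,
                               group = .data$step,
                               colour = factor(.data$step))) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (ms)", y = "response", colour = "step") +
    ggplot2::theme_minimal()
}

#' Frequency-current (f-I) summary by type
#'
#' Mean +/- SEM of evoked spike counts per step and type, the standard
#' excitability panel.
#'
#' @param step_features Long table from [extract_step_features()].
#' @param labels Tibble `neuron_id`, `label`.
#' @param feature Which long feature to draw.
#' @return A ggplot.
#' @export
plot_fi_curve <- function(step_features, labels,
                          feature = "evoked_spikes") {
  d <- step_features |>
    filter(.data$feature == !!feature) |>
    left_join(labels[c("neuron_id", "label")], by = "neuron_id") |>
    filter(.data$label != "Excluded")
  s <- summarize_groups(d, .data$value, .data$label, .data$step)
  ggplot2::ggplot(s, ggplot2::aes(.data$step, .data$mean,
                                  colour = .data$label)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$mean - .data$sem, ymax = .data$mean + .data$sem),
      size = 0.2) +
    ggplot2::labs(x = "step", y = feature, colour = "type") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Dendrogram of a Ward linkage tree
#'
#' @param object A [ward_linkage()] tree.
#' @param ... Unused.
#' @return A ggplot drawing the merge structure with leaves in tree order.
#' @export
autoplot.ward_linkage <- function(object, ...) {
  n <- length(object$labels)
  xpos <- numeric(n)
  xpos[object$order] <- seq_len(n)
  node_x <- numeric(n - 1)
  node_segments <- purrr::map(seq_len(n - 1), function(s) {
    at <- function(k) {
      if (k < 0) c(x = xpos[-k], h = 0) else c(x = node_x[k], h = object$height[k])
    }
    l <- at(object$merge[s, 1]); r <- at(object$merge[s, 2])
    node_x[s] <<- (l["x"] + r["x"]) / 2
    h <- object$height[s]
    tibble(x = c(l[["x"]], l[["x"]], r[["x"]]),
           xend = c(l[["x"]], r[["x"]], r[["x"]]),
           y = c(l[["h"]], h, r[["h"]]),
           yend = c(h, h, h))
  }) |> purrr::list_rbind()
  leaf <- tibble(x = xpos, label = object$labels)
  ggplot2::ggplot(node_segments) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$x, xend = .data$xend,
                                       y = .data$y, yend = .data$yend)) +
    ggplot2::scale_x_continuous(breaks = leaf$x, labels = leaf$label) +
    ggplot2::labs(x = NULL, y = "merge height (ward.D2)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       size = 5))
}

#' Feature heatmap in dendrogram order
#'
#' Tile heatmap of the (scaled) feature matrix with rows in the linkage
#' tree's leaf order, optionally annotated with type labels.
#'
#' @param mat Feature-matrix tibble (pass [standardize()]d values for a
#'   z-scored map).
#' @param tree Matching [ward_linkage()] tree.
#' @param labels Optional tibble `neuron_id`, `label`.
#' @return A ggplot.
#' @export
plot_feature_heatmap <- function(mat, tree, labels = NULL) {
  ord <- tree$labels[tree$order]
  d <- mat |>
    tidyr::pivot_longer(-"neuron_id", names_to = "parameter",
                        values_to = "value") |>
    mutate(neuron_id = factor(.data$neuron_id, levels = ord))
  p <- ggplot2::ggplot(d, ggplot2::aes(.data$parameter, .data$neuron_id,
                                       fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b") +
    ggplot2::labs(x = NULL, y = NULL, fill = "z") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_text(size = 4))
  p
}

#' Normalized ISI histogram panel
#'
#' @param hist Tibble from [isi_histogram()].
#' @return A ggplot faceted by type.
#' @export
plot_isi_histogram <- function(hist) {
  ggplot2::ggplot(hist, ggplot2::aes(.data$bin_lo, .data$norm_count)) +
    ggplot2::geom_col(width = unique(hist$bin_hi - hist$bin_lo)[1],
                      just = 0, fill = "grey30") +
    ggplot2::facet_wrap(~type) +
    ggplot2::labs(x = "inter-spike interval (ms)",
                  y = "count / neurons of type") +
    ggplot2::theme_minimal()
}
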