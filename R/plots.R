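#' @importFrom ggplot2 ggplot aes geom_line geom_point geom_histogram
#'   geom_col facet_wrap labs theme_minimal autoplot after_stat
#'   stat_function geom_jitter stat_summary
#' @importFrom rlang .data
NULL

#' @export
ggplot2::autoplot

#' Plot fitted two-phase curves over the observed traces
#'
#' @param object a `two_phase_fits` object (the traces it was fitted to
#'   travel along as an attribute).
#' @param cells optional subset of `cell_id`s to show (default: up to 12).
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.two_phase_fits <- function(object, cells = NULL, ...) {
  traces <- attr(object, "traces")
  fits <- tidy(object)
  cells <- cells %||% utils::head(fits$cell_id, 12)
  fits <- fits[fits$cell_id %in% cells, ]
  traces <- traces[traces$cell_id %in% cells, ]
  curves <- purrr::pmap_dfr(fits, function(cell_id, s_inh, s_rec, t_break, rss, y0) {
    t <- seq(min(traces$time_h), max(traces$time_h), length.out = 100)
    tibble::tibble(cell_id = cell_id, time_h = t,
                   rel_activity = y0 + s_inh * pmin(t, t_break) +
                     s_rec * pmax(0, t - t_break))
  })
  ggplot(traces, aes(x = .data$time_h, y = .data$rel_activity)) +
    geom_point(size = 0.6, alpha = 0.6) +
    geom_line(data = curves, colour = "firebrick") +
    facet_wrap(~cell_id) +
    labs(x = "time after treatment (h)", y = "relative ERK activity",
         title = "Two-phase linear fits") +
    theme_minimal()
}

#' Plot a slope histogram with its fitted unimodal and mixture densities
#'
#' @param object a `modality_result`.
#' @param bins histogram bins.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.modality_result <- function(object, bins = 40, ...) {
  x <- object$sample
  df <- tibble::tibble(slope = x)
  mix <- object$mixture
  uni <- object$unimodal
  dens_mix1 <- function(v) mix$weight[1] * dnorm(v, mix$mu[1], mix$sigma[1])
  dens_mix2 <- function(v) mix$weight[2] * dnorm(v, mix$mu[2], mix$sigma[2])
  dens_uni <- function(v) dnorm(v, uni$mu, uni$sigma)
  ggplot(df, aes(x = .data$slope)) +
    geom_histogram(aes(y = after_stat(.data$density)), bins = bins,
                   fill = "grey80", colour = "grey50") +
    stat_function(fun = dens_uni, colour = "black", linetype = "dashed") +
    stat_function(fun = dens_mix1, colour = "steelblue") +
    stat_function(fun = dens_mix2, colour = "firebrick") +
    labs(x = "slope (relative activity / h)", y = "density",
         title = sprintf("Modality: %s (p_uni = %.3g, p_bi = %.3g)",
                         object$verdict, object$p_uni, object$p_bi)) +
    theme_minimal()
}

#' Plot lineage sizes by signaling class
#'
#' Sorted bar plot of per-ancestor lineage sizes, colored by the ancestor's
#' early signaling class.
#'
#' @param records lineage-record tibble (see [count_descendants()]).
#' @return a ggplot.
#' @export
plot_lineage_sizes <- function(records) {
  records <- dplyr::arrange(records, dplyr::desc(.data$lineage_size))
  records$rank <- seq_len(nrow(records))
  ggplot(records, aes(x = .data$rank, y = .data$lineage_size,
                      fill = .data$signaling_class)) +
    geom_col(width = 1) +
    labs(x = "ancestor (sorted by lineage size)", y = "lineage size (cells)",
         fill = "signaling class",
         title = "Lineage sizes by early signaling class") +
    theme_minimal()
}

#' Plot cohort traces grouped by class
#'
#' Mean relative activity over time per class with a one-standard-deviation
#' ribbon.
#'
#' @param traces trace tibble with `rel_activity` (see [normalize_trace()]).
#' @param labels character class labels, one per cell (input order of
#'   `unique(traces$cell_id)`).
#' @return a ggplot.
#' @export
plot_trace_groups <- function(traces, labels) {
  lab_tbl <- tibble::tibble(cell_id = unique(traces$cell_id), label = labels)
  d <- dplyr::left_join(traces, lab_tbl, by = "cell_id") |>
    dplyr::group_by(.data$label, .data$time_h) |>
    dplyr::summarise(mean = mean(.data$rel_activity),
                     sd = sd(.data$rel_activity), .groups = "drop")
  ggplot(d, aes(x = .data$time_h, y = .data$mean, colour = .data$label,
                fill = .data$label)) +
    ggplot2::geom_ribbon(aes(ymin = .data$mean - .data$sd,
                             ymax = .data$mean + .data$sd),
                         alpha = 0.2, colour = NA) +
    geom_line(linewidth = 1) +
    labs(x = "time after treatment (h)", y = "relative ERK activity",
         title = "Signaling profiles by class") +
    theme_minimal()
}
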