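#' Normalize activity traces to each cell's observed dynamic range
#'
#' Rescales raw ring/nucleus activity ratios to relative activity in
#' \[0, 1\] using the minimum and maximum observed within the experiment
#' window. The default normalizes per cell (each cell's own range, matching
#' per-cell "range observed during the experiment" axes); `"global"` uses
#' the range pooled over all cells.
#'
#' Traces that are already in relative-activity units (for instance the
#' output of [simulate_traces()], which generates relative activity
#' directly) should use `method = "none"`, which clips to \[0, 1\] without
#' rescaling: re-normalizing an already-relative trace would divide each
#' cell's slopes by its own observed range and distort the slope
#' distributions.
#'
#' @param traces tibble with columns `cell_id`, `time_h`, `activity`.
#' @param method `"per_cell"` (default), `"global"`, or `"none"`.
#' @return the input tibble with a `rel_activity` column added.
#' @export
#' @examples
#' tr <- tibble::tibble(cell_id = "c1", time_h = 0:2 / 6, activity = c(2, 1, 0.5))
#' normalize_trace(tr)$rel_activity
normalize_trace <- function(traces, method = c("per_cell", "global", "none")) {
  method <- match.arg(method)
  traces <- check_trace_table(traces)
  if (method == "none") {
    # already-relative traces: observation noise may straddle 0 and 1 and
    # must not be truncated, or floor-level slopes become biased
    return(dplyr::mutate(traces, rel_activity = .data$activity))
  }
  if (method == "global") {
    rng <- range(traces$activity)
    if (diff(rng) == 0) abort("zero dynamic range: all activities identical")
    return(dplyr::mutate(traces,
                         rel_activity = (.data$activity - rng[1]) / diff(rng)))
  }
  out <- traces |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::mutate(
      .min = min(.data$activity), .max = max(.data$activity),
      rel_activity = (.data$activity - .data$.min) / (.data$.max - .data$.min)
    ) |>
    dplyr::ungroup()
  bad <- unique(out$cell_id[out$.max == out$.min])
  if (length(bad) > 0) {
    abort(paste0("zero dynamic range for cell(s): ",
                 paste(utils::head(bad, 5), collapse = ", ")))
  }
  dplyr::select(out, -".min", -".max")
}

#' Fit the three-parameter two-phase linear model to each cell
#'
#' Fits `y(t) = y0 + s_inh * min(t, t_break) + s_rec * max(0, t - t_break)`
#' to each cell's relative-activity trace: a continuous piecewise-linear
#' curve with an inhibition slope, a reactivation slope, and one breakpoint.
#' `y0` is anchored to the first observed value, so the three free
#' parameters are `(s_inh, s_rec, t_break)`. The breakpoint is searched on
#' the observation grid (every candidate leaving at least two points per
#' segment); at each candidate the two slopes have a closed-form
#' least-squares solution. The fit with minimal residual sum of squares is
#' returned, ties broken toward the earliest breakpoint.
#'
#' @param traces tibble with columns `cell_id`, `time_h`, `rel_activity`
#'   (see [normalize_trace()]); each cell needs at least 5 points.
#' @return a tibble of class `two_phase_fits` with one row per cell:
#'   `cell_id`, `s_inh`, `s_rec`, `t_break`, `rss`, `y0`. The input traces
#'   are attached as attribute `"traces"` for plotting.
#' @export
#' @examples
#' cohort <- simulate_traces(population_params(n_cells = 3, obs_noise_sd = 0), seed = 1)
#' fits <- cohort$traces |> normalize_trace() |> fit_two_phase()
#' fits
fit_two_phase <- function(traces) {
  traces <- check_trace_table(traces, need_rel = TRUE)
  fits <- traces |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::arrange(.data$time_h, .by_group = TRUE) |>
    dplyr::summarise(fit_two_phase_one(.data$time_h, .data$rel_activity),
                     .groups = "drop")
  fits <- fits[match(unique(traces$cell_id), fits$cell_id), ]
  structure(tibble::as_tibble(fits),
            traces = traces,
            class = c("two_phase_fits", class(tibble::tibble())))
}

# Closed-form grid fit for a single cell. Times must be sorted.
fit_two_phase_one <- function(t, y) {
  n <- length(t)
  if (n < 5) abort("two-phase fit needs at least 5 points per cell")
  y0 <- y[1]
  z <- y - y0
  best <- NULL
  for (k in 2:(n - 2)) {       # >= 2 points in each segment
    tb <- t[k]
    x1 <- pmin(t, tb)
    x2 <- pmax(0, t - tb)
    s11 <- sum(x1 * x1); s12 <- sum(x1 * x2); s22 <- sum(x2 * x2)
    b1 <- sum(x1 * z); b2 <- sum(x2 * z)
    det <- s11 * s22 - s12 * s12
    if (det <= .Machine$double.eps * s11 * s22) next
    s_inh <- (s22 * b1 - s12 * b2) / det
    s_rec <- (s11 * b2 - s12 * b1) / det
    rss <- sum((z - s_inh * x1 - s_rec * x2)^2)
    # strict improvement only: equal-rss ties keep the earliest breakpoint
    if (is.null(best) || rss < best$rss - 1e-12 * (1 + best$rss)) {
      best <- list(s_inh = s_inh, s_rec = s_rec, t_break = tb, rss = rss)
    }
  }
  if (is.null(best)) abort("two-phase fit failed: no feasible breakpoint")
  tibble::tibble(s_inh = best$s_inh, s_rec = best$s_rec,
                 t_break = best$t_break, rss = best$rss, y0 = y0)
}

#' Extract aligned inhibition- and reactivation-slope samples
#'
#' @param fits a `two_phase_fits` tibble (or any tibble with `s_inh`,
#'   `s_rec`).
#' @return a list with numeric vectors `inhibition` and `reactivation`,
#'   one entry per cell in input order.
#' @export
extract_slopes <- function(fits) {
  stopifnot(all(c("s_inh", "s_rec") %in% names(fits)))
  list(inhibition = as.numeric(fits$s_inh),
       reactivation = as.numeric(fits$s_rec))
}

check_trace_table <- function(traces, need_rel = FALSE) {
  traces <- tibble::as_tibble(traces)
  need <- c("cell_id", "time_h", "activity"[!need_rel], "rel_activity"[need_rel])
  missing <- setdiff(need, names(traces))
  if (length(missing) > 0) {
    abort(paste0("trace table is missing column(s): ", paste(missing, collapse = ", ")))
  }
  traces
}
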