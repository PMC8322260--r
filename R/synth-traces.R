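#' Simulate a cohort of single-cell ERK activity traces
#'
#' Draws per-cell two-phase linear signaling dynamics: relative activity
#' starts at 1.0, declines at the cell's inhibition slope until its
#' breakpoint, then continues at its reactivation slope. The noiseless curve
#' is continuous at the breakpoint and clipped to \[0, 1\]; i.i.d. Gaussian
#' observation noise is added on top. Cells are assigned to the reactivating
#' class with probability `frac_recovering` and draw their reactivation
#' slope from the matching mixture component.
#'
#' @param params a [population_params()] object.
#' @param seed integer seed; identical seeds and parameters give
#'   byte-identical output.
#' @return a list with class `ktr_cohort`:
#' \describe{
#'   \item{traces}{tibble with columns `cell_id`, `time_h`, `activity`
#'     (noisy relative activity).}
#'   \item{cells}{tibble of ground truth per cell: `cell_id`, `class`
#'     (`"recovering"`/`"flat"`), true `s_inh`, `s_rec`, `t_break`, `y0`.}
#' }
#' @export
#' @examples
#' cohort <- simulate_traces(population_params(n_cells = 5), seed = 1)
#' dplyr::count(cohort$cells, class)
simulate_traces <- function(params = population_params(), seed = NULL) {
  if (!inherits(params, "population_params")) {
    stop_param("`params` must be created with population_params()")
  }
  with_seed(seed, {
    n <- params$n_cells
    times <- seq(0, params$horizon, by = params$frame_interval / 60)
    recovering <- rbinom(n, 1L, params$frac_recovering) == 1L
    s_inh <- rnorm(n, params$inh_slope_mean, params$inh_slope_sd)
    s_rec <- ifelse(
      recovering,
      rnorm(n, params$rec_slope_mean_recovering, params$rec_slope_sd_recovering),
      rnorm(n, params$rec_slope_mean_flat, params$rec_slope_sd_flat)
    )
    t_break <- pmin(pmax(rnorm(n, params$t_break_mean, params$t_break_sd),
                         times[2]), params$horizon - times[2])
    # the breakpoint is the decline-arrest time: cells whose inhibition
    # slope would carry them below the activity floor before their drawn
    # breakpoint stop declining when they hit the floor, so every noiseless
    # curve is an exact two-phase curve within [0, 1]; breakpoints are then
    # snapped down to the sampling grid (a breakpoint is only identifiable
    # at the frame resolution)
    t_floor <- ifelse(s_inh < 0, 1 / abs(s_inh), Inf)
    dt <- params$frame_interval / 60
    t_break <- pmax(floor(pmin(t_break, t_floor) / dt) * dt, times[2])
    cells <- tibble::tibble(
      cell_id = sprintf("cell_%04d", seq_len(n)),
      class = ifelse(recovering, "recovering", "flat"),
      s_inh = s_inh, s_rec = s_rec, t_break = t_break, y0 = 1.0
    )
    traces <- purrr::map_dfr(seq_len(n), function(i) {
      y <- two_phase_curve(times, 1.0, s_inh[i], s_rec[i], t_break[i])
      if (params$obs_noise_sd > 0) {
        y <- y + rnorm(length(times), 0, params$obs_noise_sd)
      }
      tibble::tibble(cell_id = cells$cell_id[i], time_h = times, activity = y)
    })
    structure(list(traces = traces, cells = cells), class = "ktr_cohort")
  })
}

# Noiseless two-phase piecewise-linear relative-activity curve, continuous
# at the breakpoint and clipped to [0, 1].
two_phase_curve <- function(t, y0, s_inh, s_rec, t_break) {
  y <- y0 + s_inh * pmin(t, t_break) + s_rec * pmax(0, t - t_break)
  pmin(pmax(y, 0), 1)
}

#' @export
print.ktr_cohort <- function(x, ...) {
  n <- nrow(x$cells)
  cat(sprintf("<ktr_cohort> %d cells, %d time points each (%.0f%% reactivating)\n",
              n, nrow(x$traces) / max(n, 1L),
              100 * mean(x$cells$class == "recovering")))
  invisible(x)
}
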