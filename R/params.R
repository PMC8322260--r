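#' Population parameters for the synthetic signaling cohort
#'
#' Defines the two-component population of single-cell ERK activity traces
#' that the generator emulates: every cell is inhibited after drug addition
#' (negative inhibition slope), and a minority fraction reactivates signaling
#' after the breakpoint (positive reactivation slope) while the rest stay
#' flat. Slopes are in relative-activity units per hour, times in hours.
#'
#' Defaults encode the study conditions: cells imaged every 10 minutes over
#' 4 hours, maximal inhibition reached about 1 hour after treatment, and a
#' reactivating subpopulation of about 15% of cells. Component spreads are
#' chosen so the flat and reactivating slope components are separated by
#' well over three pooled standard deviations.
#'
#' @param n_cells number of cells in the cohort.
#' @param frac_recovering fraction of cells in the reactivating class.
#' @param inh_slope_mean,inh_slope_sd inhibition-slope component (per hour;
#'   mean negative).
#' @param rec_slope_mean_recovering,rec_slope_sd_recovering reactivation
#'   slope component of reactivating cells (per hour; mean positive).
#' @param rec_slope_mean_flat,rec_slope_sd_flat reactivation slope component
#'   of non-reactivating cells (per hour; mean ~ 0).
#' @param t_break_mean,t_break_sd breakpoint time (hours).
#' @param obs_noise_sd i.i.d. Gaussian observation noise on each sampled
#'   activity value (relative-activity units).
#' @param frame_interval sampling interval in minutes.
#' @param horizon trace duration in hours.
#' @return an object of class `population_params`.
#' @export
#' @examples
#' population_params(n_cells = 10)
population_params <- function(n_cells = 1000,
                              frac_recovering = 0.15,
                              inh_slope_mean = -1.0,
                              inh_slope_sd = 0.15,
                              rec_slope_mean_recovering = 0.15,
                              rec_slope_sd_recovering = 0.03,
                              rec_slope_mean_flat = 0.0,
                              rec_slope_sd_flat = 0.005,
                              t_break_mean = 1.0,
                              t_break_sd = 0.15,
                              obs_noise_sd = 0.03,
                              frame_interval = 10,
                              horizon = 4) {
  check_number(n_cells, "n_cells", lower = 1)
  check_fraction(frac_recovering, "frac_recovering")
  check_number(inh_slope_sd, "inh_slope_sd", lower = 0)
  check_number(rec_slope_sd_recovering, "rec_slope_sd_recovering", lower = 0)
  check_number(rec_slope_sd_flat, "rec_slope_sd_flat", lower = 0)
  check_number(t_break_sd, "t_break_sd", lower = 0)
  check_number(obs_noise_sd, "obs_noise_sd", lower = 0)
  check_number(frame_interval, "frame_interval", lower = 0, strict_lower = TRUE)
  check_number(horizon, "horizon", lower = 3 * frame_interval / 60)
  structure(
    list(
      n_cells = as.integer(n_cells), frac_recovering = frac_recovering,
      inh_slope_mean = inh_slope_mean, inh_slope_sd = inh_slope_sd,
      rec_slope_mean_recovering = rec_slope_mean_recovering,
      rec_slope_sd_recovering = rec_slope_sd_recovering,
      rec_slope_mean_flat = rec_slope_mean_flat,
      rec_slope_sd_flat = rec_slope_sd_flat,
      t_break_mean = t_break_mean, t_break_sd = t_break_sd,
      obs_noise_sd = obs_noise_sd, frame_interval = frame_interval,
      horizon = horizon
    ),
    class = "population_params"
  )
}

#' Imaging parameters for rendered synthetic time-lapse movies
#'
#' Controls the geometry and noise of the rendered two-channel movies:
#' nuclei appear as 2-D Gaussian blobs in the nuclear-tag channel; the
#' reporter channel splits a fixed per-cell total intensity between a
#' nuclear disk and a surrounding cytoplasm annulus according to the
#' activity-to-localization map (see [render_timelapse()]).
#'
#' @param field_shape image height and width in pixels (length-2 integer).
#' @param n_fields number of imaging fields the cohort is spread across.
#' @param nucleus_radius_mean,nucleus_radius_sd nucleus radius (pixels).
#' @param cell_motion_sd random per-frame cell displacement (pixels/frame).
#' @param drift_per_frame global stage drift per frame, `c(dx, dy)` pixels.
#' @param background_gradient_amp amplitude of the smooth background
#'   gradient (intensity units; nuclear blob amplitude is 1).
#' @param shot_noise_scale scale of the Poisson-like pixel noise
#'   (standard deviation is `shot_noise_scale * sqrt(signal)`).
#' @param detach_prob,divide_prob per-cell per-frame probabilities of
#'   detaching (disappearing) and of dividing.
#' @return an object of class `imaging_params`.
#' @export
imaging_params <- function(field_shape = c(512L, 512L),
                           n_fields = 1L,
                           nucleus_radius_mean = 7,
                           nucleus_radius_sd = 0.6,
                           cell_motion_sd = 1.0,
                           drift_per_frame = c(2, -1),
                           background_gradient_amp = 0.1,
                           shot_noise_scale = 0.02,
                           detach_prob = 0.004,
                           divide_prob = 0.002) {
  if (length(field_shape) != 2L || any(field_shape < 32)) {
    stop_param("`field_shape` must be two pixel dimensions >= 32")
  }
  check_number(n_fields, "n_fields", lower = 1)
  check_number(nucleus_radius_mean, "nucleus_radius_mean", lower = 0, strict_lower = TRUE)
  check_number(nucleus_radius_sd, "nucleus_radius_sd", lower = 0)
  check_number(cell_motion_sd, "cell_motion_sd", lower = 0)
  if (length(drift_per_frame) != 2L || !is.numeric(drift_per_frame)) {
    stop_param("`drift_per_frame` must be a numeric (dx, dy) pair")
  }
  check_number(background_gradient_amp, "background_gradient_amp", lower = 0)
  check_number(shot_noise_scale, "shot_noise_scale", lower = 0)
  check_fraction(detach_prob, "detach_prob")
  check_fraction(divide_prob, "divide_prob")
  structure(
    list(
      field_shape = as.integer(field_shape), n_fields = as.integer(n_fields),
      nucleus_radius_mean = nucleus_radius_mean,
      nucleus_radius_sd = nucleus_radius_sd,
      cell_motion_sd = cell_motion_sd,
      drift_per_frame = as.numeric(drift_per_frame),
      background_gradient_amp = background_gradient_amp,
      shot_noise_scale = shot_noise_scale,
      detach_prob = detach_prob, divide_prob = divide_prob
    ),
    class = "imaging_params"
  )
}

#' Growth parameters for the lineage simulation
#'
#' Class-dependent proliferation over a multi-day horizon. Under the default
#' `"delayed-arrest"` model every cell completes a further in-progress
#' division with probability `p0` before arresting (cells escape drug-induced
#' G1 arrest only until their current cycle completes); reactivating cells
#' then resume dividing as a Poisson (Yule) process at rate `lambda`.
#' `(p0, lambda)` are solved from the target class means before simulation,
#' so the expected lineage size at the horizon equals
#' `mean_lineage_flat` for non-reactivating ancestors and
#' `mean_lineage_recovering` for reactivating ones. The `"rate-switch"`
#' model instead gives each class its own pure birth rate.
#'
#' @param horizon_days observation horizon in days.
#' @param mean_lineage_recovering,mean_lineage_flat target mean lineage sizes
#'   (cells at horizon, ancestor counted) for the two classes.
#' @param division_model `"delayed-arrest"` (default) or `"rate-switch"`.
#' @return an object of class `growth_params`.
#' @export
growth_params <- function(horizon_days = 7,
                          mean_lineage_recovering = 6.6,
                          mean_lineage_flat = 2.7,
                          division_model = c("delayed-arrest", "rate-switch")) {
  division_model <- match.arg(division_model)
  check_number(horizon_days, "horizon_days", lower = 0)
  check_number(mean_lineage_recovering, "mean_lineage_recovering", lower = 1)
  check_number(mean_lineage_flat, "mean_lineage_flat", lower = 1)
  structure(
    list(
      horizon_days = horizon_days,
      mean_lineage_recovering = mean_lineage_recovering,
      mean_lineage_flat = mean_lineage_flat,
      division_model = division_model
    ),
    class = "growth_params"
  )
}

#' Segmentation parameters for nuclei detection and ring quantification
#'
#' @param tophat_radius disk radius (pixels) of the white top-hat used for
#'   illumination correction; should exceed the typical nucleus radius.
#' @param threshold_method `"otsu"` (parameter-free, default) or `"fixed"`.
#' @param fixed_threshold absolute threshold used when
#'   `threshold_method = "fixed"`.
#' @param min_area,max_area object area filter (pixels^2).
#' @param max_eccentricity objects more elongated than this are discarded
#'   (debris, merged nuclei).
#' @param ring_gap,ring_width cytoplasm ring geometry: the ring spans
#'   distances `(ring_gap, ring_gap + ring_width]` from the nucleus boundary.
#' @param background_percentile percentile (percent, in (0, 50)) of
#'   off-cell reporter pixels used as the background estimate.
#' @param ring_statistic summary statistic for ring pixels: `"p80"`
#'   (80th percentile, mirroring the nuclear statistic) or `"median"`.
#' @return an object of class `segmentation_params`.
#' @export
segmentation_params <- function(tophat_radius = 15,
                                threshold_method = c("otsu", "fixed"),
                                fixed_threshold = NULL,
                                min_area = 20,
                                max_area = 500,
                                max_eccentricity = 0.95,
                                ring_gap = 1,
                                ring_width = 3,
                                background_percentile = 25,
                                ring_statistic = c("p80", "median")) {
  threshold_method <- match.arg(threshold_method)
  ring_statistic <- match.arg(ring_statistic)
  check_number(tophat_radius, "tophat_radius", lower = 0, strict_lower = TRUE)
  check_number(min_area, "min_area", lower = 0)
  check_number(max_area, "max_area", lower = min_area, strict_lower = TRUE)
  check_fraction(max_eccentricity, "max_eccentricity")
  check_number(ring_gap, "ring_gap", lower = 0)
  check_number(ring_width, "ring_width", lower = 1)
  check_number(background_percentile, "background_percentile", lower = 0, upper = 50,
               strict_lower = TRUE)
  if (background_percentile >= 50) stop_param("`background_percentile` must be < 50")
  if (threshold_method == "fixed" && is.null(fixed_threshold)) {
    stop_param("`fixed_threshold` required when threshold_method = \"fixed\"")
  }
  structure(
    list(
      tophat_radius = tophat_radius, threshold_method = threshold_method,
      fixed_threshold = fixed_threshold, min_area = min_area,
      max_area = max_area, max_eccentricity = max_eccentricity,
      ring_gap = ring_gap, ring_width = ring_width,
      background_percentile = background_percentile,
      ring_statistic = ring_statistic
    ),
    class = "segmentation_params"
  )
}

#' Tracking parameters
#'
#' Conservative filters for frame-to-frame linking: links longer than
#' `max_displacement` (after drift correction) or with a relative area
#' change above `max_area_change` (typically mitosis) are dropped.
#'
#' @param max_displacement maximum allowed drift-corrected displacement
#'   (pixels per frame).
#' @param max_area_change maximum allowed relative area change, in (0, 1).
#' @param require_complete keep only tracks spanning every frame.
#' @return an object of class `tracking_params`.
#' @export
tracking_params <- function(max_displacement = 20,
                            max_area_change = 0.3,
                            require_complete = TRUE) {
  check_number(max_displacement, "max_displacement", lower = 0, strict_lower = TRUE)
  check_number(max_area_change, "max_area_change", lower = 0, upper = 1, strict_lower = TRUE)
  if (max_area_change >= 1) stop_param("`max_area_change` must be < 1")
  structure(
    list(max_displacement = max_displacement,
         max_area_change = max_area_change,
         require_complete = isTRUE(require_complete)),
    class = "tracking_params"
  )
}

#' @export
print.population_params <- function(x, ...) {
  cat("<population_params>\n")
  cat(sprintf("  %d cells, %.0f%% reactivating\n", x$n_cells, 100 * x$frac_recovering))
  cat(sprintf("  inhibition slope  N(%.2f, %.2f) /h\n", x$inh_slope_mean, x$inh_slope_sd))
  cat(sprintf("  reactivation slope N(%.2f, %.2f) /h (recovering), N(%.2f, %.2f) /h (flat)\n",
              x$rec_slope_mean_recovering, x$rec_slope_sd_recovering,
              x$rec_slope_mean_flat, x$rec_slope_sd_flat))
  cat(sprintf("  breakpoint N(%.2f, %.2f) h; noise sd %.3f; %g min x %g h\n",
              x$t_break_mean, x$t_break_sd, x$obs_noise_sd,
              x$frame_interval, x$horizon))
  invisible(x)
}

#' @export
print.growth_params <- function(x, ...) {
  cat("<growth_params>\n")
  cat(sprintf("  %s model, %g-day horizon; target means %.1f (recovering) / %.1f (flat)\n",
              x$division_model, x$horizon_days,
              x$mean_lineage_recovering, x$mean_lineage_flat))
  invisible(x)
}
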