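# Independent oracles used across the suite.

# Exhaustive two-phase least squares: at every feasible grid breakpoint,
# solve the two slopes with a generic solver (lm) and keep the best rss.
oracle_two_phase <- function(t, y) {
  o <- order(t)
  t <- t[o]; y <- y[o]
  n <- length(t)
  y0 <- y[1]
  z <- y - y0
  best <- NULL
  for (k in 2:(n - 2)) {
    tb <- t[k]
    x1 <- pmin(t, tb)
    x2 <- pmax(0, t - tb)
    fit <- stats::lm(z ~ 0 + x1 + x2)
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss - 1e-12 * (1 + best$rss)) {
      best <- list(s_inh = unname(stats::coef(fit)[1]),
                   s_rec = unname(stats::coef(fit)[2]),
                   t_break = tb, rss = rss)
    }
  }
  best
}

# Small synthetic cohorts for imaging tests: constant-activity traces with
# activities spread over [0, 1], so rendered frames carry a full activity
# gradient across cells.
constant_activity_cohort <- function(n_cells, n_frames = 5, interval_min = 10) {
  act <- seq(0, 1, length.out = n_cells)
  times <- (seq_len(n_frames) - 1) * interval_min / 60
  ids <- sprintf("cell_%03d", seq_len(n_cells))
  traces <- purrr::map_dfr(seq_len(n_cells), function(i) {
    tibble::tibble(cell_id = ids[i], time_h = times, activity = act[i])
  })
  list(traces = traces,
       cells = tibble::tibble(cell_id = ids, class = "flat", activity = act))
}

quiet_imaging_params <- function(...) {
  args <- list(cell_motion_sd = 0, drift_per_frame = c(0, 0),
               background_gradient_amp = 0, shot_noise_scale = 0,
               detach_prob = 0, divide_prob = 0, nucleus_radius_sd = 0)
  args <- utils::modifyList(args, list(...))
  do.call(imaging_params, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# run code under a local seed without disturbing the suite's RNG stream
with_seed_test <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(code)
}
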