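#' Configuration for an end-to-end run
#'
#' Bundles every stage's parameters with a single reproducibility seed.
#' All stochastic stages derive their own sub-seed from `seed`, so two runs
#' with identical configuration produce identical reports and tables.
#'
#' @param seed master integer seed.
#' @param out_dir output directory for intermediate tables and the report;
#'   `NULL` keeps everything in memory.
#' @param population [population_params()] for the synthetic cohort.
#' @param use_imaging if `TRUE`, traces are obtained by rendering a movie
#'   and running segmentation, quantification and tracking; otherwise the
#'   generated trace table feeds the dynamics stage directly.
#' @param imaging,segmentation,tracking parameter objects for the imaging
#'   path.
#' @param growth [growth_params()] for the lineage stage (`NULL` skips it).
#' @param alpha,n_boot modality-test level and bootstrap replicates.
#' @param normalization passed to [normalize_trace()]; `NULL` (default)
#'   picks `"none"` for the direct trace path (generated traces are already
#'   relative) and `"per_cell"` for the imaging path (ring/nucleus ratios
#'   are raw).
#' @return list of class `run_config`.
#' @export
run_config <- function(seed = 1,
                       out_dir = NULL,
                       population = population_params(),
                       use_imaging = FALSE,
                       imaging = imaging_params(),
                       segmentation = segmentation_params(),
                       tracking = tracking_params(),
                       growth = growth_params(),
                       alpha = 0.05,
                       n_boot = 200,
                       normalization = NULL) {
  structure(
    list(seed = seed, out_dir = out_dir, population = population,
         use_imaging = use_imaging, imaging = imaging,
         segmentation = segmentation, tracking = tracking,
         growth = growth, alpha = alpha, n_boot = n_boot,
         normalization = normalization),
    class = "run_config"
  )
}

#' Run the full analysis end to end
#'
#' Executes generate -> (render -> quantify -> track) -> normalize -> fit ->
#' modality -> classify -> lineage on a synthetic cohort, writing every
#' intermediate table to `out_dir` (when given) and returning a report.
#' The run is a function of the configuration alone: identical
#' configurations (including the seed) give identical reports.
#'
#' @param config a [run_config()].
#' @param quiet suppress progress messages.
#' @return list of class `run_report`: per-stage counts, the modality
#'   results for inhibition and reactivation slopes, the estimated
#'   reactivating fraction, and (when the lineage stage runs) lineage-size
#'   group statistics.
#' @export
#' @examples
#' \donttest{
#' cfg <- run_config(seed = 1, population = population_params(n_cells = 200),
#'                   n_boot = 100, growth = NULL)
#' report <- run_end_to_end(cfg)
#' report$verdicts
#' }
run_end_to_end <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (!quiet) message("[ktrdyn] ", ...)
  out <- function(name, tbl) {
    if (!is.null(config$out_dir)) {
      dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
      readr::write_csv(tbl, file.path(config$out_dir, paste0(name, ".csv")))
    }
  }
  say("simulating cohort of ", config$population$n_cells, " cells")
  cohort <- simulate_traces(config$population, seed = child_seed(config$seed, 10))
  out("true_cells", cohort$cells)
  if (config$use_imaging) {
    say("rendering and quantifying time-lapse movie")
    render <- render_timelapse(cohort, config$imaging,
                               seed = child_seed(config$seed, 20))
    obs <- purrr::map_dfr(seq_along(render$fields), function(f) {
      o <- quantify_frames(render$fields[[f]]$nuclear,
                           render$fields[[f]]$reporter,
                           config$segmentation)
      tr <- build_tracks(o, config$tracking, masks = attr(o, "masks"))
      tr$track_id <- sprintf("f%d_t%04d", f, tr$track_id)
      tr
    })
    out("tracks", obs)
    traces <- tibble::tibble(
      cell_id = obs$track_id,
      time_h = obs$frame * render$frame_interval / 60,
      activity = ratio_to_activity(obs$activity, config$imaging)
    )
  } else {
    traces <- cohort$traces
  }
  out("traces", traces)
  say("fitting two-phase model to ", dplyr::n_distinct(traces$cell_id), " traces")
  norm_method <- config$normalization %||%
    if (config$use_imaging) "per_cell" else "none"
  fits <- traces |>
    normalize_trace(method = norm_method) |>
    fit_two_phase()
  out("fits", fits)
  slopes <- extract_slopes(fits)
  say("testing modality of slope distributions")
  mod_inh <- decide_modality(slopes$inhibition, alpha = config$alpha,
                             seed = child_seed(config$seed, 30),
                             n_boot = config$n_boot)
  mod_rec <- decide_modality(slopes$reactivation, alpha = config$alpha,
                             seed = child_seed(config$seed, 31),
                             n_boot = config$n_boot)
  labels <- assign_cells(slopes$reactivation, mod_rec$mixture)
  label_tbl <- tibble::tibble(cell_id = fits$cell_id, label = labels)
  out("labels", label_tbl)
  report <- list(
    seed = config$seed,
    n_cells = config$population$n_cells,
    n_traces = dplyr::n_distinct(traces$cell_id),
    n_fits = nrow(fits),
    verdicts = c(inhibition = mod_inh$verdict, reactivation = mod_rec$verdict),
    frac_recovering = mod_rec$frac_recovering,
    p_uni = c(inhibition = mod_inh$p_uni, reactivation = mod_rec$p_uni),
    p_bi = c(inhibition = mod_inh$p_bi, reactivation = mod_rec$p_bi),
    modality = list(inhibition = mod_inh, reactivation = mod_rec),
    labels = label_tbl
  )
  if (!is.null(config$growth)) {
    say("simulating lineages over ", config$growth$horizon_days, " days")
    lab_for_growth <- ifelse(labels == "recovering", "recovering", "flat")
    lin <- simulate_lineages(
      tibble::tibble(cell_id = fits$cell_id, class = lab_for_growth),
      config$growth, seed = child_seed(config$seed, 40)
    )
    out("lineage_events", lin$events)
    recs <- count_descendants(
      lin$events,
      tibble::tibble(ancestor_id = lin$records$ancestor_id,
                     signaling_class = ifelse(lab_for_growth == "recovering",
                                              "recovering", "non_recovering")),
      config$growth$horizon_days
    )
    out("lineage_records", recs)
    report$lineage <- compare_groups(recs)
  }
  if (!is.null(config$out_dir)) {
    json <- report
    json$modality <- NULL
    json$labels <- NULL
    json$lineage <- if (!is.null(report$lineage)) as.list(report$lineage)
    jsonlite::write_json(json, file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  structure(report, class = "run_report")
}

# Invert the renderer's localization map: measured ring/nucleus intensity
# ratios back to relative activity, using the nominal compartment geometry
# of the imaging parameters.
ratio_to_activity <- function(ratio, iparams) {
  rn <- NUCLEAR_DISK_SCALE * iparams$nucleus_radius_mean
  a_nuc <- pi * rn^2
  a_cyt <- pi * ((rn + ANNULUS_WIDTH)^2 - rn^2)
  kappa <- a_nuc / a_cyt
  cf <- ratio / (ratio + kappa)
  pmin(pmax((cf - 0.3) / 0.5, 0), 1)
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  cat(sprintf("  %d cells -> %d traces -> %d fits\n",
              x$n_cells, x$n_traces, x$n_fits))
  cat(sprintf("  inhibition slopes:   %s (p_uni = %.3g)\n",
              x$verdicts["inhibition"], x$p_uni["inhibition"]))
  cat(sprintf("  reactivation slopes: %s (p_uni = %.3g)\n",
              x$verdicts["reactivation"], x$p_uni["reactivation"]))
  if (!is.na(x$frac_recovering)) {
    cat(sprintf("  reactivating fraction: %.1f%%\n", 100 * x$frac_recovering))
  }
  if (!is.null(x$lineage)) {
    cat(sprintf("  lineage means: %.2f (recovering) vs %.2f (non-recovering), rank-sum p = %.3g\n",
                x$lineage$mean_recovering, x$lineage$mean_non_recovering,
                x$lineage$p_ranksum))
  }
  invisible(x)
}

#' Stratified sample of cells by early signaling dynamics
#'
#' Reproduces the three-way experimental design used for lineage follow-up:
#' reactivating cells (by mixture label), and the non-reactivating pool
#' split at its median reactivation slope into strongly inhibited (below
#' the median) and weakly inhibited (above) strata, sampling `n_per_stratum`
#' cells from each.
#'
#' @param fits `two_phase_fits` tibble.
#' @param labels character vector from [assign_cells()], aligned with
#'   `fits`.
#' @param n_per_stratum cells sampled per stratum (default 60).
#' @param seed integer seed.
#' @return tibble: `cell_id`, `s_rec`, `stratum`
#'   (`recovering` / `inhibited_weak` / `inhibited_strong`).
#' @export
sample_signaling_strata <- function(fits, labels, n_per_stratum = 60,
                                    seed = NULL) {
  stopifnot(nrow(fits) == length(labels))
  with_seed(seed, {
    tbl <- tibble::tibble(cell_id = fits$cell_id, s_rec = fits$s_rec,
                          label = labels)
    rec <- tbl[tbl$label == "recovering", ]
    non <- tbl[tbl$label != "recovering", ]
    med <- median(non$s_rec)
    non$stratum <- ifelse(non$s_rec <= med, "inhibited_strong", "inhibited_weak")
    rec$stratum <- "recovering"
    take <- function(d, n) {
      if (nrow(d) < n) abort(sprintf("stratum %s has only %d cells (< %d)",
                                     d$stratum[1], nrow(d), n))
      d[sample.int(nrow(d), n), ]
    }
    out <- dplyr::bind_rows(
      take(rec, n_per_stratum),
      take(non[non$stratum == "inhibited_strong", ], n_per_stratum),
      take(non[non$stratum == "inhibited_weak", ], n_per_stratum)
    )
    dplyr::select(out, "cell_id", "s_rec", "stratum")
  })
}
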