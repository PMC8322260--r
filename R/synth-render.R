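#' Render a synthetic two-channel time-lapse movie
#'
#' Rasterizes a trace cohort into nuclear-tag and reporter channel stacks
#' with known ground truth. Nuclei appear in the nuclear channel as 2-D
#' Gaussian blobs (sd = radius / 2, unit amplitude). The reporter channel
#' splits a fixed per-cell total intensity between a nuclear disk and a
#' surrounding cytoplasm annulus; the cytoplasmic fraction is the fixed
#' affine map `0.3 + 0.5 * activity` of the cell's current relative
#' activity (clipped to \[0, 1\]), so both compartments always carry
#' signal. Before noise, the summed reporter intensity of a cell is exactly
#' its total intensity in every frame. A smooth background gradient,
#' per-frame global stage drift, random cell motion, division and
#' detachment events, and Poisson-like pixel noise (sd proportional to the
#' square root of the signal) complete the camera model.
#'
#' @param cohort a `ktr_cohort` from [simulate_traces()] (all traces must
#'   share one time grid).
#' @param iparams an [imaging_params()] object; cells are spread
#'   round-robin across `n_fields` fields.
#' @param seed integer seed.
#' @return list of class `ktr_render`:
#'   \describe{
#'     \item{fields}{list per field of `list(nuclear, reporter)`, each a
#'       3-D array `[y, x, frame]`.}
#'     \item{truth}{tibble of ground truth with one row per cell-frame:
#'       `field`, `frame` (0-based), `cell_id`, `x`, `y` (0-based pixel
#'       coordinates), `radius`, `area` (nominal nucleus area in pixels),
#'       `activity` (value driving the localization map).}
#'     \item{frame_interval}{minutes between frames (from the cohort grid).}
#'   }
#' @export
render_timelapse <- function(cohort, iparams = imaging_params(), seed = NULL) {
  traces <- cohort$traces
  cells <- cohort$cells
  times <- sort(unique(traces$time_h))
  n_frames <- length(times)
  per_cell <- split(traces, traces$cell_id)
  if (!all(purrr::map_int(per_cell, nrow) == n_frames)) {
    stop_param("all traces must share a common time grid")
  }
  H <- iparams$field_shape[1]; W <- iparams$field_shape[2]
  with_seed(seed, {
    cell_ids <- cells$cell_id
    field_of <- rep(seq_len(iparams$n_fields), length.out = length(cell_ids))
    radius <- pmax(rnorm(length(cell_ids), iparams$nucleus_radius_mean,
                         iparams$nucleus_radius_sd), 3)
    names(radius) <- cell_ids
    activity_mat <- vapply(cell_ids, function(id) {
      a <- per_cell[[id]]$activity[order(per_cell[[id]]$time_h)]
      pmin(pmax(a, 0), 1)
    }, numeric(n_frames))
    fields <- vector("list", iparams$n_fields)
    truth <- vector("list", iparams$n_fields)
    for (f in seq_len(iparams$n_fields)) {
      ids_f <- cell_ids[field_of == f]
      res <- render_field(ids_f, radius[ids_f],
                          activity_mat[, ids_f, drop = FALSE],
                          n_frames, H, W, iparams)
      fields[[f]] <- res[c("nuclear", "reporter")]
      res$truth$field <- f
      truth[[f]] <- res$truth
    }
    truth <- dplyr::bind_rows(truth)
    truth <- truth[, c("field", "frame", "cell_id", "x", "y", "radius",
                       "area", "activity")]
    structure(
      list(fields = fields, truth = truth,
           frame_interval = if (n_frames > 1) (times[2] - times[1]) * 60 else NA_real_),
      class = "ktr_render"
    )
  })
}

# Localization map: cytoplasmic reporter fraction as a function of activity.
cytoplasmic_fraction <- function(activity) 0.3 + 0.5 * activity

REPORTER_TOTAL <- 300   # fixed per-cell total reporter intensity
ANNULUS_WIDTH <- 5      # cytoplasm annulus width (px) beyond the nuclear disk
NUCLEAR_DISK_SCALE <- 0.8  # reporter nuclear disk radius as fraction of `radius`

render_field <- function(ids, radius, activity_mat, n_frames, H, W, iparams) {
  n <- length(ids)
  margin <- max(c(radius, 8)) + ANNULUS_WIDTH + 2
  # dart-throwing placement with a minimum center distance
  min_dist <- 2 * max(radius) + ANNULUS_WIDTH
  pos <- matrix(NA_real_, n, 2)  # columns x, y
  if (n > 0) {
    for (i in seq_len(n)) {
      placed <- FALSE
      for (try in seq_len(500)) {
        p <- c(runif(1, margin, W - margin), runif(1, margin, H - margin))
        if (i == 1 || all(sqrt(rowSums(sweep(pos[seq_len(i - 1), , drop = FALSE],
                                             2, p)^2)) >= min_dist)) {
          pos[i, ] <- p
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        abort(sprintf("overcrowding beyond field capacity at frame 0 (placing cell %d of %d)", i, n))
      }
    }
  }
  # background gradient, shared by both channels
  gx <- matrix(rep(seq_len(W) / W, each = H), H, W)
  gy <- matrix(rep(seq_len(H) / H, W), H, W)
  bg <- iparams$background_gradient_amp * (0.5 * gx + 0.5 * gy)
  nuclear <- array(0, dim = c(H, W, n_frames))
  reporter <- array(0, dim = c(H, W, n_frames))
  # live-cell state (divisions add rows, detachments remove them)
  state <- tibble::tibble(
    cell_id = ids, src = ids, x = pos[, 1], y = pos[, 2],
    radius = unname(radius)
  )
  truth <- list()
  n_extra <- 0L
  for (fr in seq_len(n_frames)) {
    if (fr > 1 && nrow(state) > 0) {
      # stage drift plus random cell motion, reflected at the margins
      state$x <- reflect(state$x + iparams$drift_per_frame[1] +
                           rnorm(nrow(state), 0, iparams$cell_motion_sd),
                         margin, W - margin)
      state$y <- reflect(state$y + iparams$drift_per_frame[2] +
                           rnorm(nrow(state), 0, iparams$cell_motion_sd),
                         margin, H - margin)
      # detachment
      keep <- runif(nrow(state)) >= iparams$detach_prob
      state <- state[keep, , drop = FALSE]
      # division: replace the mother by two displaced daughters
      div <- which(runif(nrow(state)) < iparams$divide_prob)
      if (length(div) > 0) {
        for (i in div) {
          ang <- runif(1, 0, 2 * pi)
          # daughters are born smaller, so the conservative area filter
          # terminates the mother's track at mitosis
          r_d <- max(0.75 * state$radius[i], 3)
          off <- 1.4 * r_d * c(cos(ang), sin(ang))
          for (s in c(-1, 1)) {
            n_extra <- n_extra + 1L
            state <- dplyr::bind_rows(state, tibble::tibble(
              cell_id = sprintf("%s.d%d", state$cell_id[i], n_extra),
              src = state$src[i],
              x = reflect(state$x[i] + s * off[1], margin, W - margin),
              y = reflect(state$y[i] + s * off[2], margin, H - margin),
              radius = r_d
            ))
          }
        }
        state <- state[-div, , drop = FALSE]
      }
    }
    nuc_f <- bg
    rep_f <- bg
    if (nrow(state) > 0) {
      act <- activity_mat[fr, state$src]
      cf <- cytoplasmic_fraction(act)
      for (i in seq_len(nrow(state))) {
        drawn <- draw_cell(nuc_f, rep_f, state$x[i], state$y[i],
                           state$radius[i], cf[i])
        nuc_f <- drawn$nuc; rep_f <- drawn$rep
      }
      truth[[fr]] <- tibble::tibble(
        frame = fr - 1L, cell_id = state$cell_id,
        x = state$x, y = state$y, radius = state$radius,
        area = pi * (NUCLEAR_DISK_SCALE * state$radius)^2,
        activity = act
      )
    }
    if (iparams$shot_noise_scale > 0) {
      nuc_f <- nuc_f + rnorm(H * W, 0, iparams$shot_noise_scale) * sqrt(pmax(nuc_f, 0))
      rep_f <- rep_f + rnorm(H * W, 0, iparams$shot_noise_scale) * sqrt(pmax(rep_f, 0))
      nuc_f[nuc_f < 0] <- 0
      rep_f[rep_f < 0] <- 0
    }
    nuclear[, , fr] <- nuc_f
    reporter[, , fr] <- rep_f
  }
  list(nuclear = nuclear, reporter = reporter,
       truth = dplyr::bind_rows(truth))
}

reflect <- function(x, lo, hi) {
  out <- x
  out[out < lo] <- 2 * lo - out[out < lo]
  out[out > hi] <- 2 * hi - out[out > hi]
  pmin(pmax(out, lo), hi)
}

# Add one cell to both channel frames (in-place on copies).
draw_cell <- function(nuc_f, rep_f, cx, cy, r, cf) {
  H <- nrow(nuc_f); W <- ncol(nuc_f)
  rn <- NUCLEAR_DISK_SCALE * r
  rout <- rn + ANNULUS_WIDTH
  ext <- ceiling(max(3 * r / 2, rout)) + 1L
  # 0-based pixel coordinates: pixel (row i, col j) sits at x = j-1, y = i-1
  rows <- max(1L, floor(cy + 1 - ext)):min(H, ceiling(cy + 1 + ext))
  cols <- max(1L, floor(cx + 1 - ext)):min(W, ceiling(cx + 1 + ext))
  px <- matrix(rep(cols - 1, each = length(rows)), length(rows))
  py <- matrix(rep(rows - 1, length(cols)), length(rows))
  d2 <- (px - cx)^2 + (py - cy)^2
  sigma <- r / 2
  nuc_f[rows, cols] <- nuc_f[rows, cols] + exp(-d2 / (2 * sigma^2))
  d <- sqrt(d2)
  in_nuc <- d <= rn
  in_ring <- d > rn & d <= rout
  n_nuc <- sum(in_nuc); n_ring <- sum(in_ring)
  sub <- rep_f[rows, cols]
  if (n_nuc > 0) {
    sub[in_nuc] <- sub[in_nuc] + (1 - cf) * REPORTER_TOTAL / n_nuc
  }
  if (n_ring > 0) {
    sub[in_ring] <- sub[in_ring] + cf * REPORTER_TOTAL / n_ring
  }
  rep_f[rows, cols] <- sub
  list(nuc = nuc_f, rep = rep_f)
}

#' Write a rendered movie to multi-page TIFF files
#'
#' Writes one 32-bit float multi-page TIFF per channel per field, named
#' `field<k>_nuclear.tif` and `field<k>_reporter.tif`, plus the ground
#' truth as `truth.csv`.
#'
#' @param render a `ktr_render` from [render_timelapse()].
#' @param dir output directory (created if needed).
#' @param scale intensities are divided by this constant before writing.
#' @return invisibly, the paths written.
#' @export
write_timelapse_tiff <- function(render, dir, scale = 16) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  for (f in seq_along(render$fields)) {
    for (ch in c("nuclear", "reporter")) {
      arr <- render$fields[[f]][[ch]] / scale
      pages <- purrr::map(seq_len(dim(arr)[3]), ~ arr[, , .x])
      p <- file.path(dir, sprintf("field%d_%s.tif", f, ch))
      tiff::writeTIFF(pages, p, bits.per.sample = 32)
      paths <- c(paths, p)
    }
  }
  tp <- file.path(dir, "truth.csv")
  readr::write_csv(render$truth, tp)
  invisible(c(paths, tp))
}

#' Read a multi-page TIFF stack as a 3-D array
#'
#' @param path TIFF file written by [write_timelapse_tiff()] (or any
#'   multi-page grayscale TIFF).
#' @param scale intensities are multiplied by this constant after reading
#'   (inverse of the write-side scaling).
#' @return numeric array `[y, x, frame]`.
#' @export
read_timelapse_tiff <- function(path, scale = 16) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (is.matrix(pages)) pages <- list(pages)
  arr <- array(0, dim = c(nrow(pages[[1]]), ncol(pages[[1]]), length(pages)))
  for (i in seq_along(pages)) arr[, , i] <- pages[[i]] * scale
  arr
}

#' @export
print.ktr_render <- function(x, ...) {
  d <- dim(x$fields[[1]]$nuclear)
  cat(sprintf("<ktr_render> %d field(s), %dx%d px, %d frames, %d cell-frames of truth\n",
              length(x$fields), d[1], d[2], d[3], nrow(x$truth)))
  invisible(x)
}
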