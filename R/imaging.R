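#' Correct uneven illumination with a white top-hat filter
#'
#' Applies a morphological white top-hat (image minus its grayscale opening)
#' with a disk structuring element. Structures smaller than the disk are
#' retained while the smooth background, including flat fields and slow
#' gradients, maps to approximately zero. The radius should exceed the
#' typical nucleus radius so nuclei survive the opening.
#'
#' @param image 2-D numeric matrix (rows = y, columns = x).
#' @param tophat_radius disk radius in pixels (`> 0`).
#' @return matrix of the same shape, non-negative.
#' @export
correct_illumination <- function(image, tophat_radius) {
  check_number(tophat_radius, "tophat_radius", lower = 0, strict_lower = TRUE)
  if (!is.matrix(image) || !is.numeric(image)) {
    stop_param("`image` must be a 2-D numeric matrix")
  }
  opened <- .gray_morph_cpp(.gray_morph_cpp(image, tophat_radius, 0L),
                            tophat_radius, 1L)
  out <- image - opened
  out[out < 0] <- 0
  out
}

#' Segment nuclei in a nuclear-tag frame
#'
#' Thresholds the illumination-corrected nuclear channel (Otsu by default),
#' labels connected components, and discards objects failing the area or
#' eccentricity filters (dust, debris, merged nuclei). Surviving objects are
#' relabeled densely from 1 in ascending original-label order.
#'
#' @param nuclear_image 2-D numeric matrix.
#' @param params a [segmentation_params()] object.
#' @return list with `mask` (integer label matrix, labels dense from 1) and
#'   `observations`: tibble with `object_id`, `x`, `y` (0-based pixel
#'   centroids), `area` (pixels), `eccentricity`, sorted by `object_id`.
#'   An image with no surviving objects gives an empty tibble.
#' @export
segment_nuclei <- function(nuclear_image, params = segmentation_params()) {
  if (!is.matrix(nuclear_image)) stop_param("`nuclear_image` must be a 2-D matrix")
  corrected <- correct_illumination(nuclear_image, params$tophat_radius)
  thr <- if (params$threshold_method == "fixed") {
    params$fixed_threshold
  } else {
    rng <- range(corrected)
    if (diff(rng) == 0) Inf else {
      scaled <- (corrected - rng[1]) / diff(rng)
      EBImage::otsu(EBImage::Image(scaled), range = c(0, 1)) * diff(rng) + rng[1]
    }
  }
  bw <- corrected > thr
  empty <- list(
    mask = matrix(0L, nrow(nuclear_image), ncol(nuclear_image)),
    observations = tibble::tibble(
      object_id = integer(), x = numeric(), y = numeric(),
      area = numeric(), eccentricity = numeric()
    )
  )
  if (!any(bw)) return(empty)
  labels <- EBImage::bwlabel(EBImage::Image(bw * 1))
  # EBImage treats matrix dim 1 as its x axis; our matrices are [y, x], so
  # feature m.cx is our row (y) and m.cy our column (x).
  shp <- EBImage::computeFeatures.shape(labels)
  mom <- EBImage::computeFeatures.moment(labels)
  if (is.null(shp) || nrow(shp) == 0) return(empty)
  area <- shp[, "s.area"]
  ecc <- mom[, "m.eccentricity"]
  keep <- which(area >= params$min_area & area <= params$max_area &
                  ecc <= params$max_eccentricity)
  if (length(keep) == 0) return(empty)
  lab_mat <- as.matrix(EBImage::imageData(labels))
  relabel <- integer(nrow(shp))
  relabel[keep] <- seq_along(keep)
  mask <- matrix(0L, nrow(lab_mat), ncol(lab_mat))
  nz <- lab_mat > 0
  mask[nz] <- relabel[lab_mat[nz]]
  list(
    mask = mask,
    observations = tibble::tibble(
      object_id = seq_along(keep),
      x = as.numeric(mom[keep, "m.cy"]) - 1,
      y = as.numeric(mom[keep, "m.cx"]) - 1,
      area = as.numeric(area[keep]),
      eccentricity = as.numeric(ecc[keep])
    )
  )
}

#' Quantify per-cell reporter activity from a label mask
#'
#' Estimates the background as a low percentile of reporter pixels lying
#' outside all dilated objects and subtracts it (clipping at zero). For each
#' nucleus the reporter summary is the 80th-percentile intensity within the
#' nucleus label; the cytoplasm-ring summary is taken over pixels within
#' `(ring_gap, ring_gap + ring_width]` of the nucleus boundary, excluding
#' any other nucleus and its gap zone. Activity is the ring/nucleus ratio.
#' Observations with an empty ring or zero nuclear intensity are flagged
#' invalid rather than erroring.
#'
#' @param mask integer label matrix from [segment_nuclei()].
#' @param reporter_image reporter-channel matrix, same shape as `mask`.
#' @param params a [segmentation_params()] object.
#' @return tibble with one row per object: `object_id`, `x`, `y`, `area`,
#'   `nuc_int`, `ring_int`, `activity`, `valid`.
#' @export
quantify_activity <- function(mask, reporter_image, params = segmentation_params()) {
  if (!all(dim(mask) == dim(reporter_image))) {
    stop_param("`mask` and `reporter_image` must share shape")
  }
  gap <- params$ring_gap
  width <- params$ring_width
  ids <- sort(unique(mask[mask > 0]))
  # background: percentile of reporter outside all objects + an exclusion halo
  any_obj <- mask > 0
  d_any <- distance_to_objects(any_obj)
  off_cell <- d_any > (gap + width + 1)
  bg <- if (any(off_cell)) {
    quantile(reporter_image[off_cell], params$background_percentile / 100,
             names = FALSE)
  } else 0
  rep_bs <- reporter_image - bg
  rep_bs[rep_bs < 0] <- 0
  if (length(ids) == 0) {
    return(tibble::tibble(object_id = integer(), x = numeric(), y = numeric(),
                          area = numeric(), nuc_int = numeric(),
                          ring_int = numeric(), activity = numeric(),
                          valid = logical()))
  }
  ring_stat <- function(v) {
    if (params$ring_statistic == "p80") quantile(v, 0.8, names = FALSE)
    else median(v)
  }
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- ceiling(gap + width) + 2L
  purrr::map_dfr(ids, function(id) {
    px <- which(mask == id, arr.ind = TRUE)
    nuc_vals <- rep_bs[mask == id]
    nuc_int <- quantile(nuc_vals, 0.8, names = FALSE)
    r0 <- max(1L, min(px[, 1]) - pad); r1 <- min(nr, max(px[, 1]) + pad)
    c0 <- max(1L, min(px[, 2]) - pad); c1 <- min(nc, max(px[, 2]) + pad)
    sub_mask <- mask[r0:r1, c0:c1]
    d_own <- distance_to_objects(sub_mask == id)
    ring <- d_own > gap & d_own <= gap + width &
      d_any[r0:r1, c0:c1] > gap
    ring_px <- rep_bs[r0:r1, c0:c1][ring]
    valid <- length(ring_px) > 0 && nuc_int > 0
    ring_int <- if (length(ring_px) > 0) ring_stat(ring_px) else NA_real_
    tibble::tibble(
      object_id = as.integer(id),
      x = mean(px[, 2]) - 1, y = mean(px[, 1]) - 1,
      area = nrow(px),
      nuc_int = nuc_int, ring_int = ring_int,
      activity = if (valid) ring_int / nuc_int else NA_real_,
      valid = valid
    )
  })
}

# Euclidean distance of every pixel to the nearest TRUE pixel of `obj`.
distance_to_objects <- function(obj) {
  if (!any(obj)) return(matrix(Inf, nrow(obj), ncol(obj)))
  as.matrix(EBImage::distmap(EBImage::Image(1 - obj * 1)))
}

#' Quantify a two-channel time-lapse stack
#'
#' Runs [segment_nuclei()] and [quantify_activity()] on every frame of a
#' two-channel stack and binds the per-frame observation tables.
#'
#' @param nuclear_stack,reporter_stack 3-D arrays `[y, x, frame]` or lists
#'   of matrices.
#' @param params a [segmentation_params()] object.
#' @return tibble with columns `frame` (0-based), `object_id`, `x`, `y`,
#'   `area`, `eccentricity`, `nuc_int`, `ring_int`, `activity`, `valid`.
#'   The per-frame binary nucleus masks are attached as attribute
#'   `"masks"` (used for drift registration).
#' @export
quantify_frames <- function(nuclear_stack, reporter_stack,
                            params = segmentation_params()) {
  nuc <- as_frame_list(nuclear_stack)
  rep_ <- as_frame_list(reporter_stack)
  if (length(nuc) != length(rep_)) stop_param("channel stacks differ in frame count")
  masks <- vector("list", length(nuc))
  obs <- purrr::map_dfr(seq_along(nuc), function(f) {
    seg <- segment_nuclei(nuc[[f]], params)
    masks[[f]] <<- seg$mask
    q <- quantify_activity(seg$mask, rep_[[f]], params)
    if (nrow(q) == 0) {
      return(tibble::tibble(frame = integer(), object_id = integer(),
                            x = numeric(), y = numeric(), area = numeric(),
                            eccentricity = numeric(), nuc_int = numeric(),
                            ring_int = numeric(), activity = numeric(),
                            valid = logical()))
    }
    dplyr::bind_cols(
      tibble::tibble(frame = f - 1L),
      dplyr::left_join(seg$observations,
                       dplyr::select(q, -"x", -"y", -"area"),
                       by = "object_id")
    )
  })
  structure(obs, masks = masks)
}

as_frame_list <- function(stack) {
  if (is.list(stack)) return(stack)
  if (is.array(stack) && length(dim(stack)) == 3) {
    return(purrr::map(seq_len(dim(stack)[3]), ~ stack[, , .x]))
  }
  if (is.matrix(stack)) return(list(stack))
  stop_param("stack must be a list of matrices or a 3-D array")
}

#' Estimate cells per well from imaging-field counts
#'
#' Sums nuclei counts over the imaging fields of a well and multiplies by
#' the conversion coefficient, the ratio of the well surface area to the
#' total area covered by the imaging fields.
#'
#' @param field_counts nuclei counts, one per imaging field.
#' @param well_area well surface area.
#' @param total_field_area total area of the imaging fields (same units).
#' @return estimated number of cells in the well (real-valued).
#' @export
#' @examples
#' count_nuclei_per_well(rep(10, 9), well_area = 4, total_field_area = 1)
count_nuclei_per_well <- function(field_counts, well_area, total_field_area) {
  check_number(well_area, "well_area", lower = 0, strict_lower = TRUE)
  check_number(total_field_area, "total_field_area", lower = 0, strict_lower = TRUE)
  if (any(field_counts < 0)) stop_param("field counts must be non-negative")
  sum(field_counts) * (well_area / total_field_area)
}
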