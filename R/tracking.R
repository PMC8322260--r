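#' Estimate inter-frame stage drift from binary masks
#'
#' Finds the integer-pixel translation maximizing the cross-correlation of
#' two binary nucleus masks, computed via FFT. The returned vector
#' `c(dx, dy)` is the systematic drift of the scene between the frames:
#' a static scene observed with stage drift `d` satisfies
#' `next ~ shift(prev, d)`, so next-frame centroids are corrected by
#' subtracting `d` before linking.
#'
#' @param mask_prev,mask_next binary or label matrices of the same shape.
#' @return integer vector `c(dx, dy)` in pixels. Empty masks give `c(0, 0)`
#'   with a warning.
#' @export
estimate_drift <- function(mask_prev, mask_next) {
  if (!all(dim(mask_prev) == dim(mask_next))) {
    stop_param("masks must share shape")
  }
  a <- (mask_prev > 0) * 1
  b <- (mask_next > 0) * 1
  if (!any(a > 0) || !any(b > 0)) {
    warn("empty mask: assuming zero drift")
    return(c(dx = 0L, dy = 0L))
  }
  # cross-correlation C(d) = sum_p a(p) b(p + d), cyclic via FFT
  cc <- Re(stats::fft(Conj(stats::fft(a)) * stats::fft(b), inverse = TRUE))
  peak <- arrayInd(which.max(cc), dim(cc))
  wrap <- function(idx, n) {
    s <- idx - 1L
    if (s > n / 2) s - n else s
  }
  dy <- wrap(peak[1], nrow(a))
  dx <- wrap(peak[2], ncol(a))
  c(dx = as.integer(dx), dy = as.integer(dy))
}

#' Link objects between consecutive frames
#'
#' Assigns each object of the previous frame to the spatially closest
#' object of the next frame after drift correction, greedily in ascending
#' distance (ties broken by lowest previous id, then lowest next id), with
#' the conservative filters of the tracking parameters: candidate links
#' farther than `max_displacement` or with a relative area change above
#' `max_area_change` (typically mitosis) are dropped, and matching is
#' one-to-one. Unmatched objects are legal and simply terminate or start
#' tracks.
#'
#' @param obs_prev,obs_next observation tibbles with columns `object_id`,
#'   `x`, `y`, `area`.
#' @param drift `c(dx, dy)` from [estimate_drift()] (subtracted from
#'   next-frame centroids).
#' @param params a [tracking_params()] object.
#' @return tibble of assignments: `prev_id`, `next_id`, `distance`.
#' @export
link_frames <- function(obs_prev, obs_next, drift = c(0, 0),
                        params = tracking_params()) {
  empty <- tibble::tibble(prev_id = integer(), next_id = integer(),
                          distance = numeric())
  if (nrow(obs_prev) == 0 || nrow(obs_next) == 0) return(empty)
  nx <- obs_next$x - drift[1]
  ny <- obs_next$y - drift[2]
  dx <- outer(obs_prev$x, nx, "-")
  dy <- outer(obs_prev$y, ny, "-")
  dist <- sqrt(dx^2 + dy^2)
  rel_area <- abs(outer(obs_prev$area, obs_next$area,
                        function(a, b) (b - a) / a))
  ok <- dist <= params$max_displacement & rel_area <= params$max_area_change
  if (!any(ok)) return(empty)
  cand <- which(ok, arr.ind = TRUE)
  cand <- tibble::tibble(
    i = cand[, 1], j = cand[, 2],
    prev_id = obs_prev$object_id[cand[, 1]],
    next_id = obs_next$object_id[cand[, 2]],
    distance = dist[cand]
  )
  cand <- cand[order(cand$distance, cand$prev_id, cand$next_id), ]
  used_prev <- logical(nrow(obs_prev))
  used_next <- logical(nrow(obs_next))
  keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    i <- cand$i[k]; j <- cand$j[k]
    if (!used_prev[i] && !used_next[j]) {
      used_prev[i] <- TRUE
      used_next[j] <- TRUE
      keep[k] <- TRUE
    }
  }
  out <- cand[keep, c("prev_id", "next_id", "distance")]
  out[order(out$prev_id), ]
}

#' Build per-cell tracks from per-frame observations
#'
#' Chains [link_frames()] over all consecutive frame pairs and connects the
#' assignments transitively into tracks. Track ids are assigned in order of
#' (first frame, first object id), so re-running on the same input gives
#' identical output regardless of row order.
#'
#' @param observations tibble from [quantify_frames()] (columns `frame`,
#'   `object_id`, `x`, `y`, `area`, plus any measurement columns, e.g.
#'   `activity`); frames must be consecutive integers.
#' @param params a [tracking_params()] object; with `require_complete` only
#'   tracks spanning every frame are returned.
#' @param masks optional list of per-frame masks for drift registration
#'   (defaults to the `"masks"` attribute of `observations` if present);
#'   without masks, zero drift is assumed.
#' @return tibble of the input observations with `track_id` and `complete`
#'   columns, ordered by track then frame.
#' @export
build_tracks <- function(observations, params = tracking_params(),
                         masks = NULL) {
  obs <- tibble::as_tibble(observations)
  masks <- masks %||% attr(observations, "masks")
  frames <- sort(unique(obs$frame))
  if (length(frames) < 2) stop_param("tracking needs at least 2 frames")
  if (!identical(as.integer(frames), seq(min(frames), max(frames)))) {
    stop_param("frames must be consecutive")
  }
  if ("valid" %in% names(obs)) obs <- obs[is.na(obs$valid) | obs$valid, ]
  per_frame <- split(obs, obs$frame)[as.character(frames)]
  # union-find over (frame, object_id) keys
  parent <- new.env(parent = emptyenv())
  find <- function(k) {
    p <- get0(k, envir = parent, ifnotfound = k)
    if (identical(p, k)) return(k)
    r <- find(p)
    assign(k, r, envir = parent)
    r
  }
  union_ <- function(a, b) assign(find(b), find(a), envir = parent)
  key <- function(f, id) paste0(f, ":", id)
  for (fi in seq_len(length(frames) - 1)) {
    prev <- per_frame[[fi]]; nxt <- per_frame[[fi + 1]]
    drift <- if (!is.null(masks)) {
      estimate_drift(masks[[fi]], masks[[fi + 1]])
    } else c(0, 0)
    links <- link_frames(prev, nxt, drift, params)
    for (k in seq_len(nrow(links))) {
      union_(key(frames[fi], links$prev_id[k]),
             key(frames[fi + 1], links$next_id[k]))
    }
  }
  obs$.root <- vapply(seq_len(nrow(obs)),
                      function(r) find(key(obs$frame[r], obs$object_id[r])),
                      character(1))
  obs <- obs[order(obs$.root, obs$frame), ]
  first <- obs[!duplicated(obs$.root), ]
  first <- first[order(first$frame, first$object_id), ]
  id_map <- setNames(seq_len(nrow(first)), first$.root)
  obs$track_id <- as.integer(id_map[obs$.root])
  spans <- table(obs$.root)
  obs$complete <- as.integer(spans[obs$.root]) == length(frames)
  obs <- obs[order(obs$track_id, obs$frame), ]
  obs$.root <- NULL
  if (params$require_complete) obs <- obs[obs$complete, ]
  tibble::as_tibble(obs)
}

#' Convert tracks to activity traces
#'
#' @param tracks tibble from [build_tracks()] with an `activity` column.
#' @param frame_interval sampling interval in minutes.
#' @return trace tibble (`cell_id`, `time_h`, `activity`) suitable for
#'   [normalize_trace()].
#' @export
tracks_to_traces <- function(tracks, frame_interval = 10) {
  check_number(frame_interval, "frame_interval", lower = 0, strict_lower = TRUE)
  tibble::tibble(
    cell_id = sprintf("track_%04d", tracks$track_id),
    time_h = tracks$frame * frame_interval / 60,
    activity = tracks$activity
  )
}
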