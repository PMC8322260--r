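#' Read and write the package's CSV table schemas
#'
#' Thin readr wrappers pinning the documented column layouts: per-frame
#' observations (`frame, object_id, x, y, area, eccentricity, nuc_int,
#' ring_int, activity, valid`), per-cell traces (`cell_id, time_h,
#' activity`), two-phase fits (`cell_id, s_inh, s_rec, t_break, rss, y0`),
#' lineage events (`parent_id, child_id, time_days`) and ICW well tables
#' (`condition, replicate, perk_signal, celltag_signal`).
#'
#' @param x table to write.
#' @param path file path.
#' @return `read_*` return tibbles; `write_*` return `path` invisibly.
#' @name ktr_io
NULL

#' @rdname ktr_io
#' @export
write_observations_csv <- function(x, path) {
  cols <- c("frame", "object_id", "x", "y", "area", "eccentricity",
            "nuc_int", "ring_int", "activity", "valid")
  readr::write_csv(x[, intersect(cols, names(x))], path)
  invisible(path)
}

#' @rdname ktr_io
#' @export
read_observations_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' @rdname ktr_io
#' @export
write_traces_csv <- function(x, path) {
  readr::write_csv(x, path)
  invisible(path)
}

#' @rdname ktr_io
#' @export
read_traces_csv <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("cell_id", "time_h", "activity")
  if (!all(need %in% names(out))) {
    stop_param("trace CSV must have columns ", paste(need, collapse = ", "))
  }
  out
}

#' @rdname ktr_io
#' @export
write_fits_csv <- function(x, path) {
  readr::write_csv(tibble::as_tibble(unclass(x)[c("cell_id", "s_inh", "s_rec",
                                                  "t_break", "rss", "y0")]),
                   path)
  invisible(path)
}

#' @rdname ktr_io
#' @export
read_events_csv <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("parent_id", "child_id", "time_days")
  if (!all(need %in% names(out))) {
    stop_param("event CSV must have columns ", paste(need, collapse = ", "))
  }
  out
}

#' @rdname ktr_io
#' @export
read_well_table_csv <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("condition", "replicate", "perk_signal", "celltag_signal")
  if (!all(need %in% names(out))) {
    stop_param("well-table CSV must have columns ", paste(need, collapse = ", "))
  }
  out
}
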