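#' Save and load run configurations as YAML
#'
#' Every parameter block of a [run_config()] round-trips through a single
#' YAML file, so a run is fully described by the file plus its seed.
#'
#' @param config a [run_config()] object.
#' @param path YAML file path.
#' @return `save_run_config()` returns `path` invisibly;
#'   `load_run_config()` returns a `run_config`.
#' @export
#' @examples
#' cfg <- run_config(seed = 3, population = population_params(n_cells = 50))
#' p <- tempfile(fileext = ".yaml")
#' save_run_config(cfg, p)
#' identical(load_run_config(p), cfg)
save_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  plain <- list(
    seed = config$seed,
    out_dir = config$out_dir,
    use_imaging = config$use_imaging,
    alpha = config$alpha,
    n_boot = config$n_boot,
    normalization = config$normalization,
    population = unclass(config$population),
    imaging = unclass(config$imaging),
    segmentation = unclass(config$segmentation),
    tracking = unclass(config$tracking),
    growth = if (!is.null(config$growth)) unclass(config$growth)
  )
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' @rdname save_run_config
#' @export
load_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  build <- function(ctor, block) {
    if (is.null(block)) return(NULL)
    # drop NULL-valued entries (e.g. an unset fixed threshold)
    do.call(ctor, block[!vapply(block, is.null, logical(1))])
  }
  run_config(
    seed = raw$seed,
    out_dir = raw$out_dir,
    population = build(population_params, raw$population),
    use_imaging = isTRUE(raw$use_imaging),
    imaging = build(imaging_params, raw$imaging),
    segmentation = build(segmentation_params, raw$segmentation),
    tracking = build(tracking_params, raw$tracking),
    growth = build(growth_params, raw$growth),
    alpha = raw$alpha,
    n_boot = raw$n_boot,
    normalization = raw$normalization
  )
}
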