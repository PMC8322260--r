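#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a two-phase fit table
#'
#' @param x a `two_phase_fits` object.
#' @param ... unused.
#' @return tibble with one row per cell (`cell_id`, `s_inh`, `s_rec`,
#'   `t_break`, `rss`, `y0`).
#' @export
tidy.two_phase_fits <- function(x, ...) {
  tibble::as_tibble(unclass(x)[names(x)])
}

#' One-row summary of a two-phase fit table
#'
#' @param x a `two_phase_fits` object.
#' @param ... unused.
#' @return one-row tibble: cell count, mean slopes, median breakpoint,
#'   total rss.
#' @export
glance.two_phase_fits <- function(x, ...) {
  tibble::tibble(
    n_cells = nrow(x),
    mean_s_inh = mean(x$s_inh),
    mean_s_rec = mean(x$s_rec),
    median_t_break = median(x$t_break),
    total_rss = sum(x$rss)
  )
}

#' Tidy a mixture fit
#'
#' @param x a `gaussian_mixture`.
#' @param ... unused.
#' @return tibble with one row per component (`component`, `weight`, `mu`,
#'   `sigma`); component 2 is the higher-mean (reactivating) component.
#' @export
tidy.gaussian_mixture <- function(x, ...) {
  tibble::tibble(component = 1:2, weight = x$weight, mu = x$mu,
                 sigma = x$sigma)
}

#' Tidy a modality decision
#'
#' @param x a `modality_result`.
#' @param ... unused.
#' @return tibble with one row per fitted model (`model`, `ks`, `p_value`,
#'   `rejected`).
#' @export
tidy.modality_result <- function(x, ...) {
  tibble::tibble(
    model = c("unimodal", "bimodal"),
    ks = c(x$ks_uni, x$ks_bi),
    p_value = c(x$p_uni, x$p_bi),
    rejected = c(x$p_uni, x$p_bi) < x$alpha
  )
}

#' One-row summary of a modality decision
#'
#' @param x a `modality_result`.
#' @param ... unused.
#' @return one-row tibble: `verdict`, `frac_recovering`, `p_uni`, `p_bi`,
#'   `alpha`, `n`.
#' @export
glance.modality_result <- function(x, ...) {
  tibble::tibble(
    verdict = x$verdict,
    frac_recovering = x$frac_recovering,
    p_uni = x$p_uni, p_bi = x$p_bi,
    alpha = x$alpha, n = length(x$sample)
  )
}
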