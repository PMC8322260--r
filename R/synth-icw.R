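#' Simulate an in-cell-western plate
#'
#' Generates per-well two-channel intensities for a set of conditions with
#' known true relative pERK levels. Each well draws a CellTag (700 nm)
#' signal around its nominal level; the pERK (800 nm) signal is
#' `gain * celltag * (baseline + span * mean)` plus Gaussian measurement
#' noise, so the per-well ratio is affine in the true condition mean and
#' the ratio of expectations preserves the ordering of `condition_means`.
#'
#' @param condition_means true relative pERK per condition, each in \[0, 1\].
#' @param n_replicates wells per condition (`>= 2`; the assays emulated here
#'   use triplicates).
#' @param noise_sd sd of the additive noise on the 800 nm signal.
#' @param seed integer seed.
#' @param gain,baseline,span affine map from true mean to the expected
#'   ratio: `E[ratio] = gain * (baseline + span * mean)`.
#' @param celltag_mean,celltag_sd per-well CellTag level (truncated away
#'   from zero).
#' @return tibble with columns `condition` (`"cond_01"`, ...), `replicate`,
#'   `perk_signal`, `celltag_signal`, `true_mean`.
#' @export
#' @examples
#' simulate_icw_plate(c(1, 0.2, 0), n_replicates = 3, seed = 1)
simulate_icw_plate <- function(condition_means, n_replicates = 3,
                               noise_sd = 0.02, seed = NULL,
                               gain = 2, baseline = 0.1, span = 0.9,
                               celltag_mean = 1, celltag_sd = 0.1) {
  if (length(condition_means) < 1 ||
      any(condition_means < 0 | condition_means > 1)) {
    stop_param("`condition_means` must be values in [0, 1]")
  }
  check_number(n_replicates, "n_replicates", lower = 2)
  check_number(noise_sd, "noise_sd", lower = 0)
  check_number(celltag_mean, "celltag_mean", lower = 0, strict_lower = TRUE)
  with_seed(seed, {
    grid <- tidyr::expand_grid(
      cond_index = seq_along(condition_means),
      replicate = seq_len(n_replicates)
    )
    celltag <- pmax(rnorm(nrow(grid), celltag_mean, celltag_sd),
                    celltag_mean / 10)
    mu <- condition_means[grid$cond_index]
    perk <- gain * celltag * (baseline + span * mu) +
      rnorm(nrow(grid), 0, noise_sd)
    tibble::tibble(
      condition = sprintf("cond_%02d", grid$cond_index),
      replicate = grid$replicate,
      perk_signal = perk,
      celltag_signal = celltag,
      true_mean = mu
    )
  })
}
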