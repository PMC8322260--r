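#' Per-condition relative pERK levels from an in-cell-western plate
#'
#' Normalizes each well's phospho-ERK signal (800 nm) by its CellTag
#' whole-cell signal (700 nm), averages the ratio per condition, and
#' rescales the condition means to \[0, 1\] against the minimum and maximum
#' observed across conditions. Replicate standard deviations are propagated
#' by the same scale factor.
#'
#' @param well_table tibble with columns `condition`, `replicate`,
#'   `perk_signal`, `celltag_signal`; at least 2 conditions with at least
#'   2 replicates each.
#' @param scale_on `"condition_means"` (default): min/max taken over
#'   condition mean ratios; `"pooled_wells"`: over individual well ratios.
#' @return tibble (condition order preserved): `condition`, `mean_ratio`,
#'   `sd_ratio`, `relative`, `relative_sd`.
#' @export
relative_perk <- function(well_table, scale_on = c("condition_means", "pooled_wells")) {
  scale_on <- match.arg(scale_on)
  wt <- check_well_table(well_table)
  per_cond <- wt |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(mean_ratio = mean(.data$ratio),
                     sd_ratio = sd(.data$ratio),
                     n = dplyr::n(), .groups = "drop")
  per_cond <- per_cond[match(unique(wt$condition), per_cond$condition), ]
  if (nrow(per_cond) < 2 || any(per_cond$n < 2)) {
    stop_param("need >= 2 conditions with >= 2 replicates each")
  }
  rng <- if (scale_on == "condition_means") range(per_cond$mean_ratio)
         else range(wt$ratio)
  if (diff(rng) == 0) abort("no dynamic range: all ratios identical")
  per_cond |>
    dplyr::mutate(relative = (.data$mean_ratio - rng[1]) / diff(rng),
                  relative_sd = .data$sd_ratio / diff(rng)) |>
    dplyr::select(-"n")
}

#' Bonferroni-corrected one-tailed reactivation tests
#'
#' Tests, for every non-reference condition, whether its normalized pERK
#' ratio is statistically higher than the reference (typically the maximum
#' inhibition observed) with a one-tailed Welch two-sample t-test on
#' per-well ratios. A condition is flagged significant when its p-value is
#' below `family_alpha / n_tests` (e.g. 0.01 for five tests at family
#' alpha 0.05, 0.005 for ten).
#'
#' @param well_table as in [relative_perk()].
#' @param reference_condition condition serving as the null baseline.
#' @param n_tests number of tests in the Bonferroni family; defaults to the
#'   number of non-reference conditions.
#' @param family_alpha family-wise error rate.
#' @return tibble with one row per non-reference condition: `condition`,
#'   `mean_ratio`, `p_value`, `threshold`, `significant`.
#' @export
test_reactivation <- function(well_table, reference_condition,
                              n_tests = NULL, family_alpha = 0.05) {
  wt <- check_well_table(well_table)
  conds <- unique(wt$condition)
  if (!reference_condition %in% conds) {
    abort(paste0("reference condition not present: ", reference_condition))
  }
  others <- setdiff(conds, reference_condition)
  n_tests <- n_tests %||% length(others)
  check_number(n_tests, "n_tests", lower = 1)
  check_number(family_alpha, "family_alpha", lower = 0, upper = 1, strict_lower = TRUE)
  threshold <- family_alpha / n_tests
  ref <- wt$ratio[wt$condition == reference_condition]
  purrr::map_dfr(others, function(cond) {
    x <- wt$ratio[wt$condition == cond]
    p <- if (sd(x) == 0 && sd(ref) == 0) {
      if (mean(x) > mean(ref)) 0 else 1
    } else {
      t.test(x, ref, alternative = "greater", var.equal = FALSE)$p.value
    }
    tibble::tibble(condition = cond, mean_ratio = mean(x),
                   p_value = p, threshold = threshold,
                   significant = p < threshold)
  })
}

check_well_table <- function(well_table) {
  wt <- tibble::as_tibble(well_table)
  need <- c("condition", "replicate", "perk_signal", "celltag_signal")
  if (!all(need %in% names(wt))) {
    stop_param("well table must have columns ",
               paste(need, collapse = ", "))
  }
  if (any(wt$celltag_signal <= 0)) stop_param("celltag_signal must be > 0")
  dplyr::mutate(wt, ratio = .data$perk_signal / .data$celltag_signal)
}
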