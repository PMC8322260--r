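#' Maximum-likelihood Gaussian fit of a slope sample
#'
#' @param x numeric sample, `n >= 10`.
#' @return object of class `gaussian_fit` with fields `mu`, `sigma`
#'   (population-style, i.e. divisor `n`), `loglik`, `n`.
#' @export
fit_unimodal <- function(x) {
  x <- check_sample(x, 10)
  mu <- mean(x)
  sigma <- sqrt(mean((x - mu)^2))
  if (sigma <= 0) abort("zero variance: cannot fit a Gaussian")
  structure(
    list(mu = mu, sigma = sigma,
         loglik = sum(dnorm(x, mu, sigma, log = TRUE)), n = length(x)),
    class = "gaussian_fit"
  )
}

#' Two-component Gaussian mixture fit by EM
#'
#' Fits a two-component Gaussian mixture with expectation-maximization,
#' restarting from quantile-split initializations and random assignments and
#' keeping the best log-likelihood. Components are ordered by mean
#' (component 2 = higher mean = reactivating). A variance floor
#' (`1e-4 * var(x)`) and a weight floor (0.01) guard against singular
#' solutions on small samples.
#'
#' @param x numeric sample, `n >= 20`.
#' @param n_restarts number of initializations (quantile splits first, then
#'   random).
#' @param seed optional integer seed for the random restarts; the global RNG
#'   stream is left untouched.
#' @param max_iter,tol EM iteration cap and log-likelihood convergence
#'   tolerance.
#' @return object of class `gaussian_mixture` with fields `weight`
#'   (length 2, sums to 1), `mu`, `sigma`, `loglik`, `n`, `converged`.
#' @export
fit_bimodal <- function(x, n_restarts = 5, seed = NULL,
                        max_iter = 500, tol = 1e-8) {
  x <- check_sample(x, 20)
  with_seed(seed, {
    v <- var(x)
    if (v <= 0) abort("zero variance: cannot fit a mixture")
    var_floor <- 1e-4 * v
    inits <- mixture_inits(x, n_restarts)
    best <- NULL
    for (init in inits) {
      fit <- em_gaussian2(x, init, var_floor = var_floor,
                          max_iter = max_iter, tol = tol)
      if (is.null(fit)) next
      if (is.null(best) || fit$loglik > best$loglik) best <- fit
    }
    if (is.null(best)) abort("EM failed on all restarts")
    ord <- order(best$mu)
    structure(
      list(weight = best$weight[ord], mu = best$mu[ord],
           sigma = best$sigma[ord], loglik = best$loglik,
           n = length(x), converged = best$converged),
      class = "gaussian_mixture"
    )
  })
}

mixture_inits <- function(x, n_restarts) {
  qs <- c(0.5, 0.25, 0.75)
  inits <- list()
  for (q in utils::head(qs, min(length(qs), n_restarts))) {
    cut <- quantile(x, q, names = FALSE)
    lo <- x[x <= cut]; hi <- x[x > cut]
    if (length(lo) < 2 || length(hi) < 2) next
    inits[[length(inits) + 1]] <- list(
      weight = c(length(lo), length(hi)) / length(x),
      mu = c(mean(lo), mean(hi)),
      sigma = pmax(c(sd(lo), sd(hi)), sd(x) / 10)
    )
  }
  while (length(inits) < n_restarts) {
    mu0 <- sample(x, 2)
    inits[[length(inits) + 1]] <- list(
      weight = c(0.5, 0.5), mu = sort(mu0),
      sigma = rep(sd(x) / stats::runif(1, 1, 3), 2)
    )
  }
  inits
}

# One EM run (compiled); returns NULL on numerical failure.
em_gaussian2 <- function(x, init, var_floor, max_iter, tol,
                         weight_floor = 0.01) {
  res <- .em_gaussian2_cpp(x, init$weight[2], init$mu[1], init$mu[2],
                           init$sigma[1], init$sigma[2],
                           var_floor, weight_floor,
                           as.integer(max_iter), tol)
  if (is.na(res$loglik)) return(NULL)
  res
}

#' @export
print.gaussian_fit <- function(x, ...) {
  cat(sprintf("<gaussian_fit> N(%.4g, %.4g^2), n = %d\n", x$mu, x$sigma, x$n))
  invisible(x)
}

#' @export
print.gaussian_mixture <- function(x, ...) {
  cat(sprintf("<gaussian_mixture> %.1f%% N(%.4g, %.4g^2) + %.1f%% N(%.4g, %.4g^2), n = %d\n",
              100 * x$weight[1], x$mu[1], x$sigma[1],
              100 * x$weight[2], x$mu[2], x$sigma[2], x$n))
  invisible(x)
}

model_cdf <- function(model) {
  if (inherits(model, "gaussian_fit")) {
    function(q) pnorm(q, model$mu, model$sigma)
  } else if (inherits(model, "gaussian_mixture")) {
    function(q) model$weight[1] * pnorm(q, model$mu[1], model$sigma[1]) +
      model$weight[2] * pnorm(q, model$mu[2], model$sigma[2])
  } else if (is.function(model)) {
    model
  } else {
    stop_param("`model` must be a gaussian_fit, gaussian_mixture, or a CDF function")
  }
}

model_simulate <- function(model, n) {
  if (inherits(model, "gaussian_fit")) {
    rnorm(n, model$mu, model$sigma)
  } else {
    k <- rbinom(n, 1L, model$weight[2]) + 1L
    rnorm(n, model$mu[k], model$sigma[k])
  }
}

#' Kolmogorov-Smirnov goodness-of-fit test with parametric bootstrap
#'
#' Computes the KS statistic of a sample against a fitted model CDF and a
#' parametric-bootstrap p-value: samples of the same size are simulated from
#' the fitted model, the model is refitted to each, its KS statistic
#' recomputed, and the p-value is the fraction of bootstrap statistics at
#' least as large as the observed one. The refitting step accounts for the
#' fact that model parameters were estimated from the sample itself (the
#' Lilliefors problem), which the asymptotic KS distribution does not.
#'
#' @param x numeric sample, `n >= 10`.
#' @param model a `gaussian_fit` or `gaussian_mixture` fitted to `x` (or a
#'   plain CDF function, in which case no refitting is possible and the
#'   bootstrap is skipped unless the model can be refitted).
#' @param n_boot number of bootstrap replicates, `>= 100`.
#' @param seed optional integer seed.
#' @return list with `statistic` and `p_value`.
#' @export
ks_model_test <- function(x, model, n_boot = 200, seed = NULL) {
  x <- check_sample(x, 10)
  if (n_boot < 100) stop_param("`n_boot` must be >= 100")
  cdf <- model_cdf(model)
  xs <- sort(x)
  D <- ks_statistic_cdf(xs, cdf(xs))
  if (is.function(model)) {
    # fully specified CDF: classical one-sample KS p-value
    p <- stats::ks.test(x, model)$p.value
    return(list(statistic = D, p_value = p))
  }
  with_seed(seed, {
    n <- length(x)
    Db <- if (inherits(model, "gaussian_fit")) {
      .ks_boot_normal_cpp(model$mu, model$sigma, n, as.integer(n_boot))
    } else {
      .ks_boot_mixture_cpp(model$weight[2], model$mu[1], model$mu[2],
                           model$sigma[1], model$sigma[2],
                           n, as.integer(n_boot),
                           1e-4 * var(x), 0.01, 500L, 1e-8)
    }
    Db <- Db[is.finite(Db)]
    list(statistic = D, p_value = mean(Db >= D))
  })
}

#' Decide whether a slope sample is unimodal or bimodal
#'
#' Fits both a single Gaussian and a two-component Gaussian mixture, tests
#' each with the parametric-bootstrap KS test, and returns a verdict:
#' `"bimodal"` when the unimodal fit is rejected (`p_uni < alpha`) and the
#' bimodal fit is not (`p_bi >= alpha`); `"unimodal"` when the unimodal fit
#' is not rejected; `"neither"` (flagged) when both are rejected. When the
#' verdict is bimodal, the weight of the higher-mean component is reported
#' as the reactivating fraction.
#'
#' @param x numeric slope sample, `n >= 50`.
#' @param alpha significance level of the decision.
#' @param seed optional integer seed driving the mixture restarts and both
#'   bootstraps.
#' @param n_boot bootstrap replicates per test.
#' @param n_restarts EM restarts for the main mixture fit.
#' @param rule `"and"` (default; reject-unimodal AND not-reject-bimodal) or
#'   `"statistic"` (bimodal iff unimodal rejected and the bimodal KS
#'   statistic is the smaller one).
#' @param lazy when `TRUE` (default) the mixture bootstrap p-value is only
#'   computed if the unimodal fit is rejected; otherwise the verdict is
#'   already `"unimodal"` and `p_bi` is reported as `NA`. The verdict is
#'   identical either way; set `lazy = FALSE` to always compute `p_bi`.
#' @return object of class `modality_result`: the two fits, KS statistics
#'   `ks_uni`/`ks_bi`, p-values `p_uni`/`p_bi`, `verdict`, and
#'   `frac_recovering` (NA unless bimodal).
#' @export
#' @examples
#' \donttest{
#' x <- c(rnorm(850, 0, 0.02), rnorm(150, 0.15, 0.03))
#' decide_modality(x, seed = 1, n_boot = 100)
#' }
decide_modality <- function(x, alpha = 0.05, seed = NULL, n_boot = 200,
                            n_restarts = 5, rule = c("and", "statistic"),
                            lazy = TRUE) {
  rule <- match.arg(rule)
  x <- check_sample(x, 50)
  check_number(alpha, "alpha", lower = 0, upper = 1, strict_lower = TRUE)
  uni <- fit_unimodal(x)
  bi <- fit_bimodal(x, n_restarts = n_restarts, seed = child_seed(seed, 1))
  ks_u <- ks_model_test(x, uni, n_boot = n_boot, seed = child_seed(seed, 2))
  reject_uni <- ks_u$p_value < alpha
  ks_b <- if (reject_uni || !lazy) {
    ks_model_test(x, bi, n_boot = n_boot, seed = child_seed(seed, 3))
  } else {
    # statistic is cheap; the bootstrap p-value cannot change the verdict
    xs <- sort(x)
    list(statistic = ks_statistic_cdf(xs, model_cdf(bi)(xs)),
         p_value = NA_real_)
  }
  reject_bi <- isTRUE(ks_b$p_value < alpha)
  verdict <- if (!reject_uni) {
    "unimodal"
  } else if (rule == "and") {
    if (!reject_bi) "bimodal" else "neither"
  } else {
    if (ks_b$statistic < ks_u$statistic) "bimodal" else "neither"
  }
  structure(
    list(
      unimodal = uni, mixture = bi,
      ks_uni = ks_u$statistic, ks_bi = ks_b$statistic,
      p_uni = ks_u$p_value, p_bi = ks_b$p_value,
      alpha = alpha, rule = rule, verdict = verdict,
      frac_recovering = if (verdict == "bimodal") bi$weight[2] else NA_real_,
      sample = x
    ),
    class = "modality_result"
  )
}

#' @export
print.modality_result <- function(x, ...) {
  cat(sprintf("<modality_result> verdict: %s (p_uni = %.3g, p_bi = %.3g, alpha = %g)\n",
              x$verdict, x$p_uni, x$p_bi, x$alpha))
  if (x$verdict == "bimodal") {
    cat(sprintf("  reactivating fraction: %.1f%% (component mean %.3g vs %.3g)\n",
                100 * x$frac_recovering, x$mixture$mu[2], x$mixture$mu[1]))
  }
  invisible(x)
}

#' Classify cells by mixture posterior responsibility
#'
#' Labels a cell `"recovering"` when the posterior responsibility of the
#' higher-mean mixture component exceeds 0.5; exact posterior ties go to
#' the majority (higher-weight) component.
#'
#' @param x numeric slopes, one per cell.
#' @param mixture a `gaussian_mixture` (component 2 = higher mean).
#' @return character vector (`"recovering"`/`"non_recovering"`) aligned
#'   with `x`.
#' @export
assign_cells <- function(x, mixture) {
  if (!inherits(mixture, "gaussian_mixture")) {
    stop_param("`mixture` must be a gaussian_mixture")
  }
  d1 <- mixture$weight[1] * dnorm(x, mixture$mu[1], mixture$sigma[1])
  d2 <- mixture$weight[2] * dnorm(x, mixture$mu[2], mixture$sigma[2])
  p2 <- d2 / (d1 + d2)
  majority_recovering <- mixture$weight[2] > mixture$weight[1]
  ifelse(p2 > 0.5 | (p2 == 0.5 & majority_recovering),
         "recovering", "non_recovering")
}

check_sample <- function(x, n_min) {
  x <- as.numeric(x)
  x <- x[is.finite(x)]
  if (length(x) < n_min) {
    stop_param(sprintf("sample must contain at least %d finite values", n_min))
  }
  x
}
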