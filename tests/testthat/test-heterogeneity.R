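test_that("Gaussian fits use maximum-likelihood (population) moments", {
  f <- fit_unimodal(c(-1, 0, 1, -1, 0, 1, -1, 0, 1, 0))
  expect_equal(f$mu, mean(c(-1, 0, 1, -1, 0, 1, -1, 0, 1, 0)))
  # closed form on the canonical 3-point sample (replicated to meet n >= 10)
  f3 <- fit_unimodal(rep(c(-1, 0, 1), 4))
  expect_equal(f3$mu, 0)
  expect_equal(f3$sigma, sqrt(2 / 3))
  expect_error(fit_unimodal(rep(1, 20)), "zero variance")
  expect_error(fit_unimodal(1:5), class = "ktrdyn_parameter_error")
})

test_that("Gaussian estimates converge at Monte-Carlo rates", {
  set.seed(21)
  x <- rnorm(1e4, 0.5, 0.1)
  f <- fit_unimodal(x)
  expect_lt(abs(f$mu - 0.5), 3 * 0.1 / sqrt(1e4))
  expect_lt(abs(f$sigma - 0.1), 3 * 0.1 / sqrt(2 * 1e4))
})

test_that("EM recovers well-separated mixture parameters", {
  set.seed(31)
  x <- c(rnorm(1000, -0.02, 0.03), rnorm(1000, 0.15, 0.05))
  fit <- fit_bimodal(x, seed = 1)
  expect_lt(abs(fit$mu[1] - (-0.02)), 3 * 0.03 / sqrt(1000) + 0.003)
  expect_lt(abs(fit$mu[2] - 0.15), 3 * 0.05 / sqrt(1000) + 0.003)
  expect_lt(abs(fit$weight[2] - 0.5), 0.05)
  expect_equal(sum(fit$weight), 1)
  expect_true(all(fit$weight >= 0.01))
  expect_true(fit$mu[2] >= fit$mu[1])
})

test_that("EM agrees with an independent mixture implementation", {
  skip_if_not_installed("mclust")
  suppressMessages(library(mclust))
  set.seed(32)
  x <- c(rnorm(600, 0, 0.02), rnorm(150, 0.15, 0.03))
  fit <- fit_bimodal(x, seed = 2)
  mc <- mclust::Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  expect_equal(sort(fit$mu), sort(as.numeric(mc$parameters$mean)),
               tolerance = 0.01)
  expect_equal(fit$weight[2], mc$parameters$pro[which.max(mc$parameters$mean)],
               tolerance = 0.03)
})

test_that("mixture fits on unimodal data collapse to overlapping components", {
  overlapping <- vapply(1:50, function(s) {
    set.seed(400 + s)
    x <- rnorm(400)
    fit <- fit_bimodal(x, seed = s)
    # under the null the component means stay within the bulk of the
    # pooled sample rather than isolating its extremes
    (fit$mu[2] - fit$mu[1]) < 2 * sd(x)
  }, logical(1))
  expect_gte(mean(overlapping), 0.9)
})

test_that("mixture fitting is deterministic given a seed", {
  set.seed(33)
  x <- c(rnorm(300, 0, 0.02), rnorm(60, 0.15, 0.03))
  expect_identical(fit_bimodal(x, seed = 9), fit_bimodal(x, seed = 9))
  expect_error(fit_bimodal(x[1:10]), class = "ktrdyn_parameter_error")
})

test_that("KS statistic against a sample's own empirical CDF is at most 1/n", {
  set.seed(41)
  x <- rnorm(64)
  ec <- stats::ecdf(x)
  res <- ks_model_test(x, function(q) ec(q))
  expect_lte(res$statistic, 1 / 64 + 1e-12)
})

test_that("bootstrap KS p-values are roughly uniform under the null", {
  set.seed(42)
  rejections <- vapply(1:150, function(i) {
    x <- rnorm(300, 2, 0.5)
    f <- fit_unimodal(x)
    ks_model_test(x, f, n_boot = 150, seed = i)$p_value < 0.05
  }, logical(1))
  expect_gte(mean(rejections), 0.005)
  expect_lte(mean(rejections), 0.12)
})

test_that("bootstrap KS rejects a unimodal fit on separated mixtures", {
  set.seed(43)
  rejections <- vapply(1:40, function(i) {
    x <- c(rnorm(250, 0, 1), rnorm(250, 3, 1))
    f <- fit_unimodal(x)
    ks_model_test(x, f, n_boot = 150, seed = i)$p_value < 0.05
  }, logical(1))
  expect_gte(mean(rejections), 0.95)
})

test_that("the modality verdict follows its decision rule mechanically", {
  set.seed(44)
  x <- c(rnorm(400, 0, 0.02), rnorm(100, 0.15, 0.03))
  m <- decide_modality(x, alpha = 0.05, seed = 5, n_boot = 150)
  expect_s3_class(m, "modality_result")
  expected <- if (m$p_uni >= 0.05) "unimodal"
              else if (m$p_bi >= 0.05) "bimodal" else "neither"
  expect_identical(m$verdict, expected)
  # near-certain rejection level: unimodal verdict requires p_uni >= alpha
  m2 <- decide_modality(x, alpha = 0.999999, seed = 5, n_boot = 150)
  expected2 <- if (m2$p_uni >= 0.999999) "unimodal"
               else if (m2$p_bi >= 0.999999) "bimodal" else "neither"
  expect_identical(m2$verdict, expected2)
  # determinism
  expect_identical(glance(decide_modality(x, seed = 5, n_boot = 150)),
                   glance(decide_modality(x, seed = 5, n_boot = 150)))
})

test_that("posterior assignment labels cells with the stated tie-break", {
  mix <- fit_bimodal(c(rnorm(500, 0, 0.02), rnorm(120, 0.15, 0.03)), seed = 6)
  lab <- assign_cells(c(0.5, -0.2), mix)
  expect_identical(lab, c("recovering", "non_recovering"))
  # exact posterior tie goes to the majority component (here component 1)
  root <- stats::uniroot(function(v) {
    d1 <- mix$weight[1] * dnorm(v, mix$mu[1], mix$sigma[1])
    d2 <- mix$weight[2] * dnorm(v, mix$mu[2], mix$sigma[2])
    d2 / (d1 + d2) - 0.5
  }, c(mix$mu[1], mix$mu[2]))$root
  d1 <- mix$weight[1] * dnorm(root, mix$mu[1], mix$sigma[1])
  d2 <- mix$weight[2] * dnorm(root, mix$mu[2], mix$sigma[2])
  p2 <- d2 / (d1 + d2)
  if (isTRUE(all.equal(p2, 0.5))) {
    expect_identical(assign_cells(root, mix), "non_recovering")
  }
  # label accuracy on a labelled synthetic cohort
  set.seed(45)
  truth <- c(rep("non_recovering", 500), rep("recovering", 120))
  x <- c(rnorm(500, 0, 0.02), rnorm(120, 0.15, 0.03))
  expect_gte(mean(assign_cells(x, mix) == truth), 0.9)
})

test_that("modality tidiers expose fits and the decision", {
  set.seed(46)
  x <- c(rnorm(400, 0, 0.02), rnorm(100, 0.15, 0.03))
  m <- decide_modality(x, seed = 7, n_boot = 150)
  td <- tidy(m)
  expect_equal(td$model, c("unimodal", "bimodal"))
  g <- glance(m)
  expect_identical(g$verdict, m$verdict)
  cm <- tidy(m$mixture)
  expect_equal(nrow(cm), 2)
  expect_equal(sum(cm$weight), 1)
})
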