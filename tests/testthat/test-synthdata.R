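test_that("trace sampling grid matches the imaging protocol", {
  co <- simulate_traces(population_params(n_cells = 3), seed = 1)
  one <- co$traces[co$traces$cell_id == co$traces$cell_id[1], ]
  # 10-min frames over 4 h: 25 samples at t = 0, 10, ..., 240 min
  expect_equal(nrow(one), 25)
  expect_equal(one$time_h, seq(0, 4, by = 1 / 6))
})

test_that("trace generation is reproducible and validates parameters", {
  a <- simulate_traces(population_params(n_cells = 20), seed = 7)
  b <- simulate_traces(population_params(n_cells = 20), seed = 7)
  expect_identical(a, b)
  c <- simulate_traces(population_params(n_cells = 20), seed = 8)
  expect_false(identical(a$traces$activity, c$traces$activity))
  expect_error(population_params(frac_recovering = 1.2), class = "ktrdyn_parameter_error")
  expect_error(population_params(obs_noise_sd = -1), class = "ktrdyn_parameter_error")
  expect_error(simulate_traces(list()), class = "ktrdyn_parameter_error")
})

test_that("degenerate mixture draws every reactivation slope from one component", {
  p <- population_params(n_cells = 5, frac_recovering = 0, obs_noise_sd = 0)
  co <- simulate_traces(p, seed = 3)
  expect_true(all(co$cells$class == "flat"))
  # flat component: slopes within 6 sd of the flat mean, far from +0.15
  expect_true(all(abs(co$cells$s_rec) < 6 * p$rec_slope_sd_flat))
})

test_that("recovering-label count falls in the exact binomial 99% interval", {
  co <- simulate_traces(population_params(n_cells = 1000), seed = 1)
  k <- sum(co$cells$class == "recovering")
  lo <- qbinom(0.005, 1000, 0.15)
  hi <- qbinom(0.995, 1000, 0.15)
  expect_gte(k, lo)
  expect_lte(k, hi)
})

test_that("noiseless curves are two-phase, start at 1, and stay in [0, 1]", {
  co <- simulate_traces(population_params(n_cells = 50, obs_noise_sd = 0), seed = 2)
  expect_true(all(co$traces$activity >= 0 & co$traces$activity <= 1))
  first <- co$traces[co$traces$time_h == 0, ]
  expect_true(all(first$activity == 1))
  # each curve is exactly representable: the fit recovers it with rss ~ 0
  fits <- co$traces |> normalize_trace("none") |> fit_two_phase()
  expect_lt(max(fits$rss), 1e-18)
})

test_that("lineage simulation hits boundary cases exactly", {
  flat_only <- growth_params(mean_lineage_flat = 1, mean_lineage_recovering = 4)
  lin <- simulate_lineages(rep("flat", 50), flat_only, seed = 1)
  expect_true(all(lin$records$lineage_size == 1))
  expect_equal(nrow(lin$events), 0)

  lin0 <- simulate_lineages("recovering", growth_params(horizon_days = 0), seed = 1)
  expect_equal(lin0$records$lineage_size, 1L)

  expect_error(
    simulate_lineages("flat", growth_params(mean_lineage_recovering = 1,
                                            mean_lineage_flat = 3), seed = 1),
    "uncalibratable", class = "ktrdyn_parameter_error"
  )
})

test_that("lineage class means are calibrated to their targets", {
  labels <- rep(c("recovering", "flat"), each = 1000)
  lin <- simulate_lineages(labels, growth_params(), seed = 7)
  sizes <- split(lin$records$lineage_size, lin$records$signaling_class)
  for (cls in c("recovering", "flat")) {
    target <- if (cls == "recovering") 6.6 else 2.7
    se <- sd(sizes[[cls]]) / sqrt(length(sizes[[cls]]))
    expect_lt(abs(mean(sizes[[cls]]) - target), 3 * se)
  }
  # sizes are positive integers; the event table is a forest
  expect_true(all(lin$records$lineage_size >= 1))
  expect_false(any(duplicated(lin$events$child_id)))
})

test_that("lineage event tables round-trip through count_descendants", {
  labels <- rep(c("recovering", "flat"), each = 150)
  lin <- simulate_lineages(labels, growth_params(), seed = 11)
  recs <- count_descendants(
    lin$events,
    tibble::tibble(ancestor_id = lin$records$ancestor_id,
                   signaling_class = lin$records$signaling_class),
    horizon_days = 7
  )
  expect_identical(recs$lineage_size, lin$records$lineage_size)
})

test_that("ICW plates have the expected layout and preserve ordering", {
  plate <- simulate_icw_plate(runif(10), n_replicates = 3, seed = 4)
  expect_equal(nrow(plate), 30)
  expect_equal(dplyr::n_distinct(plate$condition), 10)

  means <- c(0, 1)
  noiseless <- simulate_icw_plate(means, n_replicates = 3, noise_sd = 0, seed = 5)
  rel <- relative_perk(noiseless)
  expect_equal(rel$relative, c(0, 1))
  expect_error(simulate_icw_plate(c(0, 1), noise_sd = -1),
               class = "ktrdyn_parameter_error")
  expect_error(simulate_icw_plate(c(0, 1), n_replicates = 1),
               class = "ktrdyn_parameter_error")
})

test_that("noiseless ICW plates recover the true condition means exactly", {
  means <- c(0, 0.17, 0.42, 0.65, 1)
  plate <- simulate_icw_plate(means, n_replicates = 3, noise_sd = 0, seed = 6)
  rel <- relative_perk(plate)
  expect_equal(rel$relative, means, tolerance = 1e-12)
})

test_that("rendered reporter intensity is conserved across activity levels", {
  co <- constant_activity_cohort(5)
  rd <- render_timelapse(co, quiet_imaging_params(field_shape = c(200, 200)),
                         seed = 1)
  # no background, no noise: total reporter per frame = cells x fixed total
  tot <- apply(rd$fields[[1]]$reporter, 3, sum)
  expect_equal(tot, rep(5 * 300, 5), tolerance = 1e-9)
})

test_that("reporter localization follows the activity map over time", {
  # one static cell whose activity drops 1 -> 0: the nuclear reporter
  # fraction strictly increases while activity = 1 keeps the annulus flat
  tr <- tibble::tibble(cell_id = "c1", time_h = (0:4) / 6,
                       activity = seq(1, 0, length.out = 5))
  co <- list(traces = tr, cells = tibble::tibble(cell_id = "c1", class = "flat"))
  rd <- render_timelapse(co, quiet_imaging_params(field_shape = c(96, 96)), seed = 1)
  stack <- rd$fields[[1]]$reporter
  cx <- rd$truth$x[1] + 1; cy <- rd$truth$y[1] + 1
  rn <- 0.8 * rd$truth$radius[1]
  px <- expand.grid(r = 1:96, c = 1:96)
  in_nuc <- with(px, (c - cx)^2 + (r - cy)^2 <= rn^2)
  nuc_sum <- apply(stack, 3, function(m) sum(m[cbind(px$r, px$c)][in_nuc]))
  expect_true(all(diff(nuc_sum) > 0))

  tr2 <- dplyr::mutate(tr, activity = 1)
  co2 <- list(traces = tr2, cells = co$cells)
  rd2 <- render_timelapse(co2, quiet_imaging_params(field_shape = c(96, 96)), seed = 1)
  ann <- apply(rd2$fields[[1]]$reporter, 3, sum) -
    apply(rd2$fields[[1]]$reporter, 3, function(m) sum(m[cbind(px$r, px$c)][in_nuc]))
  expect_equal(ann, rep(ann[1], 5), tolerance = 1e-9)
})

test_that("stage drift accumulates linearly in the ground truth", {
  tr <- tibble::tibble(cell_id = "c1", time_h = (0:24) / 6, activity = 0.5)
  co <- list(traces = tr, cells = tibble::tibble(cell_id = "c1", class = "flat"))
  ip <- quiet_imaging_params(field_shape = c(300, 300), drift_per_frame = c(3, 0))
  rd <- render_timelapse(co, ip, seed = 2)
  tru <- rd$truth[order(rd$truth$frame), ]
  expect_equal(tru$x[25] - tru$x[1], 72, tolerance = 1e-9)
  expect_equal(tru$y[25] - tru$y[1], 0, tolerance = 1e-9)
})

test_that("overcrowded fields raise a generation error naming the frame", {
  co <- constant_activity_cohort(100)
  expect_error(
    render_timelapse(co, quiet_imaging_params(field_shape = c(64, 64)), seed = 1),
    "overcrowding.*frame 0"
  )
})

test_that("movies round-trip through multi-page TIFF files", {
  co <- constant_activity_cohort(4, n_frames = 3)
  rd <- render_timelapse(co, quiet_imaging_params(field_shape = c(128, 128)), seed = 3)
  dir <- withr::local_tempdir()
  write_timelapse_tiff(rd, dir)
  back <- read_timelapse_tiff(file.path(dir, "field1_nuclear.tif"))
  expect_equal(dim(back), dim(rd$fields[[1]]$nuclear))
  expect_equal(back, rd$fields[[1]]$nuclear, tolerance = 1e-6)
})
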