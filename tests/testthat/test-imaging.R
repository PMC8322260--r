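test_that("top-hat correction flattens backgrounds and keeps small structures", {
  flat <- matrix(5, 64, 64)
  expect_true(all(correct_illumination(flat, 8) == 0))

  # bright disk of radius r on a linear ramp; top-hat radius 3r
  r <- 4
  img <- matrix(rep(seq(0, 2, length.out = 96), each = 96), 96, 96)
  px <- expand.grid(y = 1:96, x = 1:96)
  disk <- (px$x - 48)^2 + (px$y - 48)^2 <= r^2
  img[cbind(px$y, px$x)[disk, ]] <- img[cbind(px$y, px$x)[disk, ]] + 10
  out <- correct_illumination(img, 3 * r)
  # oracle: direct erosion-dilation-subtract computed with plain R loops
  R <- 3 * r
  offs <- subset(expand.grid(dy = -R:R, dx = -R:R), dy^2 + dx^2 <= R^2)
  morph <- function(m, fun) {
    res <- m
    for (y in 1:96) for (x in 1:96) {
      ys <- y + offs$dy; xs <- x + offs$dx
      ok <- ys >= 1 & ys <= 96 & xs >= 1 & xs <= 96
      res[y, x] <- fun(m[cbind(ys[ok], xs[ok])])
    }
    res
  }
  oracle <- img - morph(morph(img, min), max)
  oracle[oracle < 0] <- 0
  expect_equal(out, oracle, tolerance = 1e-12)
  # disk retained, ramp removed
  expect_gt(min(out[cbind(px$y, px$x)[disk, ]]), 9)
  expect_lt(max(out[!disk]), 0.5)

  # idempotence on a sparse-blob image
  expect_equal(correct_illumination(out, 3 * r), out, tolerance = 1e-9)
  expect_error(correct_illumination(img, 0), class = "ktrdyn_parameter_error")
})

test_that("area and eccentricity filters remove specks and streaks", {
  img <- matrix(0, 80, 80)
  img[40:41, 40] <- 10          # 2-px speck
  seg <- segment_nuclei(img, segmentation_params(min_area = 20,
                                                 threshold_method = "fixed",
                                                 fixed_threshold = 1))
  expect_equal(nrow(seg$observations), 0)

  img2 <- matrix(0, 80, 80)
  img2[40, 10:70] <- 10         # elongated streak, eccentricity ~ 1
  seg2 <- segment_nuclei(img2, segmentation_params(min_area = 5, max_area = 1e4,
                                                   max_eccentricity = 0.95,
                                                   threshold_method = "fixed",
                                                   fixed_threshold = 1))
  expect_equal(nrow(seg2$observations), 0)
})

test_that("segmentation recovers rendered nuclei with sub-2px centroids", {
  co <- constant_activity_cohort(50)
  rd <- render_timelapse(co, imaging_params(field_shape = c(420, 420),
                                            cell_motion_sd = 0.5,
                                            drift_per_frame = c(0, 0),
                                            detach_prob = 0, divide_prob = 0),
                         seed = 9)
  fr <- rd$fields[[1]]$nuclear[, , 1]
  seg <- segment_nuclei(fr, segmentation_params())
  tru <- rd$truth[rd$truth$frame == 0, ]
  d <- sqrt(outer(tru$x, seg$observations$x, "-")^2 +
              outer(tru$y, seg$observations$y, "-")^2)
  nearest <- apply(d, 1, min)
  expect_gte(sum(nearest < 2), 49)
  # labels dense from 1 and consistent with the observation table
  ids <- sort(unique(seg$mask[seg$mask > 0]))
  expect_identical(ids, seq_along(ids))
  expect_identical(as.integer(seg$observations$object_id), ids)
  areas <- table(seg$mask[seg$mask > 0])
  expect_equal(as.numeric(areas[as.character(seg$observations$object_id)]),
               seg$observations$area)
})

test_that("uniform reporter images give activity 1 and gain invariance holds", {
  img <- matrix(0, 100, 100)
  for (c0 in c(25, 70)) {
    px <- expand.grid(y = 1:100, x = 1:100)
    disk <- (px$x - c0)^2 + (px$y - 50)^2 <= 36
    img[cbind(px$y, px$x)[disk, ]] <- 10
  }
  seg <- segment_nuclei(img, segmentation_params(threshold_method = "fixed",
                                                 fixed_threshold = 5))
  # reporter uniform over each cell and its ring, zero far background
  rep1 <- matrix(0, 100, 100)
  px2 <- expand.grid(y = 1:100, x = 1:100)
  near <- pmin((px2$x - 25)^2 + (px2$y - 50)^2,
               (px2$x - 70)^2 + (px2$y - 50)^2) <= 15^2
  rep1[cbind(px2$y, px2$x)[near, ]] <- 3
  a1 <- quantify_activity(seg$mask, rep1, segmentation_params())$activity
  a2 <- quantify_activity(seg$mask, rep1 * 7.3, segmentation_params())$activity
  expect_length(a1, 2)
  expect_equal(a1, c(1, 1), tolerance = 1e-12)
  # gain invariance: scaling the reporter by a positive constant
  expect_equal(a1, a2, tolerance = 1e-12)
})

test_that("rings exclude neighbouring nuclei and their gap zones", {
  img <- matrix(0, 60, 90)
  px <- expand.grid(y = 1:60, x = 1:90)
  diskA <- (px$x - 40)^2 + (px$y - 30)^2 <= 49
  diskB <- (px$x - 57)^2 + (px$y - 30)^2 <= 49   # abutting neighbour
  img[cbind(px$y, px$x)[diskA, ]] <- 10
  img[cbind(px$y, px$x)[diskB, ]] <- 10
  seg <- segment_nuclei(img, segmentation_params(threshold_method = "fixed",
                                                 fixed_threshold = 5,
                                                 max_eccentricity = 1))
  # reporter: nucleus B poisoned with a huge value; cytoplasm elsewhere = 1
  rep_img <- matrix(1, 60, 90)
  rep_img[seg$mask == 2] <- 1e6
  q <- quantify_activity(seg$mask, rep_img, segmentation_params())
  # the ring of A must not sample B's nuclear pixels
  expect_lt(q$ring_int[q$object_id == 1], 2)
})

test_that("invalid observations are flagged, not dropped silently", {
  img <- matrix(0, 40, 40)
  px <- expand.grid(y = 1:40, x = 1:40)
  disk <- (px$x - 20)^2 + (px$y - 20)^2 <= 36
  img[cbind(px$y, px$x)[disk, ]] <- 10
  seg <- segment_nuclei(img, segmentation_params(threshold_method = "fixed",
                                                 fixed_threshold = 5))
  rep_img <- matrix(0, 40, 40)  # zero everywhere: nuc intensity 0
  q <- quantify_activity(seg$mask, rep_img, segmentation_params())
  expect_false(q$valid[1])
  expect_true(is.na(q$activity[1]))
})

test_that("well counts scale by the field-to-well area coefficient", {
  expect_equal(count_nuclei_per_well(rep(10, 9), 4, 1), 360)
  expect_equal(count_nuclei_per_well(rep(0, 9), 4, 1), 0)
  expect_equal(count_nuclei_per_well(c(5, 7, 3), 2, 2), 15)
  expect_error(count_nuclei_per_well(c(1, 2), 0, 1), class = "ktrdyn_parameter_error")
  expect_error(count_nuclei_per_well(c(-1, 2), 1, 1), class = "ktrdyn_parameter_error")
})
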