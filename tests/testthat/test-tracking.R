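shift_mask <- function(m, dx, dy) {
  out <- matrix(0, nrow(m), ncol(m))
  rows <- seq_len(nrow(m)); cols <- seq_len(ncol(m))
  r2 <- rows + dy; c2 <- cols + dx
  ok_r <- r2 >= 1 & r2 <= nrow(m); ok_c <- c2 >= 1 & c2 <= ncol(m)
  out[r2[ok_r], c2[ok_c]] <- m[rows[ok_r], cols[ok_c]]
  out
}

test_that("drift estimation recovers constructed translations", {
  set.seed(1)
  m <- matrix(0, 128, 128)
  for (i in 1:12) {
    cx <- sample(20:108, 1); cy <- sample(20:108, 1)
    m[cy + (-3:3), cx + (-3:3)] <- 1
  }
  expect_equal(unname(estimate_drift(m, m)), c(0L, 0L))
  expect_equal(unname(estimate_drift(m, shift_mask(m, 5, -3))), c(5L, -3L))
  expect_warning(d0 <- estimate_drift(matrix(0, 16, 16), matrix(0, 16, 16)),
                 "empty mask")
  expect_equal(unname(d0), c(0L, 0L))
})

test_that("frame linking matches stationary cells and drops mitoses", {
  prev <- tibble::tibble(object_id = 1:2, x = c(10, 50), y = c(10, 50),
                         area = c(100, 100))
  nxt <- prev
  links <- link_frames(prev, nxt, c(0, 0), tracking_params())
  expect_equal(links$prev_id, 1:2)
  expect_equal(links$next_id, 1:2)

  # a cell doubling in area (mitosis) is left unmatched
  nxt2 <- dplyr::mutate(prev, area = c(200, 100))
  links2 <- link_frames(prev, nxt2, c(0, 0),
                        tracking_params(max_area_change = 0.3))
  expect_false(1 %in% links2$prev_id)
  expect_true(2 %in% links2$prev_id)

  # distance filter and drift correction interact correctly
  nxt3 <- dplyr::mutate(prev, x = x + 30)
  expect_equal(nrow(link_frames(prev, nxt3, c(0, 0), tracking_params())), 0)
  expect_equal(nrow(link_frames(prev, nxt3, c(30, 0), tracking_params())), 2)
})

test_that("greedy matching is one-to-one with deterministic tie-breaks", {
  prev <- tibble::tibble(object_id = 1:2, x = c(0, 4), y = c(0, 0), area = 100)
  nxt <- tibble::tibble(object_id = 1L, x = 2, y = 0, area = 100)
  links <- link_frames(prev, nxt, c(0, 0), tracking_params())
  # both prev cells are 2 px away; lowest prev_id wins the tie
  expect_equal(nrow(links), 1)
  expect_equal(links$prev_id, 1)
})

test_that("tracks chain across frames and honour completeness filters", {
  obs <- purrr::map_dfr(0:2, function(f) {
    tibble::tibble(frame = f, object_id = 1L, x = 10 + f, y = 10, area = 100)
  })
  tr <- build_tracks(obs, tracking_params())
  expect_equal(dplyr::n_distinct(tr$track_id), 1)
  expect_equal(nrow(tr), 3)
  expect_true(all(tr$complete))

  # a cell detaching mid-movie is excluded when completeness is required
  obs2 <- dplyr::bind_rows(
    obs,
    purrr::map_dfr(0:1, function(f) {
      tibble::tibble(frame = f, object_id = 2L, x = 40, y = 40, area = 100)
    })
  )
  tr2 <- build_tracks(obs2, tracking_params(require_complete = TRUE))
  expect_equal(dplyr::n_distinct(tr2$track_id), 1)
  tr3 <- build_tracks(obs2, tracking_params(require_complete = FALSE))
  expect_equal(dplyr::n_distinct(tr3$track_id), 2)
})

test_that("track construction is invariant to object id ordering", {
  set.seed(4)
  obs <- purrr::map_dfr(0:4, function(f) {
    tibble::tibble(frame = f, object_id = 1:6,
                   x = c(10, 40, 70, 100, 130, 160) + f,
                   y = rep(30, 6), area = 100)
  })
  shuffled <- obs[sample.int(nrow(obs)), ]
  shuffled$object_id <- shuffled$object_id  # ids unchanged, rows permuted
  a <- build_tracks(obs, tracking_params())
  b <- build_tracks(shuffled, tracking_params())
  key <- function(d) dplyr::arrange(d[, c("track_id", "frame", "object_id")],
                                    track_id, frame)
  expect_identical(key(a), key(b))
})

test_that("masks drive drift-corrected linking inside build_tracks", {
  # a global 6-px jump between frames would break the 20-px filter at
  # smaller thresholds; with mask registration the links survive
  set.seed(2)
  m1 <- matrix(0, 96, 96)
  centers <- cbind(x = c(20, 60, 80), y = c(30, 50, 20))
  for (i in 1:3) m1[centers[i, "y"] + (-3:3), centers[i, "x"] + (-3:3)] <- 1
  m2 <- shift_mask(m1, 6, 0)
  obs <- dplyr::bind_rows(
    tibble::tibble(frame = 0L, object_id = 1:3, x = centers[, "x"],
                   y = centers[, "y"], area = 49),
    tibble::tibble(frame = 1L, object_id = 1:3, x = centers[, "x"] + 6,
                   y = centers[, "y"], area = 49)
  )
  tr <- build_tracks(obs, tracking_params(max_displacement = 3),
                     masks = list(m1, m2))
  expect_equal(dplyr::n_distinct(tr$track_id), 3)
  expect_true(all(tr$complete))
})
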