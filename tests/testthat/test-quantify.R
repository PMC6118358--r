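test_that("rendering conserves mass and is linear", {
  one <- tibble::tibble(x = 5, y = 5, crlb_x = 0.12, crlb_y = 0.2)
  sr1 <- render(one, zoom = 10, extent = c(0, 10, 0, 10))
  expect_equal(sum(sr1$img), 1, tolerance = 1e-3)

  set.seed(71)
  many <- tibble::tibble(
    x = runif(1000, 1, 9), y = runif(1000, 1, 9),
    crlb_x = runif(1000, 0.05, 0.3), crlb_y = runif(1000, 0.05, 0.3)
  )
  srm <- render(many, zoom = 10, extent = c(0, 10, 0, 10))
  expect_equal(sum(srm$img), 1000, tolerance = 1 / 1000)

  # two identical localizations give exactly twice the single image
  two <- dplyr::bind_rows(one, one)
  sr2 <- render(two, zoom = 10, extent = c(0, 10, 0, 10))
  expect_equal(sr2$img, 2 * sr1$img)

  # imprecise localizations are flagged, not dropped
  wide <- tibble::tibble(x = 5, y = 5, crlb_x = 1.5, crlb_y = 1.5)
  srw <- render(wide, zoom = 10, extent = c(0, 10, 0, 10))
  expect_equal(srw$n_flagged, 1L)
  expect_equal(sum(srw$img), 1, tolerance = 1e-3)

  expect_warning(sr0 <- render(one[0, ], zoom = 10, extent = c(0, 1, 0, 1)))
  expect_equal(sum(sr0$img), 0)
})

test_that("movie traces honor the normalization contract", {
  cam <- camera_model(frame_size = 16, frame_rate = 2)
  const <- movie_stack(array(7, dim = c(16, 16, 10)), cam)
  tr <- movie_to_trace(const)
  expect_equal(tr$normalized_intensity, rep(1, 10))
  expect_equal(tr$time_s, (0:9) / 2)

  # monotone decaying movie: maximum of the normalized trace is frame 1
  decay <- array(0, dim = c(16, 16, 20))
  for (f in 1:20) decay[, , f] <- 2 + 100 * exp(-0.2 * f) *
      matrix(runif(256, 0.9, 1.1), 16, 16)
  trd <- movie_to_trace(movie_stack(decay, cam))
  expect_equal(which.max(trd$normalized_intensity), 1L)
  expect_equal(max(trd$normalized_intensity), 1)

  expect_error(movie_to_trace(movie_stack(array(1, dim = c(8, 8, 1)),
                                          camera_model(8))))
})

test_that("cross-talk ratios are exact and scale-invariant", {
  ct <- crosstalk(1000, 20)
  expect_equal(ct$ratio, 0.02)
  expect_equal(ct$percent, 2)
  expect_equal(crosstalk(1000, 50)$percent, 5)
  expect_equal(crosstalk(1000, 0)$ratio, 0)
  expect_equal(crosstalk(2000, 40)$ratio, crosstalk(1000, 20)$ratio)
  expect_error(crosstalk(0, 5), class = "seqstorm_undefined_ratio")
  # tibble inputs count accepted rows only
  lb <- tibble::tibble(accepted = rep(c(TRUE, FALSE), c(100, 40)))
  la <- tibble::tibble(accepted = rep(c(TRUE, FALSE), c(5, 2)))
  expect_equal(crosstalk(lb, la)$ratio, 0.05)
})

test_that("round counts summarize per-target dispersion", {
  locs <- tibble::tibble(
    round = rep(1:3, each = 100),
    target_id = 1L,
    accepted = TRUE
  )
  rc <- round_counts(locs)
  expect_equal(rc$counts$n, c(100L, 100L, 100L))
  expect_equal(rc$dispersion$cv, 0)
  single <- round_counts(tibble::tibble(round = 1L, target_id = 1L,
                                        accepted = TRUE))
  expect_true(is.na(single$dispersion$cv))
})

test_that("registration recovers constructed shifts and rejects flat images", {
  cam <- camera_model(frame_size = 64)
  sc <- make_scene(list(cluster(n = 10, sites_mean = 40, target_id = 1)),
                   6.83, seed = 81)
  a <- brightfield_reference(sc, cam, seed = 1)
  expect_equal(register_rounds(a, a), list(dx = 0, dy = 0))
  sh <- register_rounds(a, shift_image(a, 3, -2))
  expect_lt(abs(sh$dx - 3), 0.2)
  expect_lt(abs(sh$dy + 2), 0.2)
  expect_error(register_rounds(matrix(1, 8, 8), matrix(1, 8, 8)),
               class = "seqstorm_registration_failure")
})
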