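test_that("candidate detection finds isolated emitters and ignores flat frames", {
  cfg <- fit_config()
  set.seed(51)
  flat <- matrix(rpois(64 * 64, 5), 64, 64)
  none <- detect_candidates(flat, fit_config(detection_threshold =
                                               5 * sqrt(5)))
  expect_equal(nrow(none), 0L)

  one <- model_roi(64, x = 30.3, y = 20.7, N = 1000, b = 5, noisy = TRUE)
  cand <- detect_candidates(one, cfg)
  expect_equal(nrow(cand), 1L)
  expect_equal(cand$row, 21L)
  expect_equal(cand$col, 30L)

  # two emitters 2 px apart are merged into one candidate
  mu <- model_roi(64, 30, 30, 800, 5) + model_roi(64, 32, 30, 800, 0)
  two <- matrix(rpois(64 * 64, mu), 64, 64)
  cand2 <- detect_candidates(two, cfg)
  expect_equal(nrow(cand2), 1L)

  expect_error(detect_candidates(matrix(c(NA, 1:63 * 0), 8, 8), cfg))
})

test_that("MLE fitting is exact on noiseless model data", {
  cfg <- fit_config()
  roi <- model_roi(7, x = 3, y = 3, N = 500, b = 2)
  f <- fit_mle(roi, cfg)
  expect_equal(f$x, 3, tolerance = 1e-6)
  expect_equal(f$y, 3, tolerance = 1e-6)
  expect_equal(f$photons, 500, tolerance = 1e-6)
  expect_equal(f$background, 2, tolerance = 1e-6)
  expect_gt(f$pvalue, 0.999)
  # off-center, asymmetric case
  f2 <- fit_mle(model_roi(7, x = 3.4, y = 2.6, N = 900, b = 8), cfg)
  expect_equal(f2$x, 3.4, tolerance = 1e-6)
  expect_equal(f2$y, 2.6, tolerance = 1e-6)
})

test_that("empirical localization spread matches the CRLB", {
  cfg <- fit_config()
  set.seed(61)
  n <- 300
  xs <- runif(n, 2.8, 3.2)
  ys <- runif(n, 2.8, 3.2)
  rois <- array(0, c(7, 7, n))
  for (i in seq_len(n)) {
    rois[, , i] <- model_roi(7, xs[i], ys[i], 500, 2, noisy = TRUE)
  }
  f <- seqstorm:::fit_rois(rois, cfg)
  expect_lt(abs(sd(f$x - xs) - mean(f$crlb_x)) / mean(f$crlb_x), 0.15)
  expect_lt(abs(sd(f$y - ys) - mean(f$crlb_y)) / mean(f$crlb_y), 0.15)
})

test_that("the CRLB approaches the background-free closed form", {
  # fine sampling: sigma 4 px in a 33 px ROI, negligible background
  cfg <- fit_config(roi_size = 33, psf_sigma = 4, max_iterations = 40)
  f <- fit_mle(model_roi(33, 16, 16, 1e6, 1e-9, sigma = 4), cfg)
  expect_equal(f$crlb_x^2 * f$photons, 16, tolerance = 0.1)
})

test_that("acceptance filters implement the stated thresholds inclusively", {
  cfg <- fit_config()
  locs <- tibble::tibble(
    frame = 1:6,
    x = 1, y = 1,
    photons = c(251, 249, 500, 250, 500, 500),
    background = c(199, 10, 10, 200, 201, 10),
    crlb_x = 0.1, crlb_y = 0.1, loglike = 0,
    pvalue = c(0.5, 0.9, 0.005, 0.01, 0.5, 0.009)
  )
  out <- filter_localizations(locs, cfg)
  expect_equal(out$accepted, c(TRUE, FALSE, FALSE, TRUE, FALSE, FALSE))
  expect_equal(out$reject_reason[2], "min_photons")
  expect_equal(out$reject_reason[3], "pvalue")
  expect_equal(out$reject_reason[5], "max_background")
  # order and fitted values never change
  expect_equal(out$frame, locs$frame)
  expect_equal(out$photons, locs$photons)
  expect_equal(out$pvalue, locs$pvalue)
})

test_that("localize_stack recovers most true on-events in a seeded fixture", {
  cam <- camera_model(frame_size = 64)
  sc <- make_scene(list(filament(n = 3, length_um = 4, target_id = 1),
                        cluster(n = 8, sites_mean = 40, target_id = 2)),
                   field_size_um = 64 * cam$pixel_size_um, seed = 7)
  sim <- simulate_round(sc, round_spec(1, 1), photophysics_params(),
                        cam, n_frames = 200, seed = 7)
  locs <- localize_stack(sim$movie)
  expect_gte(recall_vs_truth(locs, sim$truth), 0.9)
  # accepted positions are accurate to well under a pixel
  acc <- locs[locs$accepted, ]
  expect_lt(median(acc$crlb_x), 0.2)
  # determinism: identical output on the same movie
  locs2 <- localize_stack(sim$movie)
  expect_identical(locs$x, locs2$x)
  expect_identical(locs$accepted, locs2$accepted)
})

test_that("an empty movie yields an empty localization table", {
  empty <- movie_stack(array(5, dim = c(16, 16, 3)), camera_model(16))
  locs <- localize_stack(empty)
  expect_equal(nrow(locs), 0L)
  expect_true(all(c("frame", "x", "y", "photons", "background", "crlb_x",
                    "crlb_y", "pvalue", "accepted") %in% names(locs)))
})

test_that("localization tables round-trip through delimited text", {
  locs <- tibble::tibble(
    frame = 1:3, x = c(1.5, 2.5, 3.5), y = c(4.5, 5.5, 6.5),
    photons = c(300, 400, 500), background = c(5, 6, 7),
    crlb_x = 0.1, crlb_y = 0.1, loglike = -50,
    pvalue = c(0.5, 0.6, 0.7), fit_ok = TRUE,
    accepted = TRUE, reject_reason = NA_character_
  )
  path <- withr::local_tempfile(fileext = ".csv")
  write_localizations(locs, path, config = fit_config())
  back <- read_localizations(path)
  expect_equal(back$x, locs$x)
  expect_equal(back$photons, locs$photons)
})
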