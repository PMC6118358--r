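cam64 <- camera_model(frame_size = 64)

test_that("scene construction is deterministic and geometrically exact", {
  # 2 um filament at 20 nm spacing: 101 collinear sites
  sc <- make_scene(list(filament(length_um = 2, x0_um = 1, y0_um = 1,
                                 theta = 0)),
                   field_size_um = 6, seed = 1)
  expect_equal(nrow(sc$sites), 101L)
  expect_equal(sc$sites$y_um, rep(1, 101))
  expect_equal(sc$sites$x_um, seq(1, 3, by = 0.02))

  expect_equal(nrow(make_scene(list(), 6, seed = 1)$sites), 0L)

  spec <- list(filament(n = 2, target_id = 1), cluster(n = 5, target_id = 2))
  s1 <- make_scene(spec, 6.83, seed = 7)
  s2 <- make_scene(spec, 6.83, seed = 7)
  expect_identical(s1$sites, s2$sites)
  # all sites inside the field
  expect_true(all(s1$sites$x_um >= 0 & s1$sites$x_um <= 6.83))
  expect_true(all(s1$sites$y_um >= 0 & s1$sites$y_um <= 6.83))
})

test_that("simulated rounds are bit-exact reproducible for a fixed seed", {
  sc <- make_scene(list(cluster(n = 4, target_id = 1)), 6.83, seed = 3)
  ph <- photophysics_params()
  a <- simulate_round(sc, round_spec(1, 1), ph, cam64, 50, seed = 9)
  b <- simulate_round(sc, round_spec(1, 1), ph, cam64, 50, seed = 9)
  expect_identical(a$movie$frames, b$movie$frames)
  expect_identical(a$truth, b$truth)
})

test_that("an unlabeled round is background-only", {
  sc <- make_scene(list(cluster(n = 4, target_id = 1)), 6.83, seed = 3)
  sim <- simulate_round(sc, round_spec(1, 1, label_prob = 0),
                        photophysics_params(), cam64, 30, seed = 5,
                        background = 5)
  expect_equal(nrow(sim$truth), 0L)
  # mean pixel value ~ b within 3 standard errors of the Poisson mean
  n <- length(sim$movie$frames)
  expect_lt(abs(mean(sim$movie$frames) - 5), 3 * sqrt(5 / n))
})

test_that("photons are conserved for a permanently-on emitter", {
  sc <- make_scene(list(filament(length_um = 0, x0_um = 3.4, y0_um = 3.4)),
                   6.83, seed = 1)
  expect_equal(nrow(sc$sites), 1L)
  ph <- photophysics_params(p_on = 1, mean_on_frames = 1e9,
                            photons_per_frame = 1000)
  sim <- simulate_round(sc, round_spec(1, 1), ph, cam64, 100, seed = 2,
                        background = 0)
  sums <- apply(sim$movie$frames, 3, sum)
  expect_equal(nrow(sim$truth), 100L)
  expect_lt(abs(mean(sums) - 1000), 3 * sqrt(1000 / 100))
})

test_that("carryover relabels the expected binomial fraction", {
  sc <- make_scene(list(cluster(n = 25, sites_mean = 40, target_id = 1)),
                   6.83, seed = 13)
  n_sites <- nrow(sc$sites)
  ph <- photophysics_params()
  r1 <- simulate_round(sc, round_spec(1, 1), ph, cam64, 1, seed = 1)
  expect_equal(length(r1$labeled), n_sites)    # label_prob 1
  r2 <- simulate_round(sc, round_spec(2, 1, label_prob = 0,
                                      carryover_residual = 0.02),
                       ph, cam64, 1, seed = 2, prev_labeled = r1$labeled)
  expected <- 0.02 * n_sites
  expect_lt(abs(length(r2$labeled) - expected),
            3 * sqrt(n_sites * 0.02 * 0.98) + 1)
})

test_that("truth rows coincide with elevated local intensity", {
  sc <- make_scene(list(cluster(n = 6, sites_mean = 30, target_id = 1)),
                   6.83, seed = 17)
  sim <- simulate_round(sc, round_spec(1, 1), photophysics_params(),
                        cam64, 100, seed = 21, background = 5)
  tr <- sim$truth
  tr <- tr[tr$x_px > 2 & tr$x_px < 61 & tr$y_px > 2 & tr$y_px < 61, ]
  local_mean <- vapply(seq_len(nrow(tr)), function(i) {
    r <- round(tr$y_px[i]) + 1L
    c <- round(tr$x_px[i]) + 1L
    mean(sim$movie$frames[(r - 1):(r + 1), (c - 1):(c + 1), tr$frame[i]])
  }, numeric(1))
  expect_true(all(local_mean > 5 + 3 * sqrt(5)))
})

test_that("time-course movies decay to the residual level", {
  sc <- make_scene(list(cluster(n = 20, sites_mean = 40, target_id = 1)),
                   3.4, seed = 3, margin_um = 0.3)
  cam32 <- camera_model(frame_size = 32)
  m <- kinetics_model(k_disp = 1e5, invader_conc = 2e-7,
                      residual_fraction = 0.05, bleach_rate = 0,
                      t_invader = 20)
  mv <- simulate_timecourse_movie(sc, m, cam32, duration = 300, seed = 11,
                                  background = 2)
  sums <- apply(mv$frames, 3, sum)
  times <- attr(mv, "times")
  npx <- 32^2
  early <- mean(sums[times < 20]) - 2 * npx
  late <- mean(sums[times > 250]) - 2 * npx
  expect_equal(late / early, 0.05, tolerance = 0.35)
  # pre-invader segment is flat in expectation (no bleaching)
  pre <- sums[times < 20]
  expect_lt(abs(mean(pre[1:20]) - mean(pre[21:40])), 4 * sd(pre))
})

test_that("the EMCCD stage preserves expected intensities approximately", {
  sc <- make_scene(list(cluster(n = 4, target_id = 1)), 6.83, seed = 3)
  sim <- simulate_round(sc, round_spec(1, 1), photophysics_params(),
                        cam64, 20, seed = 5, background = 10,
                        units = "adu")
  expect_equal(sim$movie$units, "adu")
  back <- (mean(sim$movie$frames) - cam64$adu_offset) / cam64$adu_per_photon
  expect_equal(back, 10, tolerance = 0.1)
})

test_that("movies round-trip through 16-bit TIFF with metadata", {
  sc <- make_scene(list(cluster(n = 2, target_id = 1)), 6.83, seed = 3)
  sim <- simulate_round(sc, round_spec(1, 1), photophysics_params(),
                        cam64, 5, seed = 5)
  path <- withr::local_tempfile(fileext = ".tif")
  write_movie(sim$movie, path)
  back <- read_movie(path)
  expect_equal(back$frames, sim$movie$frames)
  expect_equal(back$units, sim$movie$units)
  expect_equal(back$camera$pixel_size_um, sim$movie$camera$pixel_size_um)
  expect_equal(back$n_frames, 5L)
})
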