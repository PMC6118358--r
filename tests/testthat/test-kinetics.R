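test_that("displaced_fraction follows the closed form and its limits", {
  m <- kinetics_model(k_disp = 1e5, invader_conc = 4.87e-6,
                      residual_fraction = 0, t_invader = 20)
  expect_equal(displaced_fraction(20, m), 0)
  # half-life identity: k*c*(t - t_invader) = ln 2 -> fraction 1/2
  kc <- m$k_disp * m$invader_conc
  expect_equal(displaced_fraction(20 + log(2) / kc, m), 0.5)
  # exponent 1e5 * 4.87e-6 * 300 = 146.1 -> essentially complete
  expect_equal(displaced_fraction(320, m), 1 - exp(-146.1), tolerance = 1e-12)
  expect_error(displaced_fraction(10, m), class = "seqstorm_domain_error")
})

test_that("displacement is monotone in time and concentration, with the right limit", {
  m <- kinetics_model(k_disp = 1e3, invader_conc = 1e-6,
                      residual_fraction = 0.1, t_invader = 0)
  t <- seq(0, 5000, by = 50)
  f <- displaced_fraction(t, m)
  expect_true(all(diff(f) >= 0))
  expect_equal(f[length(f)], 1 - 0.1, tolerance = 1e-2)
  for (tt in c(100, 1000)) {
    concs <- c(1e-7, 1e-6, 1e-5)
    fs <- vapply(concs, function(cc) {
      displaced_fraction(tt, kinetics_model(1e3, cc, residual_fraction = 0.1,
                                            t_invader = 0))
    }, numeric(1))
    expect_true(all(diff(fs) > 0))
  }
})

test_that("intensity_model separates bleaching and displacement", {
  m0 <- kinetics_model(1e5, 4.87e-6, bleach_rate = 0, t_invader = 50)
  expect_equal(intensity_model(10, m0), 1)
  mres <- kinetics_model(1e5, 4.87e-6, bleach_rate = 0,
                         residual_fraction = 0.2, t_invader = 0)
  expect_equal(intensity_model(1e6, mres), 0.2, tolerance = 1e-9)
  mb <- kinetics_model(1e5, 4.87e-6, bleach_rate = 0.001, t_invader = 30)
  expect_equal(intensity_model(20, mb), exp(-0.02))
})

test_that("time_to_fraction inverts displaced_fraction", {
  m <- kinetics_model(k_disp = 1e5, invader_conc = 4.87e-6, t_invader = 0)
  kc <- 1e5 * 4.87e-6
  expect_equal(time_to_fraction(m, 0.5), log(2) / kc)
  expect_equal(time_to_fraction(m, 0.95), log(20) / 0.487, tolerance = 1e-9)
  mres <- kinetics_model(1e5, 4.87e-6, residual_fraction = 0.05)
  expect_error(time_to_fraction(mres, 0.99),
               class = "seqstorm_unreachable_fraction")
  # round trip within 1e-9 relative
  set.seed(31)
  for (i in 1:50) {
    mm <- kinetics_model(k_disp = 10^runif(1, 3, 6),
                         invader_conc = 10^runif(1, -7, -5),
                         residual_fraction = runif(1, 0, 0.3),
                         t_invader = runif(1, 0, 60))
    t <- mm$t_invader + 10^runif(1, -1, 3)
    f <- displaced_fraction(t, mm)
    if (f > 0 && f < 1 - mm$residual_fraction) {
      expect_equal(mm$t_invader + time_to_fraction(mm, f), t,
                   tolerance = 1e-9)
    }
  }
})

test_that("fit_trace recovers generating parameters exactly on noiseless data", {
  m <- kinetics_model(k_disp = 0.02, invader_conc = 1,
                      residual_fraction = 0.03, bleach_rate = 0,
                      t_invader = 20)
  t <- seq(0, 400, by = 1)
  f <- fit_trace(t, intensity_model(t, m), t_invader = 20)
  expect_true(f$converged)
  expect_equal(f$kc, 0.02, tolerance = 1e-6)
  expect_equal(f$model$residual_fraction, 0.03, tolerance = 1e-6)
  expect_lt(f$fit_rmse, 1e-8)
  # with a bleaching baseline estimated from the pre-segment
  mb <- kinetics_model(0.02, 1, residual_fraction = 0.03,
                       bleach_rate = 0.001, t_invader = 20)
  fb <- fit_trace(t, intensity_model(t, mb), t_invader = 20)
  expect_equal(fb$model$bleach_rate, 0.001, tolerance = 1e-3)
  expect_equal(fb$kc, 0.02, tolerance = 1e-4)
  expect_equal(fb$reduction_pct_bleach_corrected, 97, tolerance = 1e-3)
})

test_that("fit_trace is accurate under noise and improves with sampling", {
  m <- kinetics_model(0.02, 1, residual_fraction = 0.03, bleach_rate = 0,
                      t_invader = 20)
  t <- seq(0, 400, by = 1)
  y <- intensity_model(t, m)
  set.seed(41)
  errs <- replicate(50, {
    f <- fit_trace(t, y * (1 + rnorm(length(y), 0, 0.01)), 20)
    abs(f$kc - 0.02) / 0.02
  })
  expect_lt(median(errs), 0.05)
  # estimator error shrinks with sample count at fixed noise
  set.seed(42)
  med_err <- vapply(c(100, 1000), function(n) {
    tt <- seq(0, 200, length.out = n)
    yy <- intensity_model(tt, m)
    median(replicate(30, {
      abs(fit_trace(tt, yy * (1 + rnorm(n, 0, 0.05)), 20)$kc - 0.02) / 0.02
    }))
  }, numeric(1))
  expect_lt(med_err[2], med_err[1])
})

test_that("degenerate traces are handled as specified", {
  t <- seq(0, 400, by = 1)
  flat <- fit_trace(t, rep(1, length(t)), 20)
  expect_true(flat$converged)
  expect_equal(flat$model$residual_fraction, 1, tolerance = 1e-3)
  expect_equal(flat$reduction_pct, 0, tolerance = 0.1)
  expect_error(fit_trace(t, rep(0, length(t)), 20),
               class = "seqstorm_invalid_trace")
  expect_error(fit_trace(t, c(rep(1, 200), NA, rep(1, 200)), 20),
               class = "seqstorm_invalid_trace")
  expect_error(fit_trace(t[1:15], rep(1, 15), 14),
               class = "seqstorm_invalid_trace")
})

test_that("traces round-trip through delimited text", {
  tr <- tibble::tibble(time_s = seq(0, 10, by = 0.5),
                       intensity = exp(-0.1 * seq(0, 10, by = 0.5)))
  path <- withr::local_tempfile(fileext = ".csv")
  write_trace(tr, path)
  back <- read_trace(path)
  expect_equal(back$time_s, tr$time_s)
  expect_equal(back$intensity, tr$intensity)
})
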