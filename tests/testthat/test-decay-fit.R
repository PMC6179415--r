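# Reconvolution fitting and IRF reconstruction.

test_that("noiseless self-inversion recovers parameters exactly", {
  irf <- gauss_irf(0.25, n_bins = 1024)
  p <- bi_exp_params(870, 130, 0.82, 3.47)
  y <- model_decay(p, irf)
  f <- fit_decay(y, irf, options = fit_options(min_counts = 0))
  expect_true(f$converged)
  expect_lt(abs(f$params$a1 - 870) / 870, 1e-4)
  expect_lt(abs(f$params$a2 - 130) / 130, 1e-4)
  expect_lt(abs(f$params$tau1 - 0.82) / 0.82, 1e-4)
  expect_lt(abs(f$params$tau2 - 3.47) / 3.47, 1e-4)
  expect_lt(f$chi2, 1e-10)
})

test_that("fit refuses histograms with insufficient photons", {
  h <- decay_histogram(rep(1L, 256))
  expect_error(fit_decay(h, NULL), "insufficient photons")
})

test_that("fit is deterministic and orders components canonically", {
  irf <- gauss_irf(0.3, n_bins = 512)
  p <- bi_exp_params(500, 500, 0.6, 2.8)
  h <- simulate_decay_histogram(p, irf, total_counts = 2e5, seed = 99)
  f1 <- fit_decay(h, irf)
  f2 <- fit_decay(h, irf)
  expect_identical(f1$params, f2$params)
  expect_lte(f1$params$tau1, f1$params$tau2)
  expect_true(f1$alpha1 >= 0 && f1$alpha1 <= 1)
  expect_true(f1$tau_mean >= f1$params$tau1 && f1$tau_mean <= f1$params$tau2)
})

test_that("optimizer chi-square beats an exhaustive lattice on a toy histogram", {
  # independent oracle: 20^3 grid over (tau1, tau2, alpha1), amplitudes
  # scaled to the observed fluorescence total
  n <- 64; period <- 50
  irf <- delta_irf(n, period)
  truth <- bi_exp_params(600, 150, 0.9, 3.2)
  h <- simulate_decay_histogram(truth, irf, total_counts = 5e4, seed = 5)
  obs <- h$counts
  total <- sum(obs)
  best_grid <- Inf
  for (t1 in seq(0.4, 1.4, length.out = 20)) {
    for (t2 in seq(2.0, 4.5, length.out = 20)) {
      for (al in seq(0.55, 0.95, length.out = 20)) {
        m <- model_decay(bi_exp_params(al, 1 - al, t1, t2), irf,
                         n_bins = n, period = period)
        m <- m * total / sum(m)
        best_grid <- min(best_grid, chi_square(obs, m))
      }
    }
  }
  f <- fit_decay(h, irf)
  expect_lte(f$chi2, best_grid + 1e-6)
})

test_that("fitted background or afterpulse recovers the generating value", {
  # background and afterpulsing are both uniform terms, hence collinear:
  # they are fitted one at a time with the other fixed from calibration
  irf <- gauss_irf(0.25, n_bins = 512)
  p <- bi_exp_params(2000, 400, 0.8, 3.2, background = 5, afterpulse = 0.03)
  y <- model_decay(p, irf, n_bins = 512)
  f_bg <- fit_decay(y, irf,
                    options = fit_options(min_counts = 0, afterpulse = 0.03,
                                          fit_background = TRUE))
  expect_lt(abs(f_bg$params$background - 5) / 5, 1e-3)
  expect_lt(abs(f_bg$params$tau1 - 0.8) / 0.8, 1e-3)
  f_ap <- fit_decay(y, irf,
                    options = fit_options(min_counts = 0, background = 5,
                                          fit_afterpulse = TRUE))
  expect_lt(abs(f_ap$params$afterpulse - 0.03) / 0.03, 1e-3)
})

test_that("optional IRF shift parameter recovers a temporal offset", {
  n <- 512; period <- 50
  irf <- gauss_irf(0.25, n_bins = n, period = period)
  # shift the IRF by 3 bins when generating, fit with the unshifted IRF
  shifted <- instrument_response(
    c(tail(irf$weights, 3), head(irf$weights, -3)), irf$bin_width)
  p <- bi_exp_params(870, 130, 0.82, 3.47)
  y <- model_decay(p, shifted, n_bins = n, period = period)
  f <- fit_decay(y, irf,
                 options = fit_options(min_counts = 0, fit_shift = TRUE))
  expect_equal(abs(f$shift), 3 * irf$bin_width, tolerance = 0.05)
  expect_lt(abs(f$params$tau1 - 0.82) / 0.82, 0.01)
})

test_that("noiseless self-inversion holds across a property sweep", {
  set.seed(31)
  irf <- gauss_irf(0.25, n_bins = 512)
  for (i in 1:20) {
    al <- runif(1, 0.6, 0.95)
    t1 <- runif(1, 0.4, 1.2)
    t2 <- runif(1, 2.2, 4.5)
    total <- 10^runif(1, 3, 6)
    p <- bi_exp_params(al * total, (1 - al) * total, t1, t2)
    y <- model_decay(p, irf, n_bins = 512)
    f <- fit_decay(y, irf, options = fit_options(min_counts = 0))
    expect_lt(abs(f$params$tau1 - t1) / t1, 1e-4)
    expect_lt(abs(f$params$tau2 - t2) / t2, 1e-4)
    expect_lt(abs(f$alpha1 - al) / al, 1e-4)
  }
})

test_that("IRF reconstruction inverts a known Gaussian response", {
  n <- 1024
  true_irf <- gauss_irf(0.25, n_bins = n)
  # noiseless reference-dye measurement: IRF (x) 0.2 ns mono-exponential
  m <- model_decay(bi_exp_params(1, 0, 0.2, 0.2), true_irf, n_bins = n)
  m <- m / sum(m) * 1e6
  ref <- reference_measurement(
    decay_histogram(m, allow_fractional = TRUE), reference_lifetime = 0.2)
  rec <- irf_from_reference(ref)
  nrmse <- sqrt(mean((rec$weights - true_irf$weights)^2)) / max(true_irf$weights)
  expect_lt(nrmse, 0.02)
  # round trip: reconvolving the reconstruction with the reference decay
  # reproduces the measured reference histogram
  round_trip <- model_decay(bi_exp_params(1, 0, 0.2, 0.2), rec, n_bins = n)
  round_trip <- round_trip / sum(round_trip) * sum(m)
  expect_lt(max(abs(round_trip - m)) / max(m), 0.02)
})

test_that("IRF reconstruction approaches the raw histogram as tau_ref -> 0", {
  n <- 256
  true_irf <- gauss_irf(0.3, n_bins = n)
  m <- true_irf$weights * 1e6
  ref <- reference_measurement(
    decay_histogram(m, allow_fractional = TRUE), reference_lifetime = 1e-6)
  rec <- irf_from_reference(ref, smooth_window = 0)
  expect_equal(rec$weights, true_irf$weights, tolerance = 1e-4)
})

test_that("IRF reconstruction enforces preconditions", {
  h <- decay_histogram(rep(1L, 256))
  expect_error(reference_measurement(h, -0.1), "positive")
  expect_error(irf_from_reference(reference_measurement(h, 0.2)), "1e4")
})
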