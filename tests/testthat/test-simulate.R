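# Synthetic-data generator: IRFs, Poisson histograms, reflectance pairs,
# protocol datasets.

test_that("simulated IRF normalizes and reproduces the requested FWHM", {
  for (fwhm in c(0.1, 0.25, 0.5)) {
    irf <- simulate_irf(fwhm, n_bins = 1024)
    expect_equal(sum(irf$weights), 1)
    # self-measurement by half-maximum crossings
    t <- time_grid(irf)
    half <- max(irf$weights) / 2
    above <- which(irf$weights >= half)
    measured <- t[max(above)] - t[min(above)]
    expect_equal(measured, fwhm, tolerance = 2 * irf$bin_width / fwhm)
  }
  # sub-bin width collapses to a one-bin delta
  tiny <- simulate_irf(0.01, n_bins = 256)
  expect_equal(sum(tiny$weights > 0), 1)
  expect_error(simulate_irf(3), "fwhm")
})

test_that("Poisson histogram totals follow the Poisson law", {
  p <- ctrl_params()
  totals <- vapply(1:100, function(i) {
    sum(simulate_decay_histogram(p, NULL, total_counts = 1e5, seed = 1000 + i,
                                 n_bins = 256)$counts)
  }, numeric(1))
  expect_lt(abs(mean(totals) - 1e5), 3 * sqrt(1e5) / sqrt(100))
  expect_true(all(abs(totals - 1e5) < 5 * sqrt(1e5)))
  # degenerate zero-count request and reproducibility
  z <- simulate_decay_histogram(p, NULL, total_counts = 0, n_bins = 64)
  expect_equal(sum(z$counts), 0)
  h1 <- simulate_decay_histogram(p, NULL, total_counts = 1e4, seed = 7, n_bins = 64)
  h2 <- simulate_decay_histogram(p, NULL, total_counts = 1e4, seed = 7, n_bins = 64)
  expect_identical(h1$counts, h2$counts)
  expect_error(simulate_decay_histogram(p, NULL, total_counts = -1), "nonnegative")
})

test_that("fit on simulated histograms recovers the generating mean lifetime", {
  irf <- gauss_irf(0.25)
  p <- ctrl_params()
  truth_tm <- tau_mean(p)
  h <- simulate_decay_histogram(p, irf, total_counts = 1e6, seed = 123)
  f <- fit_decay(h, irf)
  expect_lt(abs(f$tau_mean - truth_tm) / truth_tm, 0.02)
  expect_lt(abs(f$alpha1 - 0.87), 0.03)
})

test_that("Monte-Carlo error of tau_mean shrinks with the photon budget", {
  irf <- gauss_irf(0.25, n_bins = 512)
  p <- ctrl_params()
  truth_tm <- tau_mean(p)
  rel_err <- vapply(c(1e4, 1e5, 1e6), function(nc) {
    errs <- vapply(1:8, function(i) {
      h <- simulate_decay_histogram(p, irf, total_counts = nc,
                                    seed = derive_seed(77, i, nc))
      abs(fit_decay(h, irf, options = fit_options(min_counts = 100))$tau_mean -
            truth_tm) / truth_tm
    }, numeric(1))
    mean(errs)
  }, numeric(1))
  expect_true(all(diff(rel_err) < 0))  # decreasing trend over the decades
})

test_that("synthetic reflectance round-trips through the absorbance module", {
  oxy <- simulate_reflectance(oxy_fraction = 1, red_cytc_fraction = 0,
                              noise_sd = 0)
  a <- absorbance(oxy$sample, oxy$white_reference)
  pk <- pracma::findpeaks(a$absorbance, minpeakdistance = 5)
  peaks_nm <- a$wavelengths[pk[, 2]]
  expect_true(any(abs(peaks_nm - 544) <= 2) && any(abs(peaks_nm - 578) <= 2))
  cytc <- simulate_reflectance(oxy_fraction = 0, red_cytc_fraction = 1,
                               noise_sd = 0)
  a2 <- absorbance(cytc$sample, cytc$white_reference)
  in_band <- a2$wavelengths >= 520 & a2$wavelengths <= 600
  expect_equal(a2$wavelengths[in_band][which.max(a2$absorbance[in_band])],
               550, tolerance = 3 / 550)
  # zero templates: sample equals reference, absorbance ~ baseline only
  flat <- simulate_reflectance(spectral_templates(baseline = 0),
                               oxy_fraction = 0, red_cytc_fraction = 0,
                               noise_sd = 0)
  # deoxy template still present at fraction 1 - oxy; suppress both
  tpl0 <- spectral_templates(baseline = 0)
  tpl0$oxy_myoglobin$amplitude[] <- 0
  tpl0$deoxy_myoglobin$amplitude[] <- 0
  tpl0$reduced_cytc$amplitude[] <- 0
  none <- simulate_reflectance(tpl0, oxy_fraction = 1, noise_sd = 0)
  expect_equal(none$sample$intensities, none$white_reference$intensities)
})

test_that("protocol simulator is reproducible and respects the transport delay", {
  spec <- scenario_spec("hypoxia", total_counts = 1e4)
  d1 <- simulate_protocol(spec, n_hearts = 1, seed = 3, emit = "intensities")
  d2 <- simulate_protocol(spec, n_hearts = 1, seed = 3, emit = "intensities")
  expect_identical(d1$hearts[[1]]$intensities, d2$hearts[[1]]$intensities)
  expect_equal(length(d1$times), 306)
  # ground truth does not depart from baseline before switch + delay
  tr <- d1$hearts[[1]]$truth
  ch2 <- tr[tr$channel == "CH2", ]
  pre <- ch2$time_s < 180 + spec$delay
  expect_equal(ch2$tau1[pre], rep(ch2$tau1[1], sum(pre)))
  expect_equal(ch2$alpha1[pre], rep(ch2$alpha1[1], sum(pre)))
})

test_that("control scenario with zero noise has constant generated parameters", {
  spec <- scenario_spec("control", total_counts = 1e4,
                        intensity_noise_sd = 0, heart_sd = 0)
  d <- simulate_protocol(spec, n_hearts = 1, seed = 2, emit = "intensities")
  tr <- d$hearts[[1]]$truth
  for (ch in c("CH1", "CH2", "CH3", "CH4")) {
    sub <- tr[tr$channel == ch, ]
    expect_equal(diff(range(sub$tau1)), 0)
    expect_equal(diff(range(sub$tau2)), 0)
    expect_equal(diff(range(sub$alpha1)), 0)
  }
})

test_that("trajectory is continuous and reaches its plateau", {
  t <- seq(0, 1525, 5)
  y <- trajectory(t, 1, 2, 45, 120)
  expect_true(all(abs(diff(y)) < 0.25))              # no jumps
  expect_equal(y[t < 300], rep(1, sum(t < 300)))     # delayed onset
  expect_equal(max(y), 2, tolerance = 1e-3)          # reaches plateau
  expect_lt(y[length(y)], 1.01)                      # recovers toward baseline
})
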