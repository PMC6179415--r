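# Bi-exponential periodic decay model, chi-square and derived metrics.

test_that("mono-exponential with delta IRF decays geometrically from a1", {
  n <- 256; period <- 50
  p <- bi_exp_params(a1 = 100, a2 = 0, tau1 = 0.5, tau2 = 0.5)
  m <- model_decay(p, delta_irf(n), n_bins = n, period = period)
  dt <- period / n
  # tau << period: steady-state factor is 1 to machine precision
  expect_equal(m[1], 100, tolerance = 1e-9)
  # ratio check restricted to bins where the decay has not underflowed
  k <- which(m > 1e-3 * max(m))  # keep bins clear of fft roundoff
  k <- k[-1]
  expect_lt(max(abs(m[k] / m[k - 1] - exp(-dt / 0.5))), 1e-9)
})

test_that("periodic model matches brute-force multi-pulse summation", {
  n <- 512; period <- 50
  p <- bi_exp_params(a1 = 0.87, a2 = 0.13, tau1 = 0.82, tau2 = 3.47)
  t <- (seq_len(n) - 1) * (period / n)
  m <- model_decay(p, NULL, n_bins = n, period = period)
  bf <- brute_force_periodic(p, t, period)
  expect_lt(max(abs(m - bf) / bf), 1e-10)
  # wraparound: value just below T exceeds the single-pulse decay there
  single <- p$a1 * exp(-t[n] / p$tau1) + p$a2 * exp(-t[n] / p$tau2)
  expect_gt(m[n], single)
})

test_that("steady-state factor matches >= 100-pulse summation over a (tau, T) sweep", {
  period <- 50
  for (ratio in c(0.005, 0.01, 0.05, 0.1, 0.2, 0.35, 0.5)) {
    tau <- ratio * period
    bf <- sum(exp(-(0:199) * period / tau))
    expect_lt(abs(periodic_steady_state(tau, period) - bf) / bf, 1e-9)
  }
})

test_that("background-only and afterpulse terms are uniform", {
  n <- 128
  p <- bi_exp_params(a1 = 0, a2 = 0, tau1 = 1, tau2 = 2, background = 7)
  expect_equal(model_decay(p, NULL, n_bins = n), rep(7, n))
  # afterpulse adds ap * fluorescence_total / n to every bin
  p2 <- bi_exp_params(a1 = 100, a2 = 0, tau1 = 0.5, tau2 = 0.5,
                      afterpulse = 0.02)
  p0 <- bi_exp_params(a1 = 100, a2 = 0, tau1 = 0.5, tau2 = 0.5)
  m2 <- model_decay(p2, NULL, n_bins = n)
  m0 <- model_decay(p0, NULL, n_bins = n)
  expect_equal(m2 - m0, rep(0.02 * sum(m0) / n, n), tolerance = 1e-12)
})

test_that("model respects IRF grid contract", {
  irf <- delta_irf(128)
  p <- ctrl_params()
  expect_error(model_decay(p, irf, n_bins = 256), "grid")
})

test_that("chi-square follows Neyman weighting with unit floor", {
  expect_equal(chi_square(c(4, 2), c(2, 1)), 1.5)
  expect_equal(chi_square(c(0, 5), c(1, 5)), 1)  # max(obs, 1) rule
  expect_equal(chi_square(c(3, 8, 1), c(3, 8, 1)), 0)
  # alternative zero-count handling drops the zero bin entirely
  expect_equal(chi_square(c(0, 5), c(1, 5), zero_counts = "exclude"), 0)
  expect_error(chi_square(c(1, 2), c(-1, 2)), "nonnegative")
  expect_error(chi_square(c(1, 2), c(1, 2, 3)), "length")
})

test_that("chi-square is invariant under a common bin permutation", {
  set.seed(11)
  obs <- rpois(64, 30)
  exp_ <- rpois(64, 30) + 0.5
  perm <- sample(64)
  expect_equal(chi_square(obs, exp_), chi_square(obs[perm], exp_[perm]))
})

test_that("tau_mean reproduces the printed control triples and bounds", {
  expect_equal(round(tau_mean(bi_exp_params(0.87, 0.13, 0.82, 3.47)), 2), 1.85)
  expect_equal(round(tau_mean(bi_exp_params(0.88, 0.12, 0.77, 3.08)), 2), 1.59)
  expect_equal(round(tau_mean(bi_exp_params(0.89, 0.11, 0.83, 3.05)), 2), 1.52)
  # degenerate equal lifetimes
  expect_equal(tau_mean(bi_exp_params(3, 9, 1.4, 1.4)), 1.4)
  expect_error(tau_mean(list(a1 = 0, a2 = 0, tau1 = 1, tau2 = 2)), "undefined")
})

test_that("tau_mean lies in [tau1, tau2] and is monotone in tau2 and a1", {
  set.seed(21)
  for (i in 1:25) {
    a1 <- runif(1, 0.1, 2); a2 <- runif(1, 0.1, 2)
    t1 <- runif(1, 0.3, 1.5); t2 <- t1 + runif(1, 0.5, 3)
    p <- bi_exp_params(a1, a2, t1, t2)
    tm <- tau_mean(p)
    expect_gte(tm, t1); expect_lte(tm, t2)
    h <- 1e-4
    up_t2 <- tau_mean(bi_exp_params(a1, a2, t1, t2 + h))
    up_a1 <- tau_mean(bi_exp_params(a1 + h, a2, t1, t2))
    expect_gt(up_t2, tm)   # increasing in tau2
    expect_lt(up_a1, tm)   # decreasing in a1
  }
})

test_that("alpha_fraction handles limits and errors", {
  expect_equal(alpha_fraction(bi_exp_params(5, 5, 1, 2)), 0.5)
  expect_equal(alpha_fraction(bi_exp_params(3, 0, 1, 2)), 1.0)
  expect_equal(alpha_fraction(bi_exp_params(870, 130, 0.82, 3.47)), 0.87)
  expect_error(alpha_fraction(list(a1 = 0, a2 = 0)), "undefined")
})

test_that("parameter constructor enforces canonical order and invariants", {
  p <- bi_exp_params(10, 90, 3.0, 0.5)  # swapped input
  expect_lte(p$tau1, p$tau2)
  expect_equal(p$a1, 90)   # amplitude follows its lifetime
  expect_error(bi_exp_params(-1, 1, 1, 2), "nonnegative")
  expect_error(bi_exp_params(1, 1, 0, 2), "positive")
})

test_that("histogram constructor validates counts and span", {
  expect_error(decay_histogram(c(1, -2)), "nonnegative")
  expect_error(decay_histogram(c(1.5, 2)), "integral")
  h <- decay_histogram(c(1.5, 2), allow_fractional = TRUE)
  expect_equal(h$n_bins, 2L)
  expect_error(decay_histogram(rep(1, 100), bin_width = 1, period = 50),
               "span")
})
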