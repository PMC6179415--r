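# Shared fixtures: small grids and canonical control-regime parameters.

ctrl_params <- function(scale = 1000) {
  bi_exp_params(a1 = 0.87 * scale, a2 = 0.13 * scale,
                tau1 = 0.82, tau2 = 3.47)
}

delta_irf <- function(n_bins = 256, period = 50) {
  w <- numeric(n_bins)
  w[1] <- 1
  instrument_response(w, bin_width = period / n_bins)
}

gauss_irf <- function(fwhm = 0.25, n_bins = 1024, period = 50) {
  simulate_irf(fwhm, n_bins = n_bins, period = period)
}

# brute-force multi-pulse model: sum the single-pulse bi-exponential
# response of `n_pulses` preceding excitations (delta IRF), the independent
# oracle for the periodic steady-state closed form
brute_force_periodic <- function(params, t, period, n_pulses = 200) {
  out <- numeric(length(t))
  for (j in 0:(n_pulses - 1)) {
    out <- out + params$a1 * exp(-(t + j * period) / params$tau1) +
                 params$a2 * exp(-(t + j * period) / params$tau2)
  }
  out
}
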