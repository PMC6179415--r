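#' Expected bi-exponential decay under periodic excitation
#'
#' Evaluates the model histogram for a bi-exponential decay excited at high
#' repetition rate and blurred by the instrument response. Each exponential
#' component is made periodic-steady-state -- at a 50 ns period long-lived
#' fluorescence from preceding pulses wraps into the current period, so each
#' component is scaled by \eqn{1/(1 - e^{-T/\tau})} ("incomplete decay") --
#' then circularly convolved with the IRF over the period. A constant
#' background and a uniform afterpulsing term (afterpulse probability times
#' total modeled fluorescence counts divided by the number of bins) are
#' added.
#'
#' @param params A [bi_exp_params()] object.
#' @param irf An [instrument_response()] on the same grid, or `NULL` for a
#'   delta-function IRF.
#' @param n_bins Number of bins (default 1024).
#' @param bin_width Bin width in ns; default `period / n_bins`.
#' @param period Repetition period in ns (default 50, i.e. 20 MHz).
#' @return Numeric vector of expected counts per bin (nonnegative).
#' @examples
#' p <- bi_exp_params(870, 130, 0.82, 3.47)
#' m <- model_decay(p, NULL, n_bins = 256)
#' @export
model_decay <- function(params, irf = NULL, n_bins = 1024L,
                        bin_width = NULL, period = 50.0) {
  stopifnot(inherits(params, "bi_exp_params"))
  if (!is.null(irf)) {
    stopifnot(inherits(irf, "instrument_response"))
    if (length(irf$weights) != n_bins) {
      stop("IRF grid length does not match histogram grid")
    }
  }
  if (is.null(bin_width)) bin_width <- period / n_bins
  irf_fft <- if (is.null(irf)) NULL else stats::fft(irf$weights)
  .model_decay_fft(c(params$a1, params$a2, params$tau1, params$tau2,
                     params$background, params$afterpulse),
                   irf_fft, n_bins, bin_width, period)
}

# Fast path used by the fitter: parameters as a plain vector
# (a1, a2, tau1, tau2, background, afterpulse) and a precomputed fft(IRF)
# (NULL = delta IRF). Returns expected counts per bin.
.model_decay_fft <- function(theta, irf_fft, n_bins, bin_width, period) {
  a1 <- theta[1]; a2 <- theta[2]; tau1 <- theta[3]; tau2 <- theta[4]
  bg <- theta[5]; ap <- theta[6]
  t <- (seq_len(n_bins) - 1) * bin_width
  decay <- a1 * periodic_steady_state(tau1, period) * exp(-t / tau1) +
           a2 * periodic_steady_state(tau2, period) * exp(-t / tau2)
  if (!is.null(irf_fft)) {
    decay <- Re(stats::fft(stats::fft(decay) * irf_fft, inverse = TRUE)) / n_bins
    decay[decay < 0] <- 0  # clip fft roundoff
  }
  fluor_total <- sum(decay)
  decay + bg + ap * fluor_total / n_bins
}

#' Periodic steady-state scaling factor for an exponential decay
#'
#' Closed form of the pile-up from all preceding excitation pulses: an
#' exponential with lifetime `tau` excited every `period` ns reaches a
#' steady state equal to the single-pulse decay scaled by
#' \eqn{1/(1 - e^{-T/\tau})}.
#'
#' @param tau Lifetime in ns, positive.
#' @param period Repetition period in ns.
#' @return Scalar scaling factor >= 1.
#' @export
periodic_steady_state <- function(tau, period) {
  stopifnot(tau > 0, period > 0)
  1 / (1 - exp(-period / tau))
}

#' Neyman chi-square between an observed histogram and a model
#'
#' \eqn{\chi^2 = \sum_k (I_k - I_{model,k})^2 / w_k} with per-bin weights
#' `w = max(I, 1)`: observed-count (Neyman) weighting with zero-count bins
#' given unit variance to avoid division by zero. Optionally zero-count bins
#' can be excluded instead.
#'
#' @param observed A [decay_histogram()] or numeric vector of counts.
#' @param expected Numeric vector of model counts, same length, nonnegative.
#' @param zero_counts `"unit_weight"` (default, w = max(obs, 1)) or
#'   `"exclude"` (drop zero-count bins from the sum).
#' @return Nonnegative scalar.
#' @examples
#' chi_square(c(4, 2), c(2, 1))  # (4-2)^2/4 + (2-1)^2/2 = 1.5
#' @export
chi_square <- function(observed, expected,
                       zero_counts = c("unit_weight", "exclude")) {
  zero_counts <- match.arg(zero_counts)
  obs <- if (inherits(observed, "decay_histogram")) observed$counts else as.numeric(observed)
  expected <- as.numeric(expected)
  if (length(obs) != length(expected)) stop("observed and expected lengths differ")
  if (any(expected < 0)) stop("expected counts must be nonnegative")
  if (zero_counts == "exclude") {
    keep <- obs > 0
    obs <- obs[keep]; expected <- expected[keep]
    w <- obs
  } else {
    w <- pmax(obs, 1)
  }
  sum((obs - expected)^2 / w)
}

#' Intensity-weighted mean fluorescence lifetime
#'
#' \eqn{\tau_{mean} = (a_1\tau_1^2 + a_2\tau_2^2) / (a_1\tau_1 + a_2\tau_2)}:
#' each component's lifetime weighted by its share of the emitted intensity
#' (amplitude times lifetime). Always lies between `tau1` and `tau2`.
#'
#' @param params A [bi_exp_params()] object, or a list with fields
#'   `a1, a2, tau1, tau2`.
#' @return Mean lifetime in ns.
#' @examples
#' tau_mean(bi_exp_params(0.87, 0.13, 0.82, 3.47))  # ~1.85 ns
#' @export
tau_mean <- function(params) {
  den <- params$a1 * params$tau1 + params$a2 * params$tau2
  if (den == 0) stop("undefined mean lifetime: a1*tau1 + a2*tau2 is zero")
  (params$a1 * params$tau1^2 + params$a2 * params$tau2^2) / den
}

#' Fractional amplitude of the fast decay component
#'
#' \eqn{\alpha_1 = a_1 / (a_1 + a_2)}: the short-lifetime component's share
#' of the initial fluorescence signal.
#'
#' @param params A [bi_exp_params()] object or list with `a1`, `a2`.
#' @return Fraction in `[0, 1]`.
#' @export
alpha_fraction <- function(params) {
  s <- params$a1 + params$a2
  if (s == 0) stop("undefined fraction: a1 + a2 is zero")
  params$a1 / s
}
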