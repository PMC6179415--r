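#' Detection channel identifiers
#'
#' The four spectral detection channels of the time-resolved
#' spectrofluorometer: CH1-CH3 are excited at 372 nm (emission bands
#' 410 +/- 10, 455 +/- 25 and 525 +/- 25 nm), CH4 at 438 nm
#' (525 +/- 25 nm). See [channel_table()].
#' @keywords internal
CHANNELS <- c("CH1", "CH2", "CH3", "CH4")

#' Construct a TCSPC decay histogram
#'
#' A photon arrival-time histogram for one detection channel and one
#' acquisition: nonnegative integer counts per time bin, spanning (at most)
#' one laser repetition period.
#'
#' @param counts Nonnegative photon counts per bin. Integral unless
#'   `allow_fractional = TRUE` (used for noiseless expected-count vectors).
#' @param bin_width Bin width in ns. Defaults to `period / length(counts)`.
#' @param period Laser repetition period in ns (50 ns at 20 MHz).
#' @param channel_id One of `"CH1".."CH4"`, or `NA`.
#' @param acquisition_time Integration time in seconds (1 s default).
#' @param allow_fractional Accept non-integral counts (model expectations).
#' @return An object of class `decay_histogram` with fields `counts`,
#'   `n_bins`, `bin_width`, `period`, `channel_id`, `acquisition_time`.
#' @examples
#' h <- decay_histogram(rpois(1024, 50))
#' h$n_bins
#' @export
decay_histogram <- function(counts, bin_width = NULL, period = 50.0,
                            channel_id = NA_character_,
                            acquisition_time = 1.0,
                            allow_fractional = FALSE) {
  counts <- as.numeric(counts)
  n_bins <- length(counts)
  if (n_bins == 0L) stop("histogram must have at least one bin")
  if (anyNA(counts) || any(counts < 0)) {
    stop("counts must be nonnegative and finite")
  }
  if (!allow_fractional && any(abs(counts - round(counts)) > 1e-8)) {
    stop("counts must be integral (set allow_fractional = TRUE for model expectations)")
  }
  if (is.null(bin_width)) bin_width <- period / n_bins
  if (bin_width <= 0 || period <= 0) stop("bin_width and period must be positive")
  if (n_bins * bin_width > period + bin_width + 1e-9) {
    stop("histogram span exceeds the repetition period")
  }
  if (!is.na(channel_id) && !channel_id %in% CHANNELS) {
    stop("channel_id must be one of ", paste(CHANNELS, collapse = ", "))
  }
  structure(
    list(counts = counts, n_bins = n_bins, bin_width = bin_width,
         period = period, channel_id = channel_id,
         acquisition_time = acquisition_time),
    class = "decay_histogram"
  )
}

#' Time grid of a decay histogram
#'
#' Bin start times in ns; bin 0 is the earliest arrival-time bin.
#' @param x A `decay_histogram` or `instrument_response`.
#' @return Numeric vector of times in ns.
#' @export
time_grid <- function(x) {
  n <- if (inherits(x, "decay_histogram")) x$n_bins else length(x$weights)
  (seq_len(n) - 1) * x$bin_width
}

#' Construct an instrument response function
#'
#' The normalized temporal response of one detection channel (laser pulse
#' shape convolved with detector transit-time spread), on the same time grid
#' as the decay histograms it will be paired with.
#'
#' @param weights Nonnegative weights per bin; normalized to unit sum.
#' @param bin_width Bin width in ns.
#' @param channel_id Optional channel identifier.
#' @return An object of class `instrument_response`.
#' @export
instrument_response <- function(weights, bin_width, channel_id = NA_character_) {
  weights <- as.numeric(weights)
  if (length(weights) == 0L) stop("IRF must have at least one bin")
  if (anyNA(weights) || any(weights < 0)) stop("IRF weights must be nonnegative")
  s <- sum(weights)
  if (s <= 0) stop("IRF weights must not all be zero")
  structure(
    list(weights = weights / s, bin_width = bin_width, channel_id = channel_id),
    class = "instrument_response"
  )
}

#' Construct bi-exponential decay parameters
#'
#' Parameters of the two-component decay model
#' \eqn{I(t) = a_1 e^{-t/\tau_1} + a_2 e^{-t/\tau_2}} plus a constant
#' background and a uniform afterpulsing component. Components are stored in
#' canonical order `tau1 <= tau2`.
#'
#' @param a1,a2 Nonnegative amplitudes (counts at t = 0 per component).
#' @param tau1,tau2 Component lifetimes in ns, positive.
#' @param background Constant counts per bin (measured offset).
#' @param afterpulse Dimensionless probability scaling a uniform component
#'   proportional to the total modeled fluorescence.
#' @return An object of class `bi_exp_params`.
#' @examples
#' p <- bi_exp_params(870, 130, 0.82, 3.47)
#' tau_mean(p)
#' @export
bi_exp_params <- function(a1, a2, tau1, tau2, background = 0, afterpulse = 0) {
  stopifnot(is.finite(a1), is.finite(a2), is.finite(tau1), is.finite(tau2))
  if (a1 < 0 || a2 < 0) stop("amplitudes must be nonnegative")
  if (tau1 <= 0 || tau2 <= 0) stop("lifetimes must be positive")
  if (background < 0) stop("background must be nonnegative")
  if (afterpulse < 0) stop("afterpulse must be nonnegative")
  if (tau1 > tau2) {  # canonical ordering: fast component first
    tmp <- tau1; tau1 <- tau2; tau2 <- tmp
    tmp <- a1; a1 <- a2; a2 <- tmp
  } else if (tau1 == tau2 && a2 > a1) {
    tmp <- a1; a1 <- a2; a2 <- tmp  # ties: larger amplitude first
  }
  structure(
    list(a1 = a1, a2 = a2, tau1 = tau1, tau2 = tau2,
         background = background, afterpulse = afterpulse),
    class = "bi_exp_params"
  )
}

#' Construct a reference-dye measurement
#'
#' A TCSPC histogram of a reference fluorophore with a known, short,
#' mono-exponential lifetime (DAPI or Erythrosin B, ~0.2 ns), used to
#' reconstruct the instrument response via [irf_from_reference()].
#'
#' @param histogram A `decay_histogram` of the reference dye.
#' @param reference_lifetime Known mono-exponential lifetime in ns.
#' @return An object of class `reference_measurement`.
#' @export
reference_measurement <- function(histogram, reference_lifetime = 0.2) {
  stopifnot(inherits(histogram, "decay_histogram"))
  if (!is.finite(reference_lifetime) || reference_lifetime <= 0) {
    stop("reference_lifetime must be positive")
  }
  if (reference_lifetime > histogram$period / 5) {
    stop("reference_lifetime must be much shorter than the repetition period")
  }
  structure(
    list(histogram = histogram, reference_lifetime = reference_lifetime),
    class = "reference_measurement"
  )
}

#' @export
print.decay_histogram <- function(x, ...) {
  cat(sprintf("<decay_histogram> %s: %d bins x %.4f ns, period %.1f ns, %g counts\n",
              ifelse(is.na(x$channel_id), "?", x$channel_id),
              x$n_bins, x$bin_width, x$period, sum(x$counts)))
  invisible(x)
}

#' @export
print.bi_exp_params <- function(x, ...) {
  cat(sprintf("<bi_exp_params> a1=%.4g a2=%.4g tau1=%.4g tau2=%.4g bg=%.4g ap=%.4g\n",
              x$a1, x$a2, x$tau1, x$tau2, x$background, x$afterpulse))
  invisible(x)
}
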