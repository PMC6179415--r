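# Synthetic Langendorff-protocol data generator: IRFs, TCSPC histograms,
# reflectance spectra and full multi-heart protocol datasets with ground
# truth, emulating control / hypoxia / glucose-depletion perfusions.

#' Derive a reproducible sub-seed from a master seed
#'
#' Counter-based split of one master seed into independent per-(heart,
#' time, channel) streams: a 32-bit integer mix keeping the result in
#' `[1, 2^31 - 2]` so partial regeneration of a dataset reproduces the same
#' draws.
#'
#' @param seed Master seed (integer).
#' @param ... Integer counters (heart index, time index, channel index...).
#' @return Integer sub-seed.
#' @export
derive_seed <- function(seed, ...) {
  ctr <- c(...)
  x <- as.double(seed) %% 2147483647
  for (c in ctr) {
    x <- (x * 48271 + as.double(c) * 16807 + 12345) %% 2147483647
  }
  as.integer(x %% 2147483645 + 1)
}

#' Simulate a Gaussian instrument response
#'
#' A normalized Gaussian temporal response centered a few bins after the
#' time origin, emulating the combined laser pulse and detector transit
#' spread (a couple of hundred ps FWHM in this instrument class).
#'
#' @param fwhm_ns Full width at half maximum in ns, in (0, 2].
#' @param n_bins,bin_width,period Time grid (defaults 1024 bins over 50 ns).
#' @param center_ns Center of the response in ns (default `4 * fwhm_ns`,
#'   keeping the rising edge on-grid).
#' @param channel_id Optional channel tag.
#' @return An [instrument_response()].
#' @export
simulate_irf <- function(fwhm_ns = 0.25, n_bins = 1024L, bin_width = NULL,
                         period = 50.0, center_ns = NULL,
                         channel_id = NA_character_) {
  if (!is.finite(fwhm_ns) || fwhm_ns <= 0 || fwhm_ns > 2) {
    stop("fwhm_ns must lie in (0, 2] ns")
  }
  if (is.null(bin_width)) bin_width <- period / n_bins
  if (is.null(center_ns)) center_ns <- 4 * fwhm_ns
  t <- (seq_len(n_bins) - 1) * bin_width
  sigma <- fwhm_ns / (2 * sqrt(2 * log(2)))
  if (sigma < bin_width / 2) {
    # sub-bin width collapses to a single-bin delta
    w <- numeric(n_bins)
    w[which.min(abs(t - center_ns))] <- 1
  } else {
    w <- exp(-0.5 * ((t - center_ns) / sigma)^2)
  }
  instrument_response(w, bin_width = bin_width, channel_id = channel_id)
}

#' Simulate a Poisson-noised TCSPC histogram
#'
#' Draws per-bin counts independently from a Poisson law whose mean is the
#' [model_decay()] expectation scaled to a requested total photon budget,
#' emulating shot noise of a photon-counting detector.
#'
#' @param params A [bi_exp_params()].
#' @param irf An [instrument_response()] or `NULL` (delta IRF).
#' @param total_counts Expected total photons (>= 0; 0 gives an all-zero
#'   histogram).
#' @param seed Seed for the Poisson draw (`NULL` uses the current RNG
#'   state).
#' @param n_bins,bin_width,period Grid when `irf` is `NULL`.
#' @param channel_id,acquisition_time Histogram metadata.
#' @return A [decay_histogram()].
#' @export
simulate_decay_histogram <- function(params, irf = NULL, total_counts = 1e6,
                                     seed = NULL, n_bins = 1024L,
                                     bin_width = NULL, period = 50.0,
                                     channel_id = NA_character_,
                                     acquisition_time = 1.0) {
  if (!is.finite(total_counts) || total_counts < 0) {
    stop("total_counts must be nonnegative")
  }
  if (!is.null(irf)) {
    n_bins <- length(irf$weights)
    bin_width <- irf$bin_width
  }
  if (is.null(bin_width)) bin_width <- period / n_bins
  if (total_counts == 0) {
    return(decay_histogram(numeric(n_bins), bin_width = bin_width,
                           period = period, channel_id = channel_id,
                           acquisition_time = acquisition_time))
  }
  mu <- model_decay(params, irf, n_bins = n_bins, bin_width = bin_width,
                    period = period)
  mu <- mu * total_counts / sum(mu)
  if (!is.null(seed)) set.seed(seed)
  counts <- stats::rpois(n_bins, mu)
  decay_histogram(counts, bin_width = bin_width, period = period,
                  channel_id = channel_id, acquisition_time = acquisition_time)
}

#' Spectral templates for the synthetic reflectance mixer
#'
#' Gaussian absorbance features of the chromophores that dominate
#' blood-free cardiac tissue: oxygenated myoglobin (alpha/beta double peak
#' at 544 and 578 nm), deoxygenated myoglobin (broad 560 nm peak) and
#' reduced cytochrome c (550 nm peak), over a flat baseline absorbance that
#' pins the pseudo-isosbestic level near 502 nm.
#'
#' @param baseline Flat absorbance level added to every template.
#' @return List of template definitions (`center`, `width_sd`, `amplitude`
#'   per Gaussian) of class `spectral_templates`.
#' @export
spectral_templates <- function(baseline = 0.2) {
  structure(list(
    baseline = baseline,
    oxy_myoglobin = data.frame(center = c(544, 578), width_sd = c(12, 10),
                               amplitude = c(0.35, 0.40)),
    deoxy_myoglobin = data.frame(center = 560, width_sd = 18, amplitude = 0.45),
    reduced_cytc = data.frame(center = 550, width_sd = 8, amplitude = 0.50)
  ), class = "spectral_templates")
}

# evaluate a set of Gaussian peaks on a wavelength grid
.gaussian_peaks <- function(peaks, wl) {
  out <- numeric(length(wl))
  for (i in seq_len(nrow(peaks))) {
    out <- out + peaks$amplitude[i] *
      exp(-0.5 * ((wl - peaks$center[i]) / peaks$width_sd[i])^2)
  }
  out
}

#' Synthetic absorbance of a chromophore mixture
#'
#' Linear mixture of the oxy/deoxy myoglobin templates (by the oxygenated
#' fraction) plus the reduced-cytochrome-c template scaled by its fraction,
#' on top of the flat baseline.
#'
#' @param templates A [spectral_templates()] object.
#' @param wavelengths Grid in nm.
#' @param oxy_fraction,red_cytc_fraction Mixing fractions in `[0, 1]`.
#' @return Numeric absorbance values.
#' @export
synthetic_absorbance <- function(templates, wavelengths, oxy_fraction,
                                 red_cytc_fraction = 0) {
  stopifnot(oxy_fraction >= 0, oxy_fraction <= 1,
            red_cytc_fraction >= 0, red_cytc_fraction <= 1)
  templates$baseline +
    oxy_fraction * .gaussian_peaks(templates$oxy_myoglobin, wavelengths) +
    (1 - oxy_fraction) * .gaussian_peaks(templates$deoxy_myoglobin, wavelengths) +
    red_cytc_fraction * .gaussian_peaks(templates$reduced_cytc, wavelengths)
}

#' Simulate a diffuse-reflectance sample / white-reference pair
#'
#' The white reference is a smooth lamp-like curve; the sample is the
#' reference attenuated by `10^(-A)` where `A` is the synthetic mixture
#' absorbance, with multiplicative log-normal noise on the sample.
#'
#' @param templates A [spectral_templates()].
#' @param oxy_fraction,red_cytc_fraction Mixing fractions in `[0, 1]`.
#' @param noise_sd Multiplicative noise SD (default 0.01; 0 disables).
#' @param seed Optional seed.
#' @param wavelengths Grid in nm (default 400-700 at 1 nm).
#' @return List with `sample` and `white_reference`
#'   ([reflectance_spectrum()] objects).
#' @export
simulate_reflectance <- function(templates = spectral_templates(),
                                 oxy_fraction = 1, red_cytc_fraction = 0,
                                 noise_sd = 0.01, seed = NULL,
                                 wavelengths = seq(400, 700, by = 1)) {
  a <- synthetic_absorbance(templates, wavelengths, oxy_fraction,
                            red_cytc_fraction)
  # smooth halogen-lamp-like reference spectrum
  i0 <- 0.4 + exp(-0.5 * ((wavelengths - 620) / 160)^2)
  i <- i0 * 10^(-a)
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    i <- i * exp(stats::rnorm(length(i), 0, noise_sd))
  }
  list(
    sample = reflectance_spectrum(wavelengths, i, role = "sample"),
    white_reference = reflectance_spectrum(wavelengths, i0,
                                           role = "white_reference")
  )
}

#' Delayed saturating-exponential trajectory
#'
#' Piecewise trajectory of one scalar parameter across the three protocol
#' phases: constant at `base` until the insult solution reaches the tissue
#' (switch time + transport delay), exponential approach to `plateau` with
#' time constant `tau_rise` during the insult, then exponential return
#' toward `base` with `tau_fall` once the reperfusion solution arrives.
#' Continuous everywhere.
#'
#' @param times Times in s.
#' @param base,plateau Baseline and insult asymptote values.
#' @param tau_rise,tau_fall Insult / reperfusion time constants in s (> 0).
#' @param t_on,t_off Solution switch times in s (default 180, 630).
#' @param delay Transport delay in s (default 120).
#' @return Numeric trajectory.
#' @export
trajectory <- function(times, base, plateau, tau_rise, tau_fall,
                       t_on = 180, t_off = 630, delay = 120) {
  stopifnot(tau_rise > 0, tau_fall > 0)
  t1 <- t_on + delay   # insult reaches the tissue
  t2 <- t_off + delay  # reperfusion reaches the tissue
  out <- rep(base, length(times))
  ins <- times >= t1 & times < t2
  out[ins] <- base + (plateau - base) * (1 - exp(-(times[ins] - t1) / tau_rise))
  v2 <- base + (plateau - base) * (1 - exp(-(t2 - t1) / tau_rise))
  rep_ <- times >= t2
  out[rep_] <- base + (v2 - base) * exp(-(times[rep_] - t2) / tau_fall)
  out
}

#' Scenario specification for the protocol simulator
#'
#' Bundles per-channel parameter trajectories (baseline value, insult
#' plateau, rise/fall time constants), the reflectance mixing trajectory,
#' noise levels and the transport delay for one experimental group.
#' Defaults encode the control-regime decay parameters (fast component
#' ~0.8 ns at fraction ~0.87-0.89, slow component ~3.0-3.5 ns) and the
#' qualitative insult dynamics of each group: hypoxia raises NAD(P)H (CH2)
#' intensity and lowers FAD (CH4) intensity with a slower recovery than
#' onset, and deoxygenates the tissue; glucose depletion slowly lowers CH2
#' intensity with little else; control is flat.
#'
#' @param group `"control"`, `"hypoxia"` or `"glucose_depletion"`.
#' @param total_counts Expected photons per 1 s acquisition (default 1e6).
#' @param delay Solution transport delay in s (default 120).
#' @param tau_insult,tau_reperfusion Insult onset / recovery time constants
#'   in s (defaults 45 / 120, recovery slower than onset).
#' @param intensity_noise_sd Multiplicative acquisition-to-acquisition
#'   intensity noise SD (motion, geometry; default 0.02).
#' @param reflectance_noise_sd Multiplicative reflectance noise SD (0.01).
#' @param heart_sd Relative SD of the once-per-heart log-normal offsets on
#'   baseline levels and effect sizes (default 0.05).
#' @param irf_fwhm_ns IRF width used for all channels (default 0.25 ns).
#' @param n_bins,period TCSPC grid (1024 bins, 50 ns).
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(group = c("control", "hypoxia", "glucose_depletion"),
                          total_counts = 1e6, delay = 120,
                          tau_insult = 45, tau_reperfusion = 120,
                          intensity_noise_sd = 0.02,
                          reflectance_noise_sd = 0.01,
                          heart_sd = 0.05, irf_fwhm_ns = 0.25,
                          n_bins = 1024L, period = 50.0) {
  group <- match.arg(group)
  stopifnot(tau_insult > 0, tau_reperfusion > 0, delay >= 0)
  # per-channel baseline decay parameters (control regime)
  base <- data.frame(
    channel = c("CH1", "CH2", "CH3", "CH4"),
    alpha1 = c(0.87, 0.87, 0.88, 0.89),
    tau1 = c(0.80, 0.82, 0.77, 0.83),
    tau2 = c(3.30, 3.47, 3.08, 3.05),
    rel_intensity = c(0.3, 1.0, 0.8, 1.0),  # CH1 dim (little collagen)
    stringsAsFactors = FALSE
  )
  # insult plateaus: multiplicative factor on intensity, absolute targets
  # for decay parameters; control keeps everything at baseline
  plateau <- base
  plateau$intensity_factor <- 1
  ref <- list(oxy_base = 1, oxy_plateau = 1, cytc_base = 0, cytc_plateau = 0)
  ti <- tau_insult; tr <- tau_reperfusion
  if (group == "hypoxia") {
    plateau$intensity_factor <- c(1.00, 1.35, 0.90, 0.70)
    plateau$tau1 <- c(0.80, 0.70, 0.68, 0.76)
    plateau$tau2 <- c(3.30, 3.70, 3.30, 2.90)
    plateau$alpha1 <- c(0.87, 0.90, 0.90, 0.84)
    ref <- list(oxy_base = 1, oxy_plateau = 0.05,
                cytc_base = 0, cytc_plateau = 0.8)
  } else if (group == "glucose_depletion") {
    # slow, partial decline of NAD(P)H intensity; no plateau inside the
    # 7.5 min insult; oxygenation unchanged
    ti <- 600; tr <- 300
    plateau$intensity_factor <- c(1.00, 0.70, 0.95, 1.00)
    plateau$tau2 <- c(3.30, 3.35, 2.95, 3.05)
    plateau$alpha1 <- c(0.87, 0.87, 0.85, 0.88)
  }
  structure(list(
    group = group, baseline = base, plateau = plateau,
    tau_insult = ti, tau_reperfusion = tr, delay = delay,
    total_counts = total_counts,
    intensity_noise_sd = intensity_noise_sd,
    reflectance_noise_sd = reflectance_noise_sd,
    heart_sd = heart_sd, irf_fwhm_ns = irf_fwhm_ns,
    n_bins = as.integer(n_bins), period = period,
    templates = spectral_templates()
  ), class = "scenario_spec")
}

#' Simulate a multi-heart Langendorff protocol dataset
#'
#' Generates, for each heart, the full three-phase protocol (306 time
#' points: 3 min baseline, 7.5 min insult, 15 min reperfusion at 5 s
#' sampling): per-channel TCSPC histograms drawn from the scenario's
#' parameter trajectories, reflectance sample/reference spectra from the
#' chromophore-mixing trajectory, and the complete ground-truth record.
#' Per-heart log-normal offsets on baselines and effect sizes are drawn
#' once per heart; all randomness derives from `seed` via [derive_seed()].
#'
#' @param spec A [scenario_spec()].
#' @param n_hearts Number of hearts (>= 1).
#' @param seed Master seed.
#' @param emit `"histograms"` (full raw data) or `"intensities"` (skip
#'   histogram storage; per-time intensities only, much lighter).
#' @param keep_every_histogram Keep raw histograms only at every k-th time
#'   point (default 1 = all); intensities are always complete.
#' @return A list of class `protocol_dataset`: `spec`, `times`, `phase`,
#'   `hearts` (each with `heart_id`, `truth` data.frame, `intensities`
#'   matrix time x channel, `histograms` nested list, `reflectance` list,
#'   `white_reference`), and `irf` per channel.
#' @export
simulate_protocol <- function(spec, n_hearts, seed = 1,
                              emit = c("histograms", "intensities"),
                              keep_every_histogram = 1L) {
  emit <- match.arg(emit)
  stopifnot(inherits(spec, "scenario_spec"), n_hearts >= 1)
  ph <- protocol_phases()
  times <- seq(0, ph$total - ph$sampling, by = ph$sampling)
  n_t <- length(times)
  phase <- segment_phases(times, c(ph$baseline_end, ph$insult_end))
  bin_width <- spec$period / spec$n_bins
  irfs <- lapply(CHANNELS, function(ch) {
    simulate_irf(spec$irf_fwhm_ns, n_bins = spec$n_bins,
                 period = spec$period, channel_id = ch)
  })
  names(irfs) <- CHANNELS
  wl <- seq(400, 700, by = 1)
  white <- reflectance_spectrum(
    wl, 0.4 + exp(-0.5 * ((wl - 620) / 160)^2), role = "white_reference")

  hearts <- vector("list", n_hearts)
  for (hh in seq_len(n_hearts)) {
    set.seed(derive_seed(seed, hh, 0, 0))
    # once-per-heart offsets: baseline scale and effect-size jitter
    scale_off <- exp(stats::rnorm(4, 0, spec$heart_sd))          # intensity
    eff_off <- exp(stats::rnorm(4, 0, spec$heart_sd))            # plateau
    tau1_off <- stats::rnorm(4, 0, 0.01)
    tau2_off <- stats::rnorm(4, 0, 0.05)
    alpha_off <- stats::rnorm(4, 0, 0.005)
    noise <- matrix(exp(stats::rnorm(n_t * 4, 0, spec$intensity_noise_sd)),
                    n_t, 4)

    truth <- vector("list", 4)
    intensities <- matrix(NA_real_, n_t, 4, dimnames = list(NULL, CHANNELS))
    hists <- if (emit == "histograms") {
      stats::setNames(vector("list", 4), CHANNELS)
    } else NULL
    for (cc in 1:4) {
      b <- spec$baseline[cc, ]; p <- spec$plateau[cc, ]
      i_base <- spec$total_counts * b$rel_intensity * scale_off[cc]
      i_plat <- i_base * (1 + (p$intensity_factor - 1) * eff_off[cc])
      traj <- function(b0, p0) {
        trajectory(times, b0, p0, spec$tau_insult, spec$tau_reperfusion,
                   t_on = ph$baseline_end, t_off = ph$insult_end,
                   delay = spec$delay)
      }
      tr <- data.frame(
        time_s = times, channel = CHANNELS[cc],
        intensity = traj(i_base, i_plat) * noise[, cc],
        alpha1 = pmin(pmax(traj(b$alpha1 + alpha_off[cc],
                                p$alpha1 + alpha_off[cc]), 0), 1),
        tau1 = traj(b$tau1 + tau1_off[cc], p$tau1 + tau1_off[cc]),
        tau2 = traj(b$tau2 + tau2_off[cc], p$tau2 + tau2_off[cc])
      )
      tr$tau_mean <- mapply(function(a1, t1, t2) {
        tau_mean(list(a1 = a1, a2 = 1 - a1, tau1 = t1, tau2 = t2))
      }, tr$alpha1, tr$tau1, tr$tau2)
      truth[[cc]] <- tr
      keep_hist <- emit == "histograms" &
        ((seq_len(n_t) - 1L) %% keep_every_histogram == 0L)
      ch_hists <- vector("list", n_t)
      for (tt in seq_len(n_t)) {
        prm <- bi_exp_params(a1 = tr$alpha1[tt], a2 = 1 - tr$alpha1[tt],
                             tau1 = tr$tau1[tt], tau2 = tr$tau2[tt])
        s <- derive_seed(seed, hh, tt, cc)
        h <- simulate_decay_histogram(prm, irfs[[cc]],
                                      total_counts = tr$intensity[tt],
                                      seed = s, channel_id = CHANNELS[cc])
        intensities[tt, cc] <- sum(h$counts)
        if (keep_hist[tt]) ch_hists[[tt]] <- h
      }
      if (emit == "histograms") hists[[cc]] <- ch_hists
    }
    truth <- do.call(rbind, truth)

    # reflectance mixing trajectory
    if (spec$group == "hypoxia") {
      oxy <- trajectory(times, 1, 0.05, spec$tau_insult,
                        spec$tau_reperfusion, t_on = ph$baseline_end,
                        t_off = ph$insult_end, delay = spec$delay)
      cytc <- trajectory(times, 0, 0.8, spec$tau_insult,
                         spec$tau_reperfusion, t_on = ph$baseline_end,
                         t_off = ph$insult_end, delay = spec$delay)
    } else {
      oxy <- rep(1, n_t); cytc <- rep(0, n_t)
    }
    refl <- vector("list", n_t)
    for (tt in seq_len(n_t)) {
      refl[[tt]] <- simulate_reflectance(
        spec$templates, oxy_fraction = oxy[tt], red_cytc_fraction = cytc[tt],
        noise_sd = spec$reflectance_noise_sd,
        seed = derive_seed(seed, hh, tt, 5))$sample
    }
    hearts[[hh]] <- list(
      heart_id = sprintf("%s_%02d", spec$group, hh),
      truth = truth,
      truth_reflectance = data.frame(time_s = times, oxy_fraction = oxy,
                                     red_cytc_fraction = cytc),
      intensities = intensities,
      histograms = hists,
      reflectance = refl
    )
  }
  structure(list(spec = spec, times = times, phase = phase,
                 hearts = hearts, irf = irfs, white_reference = white),
            class = "protocol_dataset")
}

#' @export
print.protocol_dataset <- function(x, ...) {
  cat(sprintf("<protocol_dataset> %s: %d hearts x %d time points, %s\n",
              x$spec$group, length(x$hearts), length(x$times),
              if (is.null(x$hearts[[1]]$histograms)) "intensities only"
              else "raw histograms"))
  invisible(x)
}
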