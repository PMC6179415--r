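# Delimited-text IO for every pipeline type, plus configuration
# validation. All formats are plain CSV so datasets remain inspectable.

#' Read / write a decay histogram as CSV
#'
#' Columns `time_ns,counts`. Malformed or negative-count rows are rejected
#' with the offending line number.
#'
#' @param path File path.
#' @param channel_id,acquisition_time,period Metadata not stored in the
#'   two-column format.
#' @return A [decay_histogram()].
#' @export
read_histogram_csv <- function(path, channel_id = NA_character_,
                               acquisition_time = 1.0, period = 50.0) {
  df <- utils::read.csv(path)
  if (!all(c("time_ns", "counts") %in% names(df))) {
    stop("histogram file must have columns time_ns,counts: ", path)
  }
  bad <- which(!is.finite(df$counts) | df$counts < 0)
  if (length(bad)) {
    stop(sprintf("invalid counts at line %d of %s", bad[1] + 1L, path))
  }
  bw <- if (nrow(df) > 1) stats::median(diff(df$time_ns)) else period
  decay_histogram(df$counts, bin_width = bw, period = period,
                  channel_id = channel_id, acquisition_time = acquisition_time)
}

#' @rdname read_histogram_csv
#' @param hist A [decay_histogram()] to write.
#' @export
write_histogram_csv <- function(hist, path) {
  utils::write.csv(
    data.frame(time_ns = time_grid(hist), counts = hist$counts),
    path, row.names = FALSE)
  invisible(path)
}

#' Read / write an instrument response as CSV (`time_ns,weight`)
#' @param path File path.
#' @param channel_id Channel tag.
#' @return An [instrument_response()].
#' @export
read_irf_csv <- function(path, channel_id = NA_character_) {
  df <- utils::read.csv(path)
  if (!all(c("time_ns", "weight") %in% names(df))) {
    stop("IRF file must have columns time_ns,weight: ", path)
  }
  bw <- stats::median(diff(df$time_ns))
  instrument_response(df$weight, bin_width = bw, channel_id = channel_id)
}

#' @rdname read_irf_csv
#' @param irf An [instrument_response()] to write.
#' @export
write_irf_csv <- function(irf, path) {
  utils::write.csv(
    data.frame(time_ns = time_grid(irf), weight = irf$weights),
    path, row.names = FALSE)
  invisible(path)
}

#' Read / write a spectrum as CSV (`wavelength_nm,intensity`)
#' @param path File path.
#' @param role Spectrum role.
#' @return A [reflectance_spectrum()].
#' @export
read_spectrum_csv <- function(path, role = "sample") {
  df <- utils::read.csv(path)
  if (!all(c("wavelength_nm", "intensity") %in% names(df))) {
    stop("spectrum file must have columns wavelength_nm,intensity: ", path)
  }
  reflectance_spectrum(df$wavelength_nm, df$intensity, role = role)
}

#' @rdname read_spectrum_csv
#' @param spec A [reflectance_spectrum()] to write.
#' @export
write_spectrum_csv <- function(spec, path) {
  utils::write.csv(
    data.frame(wavelength_nm = spec$wavelengths,
               intensity = spec$intensities),
    path, row.names = FALSE)
  invisible(path)
}

#' Read a long-format multi-channel histogram file
#'
#' Columns `heart_id,time_s,channel,bin_index,counts`; one histogram per
#' (heart, time, channel) combination.
#'
#' @param path File path.
#' @param bin_width,period Grid geometry in ns.
#' @return Nested list: `hearts[[heart_id]][[as.character(time_s)]][[channel]]`
#'   of [decay_histogram()] objects.
#' @export
read_long_histograms <- function(path, bin_width = 50 / 1024, period = 50.0) {
  df <- utils::read.csv(path)
  need <- c("heart_id", "time_s", "channel", "bin_index", "counts")
  if (!all(need %in% names(df))) {
    stop("long histogram file must have columns ", paste(need, collapse = ","))
  }
  bad <- which(!is.finite(df$counts) | df$counts < 0)
  if (length(bad)) {
    stop(sprintf("invalid counts at line %d of %s", bad[1] + 1L, path))
  }
  out <- list()
  for (h in unique(df$heart_id)) {
    dh <- df[df$heart_id == h, ]
    out[[as.character(h)]] <- lapply(
      split(dh, dh$time_s), function(dt) {
        lapply(split(dt, dt$channel), function(dc) {
          dc <- dc[order(dc$bin_index), ]
          decay_histogram(dc$counts, bin_width = bin_width, period = period,
                          channel_id = as.character(dc$channel[1]))
        })
      })
  }
  out
}

#' Write a fit table as CSV
#' @param fits Fit table from [fit_protocol_decays()].
#' @param path File path.
#' @export
write_fits_csv <- function(fits, path) {
  utils::write.csv(fits, path, row.names = FALSE)
  invisible(path)
}

#' Default pipeline configuration
#'
#' All tunable parameters of the pipeline with their defaults: the channel
#' table, protocol timings (180 s baseline, 450 s insult, 900 s
#' reperfusion at 5 s sampling), TCSPC grid (1024 bins over a 50 ns
#' period) and fit/reflectance options.
#'
#' @return Named list of defaults.
#' @export
default_config <- function() {
  list(
    n_bins = 1024L,
    period_ns = 50.0,
    phase_durations_s = c(baseline = 180, insult = 450, reperfusion = 900),
    sampling_s = 5,
    baseline_norm_window_s = 60,
    channels = channel_table(),
    fit = list(min_counts = 1000, background = 0, afterpulse = 0,
               tau_bounds = c(0.01, 20)),
    reflectance = list(sign_convention = "standard",
                       oxygenation_nm = c(578, 600),
                       cytochrome_nm = c(502, 550)),
    seed = 1L
  )
}

#' Validate and complete a pipeline configuration
#'
#' Merges a partial configuration (e.g. parsed from YAML) over
#' [default_config()], rejecting unknown keys and out-of-range values with
#' an aggregated report.
#'
#' @param raw Named list of overrides (possibly empty), or a YAML file
#'   path.
#' @return The completed configuration list.
#' @export
validate_config <- function(raw = list()) {
  if (is.character(raw) && length(raw) == 1) raw <- yaml::read_yaml(raw)
  if (is.null(raw)) raw <- list()
  cfg <- default_config()
  unknown <- setdiff(names(raw), names(cfg))
  errors <- character(0)
  if (length(unknown)) {
    errors <- c(errors, paste("unknown configuration keys:",
                              paste(unknown, collapse = ", ")))
  }
  for (k in intersect(names(raw), names(cfg))) {
    if (is.list(cfg[[k]]) && !is.data.frame(cfg[[k]])) {
      sub_unknown <- setdiff(names(raw[[k]]), names(cfg[[k]]))
      if (length(sub_unknown)) {
        errors <- c(errors, paste0("unknown keys under '", k, "': ",
                                   paste(sub_unknown, collapse = ", ")))
        next
      }
      cfg[[k]][names(raw[[k]])] <- raw[[k]]
    } else {
      cfg[[k]] <- raw[[k]]
    }
  }
  if (cfg$n_bins <= 0) errors <- c(errors, "n_bins must be positive")
  if (cfg$period_ns <= 0) errors <- c(errors, "period_ns must be positive")
  if (any(cfg$phase_durations_s <= 0)) {
    errors <- c(errors, "phase durations must be positive")
  }
  if (cfg$sampling_s <= 0) errors <- c(errors, "sampling_s must be positive")
  if (length(errors)) {
    stop("invalid configuration:\n  - ", paste(errors, collapse = "\n  - "))
  }
  cfg
}
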