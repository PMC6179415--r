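# End-to-end assembly: from raw per-acquisition data to phase-labeled,
# baseline-normalized protocol time courses and group summaries.

#' Per-heart metric time courses from a simulated protocol dataset
#'
#' Computes, for every heart and time point: baseline-normalized channel
#' intensities (`nCH1..nCH4`), the optical redox ratio on normalized
#' intensities (`RR`), and the reflectance oxygenation (`ox_ratio`) and
#' cytochrome-c (`cytc_ratio`) absorbance ratios. Returned tidy
#' (long-format), phase-labeled.
#'
#' @param dataset A `protocol_dataset` from [simulate_protocol()].
#' @param normalize Normalize intensities to the first baseline minute
#'   (default TRUE).
#' @return A data.frame `heart_id`, `group`, `time_s`, `phase`, `metric`,
#'   `value`.
#' @export
protocol_timecourses <- function(dataset, normalize = TRUE) {
  stopifnot(inherits(dataset, "protocol_dataset"))
  times <- dataset$times
  phase <- dataset$phase
  out <- vector("list", length(dataset$hearts))
  for (i in seq_along(dataset$hearts)) {
    h <- dataset$hearts[[i]]
    ints <- h$intensities
    norm <- if (normalize) {
      apply(ints, 2, normalize_to_baseline, times = times)
    } else ints
    rr <- redox_ratio(norm[, "CH2"], norm[, "CH3"])
    ox <- cytc <- rep(NA_real_, length(times))
    for (tt in seq_along(times)) {
      ab <- absorbance(h$reflectance[[tt]], dataset$white_reference)
      ox[tt] <- oxygenation_ratio(ab)
      cytc[tt] <- cytochrome_ratio(ab)
    }
    metrics <- cbind(norm, RR = rr, ox_ratio = ox, cytc_ratio = cytc)
    colnames(metrics)[1:4] <- paste0("n", CHANNELS)
    out[[i]] <- data.frame(
      heart_id = h$heart_id,
      group = dataset$spec$group,
      time_s = rep(times, ncol(metrics)),
      phase = rep(phase, ncol(metrics)),
      metric = rep(colnames(metrics), each = length(times)),
      value = as.vector(metrics),
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, out)
}

#' Fit decay histograms of a protocol dataset
#'
#' Runs [fit_decay()] on the stored raw histograms of every heart at a
#' (possibly thinned) set of time points and returns the fitted decay
#' parameters in the standard fit-table layout.
#'
#' @param dataset A `protocol_dataset` with `emit = "histograms"`.
#' @param channels Channels to fit (default all four).
#' @param every Fit every k-th time point (default 1 = all stored).
#' @param options A [fit_options()].
#' @return A data.frame `heart_id`, `time_s`, `channel`, `a1`, `a2`,
#'   `tau1`, `tau2`, `background`, `afterpulse`, `tau_mean`, `alpha1`,
#'   `chi2`, `reduced_chi2`, `converged`.
#' @export
fit_protocol_decays <- function(dataset, channels = CHANNELS, every = 1L,
                                options = fit_options()) {
  stopifnot(inherits(dataset, "protocol_dataset"))
  rows <- list()
  idx <- seq(1L, length(dataset$times), by = every)
  for (h in dataset$hearts) {
    if (is.null(h$histograms)) stop("dataset was generated without histograms")
    for (ch in channels) {
      for (tt in idx) {
        hist <- h$histograms[[ch]][[tt]]
        if (is.null(hist)) next
        f <- fit_decay(hist, dataset$irf[[ch]], options = options)
        rows[[length(rows) + 1L]] <- data.frame(
          heart_id = h$heart_id, time_s = dataset$times[tt], channel = ch,
          a1 = f$params$a1, a2 = f$params$a2,
          tau1 = f$params$tau1, tau2 = f$params$tau2,
          background = f$params$background, afterpulse = f$params$afterpulse,
          tau_mean = f$tau_mean, alpha1 = f$alpha1,
          chi2 = f$chi2, reduced_chi2 = f$reduced_chi2,
          converged = f$converged, stringsAsFactors = FALSE
        )
      }
    }
  }
  do.call(rbind, rows)
}

#' Group summaries for every metric of a tidy time-course table
#'
#' @param timecourses Output of [protocol_timecourses()] (possibly several
#'   groups bound together).
#' @return A data.frame `group`, `metric`, `time_s`, `mean`, `sd`, `n`.
#' @export
summarize_groups <- function(timecourses) {
  out <- list()
  for (g in unique(timecourses$group)) {
    sub <- timecourses[timecourses$group == g, , drop = FALSE]
    for (m in unique(sub$metric)) {
      s <- group_summary(sub, m)
      s$group <- g
      s$metric <- m
      out[[length(out) + 1L]] <- s
    }
  }
  res <- do.call(rbind, out)
  res[, c("group", "metric", "time_s", "mean", "sd", "n")]
}
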