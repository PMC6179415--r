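#' Detection channel configuration table
#'
#' The four spectral detection channels of the instrument: excitation
#' wavelength, emission band center and half-width in nm.
#'
#' @return A data.frame with columns `name`, `excitation_nm`,
#'   `emission_center_nm`, `emission_halfwidth_nm`.
#' @export
channel_table <- function() {
  data.frame(
    name = c("CH1", "CH2", "CH3", "CH4"),
    excitation_nm = c(372, 372, 372, 438),
    emission_center_nm = c(410, 455, 525, 525),
    emission_halfwidth_nm = c(10, 25, 25, 25),
    stringsAsFactors = FALSE
  )
}

#' Protocol phase boundaries (seconds)
#'
#' Three-phase perfusion protocol: 3 min baseline, 7.5 min insult
#' perfusion, 15 min reperfusion, sampled every 5 s (total 25.5 min).
#' @return Named list `baseline_end = 180`, `insult_end = 630`,
#'   `total = 1530`, `sampling = 5`.
#' @export
protocol_phases <- function() {
  list(baseline_end = 180, insult_end = 630, total = 1530, sampling = 5)
}

#' Normalize a metric time series to its baseline average
#'
#' Divides every value by the mean of the samples acquired in the first
#' minute of baseline (t < 60 s; 12 samples at 5 s spacing), so the
#' baseline-window mean of the output is exactly 1 and the series is
#' invariant to any common rescaling of the raw values.
#'
#' @param series Numeric metric values.
#' @param times Acquisition times in seconds, same length.
#' @param baseline_window Length of the normalization window in s (60).
#' @return Normalized numeric vector.
#' @export
normalize_to_baseline <- function(series, times, baseline_window = 60) {
  if (length(series) != length(times)) stop("series/times length mismatch")
  in_win <- times >= 0 & times < baseline_window
  if (!any(in_win)) stop("no samples inside the baseline window")
  m <- mean(series[in_win], na.rm = TRUE)
  if (!is.finite(m) || m == 0) stop("baseline mean is zero or undefined")
  series / m
}

#' Optical redox ratio
#'
#' \eqn{RR = I_{CH2} / (I_{CH2} + I_{CH3})}: the NAD(P)H-dominated channel's
#' share of the 372 nm-excited autofluorescence, a proxy for glycolytic
#' versus oxidative metabolism. By convention applied to
#' baseline-normalized intensities. `alternative = TRUE` returns the plain
#' NAD(P)H/FAD intensity ratio \eqn{I_{CH2}/I_{CH3}} instead.
#'
#' @param i_ch2,i_ch3 Nonnegative channel intensities (vectors allowed).
#' @param alternative Use the plain CH2/CH3 ratio.
#' @return Ratio in `[0, 1]` (default form).
#' @export
redox_ratio <- function(i_ch2, i_ch3, alternative = FALSE) {
  if (any(i_ch2 < 0, na.rm = TRUE) || any(i_ch3 < 0, na.rm = TRUE)) {
    stop("intensities must be nonnegative")
  }
  if (any(i_ch2 + i_ch3 == 0, na.rm = TRUE)) {
    stop("redox ratio undefined: both channel intensities are zero")
  }
  if (alternative) i_ch2 / i_ch3 else i_ch2 / (i_ch2 + i_ch3)
}

#' Label protocol phases
#'
#' Assigns each acquisition time to baseline / insult / reperfusion using
#' half-open intervals `[0, b1)`, `[b1, b2)`, `[b2, end]`.
#'
#' @param times Times in seconds.
#' @param boundaries Two increasing boundaries in s (default `c(180, 630)`).
#' @return Factor with levels `baseline`, `insult`, `reperfusion`.
#' @export
segment_phases <- function(times, boundaries = c(180, 630)) {
  if (length(boundaries) != 2 || diff(boundaries) <= 0 || boundaries[1] <= 0) {
    stop("boundaries must be two increasing positive times")
  }
  lab <- ifelse(times < boundaries[1], "baseline",
                ifelse(times < boundaries[2], "insult", "reperfusion"))
  factor(lab, levels = c("baseline", "insult", "reperfusion"))
}

#' Group mean and standard deviation across hearts
#'
#' Aggregates one metric over a set of per-heart time series onto a common
#' time grid (nearest-time match within half a sampling interval), giving
#' per-time mean, sample SD (n - 1 denominator) and number of contributing
#' hearts.
#'
#' @param timecourses A long data.frame with columns `heart_id`, `time_s`,
#'   `metric`, `value` (as produced by the pipeline), or a list of
#'   data.frames with `time_s` and the metric column.
#' @param metric Name of the metric to summarize.
#' @param match_tolerance Maximum |time difference| in s when snapping each
#'   heart's samples to the common grid (default 2.5).
#' @return A data.frame `time_s`, `mean`, `sd`, `n`.
#' @export
group_summary <- function(timecourses, metric, match_tolerance = 2.5) {
  df <- timecourses[timecourses$metric == metric, , drop = FALSE]
  hearts <- unique(df$heart_id)
  if (length(hearts) < 2) {
    stop("group summary needs at least 2 hearts (SD undefined otherwise)")
  }
  grid <- sort(unique(df$time_s))
  per_heart <- vapply(hearts, function(h) {
    sub <- df[df$heart_id == h, , drop = FALSE]
    idx <- vapply(grid, function(t) {
      d <- abs(sub$time_s - t)
      i <- which.min(d)
      if (length(i) && d[i] <= match_tolerance) i else NA_integer_
    }, integer(1))
    sub$value[idx]
  }, numeric(length(grid)))
  per_heart <- matrix(per_heart, nrow = length(grid))
  n <- rowSums(!is.na(per_heart))
  data.frame(
    time_s = grid,
    mean = rowMeans(per_heart, na.rm = TRUE),
    sd = apply(per_heart, 1, stats::sd, na.rm = TRUE),
    n = n
  )
}

#' 10-90% transition time of a metric within a protocol phase
#'
#' Characterizes how fast a metric moves between its level at the start of
#' a phase window and its settled plateau (median of the final 20% of the
#' window). Returns `t(90%) - t(10%)`, where the crossing times of the 10%
#' and 90% levels between start and plateau are linearly interpolated;
#' works for rising and falling transitions.
#'
#' @param series Metric values inside the window.
#' @param times Times in s, same length, increasing.
#' @param plateau_fraction Fraction of the window tail used for the plateau
#'   level (default 0.2).
#' @param start_samples Number of leading samples averaged for the start
#'   level (default 1; raise for noisy series).
#' @return Transition time in s, or `NA` with attribute
#'   `reason = "no transition"` when no crossing exists.
#' @examples
#' t <- seq(0, 500, 5)
#' transition_time_10_90(1 - exp(-t / 45), t)  # ~ 45 * log(9)
#' @export
transition_time_10_90 <- function(series, times, plateau_fraction = 0.2,
                                  start_samples = 1) {
  if (length(series) != length(times)) stop("series/times length mismatch")
  if (length(series) < 5) stop("window too short for transition analysis")
  n <- length(series)
  level0 <- mean(series[seq_len(min(start_samples, n))], na.rm = TRUE)
  tail_idx <- seq.int(from = ceiling(n * (1 - plateau_fraction)), to = n)
  level1 <- stats::median(series[tail_idx], na.rm = TRUE)
  amp <- level1 - level0
  if (!is.finite(amp) || amp == 0) {
    return(structure(NA_real_, reason = "no transition"))
  }
  frac <- (series - level0) / amp  # 0 at start level, 1 at plateau
  cross_time <- function(target) {
    above <- frac >= target
    i <- which(above)[1]
    if (is.na(i)) return(NA_real_)
    if (i == 1) return(times[1])
    # linear interpolation between the bracketing samples
    f0 <- frac[i - 1]; f1 <- frac[i]
    times[i - 1] + (target - f0) / (f1 - f0) * (times[i] - times[i - 1])
  }
  t10 <- cross_time(0.1)
  t90 <- cross_time(0.9)
  if (is.na(t10) || is.na(t90) || t90 < t10) {
    return(structure(NA_real_, reason = "no transition"))
  }
  t90 - t10
}
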