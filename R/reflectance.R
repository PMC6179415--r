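#' Construct a reflectance spectrum
#'
#' @param wavelengths Strictly increasing wavelengths in nm, within
#'   350-800 nm.
#' @param intensities Nonnegative detector counts / radiometric units.
#' @param role `"sample"` or `"white_reference"`.
#' @return An object of class `reflectance_spectrum`.
#' @export
reflectance_spectrum <- function(wavelengths, intensities,
                                 role = c("sample", "white_reference")) {
  role <- match.arg(role)
  wavelengths <- as.numeric(wavelengths)
  intensities <- as.numeric(intensities)
  if (length(wavelengths) != length(intensities)) stop("length mismatch")
  if (any(diff(wavelengths) <= 0)) stop("wavelengths must be strictly increasing")
  if (any(wavelengths < 350 | wavelengths > 800)) {
    stop("wavelengths must lie within 350-800 nm")
  }
  if (anyNA(intensities) || any(intensities < 0)) {
    stop("intensities must be nonnegative")
  }
  structure(list(wavelengths = wavelengths, intensities = intensities,
                 role = role),
            class = "reflectance_spectrum")
}

#' Construct an absorbance spectrum
#' @param wavelengths Wavelengths in nm.
#' @param absorbance Dimensionless absorbance values (may contain `NA` for
#'   masked bins).
#' @return An object of class `absorbance_spectrum`.
#' @export
absorbance_spectrum <- function(wavelengths, absorbance) {
  wavelengths <- as.numeric(wavelengths)
  absorbance <- as.numeric(absorbance)
  if (length(wavelengths) != length(absorbance)) stop("length mismatch")
  if (any(is.infinite(absorbance), na.rm = TRUE)) stop("absorbance must be finite")
  structure(list(wavelengths = wavelengths, absorbance = absorbance),
            class = "absorbance_spectrum")
}

#' Tissue absorbance from a diffuse-reflectance spectrum
#'
#' Normalizes a measured spectrum to a white-reference spectrum and reports
#' absorbance. The default `"standard"` convention returns
#' \eqn{A = -\log_{10}(I/I_0)}, which yields positive peaks at absorber
#' bands (oxy-myoglobin maxima near 544 and 578 nm); `"as_printed"` returns
#' \eqn{\log_{10}(I/I_0)}, its negation. The reference is linearly
#' interpolated to the sample grid if the grids differ; bins where the
#' sample intensity is zero are masked (`NA`), and a zero reference at an
#' evaluated wavelength masks the bin with a warning.
#'
#' @param sample A `reflectance_spectrum` with role `"sample"`.
#' @param reference A `reflectance_spectrum` with role `"white_reference"`.
#' @param sign_convention `"standard"` (default) or `"as_printed"`.
#' @return An [absorbance_spectrum()] on the sample grid.
#' @export
absorbance <- function(sample, reference,
                       sign_convention = c("standard", "as_printed")) {
  sign_convention <- match.arg(sign_convention)
  stopifnot(inherits(sample, "reflectance_spectrum"),
            inherits(reference, "reflectance_spectrum"))
  i0 <- if (isTRUE(all.equal(sample$wavelengths, reference$wavelengths))) {
    reference$intensities
  } else {
    stats::approx(reference$wavelengths, reference$intensities,
                  xout = sample$wavelengths, rule = 1)$y
  }
  i <- sample$intensities
  a <- rep(NA_real_, length(i))
  bad_ref <- !is.na(i0) & i0 <= 0
  if (any(bad_ref)) {
    warning(sprintf("reference intensity is zero at %d wavelength(s); masked",
                    sum(bad_ref)))
  }
  ok <- !is.na(i0) & i0 > 0 & i > 0
  a[ok] <- log10(i[ok] / i0[ok])
  if (sign_convention == "standard") a <- -a
  absorbance_spectrum(sample$wavelengths, a)
}

# linear interpolation of absorbance at an exact wavelength
.absorbance_at <- function(spec, lambda) {
  rng <- range(spec$wavelengths)
  if (lambda < rng[1] || lambda > rng[2]) {
    stop(sprintf("wavelength %g nm outside spectrum range [%g, %g]",
                 lambda, rng[1], rng[2]))
  }
  ok <- !is.na(spec$absorbance)
  stats::approx(spec$wavelengths[ok], spec$absorbance[ok], xout = lambda)$y
}

#' Tissue-oxygenation absorbance ratio A(578)/A(600)
#'
#' The 578/600 nm absorbance ratio tracks myoglobin oxygenation: 578 nm sits
#' on the oxy-myoglobin beta peak while 600 nm is insensitive, so the ratio
#' falls as tissue deoxygenates. Values at the exact wavelengths are
#' obtained by linear interpolation on the spectrometer grid.
#'
#' @param spec An [absorbance_spectrum()] covering 578 and 600 nm.
#' @param numerator_nm,denominator_nm Override wavelengths in nm.
#' @return Dimensionless ratio.
#' @export
oxygenation_ratio <- function(spec, numerator_nm = 578, denominator_nm = 600) {
  num <- .absorbance_at(spec, numerator_nm)
  den <- .absorbance_at(spec, denominator_nm)
  if (is.na(num) || is.na(den)) stop("absorbance is masked at a ratio wavelength")
  if (den == 0) stop("zero absorbance at the denominator wavelength")
  num / den
}

#' Cytochrome-c oxidation-state absorbance ratio A(502)/A(550)
#'
#' 550 nm is the absorption peak of reduced cytochrome c and 502 nm a
#' pseudo-isosbestic wavelength insensitive to oxygenation; accumulation of
#' reduced cytochrome c raises A(550) and lowers this ratio.
#'
#' @param spec An [absorbance_spectrum()] covering 502 and 550 nm.
#' @return Dimensionless ratio.
#' @export
cytochrome_ratio <- function(spec) {
  oxygenation_ratio(spec, numerator_nm = 502, denominator_nm = 550)
}

#' Difference of two absorbance spectra with extremum wavelengths
#'
#' Computes `a - b` restricted to a wavelength band and reports the
#' wavelengths of its local maxima (above a prominence threshold); used to
#' locate the wavelengths where oxygenated and deoxygenated tissue spectra
#' differ most.
#'
#' @param a,b [absorbance_spectrum()] objects on a common grid.
#' @param band Two-element band in nm (default `c(400, 700)`).
#' @param min_prominence Minimum peak height above surroundings, as a
#'   fraction of the difference's full range (default 0.05).
#' @return A list: `difference` (an `absorbance_spectrum`) and
#'   `extrema_nm` (wavelengths of qualifying local maxima).
#' @export
difference_spectrum <- function(a, b, band = c(400, 700),
                                min_prominence = 0.05) {
  stopifnot(inherits(a, "absorbance_spectrum"), inherits(b, "absorbance_spectrum"))
  if (length(a$wavelengths) != length(b$wavelengths) ||
      any(abs(a$wavelengths - b$wavelengths) > 1e-9)) {
    stop("spectra must share a common wavelength grid")
  }
  keep <- a$wavelengths >= band[1] & a$wavelengths <= band[2]
  if (!any(keep)) stop("band does not overlap the spectra")
  wl <- a$wavelengths[keep]
  d <- a$absorbance[keep] - b$absorbance[keep]
  extrema <- numeric(0)
  rng <- diff(range(d, na.rm = TRUE))
  if (is.finite(rng) && rng > 0) {
    pk <- pracma::findpeaks(d, minpeakheight = min(d, na.rm = TRUE) +
                                 min_prominence * rng,
                            minpeakdistance = 3)
    if (!is.null(pk)) extrema <- sort(wl[pk[, 2]])
  }
  list(difference = absorbance_spectrum(wl, d), extrema_nm = extrema)
}
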