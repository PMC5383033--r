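#' Wavelength-indexed optical coefficient vector
#'
#' The universal currency of the package: a spectrum is a pair of equal-length
#' vectors, wavelengths in nm (strictly increasing) and optical coefficient
#' values, plus a tag identifying what the values are (absorption by CDOM,
#' particles, phytoplankton pigment or non-algal particles; particulate
#' scattering or backscattering; or a constituent-specific IOP).
#'
#' @param wavelength numeric vector of wavelengths (nm), strictly increasing.
#' @param value numeric vector of coefficients, same length as `wavelength`.
#'   Units are m^-1 for bulk IOPs; for SIOPs the units follow the normalizer
#'   (m^2 mg^-1 Chla, m^2 g^-1 TSM, m^2 mmol^-1 POC).
#' @param kind character tag, one of `"a_CDOM"`, `"a_p"`, `"a_phi"`,
#'   `"a_nap"`, `"b_p"`, `"b_b"`, `"SIOP"`, `"R"`, `"Rrs"`.
#' @return An object of class `"spectrum"`: a list with elements
#'   `wavelength`, `value`, `kind`.
#' @examples
#' s <- optical_spectrum(400:700, exp(-0.0177 * (400:700 - 412)), "a_CDOM")
#' spectrum_at(s, c(412, 500))
#' @export
optical_spectrum <- function(wavelength, value,
                             kind = c("a_CDOM", "a_p", "a_phi", "a_nap",
                                      "b_p", "b_b", "SIOP", "R", "Rrs")) {
  kind <- match.arg(kind)
  wavelength <- as.numeric(wavelength)
  value <- as.numeric(value)
  if (length(wavelength) != length(value))
    stop("wavelength and value must have the same length")
  if (length(wavelength) < 1L)
    stop("empty spectrum")
  if (any(!is.finite(wavelength)) || any(!is.finite(value)))
    stop("spectrum contains non-finite values")
  if (any(diff(wavelength) <= 0))
    stop("wavelengths must be strictly increasing")
  structure(list(wavelength = wavelength, value = value, kind = kind),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum [%s]> %d wavelengths, %.1f-%.1f nm, range [%.4g, %.4g]\n",
              x$kind, length(x$wavelength),
              min(x$wavelength), max(x$wavelength),
              min(x$value), max(x$value)))
  invisible(x)
}

#' @export
plot.spectrum <- function(x, ..., xlab = "wavelength (nm)", ylab = x$kind,
                          type = "l") {
  graphics::plot(x$wavelength, x$value, type = type,
                 xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

#' Interpolate a spectrum at given wavelengths
#'
#' Linear interpolation within the covered range; requests outside the range
#' are an error (no extrapolation of optical coefficients).
#'
#' @param spec a [optical_spectrum()] object.
#' @param wavelength wavelengths (nm) at which to evaluate.
#' @return numeric vector of interpolated values.
#' @export
spectrum_at <- function(spec, wavelength) {
  stopifnot(inherits(spec, "spectrum"))
  if (any(wavelength < min(spec$wavelength) - 1e-9) ||
      any(wavelength > max(spec$wavelength) + 1e-9))
    stop(sprintf("wavelength outside spectrum range %.1f-%.1f nm",
                 min(spec$wavelength), max(spec$wavelength)))
  stats::approx(spec$wavelength, spec$value, xout = wavelength,
                rule = 1)$y
}

#' Restrict a spectrum to a wavelength window
#' @param spec a spectrum.
#' @param range length-2 numeric, nm.
#' @return a spectrum covering only `range`.
#' @export
spectrum_window <- function(spec, range) {
  stopifnot(inherits(spec, "spectrum"), length(range) == 2L,
            range[1] < range[2])
  keep <- spec$wavelength >= range[1] & spec$wavelength <= range[2]
  if (!any(keep)) stop("no samples within requested range")
  optical_spectrum(spec$wavelength[keep], spec$value[keep], spec$kind)
}

# trapezoidal quadrature on an irregular grid
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((y[-1] + y[-n]) / 2 * diff(x))
}
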