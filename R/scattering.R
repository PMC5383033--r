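#' Convert volume scattering function measurements to backscattering
#'
#' Two conversion modes for fixed-angle volume scattering function (VSF)
#' sensors:
#' \describe{
#'   \item{polynomial}{A quadratic in mu = cos(theta) is fitted to the
#'     measured beta(theta) per wavelength (requires >= 3 angles) and the
#'     backscattering coefficient obtained analytically as
#'     b_b = 2 pi \int beta(theta) sin(theta) dtheta = 2 pi \int beta(mu) dmu
#'     over the backward hemisphere. The scheme is exact for phase functions
#'     constant or polynomial (up to quadratic) in cos(theta).}
#'   \item{fixed_angle}{Single-angle estimate b_b = 2 pi chi beta(theta_0)
#'     with conversion factor chi (default 1.1 at the 117-degree centroid
#'     of BB-type sensors).}
#' }
#' Input beta values are assumed to be particulate (water VSF already
#' subtracted); negative values are clipped to zero with a warning.
#'
#' @param vsf data.frame with columns `wavelength_nm`, `angle_deg`,
#'   `beta` (m^-1 sr^-1). Angles must lie in (90, 180).
#' @param mode `"polynomial"` or `"fixed_angle"`.
#' @param chi conversion factor for fixed-angle mode (> 0).
#' @param angle0 centroid angle for fixed-angle mode, degrees.
#' @return a `spectrum` of kind `"b_b"` at the measured wavelengths.
#' @examples
#' v <- data.frame(wavelength_nm = 532, angle_deg = 117, beta = 1e-4)
#' vsf_to_bb(v, mode = "fixed_angle")  # 2*pi*1.1*1e-4
#' @export
vsf_to_bb <- function(vsf, mode = c("polynomial", "fixed_angle"),
                      chi = 1.1, angle0 = 117) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(vsf),
            all(c("wavelength_nm", "angle_deg", "beta") %in% names(vsf)))
  if (any(vsf$angle_deg <= 90 | vsf$angle_deg >= 180))
    stop("VSF angles must lie strictly within (90, 180) degrees")
  if (!is.finite(chi) || chi <= 0) stop("chi must be positive")
  if (any(vsf$beta < 0)) {
    warning("negative beta after water subtraction clipped to 0")
    vsf$beta <- pmax(vsf$beta, 0)
  }
  wls <- sort(unique(vsf$wavelength_nm))
  bb <- vapply(wls, function(w) {
    sub <- vsf[vsf$wavelength_nm == w, ]
    if (mode == "fixed_angle") {
      i <- which.min(abs(sub$angle_deg - angle0))
      if (abs(sub$angle_deg[i] - angle0) > 1e-6)
        stop(sprintf("no measurement at the %g-degree centroid for %g nm",
                     angle0, w))
      return(2 * pi * chi * sub$beta[i])
    }
    if (nrow(sub) < 3L)
      stop(sprintf("polynomial mode needs >= 3 angles per wavelength (%g nm has %d)",
                   w, nrow(sub)))
    mu <- cos(sub$angle_deg * pi / 180)
    fit <- stats::lm(beta ~ mu + I(mu^2), data = cbind(sub, mu = mu))
    cf <- unname(stats::coef(fit))
    # 2*pi * integral of (c0 + c1 mu + c2 mu^2) dmu over mu in [-1, 0]
    2 * pi * (cf[1] - cf[2] / 2 + cf[3] / 3)
  }, numeric(1))
  optical_spectrum(wls, bb, "b_b")
}

#' Particulate backscattering ratio
#'
#' The backscattering-to-scattering ratio beta_p(lambda) =
#' b_bp(lambda) / b_p(lambda), a proxy of particle composition: organic,
#' watery particles (e.g. cyanobacteria) backscatter weakly. The scattering
#' spectrum is interpolated to the (coarser) backscattering channels.
#'
#' @param b_bp particulate backscattering `spectrum` (m^-1).
#' @param b_p particulate scattering `spectrum` (m^-1), covering the b_bp
#'   channels; must be positive there.
#' @return object of class `"backscatter_ratio"`: per-channel values plus
#'   spectral mean and least-squares spectral slope (per nm).
#' @export
backscatter_ratio <- function(b_bp, b_p) {
  stopifnot(inherits(b_bp, "spectrum"), inherits(b_p, "spectrum"))
  bp_at <- spectrum_at(b_p, b_bp$wavelength)
  if (any(bp_at <= 0)) stop("b_p must be positive at all shared channels")
  beta <- b_bp$value / bp_at
  slope <- if (length(beta) >= 2)
    unname(stats::coef(stats::lm(beta ~ b_bp$wavelength))[2]) else NA_real_
  structure(list(wavelength = b_bp$wavelength, beta = beta,
                 spectral_mean = mean(beta), spectral_slope = slope),
            class = "backscatter_ratio")
}

#' @export
print.backscatter_ratio <- function(x, ...) {
  cat(sprintf("Particulate backscattering ratio: mean %.4f, slope %.3g nm^-1\n",
              x$spectral_mean, x$spectral_slope))
  cat(sprintf("  channels (nm): %s\n", paste(x$wavelength, collapse = ", ")))
  cat(sprintf("  beta_p:        %s\n",
              paste(sprintf("%.4f", x$beta), collapse = ", ")))
  invisible(x)
}
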