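#' Irradiance depth profile
#'
#' Spectral downwelling (and optionally upwelling) irradiance as a function
#' of depth, the raw material for diffuse attenuation and subsurface
#' reflectance. Irradiance units are mW m^-2 nm^-1.
#'
#' @param depths depths in m, positive, strictly increasing, >= 2 values.
#' @param wavelength wavelengths in nm.
#' @param Ed matrix of downwelling irradiance, `length(depths)` rows by
#'   `length(wavelength)` columns.
#' @param Eu optional matching matrix of upwelling irradiance.
#' @return object of class `"irradiance_profile"`.
#' @export
irradiance_profile <- function(depths, wavelength, Ed, Eu = NULL) {
  depths <- as.numeric(depths)
  if (length(depths) < 2L || any(depths <= 0) || any(diff(depths) <= 0))
    stop("depths must be >= 2 positive increasing values")
  Ed <- as.matrix(Ed)
  if (!all(dim(Ed) == c(length(depths), length(wavelength))))
    stop("Ed must be depths x wavelengths")
  if (!is.null(Eu)) {
    Eu <- as.matrix(Eu)
    if (!all(dim(Eu) == dim(Ed))) stop("Eu must match Ed dimensions")
  }
  structure(list(depths = depths, wavelength = wavelength, Ed = Ed, Eu = Eu),
            class = "irradiance_profile")
}

#' @export
print.irradiance_profile <- function(x, ...) {
  cat(sprintf("<irradiance_profile> %d depths (%.1f-%.1f m), %d wavelengths%s\n",
              length(x$depths), min(x$depths), max(x$depths),
              length(x$wavelength),
              if (is.null(x$Eu)) "" else ", with Eu"))
  invisible(x)
}

# per-wavelength log-linear attenuation slope; returns Kd, r2, n_used
.kd_one <- function(z, E, min_frac = 1e-6) {
  usable <- is.finite(E) & E > 0 & E > min_frac * max(E, na.rm = TRUE)
  if (sum(usable) < 3L) return(c(NA, NA, sum(usable)))
  y <- log(E[usable])
  m <- stats::lm(y ~ z[usable])
  ssy <- sum((y - mean(y))^2)
  r2 <- if (ssy > 0) 1 - sum(stats::residuals(m)^2) / ssy else 1
  c(-unname(stats::coef(m)[2]), r2, sum(usable))
}

#' Spectral diffuse attenuation from an irradiance profile
#'
#' Per-wavelength ordinary least squares of ln E_d against depth over a
#' depth window; K_d is minus the slope. The first optical depth is
#' z90 = 1/K_d (the layer from which ~90% of water-leaving radiance
#' originates) and the euphotic depth z_eu = 4.6 z90 (1% light level).
#' Depths with E_d below 1e-6 of the profile maximum (or non-positive) are
#' excluded with a warning.
#'
#' @param profile an [irradiance_profile()].
#' @param depth_range fitting window in m (default 0-15).
#' @return object of class `"kd_fit"`: `wavelength`, `Kd` (m^-1), `r2`,
#'   `z90`, `z_eu` (m), `n_used`, `depth_range`.
#' @examples
#' z <- 1:10
#' pr <- irradiance_profile(z, 500, cbind(100 * exp(-0.5 * z)))
#' fit_kd(pr)$Kd  # 0.5
#' @export
fit_kd <- function(profile, depth_range = c(0, 15)) {
  stopifnot(inherits(profile, "irradiance_profile"))
  inwin <- profile$depths >= depth_range[1] & profile$depths <= depth_range[2]
  if (sum(inwin) < 3L)
    stop("need at least 3 depths within the fitting window")
  z <- profile$depths[inwin]
  Ed <- profile$Ed[inwin, , drop = FALSE]
  if (any(Ed <= 0))
    warning("non-positive irradiance values excluded from log fits")
  res <- apply(Ed, 2, .kd_one, z = z)
  Kd <- res[1, ]
  structure(list(wavelength = profile$wavelength, Kd = Kd, r2 = res[2, ],
                 z90 = 1 / Kd, z_eu = 4.6 / Kd, n_used = res[3, ],
                 depth_range = depth_range),
            class = "kd_fit")
}

#' @export
print.kd_fit <- function(x, ...) {
  cat(sprintf("Diffuse attenuation fit over %g-%g m, %d wavelengths\n",
              x$depth_range[1], x$depth_range[2], length(x$wavelength)))
  cat(sprintf("  Kd range %.3f-%.3f m^-1; z90 %.2f-%.2f m; z_eu %.1f-%.1f m\n",
              min(x$Kd, na.rm = TRUE), max(x$Kd, na.rm = TRUE),
              min(x$z90, na.rm = TRUE), max(x$z90, na.rm = TRUE),
              min(x$z_eu, na.rm = TRUE), max(x$z_eu, na.rm = TRUE)))
  invisible(x)
}

#' Euphotic depth from the first optical depth
#'
#' The 1% light-penetration depth, z_eu = 4.6 z90; for the Baltic green
#' band (z90 = 3.0-3.5 m) this gives 13.8-16.1 m.
#' @param z90 first optical depth(s), m.
#' @export
euphotic_depth <- function(z90) 4.6 * z90

#' PAR attenuation coefficient
#'
#' Computes photosynthetically active radiation at each depth as the
#' quantum-unit integral
#' PAR(z) = \eqn{\int_{400}^{700} E_d(z,\lambda)\,\lambda / (h c N_A)\, d\lambda}
#' (micromol photons m^-2 s^-1; trapezoidal quadrature on the native grid),
#' then fits the exponential slope of ln PAR against depth over the
#' near-surface window (default 0-7 m).
#'
#' @param profile an [irradiance_profile()] covering 400-700 nm.
#' @param depth_range fitting window, m (default 0-7).
#' @return list with `Kd_par` (m^-1), `r2`, `par` (per-depth values) and
#'   `depths`.
#' @export
kd_par <- function(profile, depth_range = c(0, 7)) {
  stopifnot(inherits(profile, "irradiance_profile"))
  wl <- profile$wavelength
  if (min(wl) > 400 + 1e-9 || max(wl) < 700 - 1e-9)
    stop("profile must cover 400-700 nm for PAR")
  inpar <- wl >= 400 & wl <= 700
  h <- 6.62607015e-34; cc <- 2.99792458e8; NA_ <- 6.02214076e23
  # mW m^-2 nm^-1 -> W m^-2 nm^-1 (1e-3); lambda nm -> m (1e-9);
  # photons -> micromol (1e6 / N_A)
  conv <- 1e-3 * 1e-9 * 1e6 / (h * cc * NA_)
  par_z <- apply(profile$Ed[, inpar, drop = FALSE], 1, function(E)
    trapz(wl[inpar], E * wl[inpar]) * conv)
  inwin <- profile$depths >= depth_range[1] & profile$depths <= depth_range[2]
  if (sum(inwin) < 3L)
    stop("need at least 3 depths within the PAR fitting window")
  k <- .kd_one(profile$depths[inwin], par_z[inwin])
  list(Kd_par = k[1], r2 = k[2], par = par_z, depths = profile$depths)
}

#' Subsurface irradiance reflectance
#'
#' Extrapolates the upwelling and downwelling irradiance streams to zero
#' depth by per-wavelength log-linear regression and returns the
#' dimensionless ratio R(0-, lambda) = E_u(0-) / E_d(0-). In Baltic waters
#' this reflectance peaks in the green (560-600 nm), where the combined
#' absorption of CDOM (blue) and water (red) is smallest.
#'
#' @param profile an [irradiance_profile()] with both streams and >= 3
#'   depths.
#' @return a `spectrum` of kind `"R"`.
#' @export
subsurface_reflectance <- function(profile) {
  stopifnot(inherits(profile, "irradiance_profile"))
  if (is.null(profile$Eu)) stop("profile has no upwelling stream")
  if (length(profile$depths) < 3L) stop("need >= 3 depths")
  z <- profile$depths
  extrap0 <- function(E) {
    usable <- is.finite(E) & E > 0
    if (sum(usable) < 3L) return(NA_real_)
    cf <- stats::coef(stats::lm(log(E[usable]) ~ z[usable]))
    exp(unname(cf[1]))
  }
  e0d <- apply(profile$Ed, 2, extrap0)
  e0u <- apply(profile$Eu, 2, extrap0)
  optical_spectrum(profile$wavelength, e0u / e0d, "R")
}

#' Classify the depth of a biomass peak
#'
#' Vertical profiles of Chla or POC in the upper 15 m are classified by the
#' depth of their maximum: near-surface (< 3 m), intermediate (3-10 m) or
#' deep (>= 10 m). Profiles with a coefficient of variation below 10% are
#' considered to have no peak. The classification is invariant to uniform
#' scaling of the profile.
#'
#' @param values concentrations (>= 0) at `depths`.
#' @param depths m, at least 3 within 0-15 m.
#' @param variable `"chla"` or `"poc"` (metadata).
#' @return list with `category` (one of `"lt3m"`, `"3to10m"`, `"ge10m"`,
#'   `"no_peak"`), `cv`, `peak_depth` and `variable`.
#' @examples
#' classify_peak(c(10, 5, 5, 4), c(1, 4, 8, 12))$category  # "lt3m"
#' @export
classify_peak <- function(values, depths, variable = c("chla", "poc")) {
  variable <- match.arg(variable)
  if (any(values < 0)) stop("negative concentrations")
  if (sum(depths <= 15) < 3L) stop("need >= 3 depths within 0-15 m")
  cv <- stats::sd(values) / mean(values)
  if (!is.finite(cv) || cv < 0.10)
    return(list(category = "no_peak", cv = if (is.finite(cv)) cv else 0,
                peak_depth = NA_real_, variable = variable))
  pd <- depths[which.max(values)]
  category <- if (pd < 3) "lt3m" else if (pd < 10) "3to10m" else "ge10m"
  list(category = category, cv = cv, peak_depth = pd, variable = variable)
}
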