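#' Discrete-sample biogeochemistry at a station
#'
#' @param chla chlorophyll-a, mg m^-3.
#' @param tsm total suspended matter, g m^-3.
#' @param ism inorganic suspended matter, g m^-3 (<= tsm).
#' @param poc,pon,pop particulate organic C/N/P, micromolar.
#' @param doc dissolved organic carbon, micromolar.
#' @param salinity practical salinity (dimensionless).
#' @param season `"spring"`, `"summer"` or `"other"`.
#' @param region regional tag (see [predict_acdom412()]).
#' @param depth sampling depth, m.
#' @return object of class `"station_biogeo"` (a one-row list).
#' @export
station_biogeo <- function(chla, tsm = NA, ism = NA, poc = NA, pon = NA,
                           pop = NA, doc = NA, salinity = NA,
                           season = c("spring", "summer", "other"),
                           region = "south_of_59N", depth = 3) {
  season <- match.arg(season)
  conc <- c(chla = chla, tsm = tsm, ism = ism, poc = poc, pon = pon,
            pop = pop, doc = doc)
  if (any(conc < 0, na.rm = TRUE)) stop("concentrations must be >= 0")
  if (is.finite(tsm) && is.finite(ism) && ism > tsm + 1e-12)
    stop("ism cannot exceed tsm")
  structure(list(chla = chla, tsm = tsm, ism = ism, poc = poc, pon = pon,
                 pop = pop, doc = doc, salinity = salinity, season = season,
                 region = region, depth = depth),
            class = "station_biogeo")
}

#' @export
print.station_biogeo <- function(x, ...) {
  cat(sprintf("<station [%s, %s]> Chla %.2f mg m^-3, TSM %.2f g m^-3, POC %.1f uM, depth %g m\n",
              x$season, x$region, x$chla, x$tsm, x$poc, x$depth))
  invisible(x)
}

#' Normalize an IOP spectrum to a constituent concentration
#'
#' Converts a bulk IOP spectrum to a specific IOP (SIOP) by element-wise
#' division by a constituent concentration: Chla (mg m^-3, giving
#' m^2 mg^-1), TSM (g m^-3, giving m^2 g^-1) or POC (micromolar, which is
#' numerically identical to mmol m^-3, giving m^2 mmol^-1).
#'
#' Small negative values down to -0.002 (measurement noise in spectral
#' tails) are retained; anything more negative is rejected.
#'
#' @param spec a `spectrum` (bulk IOP, m^-1).
#' @param biogeo a [station_biogeo()].
#' @param normalizer `"chla"`, `"tsm"` or `"poc"`.
#' @return a `spectrum` of kind `"SIOP"` with attributes `normalizer`,
#'   `component` (the input kind) and `season`.
#' @examples
#' st <- station_biogeo(chla = 14.1, season = "spring")
#' aphi <- optical_spectrum(c(440, 675), c(0.282, 0.197), "a_phi")
#' to_siop(aphi, st, "chla")
#' @export
to_siop <- function(spec, biogeo, normalizer = c("chla", "tsm", "poc")) {
  stopifnot(inherits(spec, "spectrum"), inherits(biogeo, "station_biogeo"))
  normalizer <- match.arg(normalizer)
  conc <- biogeo[[normalizer]]
  if (!is.finite(conc) || conc <= 0)
    stop(sprintf("normalizer %s is zero, negative or missing", normalizer))
  if (any(spec$value < -0.002))
    stop("spectrum has values below the -0.002 noise tolerance")
  out <- optical_spectrum(spec$wavelength, spec$value / conc, "SIOP")
  attr(out, "normalizer") <- normalizer
  attr(out, "component") <- spec$kind
  attr(out, "season") <- biogeo$season
  out
}

#' Pigment-packaging power model
#'
#' Fits the decline of the Chla-specific absorption coefficient with
#' increasing biomass, a* = c Chla^d, by log-log linear regression. The
#' packaging effect makes d <= 0: cells with more pigment absorb less
#' efficiently per unit pigment.
#'
#' @param chla chlorophyll-a concentrations, mg m^-3 (> 0).
#' @param siop Chla-specific absorption at one waveband, m^2 mg^-1 (> 0).
#' @param wavelength the waveband the SIOP values refer to (nm; metadata).
#' @param season season scope tag (metadata).
#' @return object of class `"packaging_fit"` with coefficients `c`, `d`,
#'   plus `r2` (log domain) and `rmse` in original units.
#' @examples
#' ch <- exp(seq(log(0.5), log(30), length.out = 50))
#' f <- fit_packaging(ch, 0.05 * ch^-0.3)
#' coef(f)
#' @export
fit_packaging <- function(chla, siop, wavelength = NA, season = "combined") {
  if (length(chla) < 5L) stop("need at least 5 observations")
  if (any(chla <= 0) || any(siop <= 0))
    stop("power model fit requires positive Chla and SIOP values (log domain)")
  m <- stats::lm(log(siop) ~ log(chla))
  cf <- stats::coef(m)
  d <- unname(cf[2]); cc <- exp(unname(cf[1]))
  pred <- cc * chla^d
  ly <- log(siop)
  ssy <- sum((ly - mean(ly))^2)
  r2 <- if (ssy > 0) 1 - sum(stats::residuals(m)^2) / ssy else 1
  structure(list(coefficients = c(c = cc, d = d), wavelength = wavelength,
                 season = season, r2 = r2,
                 rmse = sqrt(mean((siop - pred)^2)), n = length(chla)),
            class = "packaging_fit")
}

#' @export
print.packaging_fit <- function(x, ...) {
  cat(sprintf("Pigment packaging power model (%s%s)\n", x$season,
              if (is.finite(x$wavelength)) sprintf(", %g nm", x$wavelength)
              else ""))
  cat(sprintf("  a* = %.4g Chla^%.4g   (r2 = %.3f, rmse = %.3g m^2 mg^-1, n = %d)\n",
              x$coefficients["c"], x$coefficients["d"], x$r2, x$rmse, x$n))
  invisible(x)
}

#' @export
coef.packaging_fit <- function(object, ...) object$coefficients

#' @export
predict.packaging_fit <- function(object, newdata, ...) {
  cf <- object$coefficients
  unname(cf["c"] * newdata^cf["d"])
}

# ---- seasonal SIOP library -------------------------------------------------

# Chla-specific phytoplankton absorption shape: pigment bands as Gaussian
# components with seasonal anchors at 440 and 675 nm. Anchors: spring
# 0.020 / 0.014 m^2 mg^-1, summer 0.040 / 0.021 m^2 mg^-1 (field means).
.aphi_shape <- function(wl, a440, a675, phycoerythrin = 0) {
  base <- exp(-((wl - 440) / 38)^2) +
    0.40 * exp(-((wl - 490) / 30)^2) +
    0.10 * exp(-((wl - 620) / 25)^2) +
    phycoerythrin * exp(-((wl - 550) / 22)^2)
  s <- base / base[which.min(abs(wl - 440))] * a440
  red0 <- s[which.min(abs(wl - 675))]
  red <- (a675 - red0) * exp(-((wl - 675) / 11)^2)
  pmax(s + red, 0)
}

#' Seasonal SIOP library
#'
#' Bundled seasonal mean specific IOP spectra on a 1-nm 350-800 nm grid:
#' Chla-specific phytoplankton absorption (anchored at the seasonal field
#' means at 440 and 675 nm), TSM-specific non-algal particle absorption
#' (exponential with the seasonal median slope), Chla-specific particulate
#' scattering, and the particulate backscattering ratio. Variability
#' (coefficient of variation per component) is carried as metadata for the
#' synthetic-data generator.
#'
#' @param season `"spring"` or `"summer"`.
#' @return list with `spectrum` elements `aphi_chla`, `anap_tsm`, `bp_chla`,
#'   and `beta_p`, plus a numeric `cv` vector.
#' @export
siop_library <- function(season = c("spring", "summer")) {
  season <- match.arg(season)
  wl <- 350:800
  if (season == "spring") {
    aphi <- .aphi_shape(wl, 0.020, 0.014)
    s_nap <- 0.0097
    bp <- 0.10 * rep(1, length(wl)) *
      (1 - 0.06 * .aphi_shape(wl, 1, 0.7))   # pigment dips, +-10% scale
    beta_mean <- 0.0075; beta_slope <- -4e-6
    cv <- c(aphi_chla = 0.26, anap_tsm = 0.57, bp_chla = 0.56,
            beta_p = 0.25)
  } else {
    aphi <- .aphi_shape(wl, 0.040, 0.021, phycoerythrin = 0.06)
    s_nap <- 0.0103
    bp <- 0.25 * exp(-0.0011 * (wl - 550)) *
      (1 - 0.03 * .aphi_shape(wl, 1, 0.7))
    beta_mean <- 0.0045; beta_slope <- -2e-6
    cv <- c(aphi_chla = 0.28, anap_tsm = 0.80, bp_chla = 0.56,
            beta_p = 0.25)
  }
  anap <- 0.05 * exp(-s_nap * (wl - 440))
  beta <- pmax(beta_mean + beta_slope * (wl - 532), 1e-4)
  list(
    season = season,
    aphi_chla = optical_spectrum(wl, aphi, "SIOP"),
    anap_tsm = optical_spectrum(wl, anap, "SIOP"),
    bp_chla = optical_spectrum(wl, bp, "SIOP"),
    beta_p = optical_spectrum(wl, beta, "SIOP"),
    nap_slope = s_nap,
    cv = cv)
}
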