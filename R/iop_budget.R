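#' OLCI band centres used for budget and reflectance reporting
#'
#' The 11 visible/NIR band centres of the Sentinel-3 Ocean and Land Colour
#' Instrument used throughout: 400, 412.5, 442.5, 490, 510, 560, 620, 665,
#' 673.75, 681.25, 708.75 nm. Band extraction is nearest-1-nm sampling; no
#' spectral response convolution.
#' @export
olci_bands <- function() {
  c(400, 412.5, 442.5, 490, 510, 560, 620, 665, 673.75, 681.25, 708.75)
}

#' Compose component IOPs for a station
#'
#' Assembles the component-resolved inherent optical properties of a station
#' from its biogeochemistry, the seasonal SIOP library and a CDOM model:
#' a_CDOM from the exponential model; a_phi = Chla * a*phi,chla(lambda)
#' (optionally packaging-adjusted, a*phi,chla = c(lambda) Chla^d);
#' a_nap = TSM * a*nap,TSM(lambda); b_p = Chla * b*p,chla(lambda);
#' b_bp = beta_p(lambda) * b_p(lambda). Water terms come from the bundled
#' pure-water table.
#'
#' @param biogeo a [station_biogeo()] with positive `chla` and `tsm`.
#' @param siop list from [siop_library()] (or per-station perturbed copy).
#' @param cdom a [cdom_model()].
#' @param wavelength evaluation grid, nm (default 350-800, 1 nm).
#' @param packaging optional [fit_packaging()] result applied to the
#'   phytoplankton SIOP amplitude (scales the library shape by
#'   `predict(packaging, chla) / a*phi(440)`).
#' @return object of class `"iop_bundle"`: wavelength grid plus vectors
#'   `a_w`, `a_cdom`, `a_phi`, `a_nap`, `b_w`, `b_p`, `b_bp`.
#' @export
compose_iops <- function(biogeo, siop, cdom, wavelength = 350:800,
                         packaging = NULL) {
  stopifnot(inherits(biogeo, "station_biogeo"), inherits(cdom, "cdom_model"))
  for (comp in c("aphi_chla", "anap_tsm", "bp_chla", "beta_p"))
    if (is.null(siop[[comp]]))
      stop(sprintf("SIOP library is missing component %s", comp))
  if (!is.finite(biogeo$chla) || biogeo$chla <= 0)
    stop("chla must be positive")
  if (!is.finite(biogeo$tsm) || biogeo$tsm < 0)
    stop("tsm must be non-negative")
  w <- water_iops(wavelength)
  aphi_star <- spectrum_at(siop$aphi_chla, wavelength)
  if (!is.null(packaging)) {
    ref440 <- spectrum_at(siop$aphi_chla, 440)
    aphi_star <- aphi_star * predict(packaging, biogeo$chla) / ref440
  }
  a_cdom <- cdom_spectrum(cdom, wavelength)$value
  b_p <- biogeo$chla * spectrum_at(siop$bp_chla, wavelength)
  structure(list(
    wavelength = wavelength,
    a_w = w$a_w,
    a_cdom = a_cdom,
    a_phi = biogeo$chla * aphi_star,
    a_nap = biogeo$tsm * spectrum_at(siop$anap_tsm, wavelength),
    b_w = w$b_w,
    b_p = b_p,
    b_bp = spectrum_at(siop$beta_p, wavelength) * b_p,
    b_bw = w$b_bw,
    season = biogeo$season), class = "iop_bundle")
}

#' @export
print.iop_bundle <- function(x, ...) {
  at <- function(v, wl) v[which.min(abs(x$wavelength - wl))]
  cat(sprintf("<iop_bundle> %d wavelengths %g-%g nm (%s)\n",
              length(x$wavelength), min(x$wavelength), max(x$wavelength),
              x$season))
  cat(sprintf("  at 440 nm: a_cdom %.3f, a_phi %.3f, a_nap %.3f, b_p %.3f, b_bp %.4f m^-1\n",
              at(x$a_cdom, 440), at(x$a_phi, 440), at(x$a_nap, 440),
              at(x$b_p, 440), at(x$b_bp, 440)))
  invisible(x)
}

#' Total absorption / backscattering of a bundle
#' @param bundle an `iop_bundle`.
#' @param include_water include the pure-water terms (default TRUE).
#' @return list with `a` and `b_b` vectors on the bundle grid.
#' @export
total_iops <- function(bundle, include_water = TRUE) {
  stopifnot(inherits(bundle, "iop_bundle"))
  a <- bundle$a_cdom + bundle$a_phi + bundle$a_nap
  bb <- bundle$b_bp
  if (include_water) {
    a <- a + bundle$a_w
    bb <- bb + bundle$b_bw
  }
  list(a = a, b_b = bb)
}

#' Per-band absorption budget
#'
#' Fractions of non-water absorption contributed by CDOM, phytoplankton
#' pigment and non-algal particles at a set of band centres (nearest-1-nm
#' sampling). Bands where total non-water absorption is below 0.01 m^-1 are
#' flagged (too dark to partition reliably).
#'
#' @param bundle an `iop_bundle` covering all bands.
#' @param bands band centres, nm (default [olci_bands()]).
#' @param include_water if TRUE, fractions are of total absorption including
#'   water (and no longer sum to 1 across the three constituents).
#' @return object of class `"absorption_budget"`: a data.frame with columns
#'   `band_nm`, `f_cdom`, `f_phi`, `f_nap`, `total_a`, `flagged`.
#' @export
absorption_budget <- function(bundle, bands = olci_bands(),
                              include_water = FALSE) {
  stopifnot(inherits(bundle, "iop_bundle"))
  if (any(bands < min(bundle$wavelength) | bands > max(bundle$wavelength)))
    stop("band outside bundle wavelength range")
  idx <- vapply(bands, function(b) which.min(abs(bundle$wavelength - b)),
                integer(1))
  ac <- bundle$a_cdom[idx]; ap <- bundle$a_phi[idx]; an <- bundle$a_nap[idx]
  denom <- ac + ap + an
  if (include_water) denom <- denom + bundle$a_w[idx]
  out <- data.frame(band_nm = bands,
                    f_cdom = ac / denom, f_phi = ap / denom,
                    f_nap = an / denom, total_a = denom,
                    flagged = (ac + ap + an) < 0.01)
  class(out) <- c("absorption_budget", "data.frame")
  out
}

#' @export
print.absorption_budget <- function(x, ...) {
  cat("Absorption budget (fractions of non-water absorption)\n")
  print.data.frame(cbind(x[1], round(x[2:5], 4), x[6]), row.names = FALSE)
  invisible(x)
}
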