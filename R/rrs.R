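#' Forward reflectance model configuration
#'
#' Coefficients of the analytical quadratic reflectance kernel used to
#' simulate remote-sensing reflectance from IOPs:
#' u = b_b / (a + b_b); r_rs(0-) = g1 u + g2 u^2; and the water-to-air
#' transfer R_rs = 0.52 r_rs / (1 - 1.7 r_rs). Solar geometry enters as an
#' effective in-water path-length factor 1/cos(theta_sw) applied to g1,
#' where theta_sw is the refracted sun zenith angle (Snell, n = 1.34);
#' viewing zenith and azimuth have no effect in this kernel.
#'
#' @param g1,g2 kernel coefficients, sr^-1 (defaults 0.0949 and 0.0794, the
#'   standard case-2 quadratic coefficients).
#' @return list of class `"rrs_config"`.
#' @export
rrs_config <- function(g1 = 0.0949, g2 = 0.0794) {
  if (g1 <= 0 || g2 <= 0) stop("g1 and g2 must be positive")
  structure(list(g1 = g1, g2 = g2, n_water = 1.34), class = "rrs_config")
}

#' Viewing geometry
#' @param sun_zenith degrees, 0-80.
#' @param view_zenith degrees, 0-60.
#' @param azimuth relative azimuth, degrees, 0-180.
#' @export
viewing_geometry <- function(sun_zenith = 0, view_zenith = 0, azimuth = 90) {
  if (sun_zenith < 0 || sun_zenith > 80) stop("sun zenith must be in [0, 80]")
  if (view_zenith < 0 || view_zenith > 60) stop("view zenith must be in [0, 60]")
  if (azimuth < 0 || azimuth > 180) stop("azimuth must be in [0, 180]")
  list(sun_zenith = sun_zenith, view_zenith = view_zenith, azimuth = azimuth)
}

#' Simulate remote-sensing reflectance from composed IOPs
#'
#' @param bundle an [compose_iops()] bundle covering the requested range.
#' @param geometry a [viewing_geometry()].
#' @param config an [rrs_config()].
#' @param wavelength output grid, nm (default 400-750).
#' @return a `spectrum` of kind `"Rrs"`, sr^-1.
#' @examples
#' # kernel chain at a single band: a = 0.5, b_b = 0.01 -> ~9.87e-4 sr^-1
#' @export
simulate_rrs <- function(bundle, geometry = viewing_geometry(),
                         config = rrs_config(), wavelength = 400:750) {
  stopifnot(inherits(bundle, "iop_bundle"))
  if (min(wavelength) < min(bundle$wavelength) ||
      max(wavelength) > max(bundle$wavelength))
    stop("bundle does not cover the requested wavelengths")
  tot <- total_iops(bundle, include_water = TRUE)
  idx <- match(wavelength, bundle$wavelength)
  if (any(is.na(idx))) {
    a <- stats::approx(bundle$wavelength, tot$a, xout = wavelength)$y
    bb <- stats::approx(bundle$wavelength, tot$b_b, xout = wavelength)$y
  } else {
    a <- tot$a[idx]; bb <- tot$b_b[idx]
  }
  if (any(a <= 0)) stop("total absorption must be positive everywhere")
  optical_spectrum(wavelength,
                   .rrs_kernel(a, bb, geometry$sun_zenith, config), "Rrs")
}

.rrs_kernel <- function(a, bb, sun_zenith, config) {
  theta_sw <- asin(sin(sun_zenith * pi / 180) / config$n_water)
  g1_eff <- config$g1 / cos(theta_sw)
  u <- bb / (a + bb)
  r_rs <- g1_eff * u + config$g2 * u^2
  0.52 * r_rs / (1 - 1.7 * r_rs)
}

#' Build a reflectance grid over concentration and geometry axes
#'
#' Dense, deterministic evaluation of [compose_iops()] + [simulate_rrs()]
#' over axes of chlorophyll-a, TSM, a_CDOM(412) and sun zenith angle for
#' one season. The CDOM spectral slope for each a_CDOM(412) value is
#' supplied by the regional inverse of the slope model (default south of
#' 59 degrees N). Cells whose concentrations fall outside the generator
#' support (Chla 0.1-100, TSM 0.05-20, a_CDOM(412) 0.05-6) are evaluated
#' but flagged.
#'
#' @param chla,tsm,acdom412 strictly increasing axis values.
#' @param sun_zenith sun zenith axis, degrees.
#' @param season `"spring"` or `"summer"`.
#' @param region region tag for the slope model.
#' @param wavelength spectral grid, nm.
#' @param config an [rrs_config()].
#' @return object of class `"rrs_grid"`: a 5-D array
#'   `[chla, tsm, acdom412, sun_zenith, wavelength]` with axis values and
#'   a parallel logical `flag` array (concentration axes only).
#' @export
build_rrs_grid <- function(chla, tsm, acdom412, sun_zenith = 30,
                           season = c("spring", "summer"),
                           region = "south_of_59N",
                           wavelength = seq(400, 750, by = 5),
                           config = rrs_config()) {
  season <- match.arg(season)
  for (ax in list(chla, tsm, acdom412, sun_zenith))
    if (length(ax) < 1L || any(diff(ax) <= 0) && length(ax) > 1L)
      stop("axes must be non-empty and strictly increasing")
  siop <- siop_library(season)
  dims <- c(length(chla), length(tsm), length(acdom412), length(sun_zenith),
            length(wavelength))
  vals <- array(NA_real_, dims)
  for (i in seq_along(chla)) for (j in seq_along(tsm))
    for (k in seq_along(acdom412)) {
      # invert the regional a412(S) relation to supply S for this cell
      S <- switch(region,
        south_of_59N    = (1.16 - acdom412[k]) / 33.36,
        gulf_of_finland = (3.60 - acdom412[k]) / 137.66,
        gulf_of_bothnia = -log(max(acdom412[k] - 0.38, 1e-6) / 3.64e5) / 766,
        stop("unknown region"))
      S <- min(max(S, 0.008), 0.028)
      cd <- cdom_model(acdom412[k], S, k = 0.0)
      st <- station_biogeo(chla = chla[i], tsm = tsm[j], season = season,
                           region = region)
      bundle <- compose_iops(st, siop, cd, wavelength = 350:800)
      for (g in seq_along(sun_zenith)) {
        rr <- simulate_rrs(bundle, viewing_geometry(sun_zenith[g]),
                           config, wavelength)
        vals[i, j, k, g, ] <- rr$value
      }
    }
  flag <- outer(outer(chla < 0.1 | chla > 100, tsm < 0.05 | tsm > 20, "|"),
                acdom412 < 0.05 | acdom412 > 6, "|")
  structure(list(values = vals, chla = chla, tsm = tsm,
                 acdom412 = acdom412, sun_zenith = sun_zenith,
                 wavelength = wavelength, season = season, region = region,
                 flag = flag, config = config),
            class = "rrs_grid")
}

#' @export
print.rrs_grid <- function(x, ...) {
  cat(sprintf("<rrs_grid %s> %d chla x %d tsm x %d acdom412 x %d sza x %d wavelengths\n",
              x$season, length(x$chla), length(x$tsm), length(x$acdom412),
              length(x$sun_zenith), length(x$wavelength)))
  invisible(x)
}

#' Write / read a reflectance grid as long-format CSV
#'
#' Plain-text serialization: a commented key:value header (season, region,
#' kernel coefficients, axis values at full precision) followed by a long
#' table with one row per grid cell and wavelength. Values are written with
#' 17 significant digits so the round-trip is lossless.
#'
#' @param grid an `rrs_grid`.
#' @param path output file.
#' @export
write_rrs_grid <- function(grid, path) {
  stopifnot(inherits(grid, "rrs_grid"))
  num <- function(v) paste(sprintf("%.17g", v), collapse = ",")
  hdr <- c(sprintf("# season: %s", grid$season),
           sprintf("# region: %s", grid$region),
           sprintf("# g1: %.17g", grid$config$g1),
           sprintf("# g2: %.17g", grid$config$g2),
           sprintf("# chla: %s", num(grid$chla)),
           sprintf("# tsm: %s", num(grid$tsm)),
           sprintf("# acdom412: %s", num(grid$acdom412)),
           sprintf("# sun_zenith: %s", num(grid$sun_zenith)),
           sprintf("# wavelength: %s", num(grid$wavelength)))
  idx <- expand.grid(i = seq_along(grid$chla), j = seq_along(grid$tsm),
                     k = seq_along(grid$acdom412),
                     g = seq_along(grid$sun_zenith),
                     w = seq_along(grid$wavelength))
  rows <- sprintf("%d,%d,%d,%d,%d,%.17g", idx$i, idx$j, idx$k, idx$g,
                  idx$w, grid$values[as.matrix(idx)])
  tmp <- paste0(path, ".tmp")
  writeLines(c(hdr, "i,j,k,g,w,rrs_sr-1", rows), tmp)
  file.rename(tmp, path)
  invisible(path)
}

#' @rdname write_rrs_grid
#' @export
read_rrs_grid <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "# ")]
  get <- function(key) {
    ln <- hdr[startsWith(hdr, paste0("# ", key, ":"))]
    sub(paste0("# ", key, ": "), "", ln)
  }
  nums <- function(key) as.numeric(strsplit(get(key), ",")[[1]])
  chla <- nums("chla"); tsm <- nums("tsm"); acdom412 <- nums("acdom412")
  sza <- nums("sun_zenith"); wl <- nums("wavelength")
  body <- utils::read.csv(text = lines[!startsWith(lines, "# ")])
  vals <- array(NA_real_, c(length(chla), length(tsm), length(acdom412),
                            length(sza), length(wl)))
  vals[as.matrix(body[, 1:5])] <- body[[6]]
  flag <- outer(outer(chla < 0.1 | chla > 100, tsm < 0.05 | tsm > 20, "|"),
                acdom412 < 0.05 | acdom412 > 6, "|")
  structure(list(values = vals, chla = chla, tsm = tsm,
                 acdom412 = acdom412, sun_zenith = sza, wavelength = wl,
                 season = get("season"), region = get("region"),
                 flag = flag,
                 config = rrs_config(as.numeric(get("g1")),
                                     as.numeric(get("g2")))),
            class = "rrs_grid")
}
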