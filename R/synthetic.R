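#' Configuration of the seasonal synthetic-data generator
#'
#' Bundles the distributional assumptions used to emulate spring and summer
#' Baltic field campaigns: lognormal constituent concentrations anchored at
#' the seasonal medians (Chla 14.1 mg m^-3 in spring, 4.3 in summer), a
#' bimodal a_CDOM(412) mixture with modes at 0.53 and 0.85 m^-1, the
#' regional slope coupling S(a412), seasonal POC:Chla ratios (summer about
#' twice spring), SIOP variability as per-component coefficients of
#' variation, the seasonal reciprocal Secchi coefficients (spring 2.44,
#' summer 1.98), and the exponential decay of irradiance with depth driven
#' by a K_d proxy kappa (a + b_b) / cos(theta_sw).
#'
#' @param season `"spring"` or `"summer"`.
#' @param region region tag (see [predict_acdom412()]).
#' @param n_stations number of stations to draw.
#' @param ... overrides for any default listed below.
#' @return list of class `"generator_config"`.
#' @export
generator_config <- function(season = c("spring", "summer"),
                             region = "south_of_59N",
                             n_stations = 100, ...) {
  season <- match.arg(season)
  region <- match.arg(region, .region_tags)
  spring <- season == "spring"
  cfg <- list(
    season = season, region = region, n_stations = n_stations,
    # constituent concentrations (lognormal; median anchored)
    chla_median = if (spring) 14.1 else 4.3,
    chla_sdlog = if (spring) 0.55 else 0.65,
    poc_ratio = if (spring) 3.3 else 6.6,    # uM POC per mg m^-3 Chla
    poc_sdlog = 0.30,
    tsm_median = if (spring) 2.0 else 1.2,
    tsm_sdlog = 0.40,
    tsm_coupling = if (spring) c(0, 0) else c(0.5, 0.18),  # intercept, slope
    ism_beta = c(2, 6),                       # ISM/TSM fraction ~ Beta
    pon_per_poc = 0.15,
    pon_pop_ratio = if (spring) 16 else 28,
    doc_noise_sd = 120,
    salinity_mean = c(south_of_59N = 7.0, gulf_of_finland = 5.5,
                      gulf_of_bothnia = 3.2)[[region]],
    salinity_sd = 0.8,
    # CDOM mixture and slope coupling
    acdom_modes = c(0.53, 0.85), acdom_weights = c(0.6, 0.4),
    acdom_sdlog = 0.12,
    s_noise_sd = 0.0015, s_support = c(0.008, 0.028),
    k_mean = 0.030, k_sd = 0.005,
    # SIOP multiplicative variability (median-1 lognormal factors)
    siop_cv = siop_library(season)$cv,
    # AOP generation
    secchi_f = if (spring) 2.44 else 1.98,
    secchi_f_combined = 2.14,
    secchi_noise = 0.10,
    kappa = 1.04, sun_zenith = 45,
    ed_noise = 0.02,
    profile_depths = seq(0.5, 15, by = 0.5),
    sample_depths = c(0.5, 3, 5, 7.5, 10, 12.5, 15),
    peak_probs = if (spring) c(lt3m = 0.39, `3to10m` = 0.17, ge10m = 0.00,
                               no_peak = 0.44)
                 else c(lt3m = 0.35, `3to10m` = 0.33, ge10m = 0.16,
                        no_peak = 0.16),
    wavelength = 350:800)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop("unknown generator settings: ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  structure(cfg, class = "generator_config")
}

# lognormal factor with median 1 and coefficient of variation cv
.rlnorm_cv <- function(n, cv) {
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = 0, sdlog = sdlog)
}

#' Generate a seasonal ensemble of stations
#'
#' Draws `n_stations` stations with the configured seasonal statistical
#' structure: lognormal Chla around the seasonal median; POC coupled to
#' Chla through the seasonal POC:Chla ratio; TSM weakly coupled to Chla in
#' summer only; an ISM fraction below 0.5 (organic-dominated particles);
#' a_CDOM(412) from the two-mode lognormal mixture; the spectral slope S
#' from the regional inverse model plus noise; and per-station
#' multiplicative SIOP factors (median 1, configured CV). Fully
#' reproducible for a given seed.
#'
#' @param config a [generator_config()].
#' @param seed integer seed (optional; the RNG state is used as-is when
#'   missing).
#' @return data.frame of class `"station_set"` with one row per station and
#'   the config as attribute `"config"`.
#' @export
generate_stations <- function(config, seed = NULL) {
  stopifnot(inherits(config, "generator_config"))
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_stations
  chla <- stats::rlnorm(n, log(config$chla_median), config$chla_sdlog)
  poc <- config$poc_ratio * chla *
    stats::rlnorm(n, -config$poc_sdlog^2 / 2, config$poc_sdlog)
  tsm <- if (config$tsm_coupling[2] > 0) {
    (config$tsm_coupling[1] + config$tsm_coupling[2] * chla) *
      stats::rlnorm(n, 0, 0.25)
  } else {
    stats::rlnorm(n, log(config$tsm_median), config$tsm_sdlog)
  }
  ism <- tsm * stats::rbeta(n, config$ism_beta[1], config$ism_beta[2])
  pon <- config$pon_per_poc * poc * stats::rlnorm(n, 0, 0.1)
  pop <- pon / config$pon_pop_ratio * stats::rlnorm(n, 0, 0.15)
  comp <- sample.int(2, n, replace = TRUE, prob = config$acdom_weights)
  mode <- config$acdom_modes[comp]
  a412 <- stats::rlnorm(n, log(mode) + config$acdom_sdlog^2,
                        config$acdom_sdlog)
  S <- switch(config$region,
    south_of_59N    = (1.16 - a412) / 33.36,
    gulf_of_finland = (3.60 - a412) / 137.66,
    gulf_of_bothnia = -log(pmax(a412 - 0.38, 1e-6) / 3.64e5) / 766)
  S <- pmin(pmax(S + stats::rnorm(n, 0, config$s_noise_sd),
                 config$s_support[1]), config$s_support[2])
  k <- pmax(stats::rnorm(n, config$k_mean, config$k_sd), 0)
  doc_region <- if (config$region == "gulf_of_bothnia") "gulf_of_bothnia"
                else "other"
  doc <- pmax(predict_doc(doc_region, a412) +
                stats::rnorm(n, 0, config$doc_noise_sd), 100)
  sal <- stats::rnorm(n, config$salinity_mean, config$salinity_sd)
  out <- data.frame(
    station_id = sprintf("%s_%04d", substr(config$season, 1, 2), seq_len(n)),
    season = config$season, region = config$region,
    chla = chla, tsm = tsm, ism = ism, poc = poc, pon = pon, pop = pop,
    doc = doc, salinity = sal, a412 = a412, S = S, k = k,
    f_aphi = .rlnorm_cv(n, config$siop_cv[["aphi_chla"]]),
    f_anap = .rlnorm_cv(n, config$siop_cv[["anap_tsm"]]),
    f_bp = .rlnorm_cv(n, config$siop_cv[["bp_chla"]]),
    f_beta = .rlnorm_cv(n, config$siop_cv[["beta_p"]]))
  attr(out, "config") <- config
  class(out) <- c("station_set", "data.frame")
  out
}

#' Composed IOPs of one generated station
#'
#' Reconstructs a station's component IOP bundle from its generated row:
#' the seasonal mean SIOP spectra scaled by the station's multiplicative
#' factors, the station's CDOM model, and the bundled water table.
#'
#' @param set a `station_set`.
#' @param i station index (row).
#' @param packaging optional packaging model passed to [compose_iops()].
#' @return an `iop_bundle`.
#' @export
station_iops <- function(set, i, packaging = NULL) {
  stopifnot(inherits(set, "station_set"))
  config <- attr(set, "config")
  row <- set[i, ]
  siop <- siop_library(config$season)
  scale_spec <- function(sp, f) optical_spectrum(sp$wavelength,
                                                 sp$value * f, sp$kind)
  siop$aphi_chla <- scale_spec(siop$aphi_chla, row$f_aphi)
  siop$anap_tsm <- scale_spec(siop$anap_tsm, row$f_anap)
  siop$bp_chla <- scale_spec(siop$bp_chla, row$f_bp)
  siop$beta_p <- scale_spec(siop$beta_p, row$f_beta)
  st <- station_biogeo(chla = row$chla, tsm = row$tsm, ism = row$ism,
                       poc = row$poc, pon = row$pon, pop = row$pop,
                       doc = row$doc, salinity = row$salinity,
                       season = config$season, region = config$region)
  cd <- cdom_model(row$a412, row$S, row$k)
  compose_iops(st, siop, cd, wavelength = config$wavelength,
               packaging = packaging)
}

#' Generate irradiance and biomass profiles for a station
#'
#' Derives K_d(lambda) from the station's composed IOPs through the linear
#' proxy K_d = kappa (a + b_b) / cos(theta_sw) (generator glue, not a
#' measurement model), decays a smooth surface irradiance spectrum
#' exponentially with depth with multiplicative lognormal noise, builds the
#' upwelling stream from an irradiance reflectance approximation
#' R = 0.33 b_b / a with a slightly faster decay, draws the Secchi depth
#' from the seasonal reciprocal coupling with noise (rounded to the 0.5 m
#' precision of shipboard practice), and draws vertical Chla/POC profiles
#' whose peak-depth categories follow the configured frequencies.
#'
#' @param set a `station_set`.
#' @param i station index.
#' @param seed optional integer seed for this station's substream.
#' @return list with `profile` (an [irradiance_profile()]), `kd_true`
#'   (noiseless spectral K_d), `kd_par_true`, `z_sd`, `chla_profile`,
#'   `poc_profile`, `sample_depths`, `peak_category`.
#' @export
generate_profiles <- function(set, i, seed = NULL) {
  stopifnot(inherits(set, "station_set"))
  if (!is.null(seed)) set.seed(seed)
  config <- attr(set, "config")
  row <- set[i, ]
  bundle <- station_iops(set, i)
  tot <- total_iops(bundle, include_water = TRUE)
  theta_sw <- asin(sin(config$sun_zenith * pi / 180) / 1.34)
  kd_true <- config$kappa * (tot$a + tot$b_b) / cos(theta_sw)
  wl <- bundle$wavelength
  ed0 <- 1400 * exp(-((wl - 500) / 300)^2)
  z <- config$profile_depths
  decay <- exp(-outer(z, kd_true))
  noise <- matrix(stats::rlnorm(length(z) * length(wl), 0, config$ed_noise),
                  nrow = length(z))
  Ed <- sweep(decay, 2, ed0, `*`) * noise
  R <- 0.33 * tot$b_b / tot$a
  noise_u <- matrix(stats::rlnorm(length(z) * length(wl), 0,
                                  config$ed_noise), nrow = length(z))
  Eu <- sweep(sweep(decay, 2, ed0 * R, `*`) *
                exp(-0.05 * outer(z, kd_true)), 1, rep(1, length(z)), `*`) *
    noise_u
  profile <- irradiance_profile(z, wl, Ed, Eu)
  # noiseless PAR attenuation for the Secchi coupling
  pr0 <- irradiance_profile(z, wl, sweep(decay, 2, ed0, `*`))
  kdp <- kd_par(pr0)$Kd_par
  z_sd <- config$secchi_f / kdp *
    stats::rlnorm(1, -config$secchi_noise^2 / 2, config$secchi_noise)
  z_sd <- max(round(z_sd * 2) / 2, 0.5)
  # vertical biomass structure
  zd <- config$sample_depths
  category <- sample(names(config$peak_probs), 1,
                     prob = config$peak_probs)
  base <- row$chla
  if (category == "no_peak") {
    prof <- base * (1 + stats::rnorm(length(zd), 0, 0.03))
  } else {
    z0 <- switch(category,
                 lt3m = stats::runif(1, 0.5, 1.6),
                 `3to10m` = stats::runif(1, 3.2, 8.5),
                 ge10m = stats::runif(1, 10.5, 14))
    prof <- base * (1 + 0.9 * exp(-((zd - z0) / 1.8)^2)) *
      (1 + stats::rnorm(length(zd), 0, 0.02))
  }
  prof <- pmax(prof, 0.01)
  list(profile = profile, kd_true = kd_true, kd_par_true = kdp,
       z_sd = z_sd, chla_profile = prof,
       poc_profile = prof * row$poc / row$chla,
       sample_depths = zd, peak_category = category)
}

#' Simulate (Secchi depth, PAR attenuation) pairs
#'
#' The Monte-Carlo design used to study recovery of the reciprocal Secchi
#' coupling: Secchi depths uniform over a range, rounded to the 0.5-m
#' shipboard precision, and K_d(PAR) = f / Z_SD with mean-one
#' multiplicative lognormal noise.
#'
#' @param n number of pairs.
#' @param f coupling coefficient (e.g. 2.44 spring, 1.98 summer, 2.14
#'   combined).
#' @param noise_cv lognormal noise level (default 0.10).
#' @param zsd_range Secchi depth range, m (default 2-12).
#' @param seed optional seed.
#' @return data.frame with columns `z_sd` and `kd_par`.
#' @export
simulate_secchi_pairs <- function(n, f, noise_cv = 0.10,
                                  zsd_range = c(2, 12), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  z_sd <- round(stats::runif(n, zsd_range[1], zsd_range[2]) * 2) / 2
  sdlog <- sqrt(log(1 + noise_cv^2))
  kd <- f / z_sd * stats::rlnorm(n, -sdlog^2 / 2, sdlog)
  data.frame(z_sd = z_sd, kd_par = kd)
}

#' Synthesize fixed-angle VSF channels consistent with a backscattering
#' spectrum
#'
#' Builds per-angle volume scattering function values beta(theta) at the
#' VSF-sensor centroids (100, 125, 150 degrees) plus the 117-degree BB
#' centroid, using the backward phase-function shape
#' beta(theta) = b_bp c (1 + gamma cos^2 theta) with c chosen so the
#' backward-hemisphere integral returns exactly b_bp. The default gamma
#' makes the 117-degree conversion factor chi exactly 1.1, so both the
#' polynomial and the fixed-angle inversions of [vsf_to_bb()] round-trip.
#'
#' @param b_bp a `spectrum` of particulate backscattering (m^-1).
#' @param angles measurement angles, degrees (default c(100, 125, 150, 117)).
#' @param gamma backward-shape parameter (default tuned to chi(117) = 1.1).
#' @return data.frame with columns `wavelength_nm`, `angle_deg`, `beta`.
#' @export
generate_vsf <- function(b_bp, angles = c(100, 117, 125, 150),
                         gamma = 0.1 / (1 / 3 - 1.1 * cos(117 * pi / 180)^2)) {
  stopifnot(inherits(b_bp, "spectrum"))
  cnorm <- 1 / (2 * pi * (1 + gamma / 3))
  grid <- expand.grid(wavelength_nm = b_bp$wavelength, angle_deg = angles)
  bb <- b_bp$value[match(grid$wavelength_nm, b_bp$wavelength)]
  mu2 <- cos(grid$angle_deg * pi / 180)^2
  grid$beta <- bb * cnorm * (1 + gamma * mu2)
  grid[order(grid$wavelength_nm, grid$angle_deg), ]
}
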