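test_that("SIOP normalization divides by the right analyte and inverts", {
  st <- station_biogeo(chla = 14.1, tsm = 2, poc = 47, season = "spring")
  aphi <- optical_spectrum(c(440, 675), c(0.282, 0.197), "a_phi")
  s <- to_siop(aphi, st, "chla")
  expect_equal(s$value[1], 0.020, tolerance = 1e-12)
  expect_identical(attr(s, "normalizer"), "chla")
  # unit normalizer leaves values unchanged
  st1 <- station_biogeo(chla = 1, season = "spring")
  expect_equal(to_siop(aphi, st1, "chla")$value, aphi$value)
  # exact invertibility
  back <- s$value * st$chla
  expect_equal(back, aphi$value, tolerance = 1e-12)
  # POC in micromolar is mmol m^-3: units come out in m^2 mmol^-1
  sp <- to_siop(aphi, st, "poc")
  expect_equal(sp$value[1], 0.282 / 47, tolerance = 1e-12)
  expect_error(to_siop(aphi, station_biogeo(chla = 0, season = "spring"),
                       "chla"), "chla")
})

test_that("packaging power model recovers exponents and rejects bad input", {
  ch <- exp(seq(log(0.5), log(30), length.out = 60))
  f <- fit_packaging(ch, 0.05 * ch^-0.3)
  expect_lt(abs(coef(f)["d"] + 0.3), 1e-9)
  expect_lt(abs(coef(f)["c"] - 0.05) / 0.05, 1e-9)
  # flat response: exponent ~ 0, coefficient ~ level
  flat <- fit_packaging(ch, rep(0.02, length(ch)))
  expect_lt(abs(coef(flat)["d"]), 1e-12)
  expect_equal(unname(coef(flat)["c"]), 0.02, tolerance = 1e-9)
  expect_error(fit_packaging(ch, c(-0.01, rep(0.02, 59))), "positive")
  # unbiased under lognormal scatter; d stays <= 0 in the median
  set.seed(404)
  d_hat <- replicate(60, {
    chla <- exp(runif(300, log(0.3), log(40)))
    siop <- 0.06 * chla^-0.25 * rlnorm(300, 0, 0.2)
    unname(coef(fit_packaging(chla, siop))["d"])
  })
  se <- sd(d_hat) / sqrt(length(d_hat))
  expect_lt(abs(mean(d_hat) + 0.25), 2 * se)
  expect_lte(median(d_hat), 0)
})

test_that("NAP spectral slope fits use the exponential-plus-offset model", {
  for (S in c(0.0097, 0.0103)) {
    sp <- make_cdom_spectrum(a_ref = 0.08, S = S, k = 0.005)
    fit <- fit_nap_slope(sp)
    expect_lt(abs(fit$S - S), 1e-6)
  }
  # residual pigment bump inflates rmse relative to the clean fit
  wl <- 400:700
  clean <- 0.08 * exp(-0.01 * (wl - 412)) + 0.005
  bump <- clean + 0.01 * exp(-((wl - 440) / 15)^2)
  rmse_clean <- fit_nap_slope(optical_spectrum(wl, clean, "a_nap"))$rmse
  rmse_bump <- fit_nap_slope(optical_spectrum(wl, bump, "a_nap"))$rmse
  expect_gt(rmse_bump, 10 * rmse_clean + 1e-6)
})

test_that("VSF conversion matches closed forms and quadrature", {
  # fixed angle: b_b = 2 pi chi beta(117)
  v <- data.frame(wavelength_nm = 532, angle_deg = 117, beta = 1e-4)
  expect_equal(vsf_to_bb(v, "fixed_angle")$value, 2 * pi * 1.1 * 1e-4,
               tolerance = 1e-12)
  # isotropic phase function: analytic 2 pi c
  iso <- data.frame(wavelength_nm = 532, angle_deg = c(100, 125, 150),
                    beta = 0.01)
  expect_equal(vsf_to_bb(iso, "polynomial")$value, 2 * pi * 0.01,
               tolerance = 1e-10)
  # linear in cos(theta): 2 pi (a - b/2) exactly
  ang <- c(100, 125, 150)
  bet <- 0.02 + 0.01 * cos(ang * pi / 180)
  lin <- data.frame(wavelength_nm = 470, angle_deg = ang, beta = bet)
  expect_equal(vsf_to_bb(lin, "polynomial")$value,
               2 * pi * (0.02 - 0.01 / 2), tolerance = 1e-10)
  # Petzold-like synthetic shape vs fine-grid quadrature oracle
  shape <- function(th) 1e-3 * (1 + 0.8 * (th / pi - 0.6)^2)
  th_fine <- seq(pi / 2, pi, length.out = 2000)
  g <- shape(th_fine) * sin(th_fine)
  oracle <- 2 * pi * sum(diff(th_fine) * (head(g, -1) + tail(g, -1)) / 2)
  pet <- data.frame(wavelength_nm = 660, angle_deg = ang,
                    beta = shape(ang * pi / 180))
  expect_lt(abs(vsf_to_bb(pet, "polynomial")$value - oracle) / oracle, 0.10)
  # guards
  expect_error(vsf_to_bb(iso[1:2, ], "polynomial"), ">= 3 angles")
  expect_error(vsf_to_bb(data.frame(wavelength_nm = 1, angle_deg = 80,
                                    beta = 1), "fixed_angle"), "angles")
  expect_warning(
    vsf_to_bb(data.frame(wavelength_nm = 532, angle_deg = 117,
                         beta = -1e-5), "fixed_angle"), "clipped")
})

test_that("backscattering ratio reports channels, mean and slope", {
  bbp <- optical_spectrum(c(470, 532, 660), rep(0.002, 3), "b_b")
  bp <- optical_spectrum(400:700, rep(0.1, 301), "b_p")
  br <- backscatter_ratio(bbp, bp)
  expect_equal(br$beta, rep(0.02, 3))
  expect_equal(br$spectral_slope, 0, tolerance = 1e-12)
  # proportional spectra give a constant ratio
  bp2 <- optical_spectrum(400:700, 0.05 * exp(-0.001 * (400:700 - 550)),
                          "b_p")
  bbp2 <- optical_spectrum(c(470, 532, 660),
                           0.004 * spectrum_at(bp2, c(470, 532, 660)), "b_b")
  br2 <- backscatter_ratio(bbp2, bp2)
  expect_equal(br2$beta, rep(0.004, 3), tolerance = 1e-12)
  expect_error(backscatter_ratio(bbp, optical_spectrum(400:700,
    rep(0, 301) - 0.01, "b_p")), "positive")
})

test_that("composed seasonal spectra give plausible, season-ordered ratios", {
  channels <- c(470, 532, 660)
  ratio_of <- function(bundle) {
    bbp <- optical_spectrum(channels,
                            spectrum_at(optical_spectrum(bundle$wavelength,
                              bundle$b_bp, "b_b"), channels), "b_b")
    bp <- optical_spectrum(bundle$wavelength, bundle$b_p, "b_p")
    backscatter_ratio(bbp, bp)
  }
  spring <- ratio_of(make_spring_bundle())
  summer <- ratio_of(make_summer_bundle())
  expect_gt(spring$spectral_mean, summer$spectral_mean)
  for (b in c(spring$beta, summer$beta)) {
    expect_gt(b, 0.002); expect_lt(b, 0.03)
  }
})
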