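test_that("spectral attenuation fits recover exact exponential profiles", {
  z <- 1:10
  pr <- irradiance_profile(z, c(443, 560), cbind(100 * exp(-0.5 * z),
                                                 80 * exp(-1.0 * z)))
  fit <- fit_kd(pr)
  expect_equal(fit$Kd, c(0.5, 1.0), tolerance = 1e-12)
  expect_equal(fit$r2, c(1, 1), tolerance = 1e-12)
  # optical-depth identities hold exactly
  expect_equal(fit$z90 * fit$Kd, c(1, 1), tolerance = 1e-12)
  expect_equal(fit$z_eu, 4.6 * fit$z90, tolerance = 1e-12)
  expect_equal(euphotic_depth(3.0), 13.8)
  expect_error(fit_kd(pr, depth_range = c(0, 1.5)), "3 depths")
})

test_that("PAR attenuation integrates quanta and brackets spectral Kd", {
  wl <- 400:700
  z <- seq(0.5, 7, by = 0.5)
  # spectrally flat decay: Kd(PAR) equals the common Kd
  Ed <- t(vapply(z, function(zz) 500 * exp(-0.4 * zz) * rep(1, length(wl)),
                 numeric(length(wl))))
  pr <- irradiance_profile(z, wl, Ed)
  expect_equal(kd_par(pr)$Kd_par, 0.4, tolerance = 1e-9)
  # two-band toy vs a brute-force PAR(z) oracle
  wl2 <- seq(400, 700, by = 1)
  kd2 <- ifelse(wl2 < 550, 0.2, 2.0)
  surf <- 1000 / wl2          # equal surface quanta per band
  Ed2 <- t(vapply(z, function(zz) surf * exp(-kd2 * zz),
                  numeric(length(wl2))))
  pr2 <- irradiance_profile(z, wl2, Ed2)
  got <- kd_par(pr2)$Kd_par
  expect_gt(got, 0.2); expect_lt(got, 2.0)
  par_oracle <- vapply(z, function(zz) sum(exp(-kd2 * zz)), numeric(1))
  oracle <- -coef(lm(log(par_oracle) ~ z))[[2]]
  expect_equal(got, oracle, tolerance = 1e-4)
  # bracketing property on a composed station
  prof <- generate_profiles(generate_stations(
    generator_config("summer", n_stations = 1, ed_noise = 0), seed = 31), 1,
    seed = 32)
  kp <- kd_par(prof$profile)$Kd_par
  kf <- fit_kd(prof$profile)
  vis <- kf$wavelength >= 400 & kf$wavelength <= 700
  expect_gte(kp, min(kf$Kd[vis])); expect_lte(kp, max(kf$Kd[vis]))
  expect_error(kd_par(irradiance_profile(z, 450:650,
    matrix(1, length(z), 201))), "400-700")
})

test_that("subsurface reflectance extrapolates both streams to zero depth", {
  z <- c(1, 2, 4, 6)
  wl <- c(490, 560)
  Ed <- cbind(100 * exp(-0.5 * z), 100 * exp(-0.4 * z))
  pr <- irradiance_profile(z, wl, Ed, Eu = 0.02 * Ed)
  expect_equal(subsurface_reflectance(pr)$value, c(0.02, 0.02),
               tolerance = 1e-10)
  # upwelling decaying faster: R(0-) exceeds every at-depth ratio
  Eu <- 0.02 * Ed * exp(-0.1 * z)
  pr2 <- irradiance_profile(z, wl, Ed, Eu = Eu)
  r0 <- subsurface_reflectance(pr2)$value
  expect_true(all(r0 > apply(Eu / Ed, 2, max)))
  # Baltic-like synthetic station peaks in the green
  prof <- generate_profiles(generate_stations(
    generator_config("spring", n_stations = 1, ed_noise = 0), seed = 41), 1,
    seed = 42)
  r <- subsurface_reflectance(prof$profile)
  peak <- r$wavelength[which.max(r$value)]
  expect_gte(peak, 560); expect_lte(peak, 600)
})

test_that("biomass peak classification follows the CV-and-depth rules", {
  expect_equal(classify_peak(c(5, 5, 5, 5), c(1, 4, 8, 12))$category,
               "no_peak")
  expect_equal(classify_peak(c(10, 5, 5, 4), c(1, 4, 8, 12))$category,
               "lt3m")
  p <- classify_peak(c(4, 9, 5, 4), c(1, 4, 8, 12))
  expect_equal(p$category, "3to10m")
  expect_gt(p$cv, 0.10)
  expect_equal(classify_peak(c(4, 5, 5, 9), c(1, 4, 8, 12))$category,
               "ge10m")
  # a maximum at exactly 10 m goes to the deep bin
  expect_equal(classify_peak(c(4, 9, 5), c(1, 10, 15))$category, "ge10m")
  # scaling invariance
  v <- c(3, 8, 4, 3); d <- c(1, 5, 9, 14)
  expect_identical(classify_peak(v, d)$category,
                   classify_peak(100 * v, d)$category)
  expect_error(classify_peak(c(-1, 2, 3), c(1, 5, 9)), "negative")
})

test_that("reciprocal Secchi fits recover exact and published couplings", {
  zs <- seq(2, 12, by = 0.5)
  f <- fit_secchi(2.14 / zs, zs)
  expect_equal(f$f, 2.14, tolerance = 1e-12)
  expect_equal(f$rmse, 0, tolerance = 1e-12)
  expect_equal(predict(fit_secchi(1.7 / zs, zs), 5), 0.34,
               tolerance = 1e-12)
  expect_error(fit_secchi(c(1, 1, 1), rep(4, 3)), "singular")
  expect_error(fit_secchi(c(1, 1, 1), c(-1, 2, 3)), "positive")
})

test_that("Secchi coupling recovery is unbiased at the field sample size", {
  set.seed(77)
  f_hat <- replicate(100, {
    d <- simulate_secchi_pairs(139, 2.14)
    fit_secchi(d$kd_par, d$z_sd)$f
  })
  se <- sd(f_hat) / sqrt(length(f_hat))
  expect_lt(abs(mean(f_hat) - 2.14), 2 * se)
})
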