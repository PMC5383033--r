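test_that("exponential CDOM model evaluates correctly", {
  m <- cdom_model(a_ref = 0.62, S = 0.0177, k = 0.030)
  s <- cdom_spectrum(m, c(412, 500))
  expect_equal(s$value[1], 0.650, tolerance = 1e-12)
  # hand evaluation: 0.62 * exp(-0.0177 * 88) + 0.030
  expect_equal(s$value[2], 0.62 * exp(-0.0177 * 88) + 0.030,
               tolerance = 1e-12)
  expect_equal(round(s$value[2], 4), 0.1606)
  # flat-spectrum limit: k = 0, a_ref = 1, S -> 0
  flat <- cdom_spectrum(cdom_model(1, 1e-9, 0), c(400, 550, 700))
  expect_equal(flat$value, rep(1, 3), tolerance = 1e-6)
  expect_error(cdom_model(-0.1, 0.018), "a_ref")
  expect_error(cdom_model(0.5, -0.01), "S must")
  expect_error(cdom_spectrum(m, 250), "300-800")
})

test_that("model spectra are monotone in S away from the reference band", {
  wl <- seq(350, 750, by = 10)
  for (S_pair in list(c(0.012, 0.018), c(0.015, 0.025))) {
    lo <- cdom_spectrum(cdom_model(0.8, S_pair[1], 0.02), wl)$value
    hi <- cdom_spectrum(cdom_model(0.8, S_pair[2], 0.02), wl)$value
    above <- wl > 412
    expect_true(all(hi[above] < lo[above]))
    expect_true(all(hi[wl < 412] > lo[wl < 412]))
  }
})

test_that("noiseless fits recover generating parameters to high precision", {
  # mean-spectrum parameters of the Baltic data set
  fit <- fit_cdom(make_cdom_spectrum())
  expect_lt(abs(fit$S - 0.0177), 1e-6)
  expect_lt(abs(fit$k - 0.030), 1e-6)
  expect_lt(abs(fit$a_ref - 0.62), 1e-6)
  expect_gt(fit$r2, 1 - 1e-10)
  # property: round trip across the observed parameter space
  set.seed(101)
  for (rep in 1:12) {
    a0 <- runif(1, 0.2, 3); S <- runif(1, 0.01, 0.025)
    k <- runif(1, 0, 0.05)
    f <- fit_cdom(make_cdom_spectrum(a0, S, k))
    expect_lt(abs(f$a_ref - a0) / a0, 1e-5)
    expect_lt(abs(f$S - S) / S, 1e-5)
    expect_lt(abs(f$k - k) / max(k, 1e-3), 1e-4)
  }
})

test_that("fitting is unbiased under additive spectral noise", {
  set.seed(202)
  S_hat <- replicate(100, {
    s <- make_cdom_spectrum()
    noisy <- optical_spectrum(s$wavelength,
                              s$value + rnorm(length(s$value), 0, 0.005),
                              "a_CDOM")
    fit_cdom(noisy)$S
  })
  se <- sd(S_hat) / sqrt(length(S_hat))
  expect_lt(abs(mean(S_hat) - 0.0177), 2 * se)
})

test_that("degenerate and under-sampled spectra are rejected", {
  zero <- optical_spectrum(400:700, rep(0, 301), "a_CDOM")
  expect_error(fit_cdom(zero), "degenerate")
  short <- optical_spectrum(seq(400, 700, by = 50),
                            exp(-0.018 * (seq(400, 700, by = 50) - 412)),
                            "a_CDOM")
  expect_error(fit_cdom(short), ">= 20")
})

test_that("regional slope models reproduce the published relations", {
  expect_equal(predict_acdom412("south_of_59N", 0.0177),
               1.16 - 33.36 * 0.0177, tolerance = 1e-12)
  expect_equal(round(predict_acdom412("south_of_59N", 0.0177), 4), 0.5695)
  expect_equal(round(predict_acdom412("gulf_of_finland", 0.0177), 3), 1.163)
  # Gulf of Bothnia asymptote at large S
  expect_equal(suppressWarnings(predict_acdom412("gulf_of_bothnia", 0.2)),
               0.38, tolerance = 1e-10, ignore_attr = TRUE)
  expect_warning(predict_acdom412("south_of_59N", 0.04), "support")
  expect_error(predict_acdom412("baltic_proper", 0.018))
})

test_that("DOC models evaluate the printed coefficients", {
  expect_equal(predict_doc("gulf_of_bothnia", 0), 320.25)
  expect_equal(predict_doc("gulf_of_bothnia", 1.0), 355.79)
  expect_equal(predict_doc("other", 1.0), 434.79)
  expect_error(predict_doc("other", -0.5), "non-negative")
})

test_that("bivariate fitting handles both published model forms", {
  x <- 1:10
  f <- fit_bivariate(x, 2 * x + 1)
  expect_equal(unname(coef(f)["slope"]), 2, tolerance = 1e-12)
  expect_equal(unname(coef(f)["intercept"]), 1, tolerance = 1e-12)
  expect_equal(f$r2, 1)
  expect_error(fit_bivariate(rep(1, 5), 1:5), "singular")
  # exponential-with-offset round trip on the Gulf of Bothnia curve
  S <- seq(0.012, 0.024, length.out = 40)
  y <- 3.64e5 * exp(-766 * S) + 0.38
  fe <- fit_bivariate(S, y, form = "exponential")
  cf <- coef(fe)
  expect_lt(abs(cf["B"] + 766) / 766, 1e-4)
  expect_lt(abs(cf["C"] - 0.38) / 0.38, 1e-3)
})

test_that("the south-region slope is recovered from noisy synthetic pairs", {
  set.seed(303)
  fits <- replicate(40, {
    S <- runif(75, 0.012, 0.024)
    a412 <- -33.36 * S + 1.16 + rnorm(75, 0, 0.12)
    unname(coef(fit_bivariate(S, a412))["slope"])
  })
  se <- sd(fits) / sqrt(length(fits))
  expect_lt(abs(mean(fits) + 33.36), 2 * se)
})
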