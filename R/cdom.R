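#' CDOM exponential absorption model parameters
#'
#' The absorption spectrum of chromophoric dissolved organic matter is
#' modelled as an exponential decay with wavelength plus a small offset
#' absorbing residual noise or scattering:
#' \deqn{a_{CDOM}(\lambda) = a_{CDOM}(\lambda_0)\,e^{-S(\lambda-\lambda_0)} + k}
#' where \eqn{S} (nm^-1) is the spectral slope and \eqn{k} (m^-1) the offset.
#'
#' @param a_ref absorption at the reference wavelength, m^-1 (> 0).
#' @param S spectral slope, nm^-1 (> 0).
#' @param k offset, m^-1 (any sign; |k| > 0.1 is flagged as a suspect
#'   baseline when produced by [fit_cdom()]).
#' @param lambda0 reference wavelength, nm (default 412).
#' @param fit_range wavelength window the parameters refer to (default
#'   400-700 nm).
#' @param r2,rmse,n optional fit diagnostics.
#' @return object of class `"cdom_model"`.
#' @export
cdom_model <- function(a_ref, S, k = 0, lambda0 = 412,
                       fit_range = c(400, 700),
                       r2 = NA_real_, rmse = NA_real_, n = NA_integer_) {
  if (!is.finite(a_ref) || a_ref <= 0) stop("a_ref must be positive")
  if (!is.finite(S) || S <= 0) stop("S must be positive")
  stopifnot(length(fit_range) == 2L, fit_range[1] < fit_range[2])
  structure(list(a_ref = a_ref, S = S, k = k, lambda0 = lambda0,
                 fit_range = fit_range, r2 = r2, rmse = rmse, n = n,
                 k_flagged = isTRUE(abs(k) > 0.1)),
            class = "cdom_model")
}

#' @export
print.cdom_model <- function(x, ...) {
  cat("Exponential CDOM absorption model\n")
  cat(sprintf("  a_CDOM(%g) = %.4f m^-1,  S = %.5f nm^-1,  k = %.4f m^-1\n",
              x$lambda0, x$a_ref, x$S, x$k))
  if (is.finite(x$r2))
    cat(sprintf("  fit %g-%g nm: r2 = %.4f, rmse = %.4g m^-1, n = %d\n",
                x$fit_range[1], x$fit_range[2], x$r2, x$rmse, x$n))
  if (isTRUE(x$k_flagged))
    cat("  warning: |k| > 0.1 m^-1 (suspect baseline)\n")
  invisible(x)
}

#' @export
coef.cdom_model <- function(object, ...) {
  c(a_ref = object$a_ref, S = object$S, k = object$k)
}

#' Evaluate the exponential CDOM model
#'
#' @param params a [cdom_model()] object.
#' @param wavelength wavelengths (nm), within 300-800.
#' @return a `spectrum` of kind `"a_CDOM"`.
#' @examples
#' m <- cdom_model(a_ref = 0.62, S = 0.0177, k = 0.030)
#' spectrum_at(cdom_spectrum(m, 400:700), 412)  # 0.65
#' @export
cdom_spectrum <- function(params, wavelength) {
  stopifnot(inherits(params, "cdom_model"))
  if (any(wavelength < 300 | wavelength > 800))
    stop("wavelengths must lie within 300-800 nm")
  wavelength <- sort(wavelength)
  val <- params$a_ref * exp(-params$S * (wavelength - params$lambda0)) +
    params$k
  optical_spectrum(wavelength, val, "a_CDOM")
}

#' @export
predict.cdom_model <- function(object, wavelength = 400:700, ...) {
  cdom_spectrum(object, wavelength)
}

#' Fit the exponential CDOM model to a measured spectrum
#'
#' Nonlinear least squares (Levenberg-Marquardt) of
#' \eqn{a(\lambda) = a_{ref} e^{-S(\lambda-\lambda_0)} + k} over a
#' wavelength window. Initial values are the measured value at
#' \eqn{\lambda_0} for \eqn{a_{ref}}, S = 0.018 nm^-1 (the mid-range of
#' Baltic observations), and k = 0. `k` is unconstrained in sign but
#' flagged when |k| > 0.1 m^-1.
#'
#' @param spec a `spectrum` (kind `a_CDOM` or `a_nap`) covering `fit_range`
#'   with at least 20 samples.
#' @param fit_range wavelength window, nm (default 400-700).
#' @param lambda0 reference wavelength, nm (default 412).
#' @return a `cdom_model` with diagnostics (`r2`, `rmse`, `n`) and the
#'   fitted/residual vectors attached as attributes.
#' @examples
#' truth <- cdom_model(0.62, 0.0177, 0.030)
#' fit <- fit_cdom(cdom_spectrum(truth, 400:700))
#' coef(fit)
#' @export
fit_cdom <- function(spec, fit_range = c(400, 700), lambda0 = 412) {
  stopifnot(inherits(spec, "spectrum"))
  win <- spec$wavelength >= fit_range[1] & spec$wavelength <= fit_range[2]
  if (sum(win) < 20L)
    stop(sprintf("spectrum covers fit range %g-%g nm with only %d samples (>= 20 required)",
                 fit_range[1], fit_range[2], sum(win)))
  wl <- spec$wavelength[win]
  y <- spec$value[win]
  if (all(abs(y) < 1e-12) || stats::sd(y) == 0)
    stop("degenerate spectrum: no spectral variation to fit")
  a0 <- stats::approx(wl, y, xout = lambda0, rule = 2)$y
  start <- list(a_ref = max(a0, 1e-4), S = 0.018, k = 0)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ a_ref * exp(-S * (wl - lambda0)) + k,
                      start = start,
                      lower = c(a_ref = 1e-8, S = 1e-6, k = -Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e)
      stop("CDOM model fit failed to converge: ", conditionMessage(e)))
  cf <- stats::coef(fit)
  res <- stats::residuals(fit)
  r2 <- 1 - sum(res^2) / sum((y - mean(y))^2)
  out <- cdom_model(cf[["a_ref"]], cf[["S"]], cf[["k"]], lambda0 = lambda0,
                    fit_range = fit_range,
                    r2 = max(0, min(1, r2)),
                    rmse = sqrt(mean(res^2)), n = length(y))
  attr(out, "fitted") <- stats::fitted(fit)
  attr(out, "residuals") <- res
  attr(out, "wavelength") <- wl
  out
}

#' @export
residuals.cdom_model <- function(object, ...) attr(object, "residuals")

#' Spectral slope of non-algal particle absorption
#'
#' Fits the same exponential-plus-offset model used for CDOM to a
#' non-algal particle (NAP) absorption spectrum, returning the slope
#' `S_nap` with diagnostics. Baltic medians are around 0.0097 nm^-1 in
#' spring and 0.0103 nm^-1 in summer.
#'
#' @inheritParams fit_cdom
#' @return a `cdom_model`; the `S` coefficient is the NAP spectral slope.
#' @export
fit_nap_slope <- function(spec, fit_range = c(400, 700), lambda0 = 412) {
  fit_cdom(spec, fit_range = fit_range, lambda0 = lambda0)
}

# printed regional models relating a_CDOM(412) to the spectral slope S
.region_tags <- c("south_of_59N", "gulf_of_finland", "gulf_of_bothnia")

#' Regional prediction of a_CDOM(412) from the spectral slope
#'
#' Evaluates the published regional model linking CDOM absorption at 412 nm
#' to the 400-700 nm spectral slope: linear south of 59 degrees N
#' (a412 = -33.36 S + 1.16) and in the Gulf of Finland
#' (a412 = -137.66 S + 3.60); exponential with offset in the Gulf of
#' Bothnia (a412 = 3.64e5 exp(-766 S) + 0.38).
#'
#' @param region one of `"south_of_59N"`, `"gulf_of_finland"`,
#'   `"gulf_of_bothnia"`.
#' @param S spectral slope, nm^-1. Values outside the observed support
#'   (0.005-0.03 nm^-1) are still evaluated but flagged with a warning.
#' @return predicted a_CDOM(412), m^-1, with attribute
#'   `outside_support` when applicable.
#' @examples
#' predict_acdom412("south_of_59N", 0.0177)
#' @export
predict_acdom412 <- function(region, S) {
  region <- match.arg(region, .region_tags)
  out_of_support <- S <= 0.005 | S >= 0.03
  if (any(out_of_support))
    warning("S outside observed support (0.005, 0.03) nm^-1; extrapolating")
  val <- switch(region,
    south_of_59N    = -33.36 * S + 1.16,
    gulf_of_finland = -137.66 * S + 3.60,
    gulf_of_bothnia = 3.64e5 * exp(-766 * S) + 0.38)
  if (any(out_of_support)) attr(val, "outside_support") <- out_of_support
  val
}

#' Regional prediction of DOC from CDOM absorption
#'
#' Linear models relating dissolved organic carbon to a_CDOM(412):
#' DOC = 35.54 a412 + 320.25 in the Gulf of Bothnia, and
#' DOC = 129.17 a412 + 305.62 for the other sea areas (Gulf of Finland to
#' Gotland, excluding the Bornholm Basin).
#'
#' @param region `"gulf_of_bothnia"` or `"other"`.
#' @param a412 CDOM absorption at 412 nm, m^-1 (>= 0).
#' @return DOC in micromolar.
#' @examples
#' predict_doc("gulf_of_bothnia", 1.0)  # 355.79
#' @export
predict_doc <- function(region = c("other", "gulf_of_bothnia"), a412) {
  region <- match.arg(region)
  if (any(!is.finite(a412)) || any(a412 < 0))
    stop("a412 must be non-negative")
  switch(region,
    gulf_of_bothnia = 35.54 * a412 + 320.25,
    other           = 129.17 * a412 + 305.62)
}
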