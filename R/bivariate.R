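#' Bivariate optical-biogeochemical regression
#'
#' Least-squares fit of either a straight line `y = b x + a` or an
#' exponential with offset `y = A exp(B x) + C`, the two forms used for the
#' salinity-CDOM, DOC-CDOM and seasonal biogeochemical couplings.
#'
#' @param x,y numeric vectors (n >= 3, finite).
#' @param form `"linear"` or `"exponential"` (exponential with offset).
#' @param x_name,y_name optional labels carried into the result.
#' @return object of class `"bivariate_fit"` with coefficients, `r2`,
#'   `rmse` (y units), `n` and, for the linear form, the slope `p_value`.
#' @examples
#' f <- fit_bivariate(1:10, 2 * (1:10) + 1)
#' coef(f)
#' @export
fit_bivariate <- function(x, y, form = c("linear", "exponential"),
                          x_name = deparse(substitute(x)),
                          y_name = deparse(substitute(y))) {
  form <- match.arg(form)
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) stop("need at least 3 finite (x, y) pairs")
  if (stats::sd(x) == 0) stop("singular design: x is constant")

  if (form == "linear") {
    m <- stats::lm(y ~ x)
    cf <- stats::coef(m)
    coefficients <- c(intercept = unname(cf[1]), slope = unname(cf[2]))
    p_value <- suppressWarnings(summary(m)$coefficients[2, 4])
    res <- stats::residuals(m)
  } else {
    # start from a log-linear fit of (y - min) to seed A and B
    off0 <- min(y) - 0.1 * abs(min(y)) - 1e-6
    lf <- stats::lm(log(y - off0) ~ x)
    start <- list(A = exp(unname(stats::coef(lf)[1])),
                  B = unname(stats::coef(lf)[2]), C = off0)
    m <- tryCatch(
      minpack.lm::nlsLM(y ~ A * exp(B * x) + C, start = start,
                        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e)
        stop("exponential fit failed to converge: ", conditionMessage(e)))
    cf <- stats::coef(m)
    coefficients <- c(A = unname(cf["A"]), B = unname(cf["B"]),
                      C = unname(cf["C"]))
    p_value <- NA_real_
    res <- stats::residuals(m)
  }
  r2 <- 1 - sum(res^2) / sum((y - mean(y))^2)
  structure(list(x_name = x_name, y_name = y_name, form = form,
                 coefficients = coefficients,
                 r2 = max(0, min(1, r2)), rmse = sqrt(mean(res^2)),
                 n = length(x), p_value = p_value, model = m),
            class = "bivariate_fit")
}

#' @export
print.bivariate_fit <- function(x, ...) {
  eq <- if (x$form == "linear") {
    sprintf("%s = %.4g %s %+.4g", x$y_name, x$coefficients["slope"],
            x$x_name, x$coefficients["intercept"])
  } else {
    sprintf("%s = %.4g exp(%.4g %s) %+.4g", x$y_name,
            x$coefficients["A"], x$coefficients["B"], x$x_name,
            x$coefficients["C"])
  }
  cat(sprintf("Bivariate %s fit: %s\n", x$form, eq))
  cat(sprintf("  r2 = %.3f, rmse = %.4g, n = %d", x$r2, x$rmse, x$n))
  if (is.finite(x$p_value)) cat(sprintf(", slope p = %.3g", x$p_value))
  cat("\n")
  invisible(x)
}

#' @export
coef.bivariate_fit <- function(object, ...) object$coefficients

#' @export
predict.bivariate_fit <- function(object, newdata, ...) {
  cf <- object$coefficients
  if (object$form == "linear") cf["intercept"] + cf["slope"] * newdata
  else cf["A"] * exp(cf["B"] * newdata) + cf["C"]
}
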