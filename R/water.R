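# Pure (sea)water inherent optical properties.
#
# Absorption knots compiled from standard literature values: Smith & Baker
# (1981) below 380 nm, Pope & Fry (1997) 380-720 nm, Kou et al. (1993)
# beyond 720 nm. Values are m^-1 on a 10-nm knot grid; intermediate
# wavelengths are linearly interpolated. Scattering of pure seawater follows
# the Morel power law b_w(lambda) = b_w(500) * (500/lambda)^4.32 with
# b_w(500) = 0.00288 m^-1; backscattering is half of scattering (isotropic
# in the backward hemisphere for pure water).

.aw_knots <- data.frame(
  wl = seq(300, 800, by = 10),
  aw = c(
    0.1410, 0.1050, 0.0844, 0.0678, 0.0561, 0.0463, 0.0379, 0.0300,
    0.0114, 0.0085,                                   # 380, 390
    0.00663, 0.00473, 0.00454, 0.00495, 0.00635,      # 400-440
    0.00922, 0.00979, 0.01060, 0.01270, 0.01500,      # 450-490
    0.02040, 0.03250, 0.04090, 0.04340, 0.04740,      # 500-540
    0.05650, 0.06190, 0.06950, 0.08960, 0.13510,      # 550-590
    0.22240, 0.26440, 0.27550, 0.29160, 0.31080,      # 600-640
    0.34000, 0.41000, 0.43900, 0.46500, 0.51600,      # 650-690
    0.62400, 0.82700, 1.23100, 1.79900, 2.38000,      # 700-740
    2.47000, 2.55000, 2.51000, 2.36000, 2.16000,      # 750-790
    2.07000)                                          # 800
)

#' Pure-water absorption and scattering table
#'
#' Returns pure seawater absorption `a_w` and scattering `b_w` (m^-1) at the
#' requested wavelengths, from a bundled 10-nm literature knot table
#' (see source of `R/water.R` for provenance) with linear interpolation.
#'
#' @param wavelength wavelengths in nm, within 300-800.
#' @return data.frame with columns `wavelength`, `a_w`, `b_w`, `b_bw`.
#' @examples
#' water_iops(c(412, 440, 560, 675))
#' @export
water_iops <- function(wavelength) {
  if (any(wavelength < 300 | wavelength > 800))
    stop("water IOP table covers 300-800 nm")
  a_w <- stats::approx(.aw_knots$wl, .aw_knots$aw, xout = wavelength)$y
  b_w <- 0.00288 * (500 / wavelength)^4.32
  data.frame(wavelength = wavelength, a_w = a_w, b_w = b_w,
             b_bw = b_w / 2)
}
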