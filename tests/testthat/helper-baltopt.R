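# shared fixtures built in code

# noiseless exponential CDOM spectrum on the standard grid
make_cdom_spectrum <- function(a_ref = 0.62, S = 0.0177, k = 0.030,
                               wl = 400:700) {
  cdom_spectrum(cdom_model(a_ref, S, k), wl)
}

# a spring median station with library SIOPs and the mean CDOM fit
make_spring_bundle <- function(chla = 14.1, tsm = 2.0,
                               cdom = cdom_model(0.62, 0.0177, 0.030)) {
  st <- station_biogeo(chla = chla, tsm = tsm, season = "spring")
  compose_iops(st, siop_library("spring"), cdom)
}

make_summer_bundle <- function(chla = 4.3, tsm = 1.2,
                               cdom = cdom_model(0.62, 0.0177, 0.030)) {
  st <- station_biogeo(chla = chla, tsm = tsm, season = "summer")
  compose_iops(st, siop_library("summer"), cdom)
}

# minimal hand-rolled IOP bundle for kernel-level checks
flat_bundle <- function(wl = c(500, 550), a = 0.5, b_bp = 0.01) {
  structure(list(wavelength = wl,
                 a_w = rep(a, length(wl)), a_cdom = rep(0, length(wl)),
                 a_phi = rep(0, length(wl)), a_nap = rep(0, length(wl)),
                 b_w = rep(0, length(wl)), b_p = rep(10 * b_bp, length(wl)),
                 b_bp = rep(b_bp, length(wl)), b_bw = rep(0, length(wl)),
                 season = "spring"), class = "iop_bundle")
}
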