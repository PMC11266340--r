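# Tungsten linear attenuation coefficient at the 241-Am line, mm^-1.
# NIST XCOM mass attenuation for W at 60 keV (nearest tabulated energy to
# 59.5 keV) is 3.713 cm^2/g; with the CRC tungsten density of 19.25 g/cm^3
# this gives 71.48 cm^-1 = 7.148 mm^-1.
MU_TUNGSTEN_59KEV <- 7.148

#' Mask transmission coefficient
#'
#' Fraction of photons penetrating a radiopaque sheet of the given thickness,
#' `exp(-mu * thickness)`. The default attenuation coefficient is tungsten at
#' 59.5 keV; for the 0.11 mm mask this evaluates to about 0.46, i.e. roughly
#' half of the photons pass straight through the closed mask.
#'
#' @param thickness_mm sheet thickness in mm (>= 0)
#' @param attenuation_mu linear attenuation coefficient in mm^-1 (>= 0)
#' @return transmitted fraction in `[0, 1]`
#' @examples
#' transmission_coefficient(0.11) # ~0.46
#' @export
transmission_coefficient <- function(thickness_mm,
                                     attenuation_mu = MU_TUNGSTEN_59KEV) {
  if (any(thickness_mm < 0)) stop("thickness must be >= 0")
  if (any(attenuation_mu < 0)) stop("attenuation coefficient must be >= 0")
  exp(-attenuation_mu * thickness_mm)
}

#' Transmission-aware forward projection of one slice
#'
#' The detector image expected from a source-plane slice `f_z`:
#' `(1 - t) * (f_z * h_z) + t * sum(f_z) / Npix`, i.e. a linear 2D convolution
#' of the slice with the point-spread function plus a uniform background
#' carrying the fraction `t` of the slice's total intensity (photons that
#' penetrate the closed mask lose all directional encoding).
#'
#' @param f_z non-negative source-plane slice (detector-sized matrix)
#' @param h_z point-spread function at the slice distance: a `psf_image` or a
#'   detector-sized matrix
#' @param t mask transmission fraction in `[0, 1]`
#' @return detector-sized matrix of expected counts
#' @export
forward_project <- function(f_z, h_z, t) {
  h <- psf_pixels(h_z)
  stopifnot(is.matrix(f_z), all(dim(f_z) == dim(h)))
  if (any(f_z < 0)) stop("slice f_z must be non-negative")
  if (t < 0 || t > 1) stop("transmission t must lie in [0, 1]")
  pattern <- lin_conv2(f_z, kernel_fft(h))
  pattern[pattern < 0] <- 0          # frequency-domain roundoff
  (1 - t) * pattern + t * sum(f_z) / length(f_z)
}

psf_pixels <- function(h) {
  if (inherits(h, "psf_image")) h$pixels else h
}
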