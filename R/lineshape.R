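# First-derivative pseudo-Voigt line profiles.
#
# Each hyperfine line is the field derivative of a unit-area absorption
# profile blended from a Lorentzian and a Gaussian, parameterized by its
# peak-to-peak derivative width Gpp (the distance between the derivative's
# positive and negative extrema):
#   Lorentzian HWHM  gamma = sqrt(3) * Gpp / 2   (extrema at +/- Gpp/2)
#   Gaussian sd      sigma = Gpp / 2             (extrema at +/- Gpp/2)
# The derivative peak amplitude of either component scales as 1/Gpp^2 at
# fixed integrated intensity, and the extrema sit exactly Gpp/2 from the line
# center; both facts are relied on by the feature-extraction tests.

deriv_pseudo_voigt <- function(x, center, pp_width, lorentz_frac) {
  dx <- x - center
  out <- 0
  if (lorentz_frac > 0) {
    g <- sqrt(3) * pp_width / 2
    out <- out + lorentz_frac * (-(2 / pi) * g * dx / ((dx^2 + g^2)^2))
  }
  if (lorentz_frac < 1) {
    s <- pp_width / 2
    out <- out + (1 - lorentz_frac) * (-dx / (s^3 * sqrt(2 * pi)) * exp(-dx^2 / (2 * s^2)))
  }
  out
}
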