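# Shared fixtures: everything is generated in code at test time.

default_grid <- field_grid(3250, 3430, 4096)
rigid_grid <- field_grid(3240, 3440, 4096)

# Symmetric three-line spectrum: equal widths and weights.
symmetric_params <- function(width = 2, hyperfine = 16, shape_mix = 0) {
  fluid_params(
    hyperfine_G = hyperfine, widths_G = rep(width, 3),
    rel_intensity = c(1, 1, 1), shape_mix = shape_mix
  )
}

# Analytic peak-to-peak height of an isolated unit-area derivative line.
# Lorentzian: |D| at the extremum is 9 / (8 sqrt(3) pi gamma^2), gamma =
# sqrt(3) Gpp / 2; Gaussian: exp(-1/2) / (sigma^2 sqrt(2 pi)), sigma = Gpp/2.
# Either way pp height = 2 |D| and scales as 1 / Gpp^2.
analytic_pp_height <- function(pp_width, shape_mix, weight = 1) {
  g <- sqrt(3) * pp_width / 2
  s <- pp_width / 2
  amp_l <- 9 / (8 * sqrt(3) * pi * g^2)
  amp_g <- exp(-0.5) / (s^2 * sqrt(2 * pi))
  2 * weight * (shape_mix * amp_l + (1 - shape_mix) * amp_g)
}

quiet_fit <- function(...) suppressWarnings(fit_one_site(...))
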