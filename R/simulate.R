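#' Simulate a fluid-phase three-line spectrum
#'
#' Deterministic (noise-free) first-derivative spectrum: the sum over
#' mI in \{+1, 0, -1\} of derivative pseudo-Voigt lines centered at
#' `center_G - mI * hyperfine_G`, each with its own peak-to-peak width and
#' integrated-intensity weight. The low-field (mI = +1) line is leftmost.
#'
#' @param params A [fluid_params()] object.
#' @param grid A [field_grid()].
#' @param meta Optional metadata list attached to the spectrum.
#'
#' @return An `epr_spectrum` (fluid regime).
#' @examples
#' sp <- simulate_fluid_spectrum(fluid_params(), field_grid())
#' @export
simulate_fluid_spectrum <- function(params, grid = field_grid(), meta = list()) {
  stopifnot(inherits(params, "fluid_params"), inherits(grid, "field_grid"))
  if (params$hyperfine_G < 2 * max(params$widths_G)) {
    abort(
      "lines unresolvable: `hyperfine_G` must be at least twice the largest width.",
      class = "lensepr_error_unresolved"
    )
  }
  epr_spectrum(grid$field_G, fluid_intensity(params, grid), regime = "fluid", meta = meta)
}

# Raw three-line intensity without the resolvability gate (the bound
# population of a two-component spectrum is intentionally over-broadened).
fluid_intensity <- function(params, grid) {
  x <- grid$field_G
  centers <- params$center_G - c(1, 0, -1) * params$hyperfine_G
  y <- 0
  for (k in 1:3) {
    y <- y + params$rel_intensity[k] *
      deriv_pseudo_voigt(x, centers[k], params$widths_G[k], params$shape_mix)
  }
  y
}

#' Simulate a two-component (unbound + bound) spectrum
#'
#' Weighted sum `(1 - f) * unbound + f * bound` at equal total integrated
#' intensity, emulating the coexistence of free spin labels and labels
#' immobilized by bound protein. The double integral is invariant to `f`.
#' The bound component must be broader than the unbound one on every line
#' (immobilization broadens), otherwise the call is rejected.
#'
#' @param unbound,bound [fluid_params()] for the two motional populations.
#' @param bound_fraction Proportion of spins in the bound population, in
#'   \[0, 1\].
#' @inheritParams simulate_fluid_spectrum
#'
#' @return An `epr_spectrum` (fluid regime).
#' @examples
#' u <- fluid_params()
#' b <- bound_params(u)
#' sp <- simulate_two_component_spectrum(u, b, 0.3, field_grid())
#' @export
simulate_two_component_spectrum <- function(unbound, bound, bound_fraction,
                                            grid = field_grid(), meta = list()) {
  stopifnot(inherits(unbound, "fluid_params"), inherits(bound, "fluid_params"))
  if (bound_fraction < 0 || bound_fraction > 1) {
    abort("`bound_fraction` must be in [0, 1].", class = "lensepr_error_params")
  }
  if (any(bound$widths_G <= unbound$widths_G)) {
    abort(
      paste(
        "bound-component widths must exceed unbound widths on every line:",
        "protein binding immobilizes (broadens) the label."
      ),
      class = "lensepr_error_immobilization"
    )
  }
  su <- simulate_fluid_spectrum(unbound, grid) # unbound must be resolvable
  yb <- fluid_intensity(bound, grid)
  y <- (1 - bound_fraction) * su$intensity + bound_fraction * yb
  epr_spectrum(grid$field_G, y, regime = "fluid", meta = meta)
}

#' Default bound-component parameters derived from the unbound component
#'
#' Immobilization by bound protein broadens the hyperfine lines
#' anisotropically: the outer (low- and high-field) lines broaden most. The
#' default per-line width scales are (5, 2, 5). The strong outer broadening
#' makes the bound population's contribution under the sharp low-field
#' extrema negligible (the working assumption of the percent-affected
#' amplitude ratio), while the milder central broadening makes the composite
#' h+/h0 mobility parameter fall monotonically with the bound fraction.
#'
#' @param unbound A [fluid_params()] object.
#' @param width_scale Length-3 multiplicative width scales, each > 1.
#' @return A [fluid_params()] object for the bound population.
#' @examples
#' bound_params(fluid_params())
#' @export
bound_params <- function(unbound, width_scale = c(5, 2, 5)) {
  stopifnot(inherits(unbound, "fluid_params"))
  if (length(width_scale) == 1) width_scale <- rep(width_scale, 3)
  if (any(width_scale <= 1)) {
    abort("`width_scale` must exceed 1 on every line.", class = "lensepr_error_params")
  }
  fluid_params(
    center_G = unbound$center_G,
    hyperfine_G = unbound$hyperfine_G,
    widths_G = unbound$widths_G * width_scale,
    rel_intensity = unbound$rel_intensity,
    shape_mix = unbound$shape_mix
  )
}

#' Simulate a rigid-limit (-165 degC) spectrum
#'
#' Two outer derivative features at `center_G +/- Az_G` plus a broad central
#' hump. The outermost positive extremum sits at `center_G - Az_G -
#' outer_width_G / 2` and the outermost negative extremum at `center_G + Az_G
#' + outer_width_G / 2`, so the generator's extrema-separation law is
#' `2 * Az_G + outer_width_G`.
#'
#' @param params A [rigid_params()] object.
#' @inheritParams simulate_fluid_spectrum
#'
#' @return An `epr_spectrum` (rigid regime).
#' @examples
#' sp <- simulate_rigid_spectrum(rigid_params(Az_G = 33.5), field_grid(3240, 3440))
#' @export
simulate_rigid_spectrum <- function(params, grid = field_grid(3240, 3440),
                                    meta = list()) {
  stopifnot(inherits(params, "rigid_params"), inherits(grid, "field_grid"))
  span_needed <- params$Az_G + 5 * params$outer_width_G
  if (params$center_G - span_needed < grid$start_G ||
    params$center_G + span_needed > grid$stop_G) {
    abort(
      "grid too narrow: it must span center_G +/- (Az_G + 5 * outer_width_G).",
      class = "lensepr_error_grid"
    )
  }
  x <- grid$field_G
  y <- deriv_pseudo_voigt(x, params$center_G - params$Az_G, params$outer_width_G, 0) +
    deriv_pseudo_voigt(x, params$center_G + params$Az_G, params$outer_width_G, 0) +
    params$inner_amplitude *
      deriv_pseudo_voigt(
        x, params$center_G,
        params$inner_width_factor * params$outer_width_G, 0
      )
  epr_spectrum(x, y, regime = "rigid", meta = meta)
}

#' One-site binding law
#'
#' `MSO(C) = MMSO * Ka * C / (1 + Ka * C)`: the saturable percentage of the
#' membrane surface occupied at protein concentration `C`. At `C = 1 / Ka`
#' the curve passes through half its plateau.
#'
#' @param conc_uM Protein concentration(s), uM.
#' @param mmso_pct Plateau (maximum MSO), percentage points.
#' @param ka_per_uM Association constant, 1/uM.
#' @return MSO in percent, same length as `conc_uM`.
#' @examples
#' one_site_mso(5, 60, 0.2) # 30
#' @export
one_site_mso <- function(conc_uM, mmso_pct, ka_per_uM) {
  mmso_pct * ka_per_uM * conc_uM / (1 + ka_per_uM * conc_uM)
}
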