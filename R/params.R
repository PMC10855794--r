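#' Uniform magnetic-field grid
#'
#' Defines the sweep window on which spectra are sampled. The field axis is in
#' Gauss and increases left to right, so the low-field hyperfine line is the
#' leftmost feature of a spectrum.
#'
#' @param start_G,stop_G Sweep limits in Gauss (`stop_G > start_G`).
#' @param n_points Number of evenly spaced samples (at least 64).
#'
#' @return A `field_grid` object: a list with `start_G`, `stop_G`, `n_points`,
#'   the spacing `delta_G`, and the sampled axis `field_G`.
#' @examples
#' g <- field_grid(3250, 3430, 4096)
#' g$delta_G
#' @export
field_grid <- function(start_G = 3250, stop_G = 3430, n_points = 4096) {
  if (!is.numeric(start_G) || !is.numeric(stop_G) || stop_G <= start_G) {
    abort("`stop_G` must be greater than `start_G`.", class = "lensepr_error_grid")
  }
  n_points <- as.integer(n_points)
  if (is.na(n_points) || n_points < 64) {
    abort("`n_points` must be an integer >= 64.", class = "lensepr_error_grid")
  }
  structure(
    list(
      start_G = as.numeric(start_G),
      stop_G = as.numeric(stop_G),
      n_points = n_points,
      delta_G = (stop_G - start_G) / (n_points - 1),
      field_G = seq(start_G, stop_G, length.out = n_points)
    ),
    class = "field_grid"
  )
}

#' @export
print.field_grid <- function(x, ...) {
  cat(sprintf(
    "<field_grid> %.6g to %.6g G, %d points (delta = %.4g G)\n",
    x$start_G, x$stop_G, x$n_points, x$delta_G
  ))
  invisible(x)
}

#' Fluid-phase (motionally narrowed) spectrum parameters
#'
#' Generative parameters for a three-line nitroxide first-derivative spectrum
#' at 37 degC: the mI = +1, 0, -1 hyperfine lines sit at
#' `center_G - mI * hyperfine_G`, each a derivative pseudo-Voigt with its own
#' peak-to-peak width and integrated-intensity weight.
#'
#' @param center_G Field of the central (mI = 0) line, Gauss.
#' @param hyperfine_G Effective isotropic splitting between adjacent lines,
#'   Gauss. Must exceed twice the largest width so the lines are resolvable.
#' @param widths_G Length-3 positive vector of peak-to-peak derivative widths
#'   (low-field, central, high-field), Gauss.
#' @param rel_intensity Length-3 positive vector of integrated-intensity
#'   weights (double-integral shares; normalized internally).
#' @param shape_mix Lorentzian fraction of the pseudo-Voigt blend in
#'   \[0, 1\]; 0 is pure Gaussian (the default used throughout the synthetic
#'   study, where the sweep window then conserves the double integral to
#'   better than 1e-9).
#'
#' @return A `fluid_params` object.
#' @examples
#' fluid_params(hyperfine_G = 15.2, widths_G = c(2.4, 2.0, 2.8))
#' @export
fluid_params <- function(center_G = 3340, hyperfine_G = 15.2,
                         widths_G = c(2.4, 2.0, 2.8),
                         rel_intensity = c(1, 1, 1),
                         shape_mix = 0) {
  if (!is.numeric(hyperfine_G) || hyperfine_G <= 0) {
    abort("`hyperfine_G` must be positive.", class = "lensepr_error_params")
  }
  if (length(widths_G) != 3 || any(widths_G <= 0)) {
    abort("`widths_G` must be 3 positive values.", class = "lensepr_error_params")
  }
  if (length(rel_intensity) != 3 || any(rel_intensity <= 0)) {
    abort("`rel_intensity` must be 3 positive values.", class = "lensepr_error_params")
  }
  if (shape_mix < 0 || shape_mix > 1) {
    abort("`shape_mix` must be in [0, 1].", class = "lensepr_error_params")
  }
  structure(
    list(
      center_G = as.numeric(center_G),
      hyperfine_G = as.numeric(hyperfine_G),
      widths_G = as.numeric(widths_G),
      rel_intensity = as.numeric(rel_intensity) / sum(rel_intensity),
      shape_mix = as.numeric(shape_mix)
    ),
    class = "fluid_params"
  )
}

#' Rigid-limit (-165 degC) spectrum parameters
#'
#' Simplified powder-limit model: two outer derivative features at
#' `center_G +/- Az_G` plus a broad central hump. Only the outer-extrema
#' separation is consumed downstream; the documented separation law of this
#' generator is `2 * Az_G + outer_width_G` (each derivative feature puts its
#' extremum half a peak-to-peak width beyond the canonical position).
#'
#' @param center_G Spectral center, Gauss.
#' @param Az_G z-component hyperfine coupling, Gauss (positive). Larger values
#'   mean a more polar, less hydrophobic probe environment.
#' @param outer_width_G Peak-to-peak width of the outer derivative features,
#'   Gauss.
#' @param inner_amplitude Integrated-intensity weight of the central hump
#'   relative to each outer feature (weight 1).
#' @param inner_width_factor Width of the central hump as a multiple of
#'   `outer_width_G`.
#'
#' @return A `rigid_params` object.
#' @examples
#' rigid_params(Az_G = 33.5)
#' @export
rigid_params <- function(center_G = 3340, Az_G = 33.5, outer_width_G = 3,
                         inner_amplitude = 1.5, inner_width_factor = 6) {
  if (Az_G <= 0) abort("`Az_G` must be positive.", class = "lensepr_error_params")
  if (outer_width_G <= 0) {
    abort("`outer_width_G` must be positive.", class = "lensepr_error_params")
  }
  if (inner_amplitude < 0 || inner_width_factor <= 0) {
    abort("central-hump parameters must be non-negative.", class = "lensepr_error_params")
  }
  structure(
    list(
      center_G = as.numeric(center_G),
      Az_G = as.numeric(Az_G),
      outer_width_G = as.numeric(outer_width_G),
      inner_amplitude = as.numeric(inner_amplitude),
      inner_width_factor = as.numeric(inner_width_factor)
    ),
    class = "rigid_params"
  )
}

#' Ground-truth binding parameters for a synthetic titration
#'
#' @param mmso_pct Maximum percentage of membrane surface occupied at binding
#'   saturation, in \[0, 100\].
#' @param ka_per_uM Association constant of the one-site model
#'   `MSO(C) = MMSO * Ka * C / (1 + Ka * C)`, in 1/uM (non-negative).
#'
#' @return A `binding_truth` object.
#' @examples
#' binding_truth(60, 0.2)
#' @export
binding_truth <- function(mmso_pct, ka_per_uM) {
  if (mmso_pct < 0 || mmso_pct > 100) {
    abort("`mmso_pct` must be in [0, 100].", class = "lensepr_error_params")
  }
  if (ka_per_uM < 0) abort("`ka_per_uM` must be >= 0.", class = "lensepr_error_params")
  structure(
    list(mmso_pct = as.numeric(mmso_pct), ka_per_uM = as.numeric(ka_per_uM)),
    class = "binding_truth"
  )
}

#' Titration design for the synthetic study
#'
#' Mirrors the experimental protocol: protein concentration varied from 0 to
#' about 60 uM at fixed 11.4 mM lipid plus cholesterol, with at least three
#' independently prepared replicates.
#'
#' @param concentrations_uM Protein concentrations, uM; must include 0 (the
#'   protein-free control) and be non-negative.
#' @param n_replicates Number of independent replicates (>= 1).
#' @param noise_sd_mso Standard deviation of the additive Gaussian perturbation
#'   applied to the true MSO of each point with C > 0, in percentage points.
#'   The perturbed MSO sets the bound fraction and hence the component
#'   amplitudes of the simulated spectrum.
#' @param seed Integer seed; the same seed reproduces the dataset exactly.
#' @param width_jitter_rel Relative (lognormal) scatter of all linewidths per
#'   replicate, emulating sample-prep variability. Shared between a
#'   replicate's control and protein spectra, so it cancels in the amplitude
#'   ratio and does not add MSO noise.
#'
#' @return A `titration_design` object.
#' @examples
#' titration_design(seed = 7)
#' @export
titration_design <- function(concentrations_uM = c(0, 2.5, 5, 10, 15, 20, 30, 45, 60),
                             n_replicates = 3, noise_sd_mso = 2, seed = 1,
                             width_jitter_rel = 0.003) {
  if (!any(concentrations_uM == 0)) {
    abort("`concentrations_uM` must include 0 (the protein-free control).",
      class = "lensepr_error_params"
    )
  }
  if (any(concentrations_uM < 0)) {
    abort("concentrations must be non-negative.", class = "lensepr_error_params")
  }
  if (n_replicates < 1) abort("`n_replicates` must be >= 1.", class = "lensepr_error_params")
  if (noise_sd_mso < 0 || width_jitter_rel < 0) {
    abort("noise parameters must be non-negative.", class = "lensepr_error_params")
  }
  structure(
    list(
      concentrations_uM = sort(unique(as.numeric(concentrations_uM))),
      n_replicates = as.integer(n_replicates),
      noise_sd_mso = as.numeric(noise_sd_mso),
      seed = as.integer(seed),
      width_jitter_rel = as.numeric(width_jitter_rel)
    ),
    class = "titration_design"
  )
}
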