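# Extraction of the hand-read quantities: peak-to-peak line heights (h+, h0),
# maximum splitting, and the rigid-limit outer-extrema separation (2Az).

# All local maxima of y with topographic prominence.
local_maxima_prominence <- function(y) {
  n <- length(y)
  d <- diff(y)
  idx <- which(d[-length(d)] > 0 & d[-1] <= 0) + 1
  if (!length(idx)) {
    return(tibble(index = integer(), height = numeric(), prominence = numeric()))
  }
  prom <- vapply(idx, function(p) {
    h <- y[p]
    left <- y[seq_len(p - 1)]
    higher_l <- which(left > h)
    lo_l <- if (length(higher_l)) min(y[(max(higher_l) + 1):p]) else min(y[1:p])
    right <- y[(p + 1):n]
    higher_r <- which(right > h)
    lo_r <- if (length(higher_r)) min(y[p:(p + min(higher_r) - 1)]) else min(y[p:n])
    h - max(lo_l, lo_r)
  }, numeric(1))
  tibble(index = idx, height = y[idx], prominence = prom)
}

# Three-point parabolic refinement of an extremum at index i.
refine_extremum <- function(x, y, i) {
  n <- length(y)
  if (i <= 1 || i >= n) {
    return(list(field = x[i], value = y[i]))
  }
  denom <- y[i - 1] - 2 * y[i] + y[i + 1]
  if (denom == 0) {
    return(list(field = x[i], value = y[i]))
  }
  d <- 0.5 * (y[i - 1] - y[i + 1]) / denom
  list(
    field = x[i] + d * (x[2] - x[1]),
    value = y[i] - 0.25 * (y[i - 1] - y[i + 1]) * d
  )
}

# Top-k prominent extrema subject to a minimum field separation;
# ties broken toward lower field. Returns indices sorted by field.
select_extrema <- function(x, y, k, min_sep_G) {
  cand <- local_maxima_prominence(y)
  cand <- cand[order(-cand$prominence, x[cand$index]), ]
  chosen <- integer()
  for (i in cand$index) {
    if (all(abs(x[i] - x[chosen]) >= min_sep_G)) chosen <- c(chosen, i)
    if (length(chosen) == k) break
  }
  sort(chosen)
}

maybe_smooth <- function(y, smooth_window) {
  if (is.null(smooth_window)) {
    return(y)
  }
  if (!requireNamespace("signal", quietly = TRUE)) {
    abort("Savitzky-Golay smoothing needs the 'signal' package.",
      class = "lensepr_error_dependency"
    )
  }
  if (smooth_window %% 2 == 0 || smooth_window < 5) {
    abort("`smooth_window` must be odd and >= 5.", class = "lensepr_error_params")
  }
  as.numeric(signal::sgolayfilt(y, p = 3, n = smooth_window))
}

#' Linear baseline correction
#'
#' Fits a straight line to the outer `edge_frac` of points on each edge of
#' the sweep and subtracts it, so the edge regions average to zero. If the
#' edges appear to contain spectral extrema rather than flat baseline the
#' function warns and falls back to subtracting a constant offset.
#'
#' @param spectrum An `epr_spectrum` (or data frame with `field_G`,
#'   `intensity`).
#' @param edge_frac Fraction of points on each edge taken as baseline
#'   (default 0.05).
#' @return A baseline-corrected `epr_spectrum`.
#' @examples
#' sp <- simulate_fluid_spectrum(fluid_params(), field_grid())
#' ramped <- epr_spectrum(sp$field_G, sp$intensity + 0.1 + 0.001 * sp$field_G)
#' corrected <- baseline_correct(ramped)
#' @export
baseline_correct <- function(spectrum, edge_frac = 0.05) {
  spectrum <- as_spectrum_input(spectrum)
  x <- spectrum$field_G
  y <- spectrum$intensity
  n <- length(x)
  m <- max(3L, floor(edge_frac * n))
  edge <- c(seq_len(m), (n - m + 1):n)
  fit <- lm(y[edge] ~ x[edge])
  resid_range <- max(abs(stats::residuals(fit)))
  signal_range <- max(y) - min(y)
  if (signal_range > 0 && resid_range > 0.02 * signal_range) {
    warn("edge regions look like signal, not baseline; subtracting a constant offset only.",
      class = "lensepr_warning_baseline"
    )
    y2 <- y - mean(y[edge])
  } else {
    y2 <- y - (coef(fit)[1] + coef(fit)[2] * x)
  }
  epr_spectrum(x, y2, regime = spectrum_regime(spectrum), meta = spectrum_meta(spectrum))
}

#' Locate the three hyperfine lines of a fluid-phase spectrum
#'
#' Identifies the positive/negative extremum pair of the low-field, central
#' and high-field first-derivative lines by prominence-ranked search with a
#' minimum-separation constraint, refines every extremum by 3-point parabolic
#' interpolation, and reports the peak-to-peak heights `h_plus` (low-field)
#' and `h_zero` (central) and the maximum splitting (field distance from the
#' low-field positive extremum to the high-field negative extremum).
#'
#' @param spectrum A baseline-corrected fluid-regime `epr_spectrum`.
#' @param min_sep_G Minimum field separation between candidate lines, Gauss
#'   (about half the hyperfine splitting; default 6).
#' @param smooth_window Optional odd Savitzky-Golay window (default `NULL`,
#'   no smoothing). Apply identically to control and sample spectra.
#' @return An `epr_line_features` one-row tibble: refined fields and values
#'   of all extrema, `h_plus`, `h_zero`, `mobility` (their ratio) and
#'   `max_splitting_G`.
#' @examples
#' sp <- simulate_fluid_spectrum(fluid_params(), field_grid())
#' locate_lines(sp)
#' @export
locate_lines <- function(spectrum, min_sep_G = 6, smooth_window = NULL) {
  spectrum <- as_spectrum_input(spectrum)
  x <- spectrum$field_G
  y <- maybe_smooth(spectrum$intensity, smooth_window)
  unresolved <- function() {
    abort(
      "unresolved spectrum: could not find three interleaved derivative line pairs (over-broadened lines or wrong regime?).",
      class = "lensepr_error_unresolved"
    )
  }
  imax <- select_extrema(x, y, 3, min_sep_G)
  imin <- select_extrema(x, -y, 3, min_sep_G)
  if (length(imax) < 3 || length(imin) < 3) unresolved()
  # each line is a positive extremum followed by its negative partner
  if (!all(imax < imin) || !all(imax[-1] > imin[-3])) unresolved()
  mx <- lapply(imax, function(i) refine_extremum(x, y, i))
  mn <- lapply(imin, function(i) refine_extremum(x, y, i))
  h_plus <- mx[[1]]$value - mn[[1]]$value
  h_zero <- mx[[2]]$value - mn[[2]]$value
  if (h_plus <= 0 || h_zero <= 0) unresolved()
  out <- tibble(
    low_max_G = mx[[1]]$field, low_max = mx[[1]]$value,
    low_min_G = mn[[1]]$field, low_min = mn[[1]]$value,
    cen_max_G = mx[[2]]$field, cen_max = mx[[2]]$value,
    cen_min_G = mn[[2]]$field, cen_min = mn[[2]]$value,
    high_max_G = mx[[3]]$field, high_max = mx[[3]]$value,
    high_min_G = mn[[3]]$field, high_min = mn[[3]]$value,
    h_plus = h_plus, h_zero = h_zero,
    mobility = h_plus / h_zero,
    max_splitting_G = mn[[3]]$field - mx[[1]]$field
  )
  class(out) <- c("epr_line_features", class(out))
  out
}

#' Mobility parameter h+/h0
#'
#' The ratio of the peak-to-peak height of the low-field line to that of the
#' central line. Higher values mean a more mobile membrane headgroup region;
#' protein binding and added cholesterol both lower it.
#'
#' @param features An `epr_line_features` row from [locate_lines()], or a
#'   fluid `epr_spectrum` (located on the fly).
#' @param ... Passed to [locate_lines()] when a spectrum is given.
#' @return A positive number.
#' @examples
#' sp <- simulate_fluid_spectrum(fluid_params(), field_grid())
#' mobility_parameter(sp)
#' @export
mobility_parameter <- function(features, ...) {
  if (is_epr_spectrum(features)) features <- locate_lines(features, ...)
  if (!all(c("h_plus", "h_zero") %in% names(features))) {
    abort("`features` must carry `h_plus` and `h_zero`.", class = "lensepr_error_features")
  }
  if (any(features$h_zero <= 0)) {
    abort("`h_zero` must be positive.", class = "lensepr_error_features")
  }
  features$h_plus / features$h_zero
}

#' Rigid-limit hyperfine splitting 2Az
#'
#' The field separation between the outermost positive and outermost negative
#' extrema of a rigid-limit (about -165 degC) spectrum, with parabolic
#' sub-grid refinement. 2Az measures the polarity of the probe environment:
#' a larger 2Az means a more polar, less hydrophobic headgroup region.
#'
#' @param spectrum A rigid-regime `epr_spectrum`.
#' @param prominence_frac Candidate extrema must reach this fraction of the
#'   most prominent extremum (default 0.05).
#' @param smooth_window Optional odd Savitzky-Golay window.
#' @return A one-row tibble with `two_Az_G` and the refined outer-extrema
#'   fields `low_field_G`, `high_field_G`.
#' @examples
#' sp <- simulate_rigid_spectrum(rigid_params(Az_G = 33.5), field_grid(3240, 3440))
#' rigid_limit_2az(sp)
#' @export
rigid_limit_2az <- function(spectrum, prominence_frac = 0.05, smooth_window = NULL) {
  spectrum <- as_spectrum_input(spectrum)
  x <- spectrum$field_G
  y <- maybe_smooth(spectrum$intensity, smooth_window)
  n <- length(x)
  # a clipped outer feature leaves large signal at the sweep edge and its
  # extremum invisible to a local search; reject such windows outright
  if (max(abs(y[c(1, n)])) > 0.05 * max(abs(y))) {
    abort("signal has not decayed at the sweep edges: the window is too narrow.",
      class = "lensepr_error_grid"
    )
  }
  maxima <- local_maxima_prominence(y)
  minima <- local_maxima_prominence(-y)
  if (!nrow(maxima) || !nrow(minima)) {
    abort("no extrema found in rigid-limit spectrum.", class = "lensepr_error_unresolved")
  }
  top <- max(maxima$prominence, minima$prominence)
  maxima <- maxima[maxima$prominence >= prominence_frac * top, ]
  minima <- minima[minima$prominence >= prominence_frac * top, ]
  if (!nrow(maxima) || !nrow(minima)) {
    abort("no prominent outer extrema found.", class = "lensepr_error_unresolved")
  }
  ilow <- min(maxima$index)
  ihigh <- max(minima$index)
  edge_pts <- max(3L, ceiling(0.005 * n))
  if (ilow <= edge_pts || ihigh >= n - edge_pts) {
    abort("outer extrema at the grid edges: the sweep window is too narrow.",
      class = "lensepr_error_grid"
    )
  }
  lo <- refine_extremum(x, y, ilow)
  hi <- refine_extremum(x, y, ihigh)
  tibble(
    two_Az_G = hi$field - lo$field,
    low_field_G = lo$field,
    high_field_G = hi$field
  )
}

#' Spin-count-normalized low-field amplitude
#'
#' The peak-to-peak height of the low-field line divided by the spectrum's
#' double integral. Because the lipid (and 1 mol% spin label) content is
#' fixed across a titration, the double integral is proportional to the
#' number of spins in the sample, and this normalization makes control (U0)
#' and protein-added (U0 + B0) amplitudes directly comparable; it is also
#' invariant to uniform intensity rescaling.
#'
#' @param spectrum A fluid-regime `epr_spectrum`.
#' @param features Optional pre-computed [locate_lines()] row.
#' @param ... Passed to [locate_lines()].
#' @return A positive number (1 / Gauss^2 scale).
#' @examples
#' sp <- simulate_fluid_spectrum(fluid_params(), field_grid())
#' normalized_low_field_height(sp)
#' @export
normalized_low_field_height <- function(spectrum, features = NULL, ...) {
  spectrum <- as_spectrum_input(spectrum)
  di <- double_integral(spectrum)
  if (!is.finite(di) || di <= 0) {
    abort("non-positive double integral; cannot normalize.",
      class = "lensepr_error_features"
    )
  }
  features <- features %||% locate_lines(spectrum, ...)
  features$h_plus / di
}
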