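#' Construct an EPR spectrum
#'
#' A spectrum is a tibble with columns `field_G` (strictly increasing, Gauss)
#' and `intensity` (first-derivative signal, arbitrary units), carrying the
#' temperature regime and sample metadata as attributes.
#'
#' @param field_G Numeric vector of sampled field positions, strictly
#'   increasing, length >= 64.
#' @param intensity Numeric vector of the same length.
#' @param regime `"fluid"` (37 degC, motionally narrowed) or `"rigid"`
#'   (about -165 degC, powder limit).
#' @param meta Named list of sample metadata (sample_id, protein,
#'   concentration_uM, mixing_ratio, replicate, ...).
#'
#' @return An `epr_spectrum` tibble.
#' @export
epr_spectrum <- function(field_G, intensity, regime = c("fluid", "rigid"),
                         meta = list()) {
  regime <- arg_match(regime)
  field_G <- as.numeric(field_G)
  intensity <- as.numeric(intensity)
  if (length(field_G) != length(intensity)) {
    abort("`field_G` and `intensity` must have equal length.",
      class = "lensepr_error_spectrum"
    )
  }
  if (length(field_G) < 64) {
    abort("a spectrum needs at least 64 points.", class = "lensepr_error_spectrum")
  }
  if (any(diff(field_G) <= 0)) {
    abort("`field_G` must be strictly increasing.", class = "lensepr_error_spectrum")
  }
  out <- tibble(field_G = field_G, intensity = intensity)
  attr(out, "regime") <- regime
  attr(out, "meta") <- meta
  class(out) <- c("epr_spectrum", class(out))
  out
}

is_epr_spectrum <- function(x) inherits(x, "epr_spectrum")

#' Temperature regime of a spectrum
#' @param spectrum An `epr_spectrum`.
#' @return `"fluid"` or `"rigid"`.
#' @export
spectrum_regime <- function(spectrum) attr(spectrum, "regime") %||% "fluid"

#' Sample metadata of a spectrum
#' @param spectrum An `epr_spectrum`.
#' @return Named list.
#' @export
spectrum_meta <- function(spectrum) attr(spectrum, "meta") %||% list()

as_spectrum_input <- function(spectrum, arg = "spectrum") {
  if (is_epr_spectrum(spectrum)) return(spectrum)
  if (is.data.frame(spectrum) && all(c("field_G", "intensity") %in% names(spectrum))) {
    return(epr_spectrum(spectrum$field_G, spectrum$intensity))
  }
  abort(sprintf("`%s` must be an epr_spectrum or a data frame with field_G and intensity.", arg),
    class = "lensepr_error_spectrum"
  )
}

#' Double integral of a first-derivative spectrum
#'
#' Integrates the derivative signal once (trapezoid cumulative integral) to
#' recover the absorption, then integrates the absorption. The result is
#' proportional to the number of spins and is the normalization that makes
#' low-field amplitudes comparable between control and protein-added samples.
#'
#' @param spectrum An `epr_spectrum` or data frame with `field_G`, `intensity`.
#' @return A single number (arbitrary units x Gauss^2).
#' @examples
#' sp <- simulate_fluid_spectrum(fluid_params(), field_grid())
#' double_integral(sp)
#' @export
double_integral <- function(spectrum) {
  spectrum <- as_spectrum_input(spectrum)
  absorb <- pracma::cumtrapz(spectrum$field_G, spectrum$intensity)[, 1]
  pracma::trapz(spectrum$field_G, absorb)
}

#' Write a spectrum as two-column text
#'
#' Header lines are prefixed `#` and carry the regime plus any metadata as
#' `# key: value`; data lines are `field intensity` pairs.
#'
#' @param spectrum An `epr_spectrum`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spectrum, path) {
  spectrum <- as_spectrum_input(spectrum)
  meta <- spectrum_meta(spectrum)
  hdr <- c(
    sprintf("# regime: %s", spectrum_regime(spectrum)),
    vapply(
      names(meta), function(k) sprintf("# %s: %s", k, format(meta[[k]], digits = 15)),
      character(1)
    ),
    "# field_G intensity"
  )
  body <- sprintf("%.8f %.12e", spectrum$field_G, spectrum$intensity)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a spectrum written by [write_spectrum()]
#'
#' Accepts whitespace- or comma-delimited two-column numeric text with `#`
#' header lines.
#'
#' @param path File path.
#' @return An `epr_spectrum`.
#' @export
read_spectrum <- function(path) {
  lines <- readLines(path)
  is_hdr <- startsWith(trimws(lines), "#")
  meta <- list()
  regime <- "fluid"
  for (h in lines[is_hdr]) {
    m <- regmatches(h, regexec("^#\\s*([^:]+):\\s*(.*)$", h))[[1]]
    if (length(m) == 3) {
      key <- trimws(m[2]); val <- trimws(m[3])
      if (key == "regime") {
        regime <- val
      } else if (key != "field_G intensity") {
        num <- suppressWarnings(as.numeric(val))
        meta[[key]] <- if (is.na(num)) val else num
      }
    }
  }
  body <- lines[!is_hdr & nzchar(trimws(lines))]
  parts <- strsplit(trimws(body), "[,[:space:]]+")
  mat <- vapply(parts, function(p) as.numeric(p[1:2]), numeric(2))
  epr_spectrum(mat[1, ], mat[2, ], regime = regime, meta = meta)
}

#' @export
print.epr_spectrum <- function(x, ...) {
  cat(sprintf(
    "<epr_spectrum> %s regime, %d points, %.6g to %.6g G\n",
    spectrum_regime(x), nrow(x), min(x$field_G), max(x$field_G)
  ))
  NextMethod()
}

#' Plot an EPR spectrum
#'
#' @param object An `epr_spectrum`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.epr_spectrum <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object), ggplot2::aes(.data$field_G, .data$intensity)) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "Magnetic field (G)", y = "dA/dB (a.u.)",
      title = sprintf("%s-regime EPR spectrum", spectrum_regime(object))
    ) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.epr_spectrum
#' @param spectrum An `epr_spectrum`.
#' @export
plot_spectrum <- function(spectrum, ...) autoplot.epr_spectrum(spectrum, ...)
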