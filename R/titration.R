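#' Draw a vesicle hydrodynamic radius
#'
#' Truncated-normal draw (redrawn while non-positive); `sd_nm = 0` returns
#' the mean exactly. Typical values for the model lens-lipid vesicles are
#' about 56 nm (cholesterol mixing ratios 0 and 0.5) and about 59 nm
#' (mixing ratio 1.5).
#'
#' @param mean_nm Mean radius, nm (> 0).
#' @param sd_nm Standard deviation, nm (>= 0).
#' @param seed Integer seed.
#' @return A positive radius in nm.
#' @examples
#' sample_vesicle_rh(56, 0) # 56
#' @export
sample_vesicle_rh <- function(mean_nm, sd_nm = 0, seed = 1) {
  if (mean_nm <= 0 || sd_nm < 0) {
    abort("need `mean_nm` > 0 and `sd_nm` >= 0.", class = "lensepr_error_params")
  }
  if (sd_nm == 0) {
    return(mean_nm)
  }
  withr::with_seed(seed, {
    repeat {
      r <- rnorm(1, mean_nm, sd_nm)
      if (r > 0) break
    }
    r
  })
}

#' Simulate a full protein titration with known ground truth
#'
#' For every concentration `C` and replicate, the true occupancy follows the
#' one-site law `MSO(C) = MMSO * Ka * C / (1 + Ka * C)`; the fraction of all
#' labels affected is `MSO(C) * outer_fraction` (only outer-leaflet labels
#' can be reached), and that fraction — perturbed by Gaussian noise of SD
#' `design$noise_sd_mso` on the MSO scale for `C > 0` — sets the bound
#' fraction of the simulated two-component spectrum. Replicates additionally
#' share a small lognormal linewidth jitter emulating independent sample
#' preparation. `C = 0` rows are the exact protein-free controls.
#'
#' @param truth A [binding_truth()].
#' @param design A [titration_design()]; `design$seed` makes the dataset
#'   reproducible bit for bit.
#' @param geometry A [vesicle_geometry()].
#' @param unbound [fluid_params()] of the protein-free membrane.
#' @param bound Optional [fluid_params()] of the immobilized population
#'   (default [bound_params]`(unbound)`).
#' @param grid A [field_grid()].
#' @param protein,mixing_ratio Metadata recorded on every spectrum.
#'
#' @return An `epr_titration` tibble: one row per (concentration, replicate)
#'   with `true_mso_pct`, `sim_mso_pct` (the noise-perturbed value actually
#'   encoded in the trace), `bound_fraction`, and the spectrum as a list
#'   column. Ground truth and design are carried as attributes.
#' @examples
#' ds <- simulate_titration(
#'   binding_truth(60, 0.2),
#'   titration_design(n_replicates = 1, noise_sd_mso = 0, seed = 1),
#'   vesicle_geometry(56)
#' )
#' ds[, c("conc_uM", "true_mso_pct")]
#' @export
simulate_titration <- function(truth, design = titration_design(),
                               geometry = vesicle_geometry(),
                               unbound = fluid_params(), bound = NULL,
                               grid = field_grid(),
                               protein = "alphaA", mixing_ratio = 0) {
  stopifnot(
    inherits(truth, "binding_truth"), inherits(design, "titration_design"),
    inherits(geometry, "vesicle_geometry"), inherits(unbound, "fluid_params")
  )
  bound <- bound %||% bound_params(unbound)
  true_mso <- one_site_mso(design$concentrations_uM, truth$mmso_pct, truth$ka_per_uM)
  affected <- true_mso * geometry$outer_fraction
  if (any(affected > 100)) {
    abort("impossible condition: affected label fraction exceeds 100%.",
      class = "lensepr_error_params"
    )
  }
  rows <- withr::with_seed(design$seed, {
    out <- vector("list", design$n_replicates)
    for (r in seq_len(design$n_replicates)) {
      jit <- if (design$width_jitter_rel > 0) {
        exp(rnorm(1, 0, design$width_jitter_rel))
      } else {
        1
      }
      u_r <- fluid_params(
        unbound$center_G, unbound$hyperfine_G, unbound$widths_G * jit,
        unbound$rel_intensity, unbound$shape_mix
      )
      b_r <- fluid_params(
        bound$center_G, bound$hyperfine_G, bound$widths_G * jit,
        bound$rel_intensity, bound$shape_mix
      )
      sim_mso <- true_mso
      pos <- design$concentrations_uM > 0
      if (design$noise_sd_mso > 0 && any(pos)) {
        sim_mso[pos] <- sim_mso[pos] + rnorm(sum(pos), 0, design$noise_sd_mso)
      }
      sim_mso <- pmin(pmax(sim_mso, 0), 100)
      f <- sim_mso * geometry$outer_fraction / 100
      spectra <- map2(f, design$concentrations_uM, function(fi, ci) {
        simulate_two_component_spectrum(
          u_r, b_r, fi, grid,
          meta = list(
            sample_id = sprintf("%s_r%g_rep%d_c%g", protein, mixing_ratio, r, ci),
            protein = protein, concentration_uM = ci,
            mixing_ratio = mixing_ratio, replicate = r
          )
        )
      })
      out[[r]] <- tibble(
        protein = protein, mixing_ratio = mixing_ratio,
        conc_uM = design$concentrations_uM, replicate = r,
        true_mso_pct = true_mso, sim_mso_pct = sim_mso,
        bound_fraction = f, spectrum = spectra
      )
    }
    out
  })
  ds <- bind_rows(rows)
  attr(ds, "truth") <- truth
  attr(ds, "design") <- design
  attr(ds, "geometry") <- geometry
  attr(ds, "unbound") <- unbound
  attr(ds, "bound") <- bound
  class(ds) <- c("epr_titration", class(ds))
  ds
}

#' Analyze a titration into MSO points and a one-site fit
#'
#' The full measurement chain: every spectrum is baseline-corrected, its
#' spin-count-normalized low-field amplitude extracted, the amplitude loss
#' relative to the same replicate's own protein-free control converted to
#' the percent of labels affected and then — through the outer-leaflet
#' correction — to MSO; finally the pooled points are fitted with the
#' one-site ligand-binding model.
#'
#' @param data An `epr_titration` tibble from [simulate_titration()], or any
#'   tibble with columns `conc_uM`, `replicate` and a `spectrum` list column
#'   (e.g. from [read_titration()]). Each replicate must contain exactly one
#'   `conc_uM == 0` control.
#' @param geometry A [vesicle_geometry()]; defaults to the dataset attribute
#'   when present.
#' @param noise_floor_pct Zero-binding threshold passed to [fit_one_site()].
#' @param ... Passed to [locate_lines()] (e.g. `min_sep_G`, `smooth_window`).
#'
#' @return A `titration_analysis` object: `$points` (tibble of per-sample
#'   MSO), `$fit` (a `binding_fit`), `$n_clamped` (negative affected values
#'   clamped to zero). `tidy()` returns the points, `glance()` the fit
#'   summary, `autoplot()` the fitted curve.
#' @examples
#' ds <- simulate_titration(
#'   binding_truth(60, 0.2),
#'   titration_design(n_replicates = 1, noise_sd_mso = 0, seed = 1)
#' )
#' fit <- analyze_titration(ds)
#' glance(fit)
#' @export
analyze_titration <- function(data, geometry = NULL, noise_floor_pct = 2, ...) {
  if (!is.data.frame(data) || !all(c("conc_uM", "replicate", "spectrum") %in% names(data))) {
    abort("`data` must have columns `conc_uM`, `replicate` and `spectrum`.",
      class = "lensepr_error_binding"
    )
  }
  geometry <- geometry %||% attr(data, "geometry") %||% vesicle_geometry()
  condition <- paste0(
    if ("protein" %in% names(data)) paste0(unique(data$protein), collapse = "/") else "?",
    " @ mixing ratio ",
    if ("mixing_ratio" %in% names(data)) paste0(unique(data$mixing_ratio), collapse = "/") else "?"
  )
  n_clamped <- 0L
  rows <- list()
  for (r in unique(data$replicate)) {
    sub <- data[data$replicate == r, ]
    ctrl <- sub[sub$conc_uM == 0, ]
    if (nrow(ctrl) != 1) {
      abort(
        sprintf(
          "condition %s, replicate %s: expected exactly one concentration-0 control, found %d.",
          condition, r, nrow(ctrl)
        ),
        class = "lensepr_error_missing_control"
      )
    }
    amp <- map_dbl(sub$spectrum, function(sp) {
      normalized_low_field_height(baseline_correct(sp), ...)
    })
    u0 <- amp[sub$conc_uM == 0]
    affected <- withCallingHandlers(
      percent_labels_affected(u0, amp),
      lensepr_warning_clamp = function(w) {
        n_clamped <<- n_clamped + 1L
        invokeRestart("muffleWarning")
      }
    )
    rows[[as.character(r)]] <- tibble(
      conc_uM = sub$conc_uM, replicate = r,
      u0b0_amp = amp, affected_pct = affected,
      mso_pct = mso(affected, geometry)
    )
  }
  points <- bind_rows(rows)
  fit <- fit_one_site(points, noise_floor_pct = noise_floor_pct)
  structure(
    list(points = points, fit = fit, geometry = geometry, n_clamped = n_clamped),
    class = "titration_analysis"
  )
}

#' @export
print.titration_analysis <- function(x, ...) {
  cat(sprintf(
    "<titration_analysis> %d points, %d replicate(s)%s\n",
    nrow(x$points), length(unique(x$points$replicate)),
    if (x$n_clamped > 0) sprintf(" (%d clamped)", x$n_clamped) else ""
  ))
  print(x$fit)
  invisible(x)
}

#' @export
tidy.titration_analysis <- function(x, ...) x$points

#' @export
glance.titration_analysis <- function(x, ...) {
  cbind(tidyr::pivot_wider(tidy(x$fit),
    names_from = "term",
    values_from = c("estimate", "std.error")
  ), glance(x$fit)) |> as_tibble()
}

#' @export
autoplot.titration_analysis <- function(object, ...) autoplot(object$fit, ...)

#' Write a titration dataset as spectrum files plus a manifest
#'
#' Each spectrum goes to a two-column text file; `manifest.tsv` lists one row
#' per file with the sample metadata.
#'
#' @param data An `epr_titration` tibble.
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_titration <- function(data, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- pmap(
    list(data$spectrum, seq_len(nrow(data))),
    function(sp, i) {
      meta <- spectrum_meta(sp)
      file <- sprintf("spectrum_%03d.txt", i)
      write_spectrum(sp, file.path(dir, file))
      tibble(
        file = file,
        sample_id = meta$sample_id %||% sprintf("s%03d", i),
        regime = spectrum_regime(sp),
        protein = meta$protein %||% NA_character_,
        concentration_uM = meta$concentration_uM %||% NA_real_,
        mixing_ratio = meta$mixing_ratio %||% NA_real_,
        replicate = meta$replicate %||% NA_integer_
      )
    }
  )
  manifest <- bind_rows(rows)
  path <- file.path(dir, "manifest.tsv")
  readr::write_tsv(manifest, path)
  invisible(path)
}

#' Read a titration dataset from a manifest
#'
#' @param manifest Path to a `manifest.tsv` written by [write_titration()]
#'   (or a data frame with the same columns; relative `file` paths are
#'   resolved against `dir`).
#' @param dir Directory containing the spectrum files (defaults to the
#'   manifest's directory).
#' @return A tibble with `protein`, `mixing_ratio`, `conc_uM`, `replicate`
#'   and a `spectrum` list column, ready for [analyze_titration()].
#' @export
read_titration <- function(manifest, dir = NULL) {
  if (is.character(manifest)) {
    dir <- dir %||% dirname(manifest)
    manifest <- readr::read_tsv(manifest, show_col_types = FALSE)
  }
  if (is.null(dir)) dir <- "."
  spectra <- map(manifest$file, function(f) read_spectrum(file.path(dir, f)))
  tibble(
    protein = manifest$protein,
    mixing_ratio = manifest$mixing_ratio,
    conc_uM = manifest$concentration_uM,
    replicate = manifest$replicate,
    spectrum = spectra
  )
}
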