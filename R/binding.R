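#' Outer-leaflet fraction of a spherical vesicle
#'
#' For a small unilamellar vesicle of hydrodynamic radius `rh_nm` and bilayer
#' thickness `bilayer_thickness_nm`, the fraction of lipids (and hence of
#' cholestane spin labels) residing on the outer leaflet is the area ratio
#' `Ro^2 / (Ro^2 + Ri^2)` with `Ro = rh_nm` and
#' `Ri = rh_nm - bilayer_thickness_nm`. At Rh = 56 nm and 4 nm thickness this
#' is 0.537, i.e. about 54% — only these outer-surface labels can be affected
#' by protein binding.
#'
#' @param rh_nm Hydrodynamic radius, nm.
#' @param bilayer_thickness_nm Bilayer thickness, nm (default 4).
#' @return A proportion in (0.5, 1).
#' @examples
#' round(100 * outer_leaflet_fraction(56, 4)) # 54
#' @export
outer_leaflet_fraction <- function(rh_nm, bilayer_thickness_nm = 4) {
  if (any(bilayer_thickness_nm <= 0) || any(rh_nm <= bilayer_thickness_nm)) {
    abort("need `rh_nm` > `bilayer_thickness_nm` > 0.", class = "lensepr_error_geometry")
  }
  ro <- rh_nm
  ri <- rh_nm - bilayer_thickness_nm
  ro^2 / (ro^2 + ri^2)
}

#' Vesicle geometry and the MSO correction factor
#'
#' Bundles the vesicle size with the derived outer-leaflet fraction and the
#' correction factor `1 / outer_fraction` by which the percent of affected
#' labels is scaled to the percentage of (outer) membrane surface occupied.
#' With the default geometry (Rh = 56 nm, thickness 4 nm) the fraction is
#' 0.537 and the correction factor about 100/54.
#'
#' @inheritParams outer_leaflet_fraction
#' @param outer_fraction Optional override of the computed fraction (for
#'   example the rounded 0.54 convention); must lie in (0.5, 1).
#' @return A `vesicle_geometry` object with fields `rh_nm`,
#'   `bilayer_thickness_nm`, `outer_fraction`, `correction_factor`.
#' @examples
#' vesicle_geometry(56)
#' @export
vesicle_geometry <- function(rh_nm = 56, bilayer_thickness_nm = 4,
                             outer_fraction = NULL) {
  frac <- outer_fraction %||% outer_leaflet_fraction(rh_nm, bilayer_thickness_nm)
  if (frac <= 0.5 || frac >= 1) {
    abort("`outer_fraction` must be in (0.5, 1).", class = "lensepr_error_geometry")
  }
  structure(
    list(
      rh_nm = as.numeric(rh_nm),
      bilayer_thickness_nm = as.numeric(bilayer_thickness_nm),
      outer_fraction = as.numeric(frac),
      correction_factor = 1 / as.numeric(frac)
    ),
    class = "vesicle_geometry"
  )
}

#' @export
print.vesicle_geometry <- function(x, ...) {
  cat(sprintf(
    "<vesicle_geometry> Rh = %.3g nm, thickness = %.3g nm, outer fraction = %.3f (factor %.4g)\n",
    x$rh_nm, x$bilayer_thickness_nm, x$outer_fraction, x$correction_factor
  ))
  invisible(x)
}

#' Percent of spin labels affected by protein binding
#'
#' The amplitude-loss ratio `(U0 - (U0 + B0)) / U0 * 100`: `u0_amp` is the
#' normalized low-field amplitude of the protein-free control and `u0b0_amp`
#' that of the protein-added sample (both from
#' [normalized_low_field_height()], i.e. on the same spin-count
#' normalization). Small negative values — the sample amplitude exceeding the
#' control's through noise — are clamped to 0 with a warning.
#'
#' @param u0_amp Control amplitude (> 0).
#' @param u0b0_amp Sample amplitude.
#' @return Percentage of labels affected, in \[0, 100\].
#' @examples
#' percent_labels_affected(1, 0.8) # 20
#' @export
percent_labels_affected <- function(u0_amp, u0b0_amp) {
  if (any(u0_amp <= 0)) {
    abort("`u0_amp` must be positive.", class = "lensepr_error_binding")
  }
  pct <- (u0_amp - u0b0_amp) / u0_amp * 100
  if (any(pct < 0)) {
    warn(sprintf(
      "%d negative affected-percentage value(s) clamped to 0 (sample amplitude above control).",
      sum(pct < 0)
    ), class = "lensepr_warning_clamp")
    pct <- pmax(pct, 0)
  }
  pct
}

#' Percentage of membrane surface occupied (MSO)
#'
#' Scales the percent of affected labels by the outer-leaflet correction
#' factor: only outer-surface labels can be touched by bound protein, so
#' `MSO = percent_affected / outer_fraction` (the 100/54 correction for the
#' default vesicle geometry). Values that would exceed 100 are clamped with a
#' warning.
#'
#' @param percent_affected Percent of labels affected, from
#'   [percent_labels_affected()].
#' @param geometry A [vesicle_geometry()].
#' @return MSO in percent, in \[0, 100\].
#' @examples
#' mso(27, vesicle_geometry(outer_fraction = 0.54)) # 50
#' @export
mso <- function(percent_affected, geometry = vesicle_geometry()) {
  stopifnot(inherits(geometry, "vesicle_geometry"))
  if (any(percent_affected < 0)) {
    abort("`percent_affected` must be non-negative.", class = "lensepr_error_binding")
  }
  out <- percent_affected * geometry$correction_factor
  if (any(out > 100)) {
    warn(sprintf(
      "%d MSO value(s) above 100%% clamped (affected fraction beyond the outer leaflet).",
      sum(out > 100)
    ), class = "lensepr_warning_clamp")
    out <- pmin(out, 100)
  }
  out
}

#' Fit the one-site ligand-binding model
#'
#' Nonlinear least squares of `MSO(C) = MMSO * Ka * C / (1 + Ka * C)` on
#' pooled titration points, with bounds MMSO in \[0, 100\] and Ka >= 0 and
#' multi-start initialization (Ka seeds spanning 1e-3 to 10 per uM). If the
#' responses are at the noise level — the mean MSO at or below
#' `noise_floor_pct`, which any all-below-threshold dataset satisfies — the
#' saturable model is unidentifiable and the fit returns MMSO = 0, Ka = 0
#' with `converged = TRUE`: the zero-binding convention used for
#' cholesterol-saturated membranes.
#'
#' @param points Data frame with columns `conc_uM` and `mso_pct` (a
#'   `replicate` column is carried through if present). At least 4 distinct
#'   concentrations including 0.
#' @param noise_floor_pct Zero-binding threshold in MSO percentage points
#'   (default 2).
#'
#' @return A `binding_fit` object; see [tidy()] and [glance()] methods.
#' @examples
#' pts <- tibble::tibble(conc_uM = c(0, 2, 5, 10, 20, 40, 60))
#' pts$mso_pct <- one_site_mso(pts$conc_uM, 60, 0.2)
#' fit <- fit_one_site(pts)
#' tidy(fit)
#' @export
fit_one_site <- function(points, noise_floor_pct = 2) {
  if (!is.data.frame(points) || !all(c("conc_uM", "mso_pct") %in% names(points))) {
    abort("`points` must have columns `conc_uM` and `mso_pct`.",
      class = "lensepr_error_binding"
    )
  }
  points <- as_tibble(points)
  concs <- sort(unique(points$conc_uM))
  if (length(concs) < 4 || !any(concs == 0)) {
    abort("need >= 4 distinct concentrations including 0.",
      class = "lensepr_error_binding"
    )
  }
  n_pts <- nrow(points)

  # Zero-binding convention: responses indistinguishable from the noise
  # floor make the saturable model unidentifiable. Triggered when the mean
  # response is at or below the floor (noise on a true-zero titration is
  # clamped at 0, so its mean sits well under the floor while single points
  # may poke above it); any dataset with every point below the floor
  # necessarily triggers too.
  if (mean(points$mso_pct) <= noise_floor_pct) {
    return(new_binding_fit(
      mmso_pct = 0, mmso_se = NA_real_, ka_per_uM = 0, ka_se = NA_real_,
      r_squared = NA_real_, converged = TRUE, n_points = n_pts,
      points = points, zero_binding = TRUE
    ))
  }

  ka_starts <- 10^seq(-3, 1, length.out = 9)
  mmso_start <- min(100, max(points$mso_pct))
  best <- NULL
  best_rss <- Inf
  diagnostics <- character()
  for (ka0 in ka_starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        mso_pct ~ mmso * ka * conc_uM / (1 + ka * conc_uM),
        data = points,
        start = list(mmso = mmso_start, ka = ka0),
        lower = c(mmso = 0, ka = 0), upper = c(mmso = 100, ka = Inf),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) e
    )
    if (inherits(fit, "error")) {
      diagnostics <- c(diagnostics, conditionMessage(fit))
      next
    }
    rss <- sum(stats::resid(fit)^2)
    if (rss < best_rss) {
      best <- fit
      best_rss <- rss
    }
  }

  if (is.null(best)) {
    return(new_binding_fit(
      mmso_pct = NA_real_, mmso_se = NA_real_, ka_per_uM = NA_real_,
      ka_se = NA_real_, r_squared = NA_real_, converged = FALSE,
      n_points = n_pts, points = points, zero_binding = FALSE,
      diagnostics = unique(diagnostics)
    ))
  }

  est <- coef(best)
  se <- tryCatch(summary(best)$coefficients[, "Std. Error"],
    error = function(e) c(mmso = NA_real_, ka = NA_real_)
  )
  tss <- sum((points$mso_pct - mean(points$mso_pct))^2)
  r2 <- if (tss > 0) 1 - best_rss / tss else NA_real_
  new_binding_fit(
    mmso_pct = unname(est["mmso"]), mmso_se = unname(se["mmso"]),
    ka_per_uM = unname(est["ka"]), ka_se = unname(se["ka"]),
    r_squared = r2, converged = TRUE, n_points = n_pts,
    points = points, zero_binding = FALSE, nls = best
  )
}

new_binding_fit <- function(mmso_pct, mmso_se, ka_per_uM, ka_se, r_squared,
                            converged, n_points, points, zero_binding,
                            nls = NULL, diagnostics = character()) {
  structure(
    list(
      mmso_pct = mmso_pct, mmso_se = mmso_se,
      ka_per_uM = ka_per_uM, ka_se = ka_se,
      r_squared = r_squared, converged = converged, n_points = n_points,
      points = points, zero_binding = zero_binding, nls = nls,
      diagnostics = diagnostics
    ),
    class = "binding_fit"
  )
}

#' @export
print.binding_fit <- function(x, ...) {
  cat("<binding_fit> one-site ligand binding\n")
  cat(sprintf(
    "  MMSO = %.3g +/- %.2g %%   Ka = %.4g +/- %.2g /uM\n",
    x$mmso_pct, x$mmso_se, x$ka_per_uM, x$ka_se
  ))
  cat(sprintf(
    "  R^2 = %.4g, n = %d, converged = %s%s\n",
    x$r_squared, x$n_points, x$converged,
    if (isTRUE(x$zero_binding)) " (zero-binding convention)" else ""
  ))
  if (!x$converged && length(x$diagnostics)) {
    cat("  diagnostics:", paste(x$diagnostics, collapse = "; "), "\n")
  }
  invisible(x)
}

#' Tidy a one-site binding fit
#' @param x A `binding_fit`.
#' @param ... Unused.
#' @return A tibble with one row per parameter (`mmso_pct`, `ka_per_uM`).
#' @export
tidy.binding_fit <- function(x, ...) {
  tibble(
    term = c("mmso_pct", "ka_per_uM"),
    estimate = c(x$mmso_pct, x$ka_per_uM),
    std.error = c(x$mmso_se, x$ka_se)
  )
}

#' @rdname tidy.binding_fit
#' @return For `glance()`: a one-row tibble of fit summaries.
#' @export
glance.binding_fit <- function(x, ...) {
  tibble(
    r.squared = x$r_squared, converged = x$converged,
    zero.binding = x$zero_binding, nobs = x$n_points
  )
}

#' @rdname tidy.binding_fit
#' @param data Optional data frame of points to augment (defaults to the
#'   fitted points).
#' @return For `augment()`: the points with a `.fitted` MSO column.
#' @export
augment.binding_fit <- function(x, data = NULL, ...) {
  data <- as_tibble(data %||% x$points)
  data$.fitted <- one_site_mso(data$conc_uM, x$mmso_pct, x$ka_per_uM)
  data
}

#' Plot a binding fit
#'
#' MSO points against protein concentration with the fitted one-site curve.
#'
#' @param object A `binding_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.binding_fit <- function(object, ...) {
  pts <- as_tibble(object$points)
  curve <- tibble(conc_uM = seq(0, max(pts$conc_uM), length.out = 200))
  curve$mso_pct <- one_site_mso(curve$conc_uM, object$mmso_pct, object$ka_per_uM)
  ggplot2::ggplot(pts, ggplot2::aes(.data$conc_uM, .data$mso_pct)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = curve, colour = "red3") +
    ggplot2::labs(
      x = "Protein concentration (uM)", y = "Membrane surface occupied (%)",
      title = sprintf(
        "One-site fit: MMSO = %.1f%%, Ka = %.3g /uM",
        object$mmso_pct, object$ka_per_uM
      )
    ) +
    ggplot2::theme_minimal()
}
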