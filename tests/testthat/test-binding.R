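test_that("percent of affected labels is the amplitude-loss ratio with clamping", {
  expect_equal(percent_labels_affected(1, 1), 0)
  expect_equal(percent_labels_affected(1, 0.8), 20)
  expect_warning(
    out <- percent_labels_affected(1, 1.03),
    class = "lensepr_warning_clamp"
  )
  expect_equal(out, 0)
  expect_error(percent_labels_affected(0, 0.5), class = "lensepr_error_binding")
})

test_that("outer-leaflet fraction is the spherical area ratio", {
  oracle <- function(rh, t) rh^2 / (rh^2 + (rh - t)^2)
  expect_equal(outer_leaflet_fraction(56, 4), oracle(56, 4))
  expect_equal(round(100 * outer_leaflet_fraction(56, 4)), 54)
  expect_equal(outer_leaflet_fraction(59, 4), oracle(59, 4))
  expect_equal(round(outer_leaflet_fraction(59, 4), 3), 0.535)
  # equal leaflets in the thin-shell limit
  expect_equal(outer_leaflet_fraction(56, 1e-9), 0.5, tolerance = 1e-9)
  expect_error(outer_leaflet_fraction(3, 4), class = "lensepr_error_geometry")
})

test_that("vesicle geometry carries the reciprocal correction factor", {
  g <- vesicle_geometry(56, 4)
  expect_equal(g$correction_factor, 1 / g$outer_fraction)
  expect_equal(g$correction_factor, 100 / 54, tolerance = 0.01)
})

test_that("MSO scales affected labels by the outer-leaflet correction", {
  g54 <- vesicle_geometry(outer_fraction = 0.54)
  expect_equal(mso(27, g54), 50)
  expect_equal(mso(0, g54), 0)
  expect_equal(mso(54, g54), 100)
  expect_warning(capped <- mso(60, g54), class = "lensepr_warning_clamp")
  expect_equal(capped, 100)
})

test_that("one-site fit recovers noiseless truth to high precision", {
  concs <- c(0, 1, 2.5, 5, 10, 20, 40, 60)
  pts <- tibble::tibble(conc_uM = concs, mso_pct = one_site_mso(concs, 60, 0.2))
  fit <- fit_one_site(pts)
  expect_true(fit$converged)
  expect_equal(fit$mmso_pct, 60, tolerance = 1e-6)
  expect_equal(fit$ka_per_uM, 0.2, tolerance = 1e-6)
  expect_gt(fit$r_squared, 1 - 1e-10)
  # half-saturation property of the fitted curve
  expect_equal(one_site_mso(1 / fit$ka_per_uM, fit$mmso_pct, fit$ka_per_uM),
    fit$mmso_pct / 2,
    tolerance = 1e-9
  )
  td <- tidy(fit)
  expect_identical(td$term, c("mmso_pct", "ka_per_uM"))
  expect_equal(td$estimate, c(fit$mmso_pct, fit$ka_per_uM))
})

test_that("one-site fit is invariant to point order and replicate relabeling", {
  concs <- rep(c(0, 2.5, 5, 10, 20, 40, 60), 2)
  set.seed(42)
  pts <- tibble::tibble(
    conc_uM = concs,
    mso_pct = pmax(one_site_mso(concs, 45, 0.3) + rnorm(length(concs), 0, 2), 0),
    replicate = rep(1:2, each = 7)
  )
  f1 <- fit_one_site(pts)
  f2 <- fit_one_site(pts[sample(nrow(pts)), ])
  f3 <- fit_one_site(dplyr::mutate(pts, replicate = 3 - replicate))
  expect_equal(f1$mmso_pct, f2$mmso_pct, tolerance = 1e-8)
  expect_equal(f1$ka_per_uM, f2$ka_per_uM, tolerance = 1e-8)
  expect_equal(f1$mmso_pct, f3$mmso_pct, tolerance = 1e-12)
})

test_that("responses at the noise floor trigger the zero-binding convention", {
  pts <- tibble::tibble(conc_uM = c(0, 5, 15, 30, 60), mso_pct = c(0, 0.5, 1.2, 0.8, 1.9))
  fit <- fit_one_site(pts)
  expect_true(fit$converged)
  expect_true(fit$zero_binding)
  expect_identical(fit$mmso_pct, 0)
  expect_identical(fit$ka_per_uM, 0)
})

test_that("degenerate designs are rejected", {
  expect_error(
    fit_one_site(tibble::tibble(conc_uM = c(0, 5, 10), mso_pct = c(0, 10, 20))),
    class = "lensepr_error_binding"
  )
  expect_error(
    fit_one_site(tibble::tibble(conc_uM = c(1, 5, 10, 20), mso_pct = c(5, 10, 20, 30))),
    class = "lensepr_error_binding"
  )
})

test_that("the Eq-(1)+(2) chain recovers the simulated outer-leaflet bound fraction", {
  # brute-force oracle: a fraction f of all labels is bound, i.e. a fraction
  # f / outer_fraction of outer-leaflet labels; the pipeline must report
  # MSO = 100 * f / outer_fraction
  u <- fluid_params()
  b <- bound_params(u)
  geom <- vesicle_geometry(56)
  g <- default_grid
  ctrl <- normalized_low_field_height(baseline_correct(
    simulate_two_component_spectrum(u, b, 0, g)
  ))
  for (f in c(0.05, 0.15, 0.3)) {
    sp <- simulate_two_component_spectrum(u, b, f, g)
    amp <- normalized_low_field_height(baseline_correct(sp))
    got <- mso(percent_labels_affected(ctrl, amp), geom)
    expect_equal(got, 100 * f / geom$outer_fraction, tolerance = 0.02)
  }
})

test_that("noiseless titration analysis recovers MMSO within 1 pp and Ka within 5 percent", {
  ds <- simulate_titration(
    binding_truth(60, 0.2),
    titration_design(n_replicates = 1, noise_sd_mso = 0, width_jitter_rel = 0, seed = 1),
    vesicle_geometry(56)
  )
  ana <- analyze_titration(ds)
  expect_true(ana$fit$converged)
  expect_lt(abs(ana$fit$mmso_pct - 60), 1)
  expect_lt(abs(ana$fit$ka_per_uM - 0.2) / 0.2, 0.05)
})

test_that("a no-binding titration yields MMSO = 0 and Ka = 0", {
  ds <- simulate_titration(
    binding_truth(0, 0),
    titration_design(n_replicates = 1, noise_sd_mso = 0, width_jitter_rel = 0, seed = 1),
    vesicle_geometry(56)
  )
  fit <- analyze_titration(ds)$fit
  expect_identical(fit$mmso_pct, 0)
  expect_identical(fit$ka_per_uM, 0)
  expect_true(fit$converged)
})

test_that("MSO points are invariant to a uniform rescaling of all spectra", {
  ds <- simulate_titration(
    binding_truth(40, 0.25),
    titration_design(
      concentrations_uM = c(0, 5, 15, 40), n_replicates = 1,
      noise_sd_mso = 0, width_jitter_rel = 0, seed = 2
    ),
    vesicle_geometry(56)
  )
  scaled <- ds
  scaled$spectrum <- lapply(ds$spectrum, function(sp) {
    epr_spectrum(sp$field_G, 7.3 * sp$intensity, meta = spectrum_meta(sp))
  })
  p1 <- analyze_titration(ds)$points
  p2 <- analyze_titration(scaled)$points
  expect_equal(p1$mso_pct, p2$mso_pct, tolerance = 1e-9)
})

test_that("a missing protein-free control is reported with its condition", {
  ds <- simulate_titration(
    binding_truth(40, 0.25),
    titration_design(
      concentrations_uM = c(0, 5, 15, 40), n_replicates = 1,
      noise_sd_mso = 0, seed = 2
    ),
    vesicle_geometry(56),
    protein = "alphaB", mixing_ratio = 0.5
  )
  broken <- ds[ds$conc_uM > 0, ]
  expect_error(
    analyze_titration(broken),
    regexp = "alphaB.*0\\.5",
    class = "lensepr_error_missing_control"
  )
})
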