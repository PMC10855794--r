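test_that("three equal lines give a symmetric spectrum with h+/h0 = 1", {
  sp <- simulate_fluid_spectrum(symmetric_params(), default_grid)
  f <- locate_lines(sp)
  expect_equal(f$mobility, 1, tolerance = 1e-3)
  expect_equal(f$h_plus, f$h_zero, tolerance = 1e-3)
})

test_that("doubling a line's width at fixed integrated intensity cuts its pp height fourfold", {
  # Closed form: derivative pseudo-Voigt pp amplitude scales as 1/width^2.
  # Hyperfine 30 G keeps neighbour-tail overlap negligible for the oracle.
  for (mix in c(0, 1)) {
    narrow <- fluid_params(
      hyperfine_G = 30, widths_G = c(2, 2, 2),
      shape_mix = mix
    )
    wide <- fluid_params(
      hyperfine_G = 30, widths_G = c(4, 2, 2),
      shape_mix = mix
    )
    h_narrow <- locate_lines(simulate_fluid_spectrum(narrow, default_grid))$h_plus
    h_wide <- locate_lines(simulate_fluid_spectrum(wide, default_grid))$h_plus
    expect_equal(h_narrow / h_wide, 4, tolerance = 0.01)
    # and both match the analytic amplitude (weight 1/3 per line)
    expect_equal(h_narrow, analytic_pp_height(2, mix, 1 / 3), tolerance = 0.01)
    expect_equal(h_wide, analytic_pp_height(4, mix, 1 / 3), tolerance = 0.01)
  }
})

test_that("pure Lorentzian extrema sit half a pp width beyond the line centers", {
  # A = 16 G, all pp widths 2 G: low-field maximum to high-field minimum
  # spans 2A + width = 34 G.
  sp <- simulate_fluid_spectrum(symmetric_params(2, 16, shape_mix = 1), default_grid)
  f <- locate_lines(sp)
  expect_equal(f$max_splitting_G, 34, tolerance = default_grid$delta_G)
})

test_that("unresolvable lines are rejected", {
  bad <- fluid_params(hyperfine_G = 5, widths_G = c(3, 3, 3))
  expect_error(
    simulate_fluid_spectrum(bad, default_grid),
    class = "lensepr_error_unresolved"
  )
})

test_that("two-component spectrum reduces to its pure endpoints", {
  u <- symmetric_params(2, 16)
  b <- fluid_params(hyperfine_G = 16, widths_G = c(3, 3, 3))
  g <- default_grid
  s0 <- simulate_two_component_spectrum(u, b, 0, g)
  s1 <- simulate_two_component_spectrum(u, b, 1, g)
  expect_equal(s0$intensity, simulate_fluid_spectrum(u, g)$intensity)
  expect_equal(s1$intensity, simulate_fluid_spectrum(b, g)$intensity)
})

test_that("a bound component no broader than the unbound one is rejected", {
  u <- symmetric_params(2, 16)
  expect_error(
    simulate_two_component_spectrum(u, u, 0.3, default_grid),
    class = "lensepr_error_immobilization"
  )
  narrower <- fluid_params(hyperfine_G = 16, widths_G = c(1.5, 3, 3))
  expect_error(
    simulate_two_component_spectrum(u, narrower, 0.3, default_grid),
    class = "lensepr_error_immobilization"
  )
})

test_that("partial binding lowers the low-field line while conserving the double integral", {
  u <- fluid_params() # study defaults, Gaussian lines
  b <- bound_params(u, width_scale = 3)
  g <- default_grid
  h <- vapply(c(0, 0.3, 1), function(f) {
    locate_lines(simulate_two_component_spectrum(u, b, f, g))$h_plus
  }, numeric(1))
  expect_lt(h[2], h[1])
  expect_gt(h[2], h[3])
  di <- vapply(c(0, 0.3, 1), function(f) {
    double_integral(simulate_two_component_spectrum(u, b, f, g))
  }, numeric(1))
  expect_lt(abs(di[2] - di[1]) / abs(di[1]), 1e-9)
  expect_lt(abs(di[3] - di[1]) / abs(di[1]), 1e-9)
})

test_that("double integral is conserved under width changes at fixed intensity weights", {
  g <- default_grid
  di1 <- double_integral(simulate_fluid_spectrum(fluid_params(widths_G = c(2.4, 2.0, 2.8)), g))
  di2 <- double_integral(simulate_fluid_spectrum(fluid_params(widths_G = c(4.8, 3.1, 5.2)), g))
  expect_lt(abs(di1 - di2) / abs(di1), 1e-9)
})

test_that("low-field pp height is monotone non-increasing in the bound fraction", {
  u <- fluid_params()
  b <- bound_params(u)
  h <- vapply(seq(0, 0.6, by = 0.1), function(f) {
    locate_lines(simulate_two_component_spectrum(u, b, f, default_grid))$h_plus
  }, numeric(1))
  expect_true(all(diff(h) <= 0))
})

test_that("rigid-limit simulator obeys its extrema-separation law", {
  # documented law: separation = 2 Az + outer width
  sp <- simulate_rigid_spectrum(rigid_params(Az_G = 33.5, outer_width_G = 3), rigid_grid)
  expect_equal(rigid_limit_2az(sp)$two_Az_G, 70, tolerance = rigid_grid$delta_G)
  # halving the width shrinks the separation by exactly the width change
  sp2 <- simulate_rigid_spectrum(rigid_params(Az_G = 33.5, outer_width_G = 1.5), rigid_grid)
  expect_equal(
    rigid_limit_2az(sp)$two_Az_G - rigid_limit_2az(sp2)$two_Az_G,
    1.5,
    tolerance = 2 * rigid_grid$delta_G
  )
})

test_that("rigid-limit 2Az is invariant to a shift of the spectral center", {
  a <- simulate_rigid_spectrum(rigid_params(center_G = 3340, Az_G = 33.5), rigid_grid)
  b <- simulate_rigid_spectrum(rigid_params(center_G = 3350, Az_G = 33.5), rigid_grid)
  # identical up to the sub-grid parabolic-interpolation residual (~1e-4 G)
  expect_lt(abs(rigid_limit_2az(a)$two_Az_G - rigid_limit_2az(b)$two_Az_G), 1e-3)
})

test_that("a too-narrow grid for the rigid spectrum is rejected", {
  expect_error(
    simulate_rigid_spectrum(rigid_params(Az_G = 33.5), field_grid(3320, 3360, 256)),
    class = "lensepr_error_grid"
  )
})

test_that("the one-site law passes through its anchor points", {
  expect_equal(one_site_mso(0, 60, 0.2), 0)
  expect_equal(one_site_mso(1 / 0.2, 60, 0.2), 30) # half saturation at C = 1/Ka
  expect_equal(one_site_mso(5, 60, 0.2), 30) # direct evaluation
  # asymptote: within 0.2 pp of the plateau at C = 1000/Ka
  expect_lt(60 - one_site_mso(1000 / 0.2, 60, 0.2), 0.2)
  # monotone in concentration
  expect_true(all(diff(one_site_mso(seq(0, 60, 2), 60, 0.2)) >= 0))
})

test_that("titration controls are exact and ground truth follows the one-site law", {
  ds <- simulate_titration(
    binding_truth(60, 0.2),
    titration_design(n_replicates = 1, noise_sd_mso = 0, width_jitter_rel = 0, seed = 1),
    vesicle_geometry(56)
  )
  ctrl <- ds$spectrum[[which(ds$conc_uM == 0)]]
  free <- simulate_fluid_spectrum(fluid_params(), field_grid())
  expect_equal(ctrl$intensity, free$intensity)
  expect_equal(ds$true_mso_pct, one_site_mso(ds$conc_uM, 60, 0.2))
  expect_equal(ds$bound_fraction, ds$sim_mso_pct * vesicle_geometry(56)$outer_fraction / 100)
})

test_that("the same seed reproduces a titration dataset exactly", {
  mk <- function() {
    simulate_titration(
      binding_truth(40, 0.15),
      titration_design(
        concentrations_uM = c(0, 5, 15, 40), n_replicates = 2,
        noise_sd_mso = 2, seed = 11
      ),
      vesicle_geometry(56)
    )
  }
  a <- mk()
  b <- mk()
  expect_identical(serialize(a, NULL), serialize(b, NULL))
})

test_that("vesicle radius sampling is truncated, seeded and degenerate at sd 0", {
  expect_identical(sample_vesicle_rh(56, 0), 56)
  expect_identical(sample_vesicle_rh(59, 0), 59)
  expect_identical(sample_vesicle_rh(56, 2, seed = 1), sample_vesicle_rh(56, 2, seed = 1))
  expect_gt(sample_vesicle_rh(0.5, 5, seed = 4), 0)
  expect_error(sample_vesicle_rh(-1, 1), class = "lensepr_error_params")
})
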