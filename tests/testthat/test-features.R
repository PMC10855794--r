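test_that("baseline correction removes an added linear ramp exactly", {
  sp <- simulate_fluid_spectrum(fluid_params(), default_grid)
  ramp_a <- 0.02
  ramp_b <- 5e-4
  ramped <- epr_spectrum(sp$field_G, sp$intensity + ramp_a + ramp_b * (sp$field_G - 3340))
  fixed <- baseline_correct(ramped)
  ramp_amp <- max(abs(ramp_a + ramp_b * (sp$field_G - 3340)))
  expect_lt(max(abs(fixed$intensity - sp$intensity)), 1e-8 * ramp_amp)
})

test_that("baseline correction leaves clean spectra essentially untouched", {
  flat <- epr_spectrum(default_grid$field_G, rep(0, default_grid$n_points))
  expect_equal(baseline_correct(flat)$intensity, flat$intensity)
  sp <- simulate_fluid_spectrum(fluid_params(), default_grid)
  fixed <- baseline_correct(sp)
  expect_lt(max(abs(fixed$intensity - sp$intensity)), 1e-6 * max(abs(sp$intensity)))
})

test_that("baseline correction falls back to a constant offset when edges hold signal", {
  # push the lines against the sweep edges so the edge windows contain them
  p <- fluid_params(center_G = 3340, hyperfine_G = 40, widths_G = c(8, 8, 8))
  sp <- simulate_fluid_spectrum(p, field_grid(3290, 3390, 1024))
  shifted <- epr_spectrum(sp$field_G, sp$intensity + 0.01)
  expect_warning(out <- baseline_correct(shifted), class = "lensepr_warning_baseline")
  n <- nrow(out)
  m <- floor(0.05 * n)
  edge <- c(seq_len(m), (n - m + 1):n)
  expect_equal(mean(out$intensity[edge]), 0, tolerance = 1e-10)
})

test_that("line location matches the analytic extrema of the generative model", {
  # positions within one grid step, heights within 2 percent
  cases <- list(
    list(A = 15.2, w = c(2.4, 2.0, 2.8), mix = 0),
    list(A = 16.0, w = c(2.8, 2.3, 3.2), mix = 0),
    list(A = 16.0, w = c(2.0, 2.0, 2.0), mix = 1)
  )
  for (cs in cases) {
    p <- fluid_params(hyperfine_G = cs$A, widths_G = cs$w, shape_mix = cs$mix)
    f <- locate_lines(simulate_fluid_spectrum(p, default_grid))
    expect_equal(f$low_max_G, 3340 - cs$A - cs$w[1] / 2, tolerance = default_grid$delta_G)
    expect_equal(f$high_min_G, 3340 + cs$A + cs$w[3] / 2, tolerance = default_grid$delta_G)
    expect_equal(f$max_splitting_G, 2 * cs$A + (cs$w[1] + cs$w[3]) / 2,
      tolerance = default_grid$delta_G
    )
    expect_equal(f$h_plus, analytic_pp_height(cs$w[1], cs$mix, 1 / 3), tolerance = 0.02)
    expect_equal(f$h_zero, analytic_pp_height(cs$w[2], cs$mix, 1 / 3), tolerance = 0.02)
    expect_true(f$low_max_G < f$cen_max_G && f$cen_max_G < f$high_min_G)
    expect_true(all(c(f$h_plus, f$h_zero) > 0))
  }
})

test_that("feature extraction is invariant to intensity scaling and field translation", {
  sp <- simulate_fluid_spectrum(fluid_params(), default_grid)
  f0 <- locate_lines(sp)
  scaled <- epr_spectrum(sp$field_G, 5 * sp$intensity)
  fs <- locate_lines(scaled)
  expect_equal(fs$mobility, f0$mobility, tolerance = 1e-12)
  expect_equal(fs$max_splitting_G, f0$max_splitting_G, tolerance = 1e-12)
  shifted <- epr_spectrum(sp$field_G + 10, sp$intensity)
  ft <- locate_lines(shifted)
  expect_equal(ft$max_splitting_G, f0$max_splitting_G, tolerance = 1e-9)
  expect_equal(ft$low_max_G, f0$low_max_G + 10, tolerance = 1e-9)
})

test_that("a spectrum without three resolvable lines raises an unresolved error", {
  lone <- epr_spectrum(
    default_grid$field_G,
    exp(-(default_grid$field_G - 3340)^2 / 50) * (3340 - default_grid$field_G)
  )
  expect_error(locate_lines(lone), class = "lensepr_error_unresolved")
})

test_that("mobility parameter is h+/h0 with its closed-form width dependence", {
  f <- locate_lines(simulate_fluid_spectrum(symmetric_params(), default_grid))
  expect_equal(mobility_parameter(f), 1, tolerance = 1e-3)
  # equal intensities, low-field width doubled: ratio 1/4 within 2 percent
  p <- fluid_params(hyperfine_G = 30, widths_G = c(4, 2, 2), shape_mix = 1)
  expect_equal(
    mobility_parameter(simulate_fluid_spectrum(p, default_grid)),
    0.25,
    tolerance = 0.02 * 0.25
  )
  bad <- tibble::tibble(h_plus = 1, h_zero = 0)
  expect_error(mobility_parameter(bad), class = "lensepr_error_features")
})

test_that("mobility falls monotonically as the bound fraction grows", {
  u <- fluid_params()
  b <- bound_params(u)
  mob <- vapply(seq(0, 0.6, by = 0.1), function(f) {
    mobility_parameter(simulate_two_component_spectrum(u, b, f, default_grid))
  }, numeric(1))
  expect_true(all(diff(mob) < 0))
})

test_that("maximum splitting ignores pure amplitude changes", {
  base <- fluid_params(rel_intensity = c(1, 1, 1))
  reweighted <- fluid_params(rel_intensity = c(0.6, 1.3, 0.9))
  s1 <- locate_lines(simulate_fluid_spectrum(base, default_grid))
  s2 <- locate_lines(simulate_fluid_spectrum(reweighted, default_grid))
  expect_equal(s1$max_splitting_G, s2$max_splitting_G, tolerance = default_grid$delta_G)
})

test_that("rigid-limit 2Az tracks Az changes and polarity ordering", {
  lo <- rigid_limit_2az(simulate_rigid_spectrum(rigid_params(Az_G = 33.5), rigid_grid))
  hi <- rigid_limit_2az(simulate_rigid_spectrum(rigid_params(Az_G = 35.0), rigid_grid))
  expect_equal(lo$two_Az_G, 70, tolerance = 0.5)
  # a 1.5 G Az increase (more polar, less hydrophobic) grows 2Az by 3 G
  expect_equal(hi$two_Az_G - lo$two_Az_G, 3, tolerance = 0.05)
})

test_that("outer extrema at the sweep edges are reported as a grid problem", {
  wide <- simulate_rigid_spectrum(rigid_params(Az_G = 33.5), rigid_grid)
  keep <- abs(wide$field_G - 3340) <= 35
  clipped <- epr_spectrum(wide$field_G[keep], wide$intensity[keep], regime = "rigid")
  expect_error(rigid_limit_2az(clipped), class = "lensepr_error_grid")
})

test_that("normalized low-field height is scale invariant and tracks binding", {
  u <- fluid_params()
  b <- bound_params(u)
  ctrl <- simulate_two_component_spectrum(u, b, 0, default_grid)
  n0 <- normalized_low_field_height(ctrl)
  scaled <- epr_spectrum(ctrl$field_G, 5 * ctrl$intensity)
  expect_equal(normalized_low_field_height(scaled), n0, tolerance = 1e-9)
  expect_equal(normalized_low_field_height(simulate_fluid_spectrum(u, default_grid)) / n0,
    1,
    tolerance = 1e-6
  )
  bound30 <- simulate_two_component_spectrum(u, b, 0.3, default_grid)
  expect_lt(normalized_low_field_height(bound30) / n0, 1)
})

test_that("optional Savitzky-Golay smoothing preserves noiseless features", {
  skip_if_not_installed("signal")
  sp <- simulate_fluid_spectrum(fluid_params(), default_grid)
  raw <- locate_lines(sp)
  smoothed <- locate_lines(sp, smooth_window = 11)
  expect_equal(smoothed$mobility, raw$mobility, tolerance = 1e-3)
  expect_equal(smoothed$max_splitting_G, raw$max_splitting_G, tolerance = default_grid$delta_G)
})
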