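test_that("shell normalization volume matches closed forms and scaling", {
  expect_equal(normalization_volume(2, 1), 2 * sqrt(pi), tolerance = 1e-9)
  expect_equal(normalization_volume(2, 2.5), 2.5 * 2 * sqrt(pi),
               tolerance = 1e-9)
  # closed-form first absolute moment: V = 2 gamma Gamma(1 - 1/alpha)
  for (a in c(1.2, 1.5, 1.85))
    expect_equal(normalization_volume(a, 1), 2 * gamma(1 - 1 / a),
                 tolerance = 1e-8)
  # grows toward the alpha -> 1 divergence
  expect_gt(normalization_volume(1.01, 1), normalization_volume(1.5, 1))
  expect_error(normalization_volume(1, 1), "diverges")
  expect_error(normalization_volume(0.8, 1), "diverges")
})

test_that("V table interpolates within 0.1% and refuses extrapolation", {
  tb <- precompute_V_table(seq(1.5, 2, by = 0.05), seq(0.5, 5, by = 0.5))
  # exact at a node
  expect_equal(predict(tb, 1.85, 2.5), normalization_volume(1.85, 2.5),
               tolerance = 1e-12)
  # off-grid midpoints
  for (a in c(1.675, 1.875, 1.975)) for (g in c(0.75, 2.7))
    expect_lt(abs(predict(tb, a, g) - normalization_volume(a, g)) /
                normalization_volume(a, g), 1e-3)
  # monotone in gamma at fixed alpha (linear scaling)
  vg <- vapply(seq(0.5, 5, by = 0.5), function(g) predict(tb, 1.7, g),
               numeric(1))
  expect_true(all(diff(vg) > 0))
  expect_error(predict(tb, 1.2, 1), "outside")
  expect_error(predict(tb, 1.7, 10), "outside")
})

test_that("2D lateral profile is unit-volume and closes the Gaussian form", {
  dp <- depth_parameterization(100, c(0, 50, 100), alpha = c(2, 2, 2),
                               gamma = c(2, 3, 4), integral_dose = c(1, 1, 1),
                               range = 90)
  g_mid <- 3
  expect_equal(lateral_2d(0, 50, dp), 1 / (4 * pi * g_mid^2),
               tolerance = 1e-9)
  # shell integral of L equals 1
  dp2 <- depth_parameterization(100, c(0, 50, 100), alpha = c(1.8, 1.8, 1.8),
                                gamma = c(2.5, 2.5, 2.5),
                                integral_dose = c(1, 1, 1), range = 90)
  shell <- stats::integrate(function(r) 2 * pi * r * lateral_2d(r, 50, dp2),
                            0, 400, rel.tol = 1e-10, subdivisions = 1000L)$value
  a <- 1.8; g <- 2.5; R <- 400; tail <- 0  # analytic power-law tail beyond R
  for (k in 1:4)
    tail <- tail + (-1)^(k + 1) * gamma(k * a + 1) / factorial(k) *
      sin(k * pi * a / 2) / pi * g^(k * a) * R^(1 - k * a) / (k * a - 1)
  tail_mass <- 2 * pi * tail / normalization_volume(a, g)
  expect_equal(shell + tail_mass, 1, tolerance = 1e-7)
  expect_equal(lateral_2d(-7, 50, dp2), lateral_2d(7, 50, dp2))
  expect_error(lateral_2d(0, 120, dp), "outside")
})

test_that("reconstruction conserves the per-plane integral dose", {
  dp <- depth_parameterization(120, c(0, 40, 80), alpha = c(1.9, 1.8, 1.95),
                               gamma = c(2, 2.6, 3.1),
                               integral_dose = c(0.4, 0.7, 1.2), range = 75)
  for (z in c(20, 60)) {
    id <- stats::approx(dp$depths, dp$integral_dose, z)$y
    plane <- stats::integrate(function(r)
      2 * pi * r * reconstruct_lateral(r, z, dp), 0, 2000,
      rel.tol = 1e-8, subdivisions = 2000L)$value
    expect_equal(plane, id, tolerance = 1e-3)
    expect_equal(reconstruct_lateral(0, z, dp), id * lateral_2d(0, z, dp))
  }
  dp0 <- depth_parameterization(120, c(0, 40, 80), alpha = c(1.9, 1.8, 1.95),
                                gamma = c(2, 2.6, 3.1),
                                integral_dose = c(0, 0, 0), range = 75)
  expect_identical(reconstruct_lateral(c(0, 5, 10), 40, dp0), c(0, 0, 0))
})

test_that("parameterize_beam recovers per-depth curves and round trips", {
  depths <- c(10, 30, 50, 70, 85)
  a_true <- c(1.95, 1.88, 1.82, 1.80, 1.90)
  g_true <- c(2.0, 2.3, 2.7, 3.2, 3.6)
  id_true <- c(0.35, 0.4, 0.5, 0.8, 1.4)
  grid <- std_grid(100)
  profs <- lapply(seq_along(depths), function(i) {
    amp <- id_true[i] / normalization_volume(a_true[i], g_true[i])
    make_profile(symmetric_stable_params(a_true[i], g_true[i]), grid,
                 noise_model(0), amplitude = amp, depth = depths[i],
                 energy = 100)
  })
  dp <- parameterize_beam(profs[c(3, 1, 2, 5, 4)], energy = 100, range = 88)
  expect_equal(dp$depths, depths)                   # sorted ascending
  expect_lt(max(abs(dp$alpha_z - a_true) / a_true), 0.01)
  expect_lt(max(abs(dp$gamma_z - g_true) / g_true), 0.005)
  expect_lt(max(abs(dp$integral_dose - id_true) / id_true), 0.01)
  # round trip: reconstruct the input profiles from the parameterization
  for (i in c(2, 4)) {
    rec <- reconstruct_lateral(grid$abscissae, depths[i], dp)
    rms <- sqrt(mean((rec - profs[[i]]$dose)^2)) / max(profs[[i]]$dose)
    expect_lt(rms, 0.01)
  }
})

test_that("machine library enforces the alpha > 1 load-time constraint", {
  dp_bad <- depth_parameterization(100, c(0, 50, 100), alpha = c(1.9, 0.9, 1.9),
                                   gamma = c(2, 3, 4),
                                   integral_dose = c(1, 1, 1), range = 90)
  expect_error(machine_library(list(dp_bad)), "diverges")
  expect_error(depth_parameterization(100, c(0, 50), alpha = c(2, 2),
                                      gamma = c(1, 1), integral_dose = c(1, 1),
                                      range = 50), ">= 3")
})

test_that("dose engine places the Bragg peak and respects geometry", {
  rec <- machine_recipe(c(70, 95, 120), sigma0_ref_mm = 8, e_ref = 70,
                        n_depths = 181L)
  mach <- make_machine(rec)
  gs <- grid_spec(c(30, 30, 90), 1, origin = c(0, 0, 0.5))
  bm <- beam_spec(95, entry = c(14.5, 14.5, 0), direction = c(0, 0, 1))
  dg <- compute_dose_grid(mach, bm, gs)
  cax <- dg$values[15, 15, ]
  z_peak_true <- 0.96 * mach$beams[[2]]$range
  expect_lt(abs((0.5 + which.max(cax) - 1) - z_peak_true), 1 + 0.5)
  # mirrored beam gives the mirrored grid
  bm_rev <- beam_spec(95, entry = c(14.5, 14.5, 90), direction = c(0, 0, -1))
  dg_rev <- compute_dose_grid(mach, bm_rev, gs)
  expect_equal(dg_rev$values, dg$values[, , 90:1], tolerance = 1e-12)
  # beyond the tabulated depth interval (1.2 x range here) the dose is zero
  expect_gt(sum(dg$values[, , 84]), 0)
  expect_equal(sum(dg$values[, , 85]), 0)
  # non-intersecting beam warns and returns an empty grid
  bm_out <- beam_spec(95, entry = c(14.5, 14.5, 500), direction = c(0, 0, 1))
  expect_warning(dg0 <- compute_dose_grid(mach, bm_out, gs), "intersect")
  expect_equal(max(dg0$values), 0)
})

test_that("uncommissioned energies are morphed inside the engine", {
  mach <- make_machine(machine_recipe(c(90, 100, 110), n_depths = 60L))
  gs <- grid_spec(c(20, 20, 100), c(2, 2, 1), origin = c(0, 0, 0.5))
  bm <- beam_spec(105, entry = c(19, 19, 0), direction = c(0, 0, 1))
  dg <- compute_dose_grid(mach, bm, gs)
  z_peak <- 0.5 + which.max(dg$values[10, 10, ]) - 1
  expect_lt(abs(z_peak - 0.96 * proton_range(range_model_power_law(), 105)), 2)
  mach_norm <- machine_library(mach$beams)   # no range model
  expect_error(compute_dose_grid(mach_norm, bm, gs), "range model")
  expect_error(compute_dose_grid(mach, beam_spec(80, entry = c(19, 19, 0)),
                                 gs), "interval")
})

test_that("in-air source spread is folded into the lateral scale", {
  mach <- make_machine(machine_recipe(c(90, 100, 110)))
  bm0 <- beam_spec(100)
  bm1 <- beam_spec(100, sigma_air = 4)
  dp0 <- stabledose:::.resolve_beam(mach, bm0)
  dp1 <- stabledose:::.resolve_beam(mach, bm1)
  a0 <- dp0$alpha_z[1]
  expect_equal(dp1$gamma_z,
               vapply(dp0$gamma_z, combine_stable_scales, numeric(1),
                      gamma2 = 4 / sqrt(2), alpha = a0),
               tolerance = 1e-12)
  expect_true(all(dp1$gamma_z > dp0$gamma_z))
})
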