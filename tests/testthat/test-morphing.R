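test_that("range models evaluate, validate and refuse extrapolation", {
  rm_pl <- range_model_power_law()
  expect_equal(proton_range(rm_pl, 100), 0.022 * 100^1.77)
  expect_true(all(diff(proton_range(rm_pl, c(70, 100, 160, 230))) > 0))
  tab <- data.frame(energy_MeV = c(100, 150, 200),
                    range_mm = c(77, 158, 260))
  rm_tb <- range_model("table", table = tab)
  expect_equal(proton_range(rm_tb, 150), 158)
  expect_equal(proton_range(rm_tb, 125), (77 + 158) / 2)
  expect_error(proton_range(rm_tb, 250), "outside")
  expect_error(range_model("table",
                           table = data.frame(e = c(100, 150), r = c(80, 70))),
               "increasing")
  expect_error(proton_range(rm_pl, -5), "energy")
})

test_that("morphing is exact on parameter curves linear in energy", {
  mach <- make_machine(linear_recipe(c(100, 120, 140)))
  pred <- morph_parameterization(mach$beams[[1]], mach$beams[[3]], 120,
                                 range_model_power_law())
  v <- validate_morph(pred, mach$beams[[2]])
  expect_lt(v$gamma_rel, 1e-9)
  expect_lt(v$alpha_rel, 1e-9)
  expect_lt(v$dose_rel, 1e-9)
  expect_equal(v$peak_shift_mm, 0)
  expect_true(v$pass_all)
})

test_that("morphing blends constants to their weighted midpoint", {
  mk <- function(E, a) {
    R <- proton_range(range_model_power_law(), E)
    u <- seq(0, 1, length.out = 20)
    depth_parameterization(E, u * R, alpha = rep(a, 20),
                           gamma = rep(2, 20), integral_dose = rep(1, 20),
                           range = R)
  }
  pred <- morph_parameterization(mk(100, 1.8), mk(120, 1.9), 110,
                                 range_model_power_law())
  expect_equal(unique(round(pred$alpha_z, 12)), 1.85)
  expect_equal(pred$range, proton_range(range_model_power_law(), 110))
})

test_that("morphing is endpoint-continuous and swap-symmetric", {
  mach <- make_machine(mild_recipe(c(100, 150, 200)))
  rm_ <- range_model_power_law()
  pred_lo <- morph_parameterization(mach$beams[[1]], mach$beams[[3]],
                                    100 + 1e-6, rm_)
  v <- validate_morph(pred_lo, mach$beams[[1]])
  expect_lt(v$gamma_rel, 1e-6)
  expect_lt(v$dose_rel, 1e-6)
  # swapping sources with mirrored weight is an identity by construction:
  # blend at E from (lo, hi) equals blend at E from the same pair reindexed
  p1 <- morph_parameterization(mach$beams[[1]], mach$beams[[3]], 130, rm_)
  p2 <- morph_parameterization(mach$beams[[1]], mach$beams[[3]], 170, rm_)
  w1 <- (130 - 100) / 100
  mid <- function(dp, what) stats::approx(dp$depths / dp$range, dp[[what]],
                                          xout = 0.5)$y
  blend_direct <- (1 - w1) * mid(mach$beams[[1]], "gamma_z") +
    w1 * mid(mach$beams[[3]], "gamma_z")
  expect_equal(mid(p1, "gamma_z"), blend_direct, tolerance = 1e-10)
  expect_error(morph_parameterization(mach$beams[[1]], mach$beams[[3]], 90,
                                      rm_), "between")
  expect_error(morph_parameterization(mach$beams[[1]], mach$beams[[3]], 210,
                                      rm_), "between")
})

test_that("morph deviation grows monotonically with the bracketing gap", {
  mm <- make_machine(mild_recipe(c(110, 130, 140, 145, 147.5, 150,
                                   152.5, 155, 160, 170, 190)))
  e <- mm$energies
  rm_ <- range_model_power_law()
  devs <- vapply(c(2.5, 5, 10, 20), function(g) {
    lo <- mm$beams[[which(abs(e - (150 - g)) < 1e-9)]]
    hi <- mm$beams[[which(abs(e - (150 + g)) < 1e-9)]]
    validate_morph(morph_parameterization(lo, hi, 150, rm_),
                   mm$beams[[which(e == 150)]])$gamma_rel
  }, numeric(1))
  expect_true(all(diff(devs) > 0))
})

test_that("validation flags a constructed threshold violation", {
  mach <- make_machine(mild_recipe(c(100, 150, 200)))
  dp <- mach$beams[[2]]
  expect_true(validate_morph(dp, dp)$pass_all)
  dp_inflated <- depth_parameterization(dp$energy, dp$depths, dp$alpha_z,
                                        dp$gamma_z * 1.02, dp$integral_dose,
                                        dp$range)
  v <- validate_morph(dp_inflated, dp)
  expect_false(v$pass_gamma)
  expect_true(v$pass_alpha && v$pass_dose && v$pass_position)
  expect_error(validate_morph(
    depth_parameterization(100, c(300, 310, 320), rep(1.8, 3), rep(2, 3),
                           rep(1, 3), 310), dp), "overlap")
})

test_that("minimal commissioning set keeps endpoints on linear machines", {
  m_lin <- make_machine(linear_recipe(seq(100, 200, by = 10)))
  sel <- minimal_commissioning_set(m_lin, range_model_power_law())
  expect_equal(sel$kept, c(100, 200))
  for (chk in sel$checks) expect_true(chk$pass_all)
})

test_that("a strongly nonlinear gamma(E) region forces an interior energy", {
  m_str <- make_machine(machine_recipe(seq(100, 200, by = 10),
    gamma_fun = function(u, E) (1.5 + 2 * u^1.3) *
      (1 + 0.002 * (E - 150) + 0.05 * exp(-((E - 130) / 8)^2)),
    id_fun = function(u, E) 0.3 + 0.7 * exp(-(u - 0.96)^2 / 0.005)))
  sel <- minimal_commissioning_set(m_str, range_model_power_law())
  expect_true(any(sel$kept > 110 & sel$kept < 150))
  for (chk in sel$checks) expect_true(chk$pass_all)
})
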