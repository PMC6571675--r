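test_that("characteristic function matches its defining expression", {
  p <- stable_params(2, gamma = 1)
  expect_equal(stable_cf(0, p), 1 + 0i)
  expect_equal(stable_cf(0, stable_params(1.3, 0.7, 2.2, -3)), 1 + 0i)
  expect_equal(Re(stable_cf(1, p)), exp(-1), tolerance = 1e-12)
  # skewed alpha = 1 branch against direct complex arithmetic
  ps <- stable_params(1, beta = 0.5, gamma = 1, delta = 0)
  for (t in c(-2, 0.5, 1, 3)) {
    phi <- -(2 / pi) * log(abs(t))
    oracle <- exp(-abs(t) * (1 - 1i * 0.5 * sign(t) * phi))
    expect_equal(stable_cf(t, ps), oracle, tolerance = 1e-12)
  }
  # general-case modulus bound and hermitian symmetry
  pg <- stable_params(1.6, beta = -0.8, gamma = 2, delta = 1)
  tt <- seq(-4, 4, by = 0.37)
  expect_true(all(Mod(stable_cf(tt, pg)) <= 1 + 1e-12))
  expect_equal(stable_cf(-tt, pg), Conj(stable_cf(tt, pg)), tolerance = 1e-12)
  expect_error(stable_cf(Inf, p), "finite")
  expect_error(stable_params(0, gamma = 1), "alpha")
  expect_error(stable_params(1.5, gamma = -1), "gamma")
})

test_that("numerically inverted density reproduces the closed-form members", {
  x <- seq(-10, 10, by = 0.05)
  expect_lt(max(abs(dstable(x, stable_params(2)) - dstable_closed(x, "gauss"))),
            1e-9)
  expect_lt(max(abs(dstable(x, stable_params(1)) - dstable_closed(x, "lorentz"))),
            1e-9)
  # peak value Gamma(1 + 1/alpha) / (pi * gamma)
  for (a in c(1.2, 1.5, 1.8))
    expect_equal(dstable(0, stable_params(a, gamma = 1.7)),
                 gamma(1 + 1 / a) / (pi * 1.7), tolerance = 1e-10)
  # closed-form spot checks
  expect_equal(dstable_closed(0, "gauss", 1), 1 / (2 * sqrt(pi)))
  expect_equal(dstable_closed(2, "lorentz", 2), 1 / (4 * pi))
  expect_identical(dstable_closed(c(-1, 0), "levy", 1), c(0, 0))
  expect_gt(dstable_closed(0.5, "levy", 1), 0)
})

test_that("density obeys the scaling law and normalizes", {
  x <- c(0, 0.3, 1, 2.7, 8, 31)
  for (a in c(0.8, 1.2, 1.7)) {
    g <- 2.4
    expect_equal(dstable(x, stable_params(a, gamma = g)),
                 dstable(x / g, stable_params(a)) / g, tolerance = 1e-12)
  }
  for (a in c(0.8, 1.0, 1.5, 2.0)) {
    p <- stable_params(a)
    num <- stats::integrate(function(u) dstable(u, p), -500, 500,
                            rel.tol = 1e-10, subdivisions = 2000L)$value
    tail <- 0
    if (a < 2)
      for (k in 1:4)
        tail <- tail + 2 * (-1)^(k + 1) * gamma(k * a + 1) / factorial(k) *
          sin(k * pi * a / 2) / pi * 500^(-k * a) / (k * a)
    expect_equal(num + tail, 1, tolerance = 1e-6)
  }
})

test_that("heavier tails for smaller alpha at fixed scale", {
  g <- 1.3
  vals <- vapply(c(2.0, 1.8, 1.5, 1.2), function(a)
    dstable(10 * g, stable_params(a, gamma = g)), numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("fft backend agrees with the quadrature backend", {
  x <- seq(-20, 20, by = 0.37)
  for (a in c(1.2, 1.5, 2)) {
    p <- stable_params(a, gamma = 1.3)
    expect_lt(max(abs(dstable(x, p) - dstable(x, p, method = "fft"))), 1e-8)
  }
  # skewed evaluation cross-checked between the two independent backends
  ps <- stable_params(1.5, beta = 0.5)
  expect_lt(max(abs(dstable(c(-2, 0, 2), ps) -
                      dstable(c(-2, 0, 2), ps, method = "fft"))), 1e-8)
  expect_false(isTRUE(all.equal(dstable(1, ps), dstable(-1, ps))))
})

test_that("dual model density is the stated mixture", {
  m <- dual_stable_model(1.85, 2.7, q = 0.1, sigma = 20)
  expect_equal(m$gamma2, 20 / sqrt(2))
  x <- c(0, 5, 30, 80)
  oracle <- 0.9 * dstable(x, symmetric_stable_params(1.85, 2.7)) +
    0.1 * dnorm(x, sd = 20)
  expect_equal(ddualstable(x, m), oracle, tolerance = 1e-12)
  m0 <- dual_stable_model(1.6, 2, q = 0, sigma = 5)
  expect_equal(ddualstable(x, m0), dstable(x, symmetric_stable_params(1.6, 2)))
  m1 <- dual_stable_model(1.6, 2, q = 1, sigma = 2)
  expect_equal(ddualstable(0, m1), 1 / (2 * sqrt(2 * pi)))
  expect_error(dual_stable_model(1.5, 2, q = 1.2, sigma = 5), "q")
})

test_that("same-shape scales combine by the alpha-power rule", {
  expect_equal(combine_stable_scales(3, 4, 2), 5)
  expect_equal(combine_stable_scales(2, 2, 1), 4)
  expect_equal(combine_stable_scales(1.7, 0, 1.4), 1.7)
  expect_equal(combine_stable_scales(2, 3, 1.5), combine_stable_scales(3, 2, 1.5))
  expect_gte(combine_stable_scales(2, 3, 1.5), 3)
  expect_error(combine_stable_scales(1, 1, 2.5), "alpha")
  expect_error(combine_stable_scales(0, 0, 1.5), "scales")
})

test_that("sampling is seeded, reproducible and matches the CF", {
  p <- stable_params(1.5)
  x1 <- rstable_sym(1000, p, seed = 42)
  x2 <- rstable_sym(1000, p, seed = 42)
  expect_identical(x1, x2)
  expect_false(identical(x1, rstable_sym(1000, p, seed = 43)))
  # empirical CF at t = 0.5 vs exp(-0.5^1.5)
  xs <- rstable_sym(1e5, p, seed = 7)
  mc_se <- sd(cos(0.5 * xs)) / sqrt(1e5)
  expect_lt(abs(mean(cos(0.5 * xs)) - exp(-0.5^1.5)), 3 * mc_se)
  # Gaussian member: sd = gamma * sqrt(2)
  xg <- rstable_sym(1e5, stable_params(2), seed = 1)
  expect_lt(abs(sd(xg) - sqrt(2)), 3 * sqrt(2) / sqrt(2 * (1e5 - 1)) * sqrt(2))
  expect_error(rstable_sym(0, p, seed = 1), "n")
  expect_error(rstable_sym(10, stable_params(1.5, beta = 0.3), seed = 1),
               "symmetric")
})
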