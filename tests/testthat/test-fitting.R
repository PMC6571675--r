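test_that("noiseless profiles recover their generating parameters", {
  grid <- std_grid(100)
  for (a in c(1.5, 1.8)) for (g in c(1, 2.5)) {
    pr <- make_profile(symmetric_stable_params(a, g), grid, noise_model(0))
    f <- fit_stable(pr)
    expect_true(f$converged)
    expect_lt(abs(f$params$alpha - a) / a, 0.01)
    expect_lt(abs(f$params$gamma - g) / g, 0.005)
  }
})

test_that("a pure Gaussian profile is identified as the alpha = 2 member", {
  r <- seq(-100, 100, by = 1)
  pr <- lateral_profile(r, 1000 * dnorm(r, sd = 3))
  f <- fit_stable(pr)
  expect_gte(f$params$alpha, 1.99)
  expect_lt(abs(f$params$gamma - 3 / sqrt(2)) / (3 / sqrt(2)), 0.01)
})

test_that("fit is stable under the 0.5% profile noise model", {
  pr <- make_profile(symmetric_stable_params(1.5, 2), std_grid(100),
                     noise_model(0.005, seed = 42))
  f <- fit_stable(pr)
  expect_lt(abs(f$params$alpha - 1.5), 0.05)
  expect_lt(abs(f$params$gamma - 2) / 2, 0.02)
  expect_gt(f$gof$chi2_reduced, 0.5)
  expect_lt(f$gof$chi2_reduced, 1.5)
})

test_that("refitting a fit's own noiseless prediction reproduces it", {
  pr <- make_profile(symmetric_stable_params(1.7, 1.8), std_grid(80),
                     noise_model(0.005, seed = 9))
  f1 <- fit_stable(pr)
  pred <- make_profile(f1$params, std_grid(80), noise_model(0),
                       amplitude = f1$amplitude)
  f2 <- fit_stable(pred)
  expect_lt(abs(f2$params$alpha - f1$params$alpha), 1e-3)
  expect_lt(abs(f2$params$gamma - f1$params$gamma) / f1$params$gamma, 1e-3)
})

test_that("the log-chi-square objective also recovers parameters", {
  pr <- make_profile(symmetric_stable_params(1.8, 2.5), std_grid(100),
                     noise_model(0))
  f <- fit_stable(pr, fit_options(objective = "logchi2"))
  expect_lt(abs(f$params$alpha - 1.8) / 1.8, 0.01)
  expect_lt(abs(f$params$gamma - 2.5) / 2.5, 0.005)
})

test_that("profiles that are too sparse raise an insufficient-data error", {
  expect_error(lateral_profile(1:5, rep(1, 5)), ">= 8")
  r <- seq(0, 20, by = 1)
  d <- c(rep(0, 14), 1, rep(0, 6))
  expect_error(fit_stable(lateral_profile(r, d)), "insufficient")
})

test_that("dual fit recovers a genuine Gaussian background", {
  pr <- make_halo_profile(halo_model(), std_grid(200, signed = FALSE),
                          noise_model(0))
  fd <- fit_dual_stable(pr)
  expect_true(fd$converged)
  expect_gt(fd$model$q, 0.08)
  expect_lt(fd$model$q, 0.12)
  expect_lt(abs(fd$model$sigma - 20) / 20, 0.1)
  expect_lte(fd$gof_dual$chi2_reduced, fd$gof_single$chi2_reduced)
})

test_that("dual fit on a background-free profile pins q at zero", {
  pr <- make_profile(symmetric_stable_params(1.8, 2.5),
                     std_grid(200, signed = FALSE), noise_model(0))
  fd <- fit_dual_stable(pr)
  expect_lte(fd$model$q, 0.01)
  expect_true(any(grepl("background not supported", fd$flags)))
})

test_that("double-Gaussian fit recovers its own family and degenerates cleanly", {
  r <- seq(-100, 100, by = 1)
  dg_true <- function(r) 0.9 * dnorm(r, sd = 4) + 0.1 * dnorm(r, sd = 22)
  pr <- lateral_profile(r, 1000 * dg_true(r))
  f <- fit_double_gaussian(pr)
  expect_lt(abs(f$sigma1 - 4) / 4, 0.01)
  expect_lt(abs(f$sigma2 - 22) / 22, 0.01)
  expect_lt(abs(f$q - 0.1), 0.01)
  # one pure Gaussian: either q -> 0/1 or sigma1 ~ sigma2
  prg <- lateral_profile(r, 1000 * dnorm(r, sd = 3))
  fg <- fit_double_gaussian(prg)
  degenerate <- fg$q < 0.01 || fg$q > 0.99 ||
    abs(fg$sigma2 - fg$sigma1) / fg$sigma2 < 0.05
  expect_true(degenerate)
  expect_lt(abs(fg$sigma1 - 3) / 3, 0.05)
})

test_that("centroid option re-centers shifted signed profiles", {
  r <- seq(-80, 80, by = 1)
  shift <- 3.2
  d <- 1000 * dstable(r - shift, stable_params(1.8, gamma = 2))
  f <- fit_stable(lateral_profile(r, d), fit_options(center = TRUE))
  expect_lt(abs(f$params$gamma - 2) / 2, 0.02)
  expect_lt(abs(f$params$alpha - 1.8), 0.02)
})
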