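# Synthetic fixtures: noisy lateral profiles, halo profiles, multi-energy
# machine libraries with smooth parameter curves, and brute-force reference
# dose grids. Every generator is a pure function of (recipe, seed).

#' Multiplicative Gaussian noise model
#'
#' Emulates the relative measurement uncertainty of commissioning profile
#' data; the default 0.5% matches the precision of typical pin-point chamber
#' measurements of pencil-beam lateral profiles.
#'
#' @param relative_sd fractional standard deviation (default 0.005).
#' @param floor_sd absolute noise floor in dose units (default 0).
#' @param seed integer seed; required whenever `relative_sd` or `floor_sd`
#'   is non-zero.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(relative_sd = 0.005, floor_sd = 0, seed = NULL) {
  stopifnot(relative_sd >= 0, floor_sd >= 0)
  if ((relative_sd > 0 || floor_sd > 0) && is.null(seed))
    stop("a seed is required for a non-degenerate noise model", call. = FALSE)
  structure(list(relative_sd = relative_sd, floor_sd = floor_sd, seed = seed),
            class = "noise_model")
}

.apply_noise <- function(signal, noise) {
  sd_i <- sqrt((noise$relative_sd * signal)^2 + noise$floor_sd^2)
  if (all(sd_i == 0)) return(list(dose = signal, sigma = NULL))
  dose <- .with_seed(noise$seed,
                     pmax(signal + stats::rnorm(length(signal), sd = sd_i), 0))
  # a strictly positive sigma column even where the signal underflows to 0
  list(dose = dose, sigma = pmax(sd_i, max(sd_i) * 1e-9))
}

#' Synthetic single-stable lateral profile
#'
#' `dose = amplitude * f(r; alpha, gamma) * (1 + noise)`, with the sigma
#' column holding the true per-point noise standard deviation.
#'
#' @param p a symmetric [stable_params()].
#' @param grid an [evaluation_grid()] of radii (mm).
#' @param noise a [noise_model()].
#' @param amplitude profile normalization (dose · mm), > 0.
#' @param depth,energy metadata carried on the profile.
#' @return A [lateral_profile()]; reproducible for a fixed seed.
#' @export
make_profile <- function(p, grid, noise = noise_model(seed = 1),
                         amplitude = 1000, depth = NA_real_,
                         energy = NA_real_) {
  stopifnot(inherits(p, "stable_params"), inherits(grid, "evaluation_grid"),
            inherits(noise, "noise_model"), amplitude > 0)
  r <- grid$abscissae
  signal <- amplitude * dstable(r, p)
  ns <- .apply_noise(signal, noise)
  lateral_profile(r, ns$dose, sigma = ns$sigma, depth = depth, energy = energy)
}

#' Synthetic halo profile from the dual stable model
#'
#' As [make_profile()] but with the stable-plus-Gaussian mixture density of a
#' [dual_stable_model()]; emulates the mid-radius halo excess of high-energy
#' beams that a single stable law underestimates.
#'
#' @param m a [dual_stable_model()].
#' @inheritParams make_profile
#' @return A [lateral_profile()].
#' @export
make_halo_profile <- function(m, grid, noise = noise_model(seed = 1),
                              amplitude = 1000, depth = NA_real_,
                              energy = NA_real_) {
  stopifnot(inherits(m, "dual_stable_model"), inherits(grid, "evaluation_grid"),
            inherits(noise, "noise_model"), amplitude > 0)
  r <- grid$abscissae
  signal <- amplitude * ddualstable(r, m)
  ns <- .apply_noise(signal, noise)
  lateral_profile(r, ns$dose, sigma = ns$sigma, depth = depth, energy = energy)
}

#' Machine recipe: parametric curves for a synthetic beam library
#'
#' Defines a deterministic multi-energy machine on the fractional-depth axis
#' `u = z / range(E)`. The default curves emulate commissioning data in
#' water:
#' * `alpha_fun`: `2 - 0.2 * sin(pi * min(u, 1))^2`, floored at 1.5 — the
#'   shape dips mid-range as the scattered-proton halo builds and returns
#'   toward the Gaussian limit past the Bragg peak;
#' * `gamma_fun`: a quadrature sum of the (energy-dependent) in-air spot
#'   scale and a multiple-scattering term growing like `u^1.7`, reaching
#'   about 2.1% of the range at the peak — Highland-like growth;
#' * `id_fun`: a gently rising entrance plateau plus a Gaussian Bragg peak at
#'   `u = 0.96` of width `bragg_width_mm`, with the plateau switched off
#'   distally to the peak.
#'
#' `sigma0_ref_mm` is the in-air spot sigma (mm) at `e_ref` MeV; spots narrow
#' with energy like `(e_ref/E)^0.6`, emulating a scanning nozzle.
#'
#' @param energies nominal energies (MeV), >= 1, strictly increasing.
#' @param range_model a [range_model()]; default Bragg-Kleeman water power
#'   law.
#' @param n_depths tabulated depths per beam (>= 50 by contract of the
#'   generated [depth_parameterization()]).
#' @param u_max tabulation extends to `u_max * range(E)`.
#' @param alpha_fun,gamma_fun,id_fun optional overrides `function(u, E)`.
#' @param sigma0_ref_mm,e_ref in-air spot model, see above.
#' @param bragg_width_mm Gaussian Bragg-peak width (mm), default 5.
#' @return An object of class `machine_recipe`.
#' @export
machine_recipe <- function(energies, range_model = NULL, n_depths = 60L,
                           u_max = 1.2, alpha_fun = NULL, gamma_fun = NULL,
                           id_fun = NULL, sigma0_ref_mm = 6, e_ref = 70,
                           bragg_width_mm = 5) {
  energies <- as.numeric(energies)
  if (length(energies) < 1L || any(!is.finite(energies)) || any(energies <= 0) ||
      any(diff(energies) <= 0))
    stop("energies must be positive and strictly increasing", call. = FALSE)
  if (is.null(range_model)) range_model <- range_model_power_law()
  rm_ <- range_model
  if (is.null(alpha_fun))
    alpha_fun <- function(u, E) pmax(2 - 0.2 * sin(pi * pmin(u, 1))^2, 1.5)
  if (is.null(gamma_fun)) {
    gamma_fun <- function(u, E) {
      g0 <- sigma0_ref_mm * (e_ref / E)^0.6 / sqrt(2)
      gs <- 0.021 * proton_range(rm_, E) * pmin(u, 1)^1.7 / sqrt(2)
      sqrt(g0^2 + gs^2)
    }
  }
  if (is.null(id_fun)) {
    id_fun <- function(u, E) {
      w_u <- bragg_width_mm / proton_range(rm_, E)
      plateau <- 0.28 * (1 + 0.4 * pmin(u, 0.96)) / (1 + exp((u - 1.0) / 0.015))
      plateau + 0.75 * exp(-(u - 0.96)^2 / (2 * w_u^2))
    }
  }
  structure(list(energies = energies, range_model = range_model,
                 n_depths = as.integer(n_depths), u_max = u_max,
                 alpha_fun = alpha_fun, gamma_fun = gamma_fun,
                 id_fun = id_fun),
            class = "machine_recipe")
}

#' Generate a synthetic machine library
#'
#' Tabulates each energy of the recipe on a shared fractional-depth grid
#' `u_k` (so that beams of different energies sample identical `u` nodes and
#' range-scaled comparisons are exact), producing one
#' [depth_parameterization()] per energy. Deterministic given the recipe.
#'
#' @param recipe a [machine_recipe()].
#' @return A [machine_library()] carrying the recipe's range model.
#' @export
make_machine <- function(recipe) {
  stopifnot(inherits(recipe, "machine_recipe"))
  u <- seq(0, recipe$u_max, length.out = recipe$n_depths)
  beams <- lapply(recipe$energies, function(E) {
    R <- proton_range(recipe$range_model, E)
    a <- recipe$alpha_fun(u, E)
    if (any(a <= 1))
      stop(sprintf("recipe yields alpha <= 1 at E = %g MeV: 2D normalization diverges", E),
           call. = FALSE)
    depth_parameterization(energy = E, depths = u * R,
                           alpha = a, gamma = recipe$gamma_fun(u, E),
                           integral_dose = recipe$id_fun(u, E),
                           range = R)
  })
  machine_library(beams, medium = "water", range_model = recipe$range_model)
}

#' Brute-force reference dose grid
#'
#' Independent oracle for [compute_dose_grid()]: the same physics evaluated
#' by dense sub-voxel quadrature (`n_sub^3` samples per voxel, default 5^3,
#' i.e. voxel-averaged dose) with the shell normalization `V` computed
#' directly per sub-slice by [normalization_volume()] — no V-table, no
#' engine caching of depth slices.
#'
#' @inheritParams compute_dose_grid
#' @param n_sub sub-samples per voxel axis, >= 5.
#' @return A `dose_grid`.
#' @export
brute_force_dose <- function(machine, beam, grid, n_sub = 5L) {
  stopifnot(inherits(machine, "machine_library"), inherits(beam, "beam_spec"),
            inherits(grid, "grid_spec"))
  n_sub <- as.integer(n_sub)
  if (n_sub < 5L) stop("`n_sub` must be >= 5", call. = FALSE)
  dp <- .resolve_beam(machine, beam)
  zmax <- max(dp$depths)
  kernel <- function(depth, r) {
    vals <- numeric(length(depth))
    inside <- depth >= 0 & depth <= zmax
    if (!any(inside)) return(vals)
    zq <- depth[inside]; rq <- r[inside]
    uz <- unique(zq)
    av <- stats::approx(dp$depths, dp$alpha_z, xout = uz)$y
    gv <- stats::approx(dp$depths, dp$gamma_z, xout = uz)$y
    iv <- stats::approx(dp$depths, dp$integral_dose, xout = uz)$y
    out <- numeric(length(zq))
    idx <- match(zq, uz)
    for (k in seq_along(uz)) {
      if (iv[k] <= 0) next
      sel <- idx == k
      V <- normalization_volume(av[k], gv[k])     # direct, no table
      f <- .stable_pdf_std_cached(rq[sel] / gv[k], av[k]) / gv[k]
      out[sel] <- iv[k] * f / V
    }
    vals[inside] <- out
    vals
  }
  acc <- .dose_accumulate(beam, grid, sub = n_sub, kernel)
  dose_grid(acc$values, spacing = grid$spacing, origin = grid$origin)
}

#' Analytic Gaussian pencil-beam dose (closed-form limit)
#'
#' Reference implementation for machines whose shape is exactly `alpha = 2`
#' everywhere: the lateral kernel is the closed-form radial 2D Gaussian
#' \eqn{\exp(-r^2/2\sigma^2)/(2\pi\sigma^2)} with \eqn{\sigma = \gamma\sqrt2},
#' the depth factor the linearly interpolated tabulated `I_D(z)`. No stable
#' quadrature, spline cache or V-table is involved, so this path is an
#' independent check of the dose engine in its Gaussian limit.
#'
#' @inheritParams compute_dose_grid
#' @return A `dose_grid`.
#' @export
gaussian_pencil_dose <- function(machine, beam, grid) {
  stopifnot(inherits(machine, "machine_library"), inherits(beam, "beam_spec"),
            inherits(grid, "grid_spec"))
  dp <- .resolve_beam(machine, beam)
  if (any(abs(dp$alpha_z - 2) > 1e-12))
    stop("gaussian_pencil_dose requires alpha = 2 at every depth", call. = FALSE)
  zmax <- max(dp$depths)
  kernel <- function(depth, r) {
    vals <- numeric(length(depth))
    inside <- depth >= 0 & depth <= zmax
    if (!any(inside)) return(vals)
    zq <- depth[inside]; rq <- r[inside]
    gv <- stats::approx(dp$depths, dp$gamma_z, xout = zq)$y
    iv <- stats::approx(dp$depths, dp$integral_dose, xout = zq)$y
    s2 <- 2 * gv^2                      # sigma^2 with sigma = gamma*sqrt(2)
    vals[inside] <- iv * exp(-rq^2 / (2 * s2)) / (2 * pi * s2)
    vals
  }
  acc <- .dose_accumulate(beam, grid, sub = 1L, kernel)
  dose_grid(acc$values, spacing = grid$spacing, origin = grid$origin)
}
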