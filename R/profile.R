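#' Per-depth lateral dose profile
#'
#' One radial (or signed, both sides of the central axis) dose profile at a
#' single depth: the fit target of the package. Radii must be strictly
#' increasing; uncertainties, when present, are per-point standard deviations
#' in the same dose units.
#'
#' @param radii offsets r_i in mm, strictly increasing; may be signed.
#' @param dose dose values S_i >= 0 (arbitrary units); at least one > 0.
#' @param sigma optional per-point uncertainties, > 0.
#' @param depth depth z of the profile plane (mm), or `NA`.
#' @param energy nominal beam energy (MeV), or `NA`.
#' @return An object of class `lateral_profile`.
#' @export
lateral_profile <- function(radii, dose, sigma = NULL, depth = NA_real_,
                            energy = NA_real_) {
  radii <- as.numeric(radii); dose <- as.numeric(dose)
  n <- length(radii)
  if (n < 8L) stop("profile needs >= 8 points", call. = FALSE)
  if (length(dose) != n)
    stop("`radii` and `dose` must have equal length", call. = FALSE)
  if (any(!is.finite(radii)) || any(!is.finite(dose)))
    stop("radii and dose must be finite", call. = FALSE)
  if (any(diff(radii) <= 0))
    stop("radii must be strictly increasing", call. = FALSE)
  if (any(dose < 0)) stop("dose must be >= 0", call. = FALSE)
  if (!any(dose > 0)) stop("at least one dose value must be > 0", call. = FALSE)
  if (!is.null(sigma)) {
    sigma <- as.numeric(sigma)
    if (length(sigma) != n || any(!is.finite(sigma)) || any(sigma <= 0))
      stop("`sigma` must be positive, finite and of matching length",
           call. = FALSE)
  }
  structure(list(radii = radii, dose = dose, sigma = sigma,
                 depth = as.numeric(depth), energy = as.numeric(energy)),
            class = "lateral_profile")
}

#' @export
print.lateral_profile <- function(x, ...) {
  cat(sprintf(
    "lateral_profile: %d points, r in [%.4g, %.4g] mm, depth %.4g mm, energy %.4g MeV, %s\n",
    length(x$radii), min(x$radii), max(x$radii), x$depth, x$energy,
    if (is.null(x$sigma)) "no sigmas" else "with sigmas"))
  invisible(x)
}

# Effective per-point uncertainties: stated sigmas, else a relative fallback.
.profile_sigmas <- function(profile, rel_fallback = 0.005) {
  if (!is.null(profile$sigma)) profile$sigma
  else pmax(rel_fallback * profile$dose, rel_fallback * max(profile$dose) * 1e-6)
}

# Bin widths of the (possibly irregular) radius grid, midpoint rule.
.grid_widths <- function(r) {
  n <- length(r)
  w <- numeric(n)
  mid <- (r[-1] + r[-n]) / 2
  w[1] <- mid[1] - (r[1] - (r[2] - r[1]) / 2)
  w[n] <- (r[n] + (r[n] - r[n - 1]) / 2) - mid[n - 1]
  if (n > 2) w[2:(n - 1)] <- diff(mid)
  w
}
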