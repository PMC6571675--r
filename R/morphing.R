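# Intermediate morphing: a full depth parameterization at an uncommissioned
# energy is obtained by linearly blending the parameter curves of the two
# bracketing commissioned energies on the fractional-depth axis u = z/R(E),
# then mapping back through the range of the target energy.

#' Proton range model
#'
#' Either an explicit energy -> range table (linearly interpolated, strictly
#' increasing) or the Bragg-Kleeman power law \eqn{R = a E^p}.
#'
#' @param mode `"table"` or `"power_law"`.
#' @param table two-column data frame / matrix `(energy_MeV, range_mm)` for
#'   `"table"` mode.
#' @param a,p power-law coefficients (range in mm, energy in MeV).
#' @return An object of class `range_model`.
#' @seealso [range_model_power_law()] for the water default.
#' @export
range_model <- function(mode = c("power_law", "table"), table = NULL,
                        a = NULL, p = NULL) {
  mode <- match.arg(mode)
  if (mode == "table") {
    table <- as.data.frame(table)
    if (ncol(table) != 2L || nrow(table) < 2L)
      stop("`table` needs >= 2 rows of (energy, range)", call. = FALSE)
    names(table) <- c("energy_MeV", "range_mm")
    o <- order(table$energy_MeV)
    table <- table[o, ]
    if (any(!is.finite(as.matrix(table))) || any(diff(table$range_mm) <= 0) ||
        any(diff(table$energy_MeV) <= 0))
      stop("ranges must be strictly increasing in energy", call. = FALSE)
    structure(list(mode = "table", table = table), class = "range_model")
  } else {
    if (is.null(a)) a <- 0.022
    if (is.null(p)) p <- 1.77
    if (!is.finite(a) || a <= 0 || !is.finite(p) || p <= 0)
      stop("power-law coefficients must be > 0", call. = FALSE)
    structure(list(mode = "power_law", a = a, p = p), class = "range_model")
  }
}

#' Default water range model
#'
#' Bragg-Kleeman power law with standard literature coefficients for protons
#' in water, \eqn{R\,[\mathrm{cm}] = 0.0022\,E^{1.77}} (returned in mm). A
#' user-supplied range table always takes precedence over this convenience
#' default.
#'
#' @return A power-law [range_model()].
#' @export
range_model_power_law <- function() range_model("power_law", a = 0.022, p = 1.77)

#' Evaluate a range model
#'
#' @param rm a [range_model()].
#' @param energy energies (MeV); for table mode, must lie inside the table.
#' @return Ranges (mm).
#' @export
proton_range <- function(rm, energy) {
  stopifnot(inherits(rm, "range_model"))
  if (any(!is.finite(energy)) || any(energy <= 0))
    stop("energy must be > 0", call. = FALSE)
  if (rm$mode == "power_law") return(rm$a * energy^rm$p)
  r <- stats::approx(rm$table$energy_MeV, rm$table$range_mm, xout = energy)$y
  if (any(is.na(r)))
    stop("energy outside the range table (no extrapolation)", call. = FALSE)
  r
}

#' Morph validation thresholds
#'
#' Acceptance thresholds for a morphed parameterization against a reference:
#' 1% on the width `gamma`, 3% on the shape `alpha`, 1% on the integral dose
#' and 1 mm on the Bragg-peak position.
#'
#' @param gamma_rel,alpha_rel,dose_rel relative tolerances, > 0.
#' @param position_mm positional tolerance (mm), > 0.
#' @return An object of class `morph_thresholds`.
#' @export
morph_thresholds <- function(gamma_rel = 0.01, alpha_rel = 0.03,
                             dose_rel = 0.01, position_mm = 1.0) {
  v <- c(gamma_rel, alpha_rel, dose_rel, position_mm)
  if (any(!is.finite(v)) || any(v <= 0))
    stop("all thresholds must be > 0", call. = FALSE)
  structure(list(gamma_rel = gamma_rel, alpha_rel = alpha_rel,
                 dose_rel = dose_rel, position_mm = position_mm),
            class = "morph_thresholds")
}

# Resample a depth curve onto a fractional-depth grid by piecewise-linear
# interpolation.
.dp_on_u <- function(dp, u, what) {
  stats::approx(dp$depths / dp$range, dp[[what]], xout = u, rule = 1)$y
}

#' Morph a depth parameterization to an intermediate energy
#'
#' Implements range-scaled intermediate morphing: both source curves are
#' mapped onto the fractional-depth axis `u = z / R(E)` (which aligns the
#' Bragg peaks; equivalently, depths correspond through
#' \eqn{z_i = z_l\,R(E_i)/R(E_l)}), linearly blended with weight
#' \eqn{w = (E_i - E_l)/(E_u - E_l)}, and mapped back through the range of
#' the target energy: output depths are `u * R(E_i)`, output range `R(E_i)`.
#' The common `u`-grid is the union of both source node sets merged with a
#' uniform grid of `n_u` points (so machines tabulated on a shared
#' fractional-depth grid morph exactly). No extrapolation: `E_i` must lie
#' strictly between the source energies.
#'
#' @param dp_l,dp_u bracketing [depth_parameterization()]s,
#'   `dp_l$energy < E_i < dp_u$energy`.
#' @param E_i target energy (MeV).
#' @param rm a [range_model()] covering `E_i`.
#' @param n_u minimum number of fractional-depth samples (default 512).
#' @return A [depth_parameterization()] at `E_i`.
#' @export
morph_parameterization <- function(dp_l, dp_u, E_i, rm, n_u = 512L) {
  stopifnot(inherits(dp_l, "depth_parameterization"),
            inherits(dp_u, "depth_parameterization"),
            inherits(rm, "range_model"))
  if (!(dp_l$energy < E_i && E_i < dp_u$energy))
    stop("E_i must lie strictly between the source energies (no extrapolation)",
         call. = FALSE)
  w <- (E_i - dp_l$energy) / (dp_u$energy - dp_l$energy)
  u_max <- min(max(dp_l$depths) / dp_l$range, max(dp_u$depths) / dp_u$range)
  u_min <- max(min(dp_l$depths) / dp_l$range, min(dp_u$depths) / dp_u$range)
  u <- sort(unique(c(seq(u_min, u_max, length.out = n_u),
                     dp_l$depths / dp_l$range, dp_u$depths / dp_u$range)))
  u <- u[u >= u_min & u <= u_max]
  u <- u[c(TRUE, diff(u) > 1e-12)]      # drop floating-point near-duplicates
  blend <- function(what)
    (1 - w) * .dp_on_u(dp_l, u, what) + w * .dp_on_u(dp_u, u, what)
  R_i <- proton_range(rm, E_i)
  depth_parameterization(E_i, depths = u * R_i, alpha = blend("alpha_z"),
                         gamma = blend("gamma_z"),
                         integral_dose = blend("integral_dose"),
                         range = R_i)
}

# Bragg-peak depth of a tabulated integral-dose curve (argmax node).
.bragg_peak_depth <- function(dp) dp$depths[which.max(dp$integral_dose)]

#' Validate a morphed parameterization against a reference
#'
#' Compares the predicted and reference depth curves on their overlapping
#' fractional-depth interval: maximum relative deviations of `gamma` and
#' `alpha` (pointwise), of `I_D` (relative to the curve maximum), and the
#' Bragg-peak position shift in mm; each is checked against its
#' [morph_thresholds()] entry.
#'
#' @param dp_pred,dp_ref [depth_parameterization()]s with overlapping depth
#'   coverage.
#' @param th a [morph_thresholds()].
#' @return A list of class `morph_validation`: deviations `gamma_rel`,
#'   `alpha_rel`, `dose_rel`, `peak_shift_mm`, per-check logical `pass`
#'   fields and overall `pass_all`.
#' @export
validate_morph <- function(dp_pred, dp_ref, th = morph_thresholds()) {
  stopifnot(inherits(dp_pred, "depth_parameterization"),
            inherits(dp_ref, "depth_parameterization"),
            inherits(th, "morph_thresholds"))
  lo <- max(min(dp_pred$depths), min(dp_ref$depths))
  hi <- min(max(dp_pred$depths), max(dp_ref$depths))
  if (lo >= hi) stop("depth ranges do not overlap", call. = FALSE)
  z <- sort(unique(c(dp_pred$depths, dp_ref$depths,
                     seq(lo, hi, length.out = 256))))
  z <- z[z >= lo & z <= hi]
  ip <- function(dp, what) stats::approx(dp$depths, dp[[what]], xout = z)$y
  g_rel <- max(abs(ip(dp_pred, "gamma_z") - ip(dp_ref, "gamma_z")) /
                 ip(dp_ref, "gamma_z"))
  a_rel <- max(abs(ip(dp_pred, "alpha_z") - ip(dp_ref, "alpha_z")) /
                 ip(dp_ref, "alpha_z"))
  id_p <- ip(dp_pred, "integral_dose"); id_r <- ip(dp_ref, "integral_dose")
  d_rel <- max(abs(id_p - id_r)) / max(id_r)
  shift <- abs(.bragg_peak_depth(dp_pred) - .bragg_peak_depth(dp_ref))
  res <- list(gamma_rel = g_rel, alpha_rel = a_rel, dose_rel = d_rel,
              peak_shift_mm = shift,
              pass_gamma = g_rel <= th$gamma_rel,
              pass_alpha = a_rel <= th$alpha_rel,
              pass_dose = d_rel <= th$dose_rel,
              pass_position = shift <= th$position_mm)
  res$pass_all <- res$pass_gamma && res$pass_alpha && res$pass_dose &&
    res$pass_position
  structure(res, class = "morph_validation")
}

#' @export
print.morph_validation <- function(x, ...) {
  cat(sprintf(
    "morph_validation: dGamma=%.3g%% dAlpha=%.3g%% dDose=%.3g%% dPeak=%.3g mm -> %s\n",
    100 * x$gamma_rel, 100 * x$alpha_rel, 100 * x$dose_rel, x$peak_shift_mm,
    if (x$pass_all) "PASS" else "FAIL"))
  invisible(x)
}

#' Select a minimal commissioning set of energies
#'
#' Greedy selection: starting from the two endpoint energies (always kept),
#' every omitted energy is morphed from its bracketing kept energies and
#' validated against the machine's own curve; while any omitted energy fails,
#' the worst violator (largest deviation-to-threshold ratio) is added to the
#' kept set. On return every omitted energy passes [validate_morph()]. If
#' nothing can be omitted the full set is returned with a warning.
#'
#' @param machine a [machine_library()] with >= 3 energies.
#' @param rm a [range_model()] covering the machine's energies.
#' @param th a [morph_thresholds()].
#' @return A list: `kept` (energies), `fraction_kept`, and `checks` (the
#'   final [validate_morph()] result per omitted energy).
#' @export
minimal_commissioning_set <- function(machine, rm, th = morph_thresholds()) {
  stopifnot(inherits(machine, "machine_library"), inherits(rm, "range_model"))
  e <- machine$energies
  if (length(e) < 3L) stop("machine needs >= 3 energies", call. = FALSE)
  kept <- c(1L, length(e))
  repeat {
    omitted <- setdiff(seq_along(e), kept)
    if (!length(omitted)) {
      warning("no energy could be omitted under the given thresholds")
      checks <- list()
      break
    }
    checks <- list()
    scores <- numeric(length(omitted))
    for (k in seq_along(omitted)) {
      i <- omitted[k]
      lo <- max(kept[kept < i]); hi <- min(kept[kept > i])
      pred <- morph_parameterization(machine$beams[[lo]], machine$beams[[hi]],
                                     e[i], rm)
      v <- validate_morph(pred, machine$beams[[i]], th)
      checks[[as.character(e[i])]] <- v
      scores[k] <- max(v$gamma_rel / th$gamma_rel, v$alpha_rel / th$alpha_rel,
                       v$dose_rel / th$dose_rel,
                       v$peak_shift_mm / th$position_mm)
    }
    if (all(scores <= 1)) break
    kept <- sort(c(kept, omitted[which.max(scores)]))
  }
  list(kept = e[kept], fraction_kept = length(kept) / length(e),
       checks = checks)
}
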