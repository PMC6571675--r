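# Reduced chi-square in linear and log10 space, with the Monte-Carlo relative
# error floor used when simulated tails carry unrealistically small errors.

.gof_report <- function(chi2, ndf, space, floor_fraction, n_excluded = 0L) {
  structure(list(chi2 = chi2, ndf = ndf, chi2_reduced = chi2 / ndf,
                 space = space, error_floor_fraction = floor_fraction,
                 n_excluded = n_excluded),
            class = "gof_report")
}

#' @export
print.gof_report <- function(x, ...) {
  cat(sprintf("gof_report [%s]: chi2=%.6g ndf=%d chi2/NDF=%.6g (floor %.3g, %d excluded)\n",
              x$space, x$chi2, x$ndf, x$chi2_reduced,
              x$error_floor_fraction, x$n_excluded))
  invisible(x)
}

#' Reduced chi-square in linear space
#'
#' \eqn{\chi^2 = \sum_i ((S_i - \mathbf{S}_i)/\sigma_i)^2} divided by the
#' degrees of freedom, the number of points minus the number of fitted
#' parameters.
#'
#' @param observed,model numeric vectors of equal length (dose units).
#' @param sigmas per-point uncertainties, > 0, same length.
#' @param n_params number of model parameters; must be < number of points.
#' @return A `gof_report` with fields `chi2`, `ndf`, `chi2_reduced`.
#' @export
reduced_chi2 <- function(observed, model, sigmas, n_params) {
  n <- length(observed)
  if (length(model) != n || length(sigmas) != n)
    stop("`observed`, `model`, `sigmas` must have equal length", call. = FALSE)
  if (any(!is.finite(observed)) || any(!is.finite(model)) ||
      any(!is.finite(sigmas)) || any(sigmas <= 0))
    stop("inputs must be finite with sigmas > 0", call. = FALSE)
  if (n <= n_params)
    stop("need more points than parameters", call. = FALSE)
  chi2 <- sum(((observed - model) / sigmas)^2)
  .gof_report(chi2, n - n_params, "linear", 0)
}

#' Log-transform error-propagation coefficient
#'
#' The factor mapping a relative uncertainty onto the uncertainty of the
#' log10-transformed value: \eqn{\sigma_{\log_{10} X} =
#' \sigma_X / (X \ln 10) = 0.434\,\sigma_X/X}. Returned at full precision
#' (\eqn{1/\ln 10}); it rounds to 0.434 at three decimals.
#'
#' @return `1 / log(10)`.
#' @export
log_error_coefficient <- function() 1 / log(10)

#' Reduced chi-square in log10 space with error floor
#'
#' For strongly non-linear profiles spanning orders of magnitude the linear
#' statistic is dominated by the peak; the log10-transformed form
#' \deqn{\chi^2 = \sum_i \left[\frac{\log_{10} S_i - \log_{10}\mathbf{S}_i}
#'       {0.434\,\sigma_i'/S_i}\right]^2,\qquad
#'       \sigma_i' = \max(\sigma_i,\ \mathrm{floor}\cdot S_i)}
#' weights all decades alike. The relative error floor (default 5%) guards
#' against the vanishing Monte-Carlo uncertainties of high-dose voxels;
#' set `floor_fraction = 0` for measured data with trusted errors.
#' Points with non-positive observed or model values are excluded (the log is
#' undefined there) and counted in the report; `ndf` counts included points
#' only.
#'
#' @inheritParams reduced_chi2
#' @param floor_fraction relative error floor, >= 0 (default 0.05).
#' @return A `gof_report` (`space = "log10"`) with `n_excluded`.
#' @export
log10_chi2 <- function(observed, model, sigmas, n_params, floor_fraction = 0.05) {
  n <- length(observed)
  if (length(model) != n || length(sigmas) != n)
    stop("`observed`, `model`, `sigmas` must have equal length", call. = FALSE)
  if (!is.numeric(floor_fraction) || floor_fraction < 0)
    stop("`floor_fraction` must be >= 0", call. = FALSE)
  keep <- is.finite(observed) & is.finite(model) & observed > 0 & model > 0 &
    is.finite(sigmas) & sigmas >= 0
  n_exc <- sum(!keep)
  if (sum(keep) <= n_params)
    stop("too few usable (positive) points for the log10 chi-square",
         call. = FALSE)
  s <- observed[keep]; m <- model[keep]
  sig <- pmax(sigmas[keep], floor_fraction * s)
  if (any(sig <= 0))
    stop("sigmas must be > 0 after flooring", call. = FALSE)
  z <- (log10(s) - log10(m)) / (log_error_coefficient() * sig / s)
  .gof_report(sum(z^2), sum(keep) - n_params, "log10", floor_fraction, n_exc)
}
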