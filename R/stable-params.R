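#' Stable-distribution parameter set
#'
#' Bundles the four parameters of an alpha-stable law: shape (tail index)
#' `alpha`, skewness `beta`, scale `gamma` (mm) and location `delta` (mm).
#' The characteristic function is
#' \deqn{\varphi(t) = \exp[i t \delta - |\gamma t|^\alpha
#'       (1 - i\beta\,\mathrm{sgn}(t)\,\phi(t))]}
#' with \eqn{\phi(t) = \tan(\pi\alpha/2)} for \eqn{\alpha \ne 1} and
#' \eqn{\phi(t) = -(2/\pi)\log|t|} on the \eqn{\alpha = 1} branch.
#' `alpha = 2` is the Gaussian with \eqn{\sigma = \gamma\sqrt{2}},
#' `alpha = 1`, `beta = 0` the Lorentz/Cauchy law.
#'
#' @param alpha shape exponent, in (0, 2].
#' @param beta skewness, in \[-1, 1\]. Supported for evaluation only; fitting
#'   is restricted to symmetric laws.
#' @param gamma scale in mm, > 0.
#' @param delta location in mm, finite.
#' @return An object of class `stable_params`.
#' @examples
#' stable_params(1.8, gamma = 2.5)
#' @export
stable_params <- function(alpha, beta = 0, gamma = 1, delta = 0) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L,
            is.numeric(beta), length(beta) == 1L,
            is.numeric(gamma), length(gamma) == 1L,
            is.numeric(delta), length(delta) == 1L)
  if (!is.finite(alpha) || alpha <= 0 || alpha > 2)
    stop("`alpha` must lie in (0, 2]", call. = FALSE)
  if (!is.finite(beta) || beta < -1 || beta > 1)
    stop("`beta` must lie in [-1, 1]", call. = FALSE)
  if (!is.finite(gamma) || gamma <= 0)
    stop("`gamma` must be > 0", call. = FALSE)
  if (!is.finite(delta))
    stop("`delta` must be finite", call. = FALSE)
  structure(list(alpha = alpha, beta = beta, gamma = gamma, delta = delta),
            class = "stable_params")
}

#' @export
print.stable_params <- function(x, ...) {
  cat(sprintf("stable_params: alpha=%.6g beta=%.6g gamma=%.6g mm delta=%.6g mm\n",
              x$alpha, x$beta, x$gamma, x$delta))
  invisible(x)
}

#' Symmetric zero-centered stable parameters
#'
#' Convenience constructor for the symmetric case `beta = delta = 0`, whose
#' characteristic function reduces to \eqn{\exp(-|\gamma t|^\alpha)}.
#'
#' @inheritParams stable_params
#' @return A `stable_params` object with `beta = delta = 0`.
#' @export
symmetric_stable_params <- function(alpha, gamma = 1) {
  stable_params(alpha, beta = 0, gamma = gamma, delta = 0)
}

is_symmetric_stable <- function(p) p$beta == 0 && p$delta == 0

#' Stable core plus Gaussian background mixture
#'
#' Dual model for the nuclear-halo regime at high beam energies: a heavy-tailed
#' stable core (share `1 - q`) plus a broad normal background (share `q`,
#' spread `sigma`). Because a normal law is itself stable with `alpha = 2` and
#' scale `gamma2 = sigma / sqrt(2)`, the mixture's characteristic function is
#' \deqn{\varphi(t) = (1-q)\exp(-|\gamma_1 t|^\alpha) + q\exp(-|\gamma_2 t|^2).}
#'
#' @param alpha shape of the stable core, in (0, 2].
#' @param gamma1 core scale (mm), > 0.
#' @param q background mixing fraction, in \[0, 1\].
#' @param sigma background Gaussian standard deviation (mm), > 0.
#' @return An object of class `dual_stable_model` with the derived `gamma2`.
#' @examples
#' dual_stable_model(alpha = 1.85, gamma1 = 2.7, q = 0.1, sigma = 20)
#' @export
dual_stable_model <- function(alpha, gamma1, q, sigma) {
  if (!is.numeric(q) || length(q) != 1L || !is.finite(q) || q < 0 || q > 1)
    stop("`q` must lie in [0, 1]", call. = FALSE)
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) || sigma <= 0)
    stop("`sigma` must be > 0", call. = FALSE)
  core <- stable_params(alpha, gamma = gamma1)  # validates alpha, gamma1
  structure(list(alpha = core$alpha, gamma1 = core$gamma, q = q,
                 sigma = sigma, gamma2 = sigma / sqrt(2)),
            class = "dual_stable_model")
}

#' @export
print.dual_stable_model <- function(x, ...) {
  cat(sprintf(
    "dual_stable_model: alpha=%.6g gamma1=%.6g mm q=%.6g sigma=%.6g mm (gamma2=%.6g mm)\n",
    x$alpha, x$gamma1, x$q, x$sigma, x$gamma2))
  invisible(x)
}

#' Evaluation grid of strictly increasing abscissae
#'
#' @param abscissae numeric vector of radii/offsets in mm; finite, strictly
#'   increasing, at least 2 points.
#' @return An object of class `evaluation_grid`.
#' @export
evaluation_grid <- function(abscissae) {
  x <- as.numeric(abscissae)
  if (length(x) < 2L || any(!is.finite(x)) || any(diff(x) <= 0))
    stop("grid must hold >= 2 finite, strictly increasing abscissae",
         call. = FALSE)
  structure(list(abscissae = x), class = "evaluation_grid")
}
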