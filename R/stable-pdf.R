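# Numerical evaluation of alpha-stable densities from the characteristic
# function. Convention used throughout the package:
#   phi(t) = Int f(x) exp(i x t) dx         (forward transform)
#   f(x)   = (1/pi) Int_0^Inf phi(t) cos(x t) dt   for symmetric phi
# so that every density integrates to 1.

.sd_cache <- new.env(parent = emptyenv())

# 10-point Gauss-Legendre reference rule on [0, 1], computed once per process.
.gl_rule <- function() {
  rule <- .sd_cache$gl10
  if (is.null(rule)) {
    rule <- pracma::gaussLegendre(10, 0, 1)
    .sd_cache$gl10 <- rule
  }
  rule
}

# Truncation point of the damped CF integrand: exp(-t^alpha) < eps beyond.
.stable_tmax <- function(alpha, eps = 1e-16) (-log(eps))^(1 / alpha)

# Panel breakpoints on [0, tmax]: uniform panels no wider than half a period
# of cos(s_max * t), with geometric grading toward t = 0 to absorb the t^alpha
# cusp of the integrand for alpha < 1 (and its higher derivatives for
# non-integer alpha).
.stable_t_nodes <- function(alpha, s_max) {
  tmax <- .stable_tmax(alpha)
  width <- min(pi / max(s_max, 1e-12), tmax / 16)
  brk <- seq(0, tmax, by = width)
  if (brk[length(brk)] < tmax) brk <- c(brk, tmax)
  graded <- brk[2] * 2^seq(-24, -1)
  brk <- sort(unique(c(graded, brk)))
  gl <- .gl_rule()
  h <- diff(brk)
  # nodes/weights for all panels at once
  t <- as.vector(outer(gl$x, h) + rep(brk[-length(brk)], each = length(gl$x)))
  w <- as.vector(outer(gl$w, h))
  list(t = t, w = w)
}

# Asymptotic power-law tail of the standardized symmetric stable density,
# first `terms` terms:
#   f(s) ~ (1/pi) sum_k (-1)^(k+1) Gamma(k*alpha + 1)/k! sin(k pi alpha/2)
#          s^(-k*alpha - 1)
.stable_tail_std <- function(s, alpha, terms = 4L) {
  out <- numeric(length(s))
  for (k in seq_len(terms)) {
    ck <- (-1)^(k + 1) * gamma(k * alpha + 1) / factorial(k) *
      sin(k * pi * alpha / 2) / pi
    out <- out + ck * s^(-k * alpha - 1)
  }
  pmax(out, 0)
}

# Standardized symmetric stable density f(s; alpha), gamma = 1. Vectorized
# over s through a shared panel rule sized for max(|s|); beyond the switch
# point the asymptotic series is used (both agree to well below 1e-9 there).
.stable_pdf_std <- function(s, alpha, tail_switch = 500) {
  s <- abs(as.numeric(s))
  out <- numeric(length(s))
  far <- s > tail_switch
  if (alpha < 2) out[far] <- .stable_tail_std(s[far], alpha)
  if (any(!far)) {
    ss <- s[!far]
    nodes <- .stable_t_nodes(alpha, max(ss))
    g <- nodes$w * exp(-nodes$t^alpha)
    vals <- numeric(length(ss))
    chunk <- max(1L, floor(4e6 / length(nodes$t)))
    idx <- 1L
    while (idx <= length(ss)) {
      j <- idx:min(idx + chunk - 1L, length(ss))
      vals[j] <- as.vector(cos(outer(ss[j], nodes$t)) %*% g)
      idx <- idx + chunk
    }
    out[!far] <- pmax(vals / pi, 0)
  }
  out
}

# Memoised natural-spline representation of the standardized density for one
# exact alpha, valid on s in [0, s_cap]; used by the dose engine and fitting
# helpers where the same alpha is evaluated at many abscissae.
.stable_spline_std <- function(alpha, s_cap = 520) {
  key <- sprintf("spl_%.12g_%g", alpha, s_cap)
  f <- .sd_cache[[key]]
  if (is.null(f)) {
    grid <- c(seq(0, 4, by = 0.02), seq(4, 20, by = 0.1),
              if (s_cap > 20) seq(20, min(60, s_cap), by = 0.5),
              if (s_cap > 60) seq(60, s_cap, by = 2.5))
    grid <- unique(c(grid[grid <= s_cap], s_cap))
    vals <- .stable_pdf_std(grid, alpha)
    f <- stats::splinefun(grid, vals, method = "natural")
    .sd_cache[[key]] <- f
  }
  f
}

# Standardized density evaluated through the spline cache with series tail.
.stable_pdf_std_cached <- function(s, alpha, s_cap = 520) {
  s <- abs(as.numeric(s))
  out <- numeric(length(s))
  far <- s > s_cap
  if (alpha < 2) out[far] <- .stable_tail_std(s[far], alpha)
  if (any(!far)) out[!far] <- pmax(.stable_spline_std(alpha, s_cap)(s[!far]), 0)
  out
}

.phi_factor <- function(t, alpha) {
  if (alpha == 1) -(2 / pi) * log(abs(t)) else tan(pi * alpha / 2)
}

#' Characteristic function of a stable law
#'
#' Evaluates \eqn{\varphi(t) = \exp[i t \delta - |\gamma t|^\alpha
#' (1 - i\beta\,\mathrm{sgn}(t)\,\phi(t))]} with
#' \eqn{\phi(t)=\tan(\pi\alpha/2)} (\eqn{\alpha\neq 1}) or
#' \eqn{-(2/\pi)\log|t|} (\eqn{\alpha=1}). For `beta = delta = 0` this is the
#' real-valued \eqn{\exp(-|\gamma t|^\alpha)}.
#'
#' @param t numeric vector of frequencies (1/mm); finite.
#' @param p a [stable_params()] object.
#' @return Complex vector of the same length as `t`; `stable_cf(0, p)` is 1.
#' @examples
#' stable_cf(1, stable_params(2))   # exp(-1)
#' @export
stable_cf <- function(t, p) {
  stopifnot(inherits(p, "stable_params"))
  if (any(!is.finite(t))) stop("`t` must be finite", call. = FALSE)
  out <- complex(length(t))
  nz <- t != 0
  out[!nz] <- 1 + 0i
  if (any(nz)) {
    tn <- t[nz]
    phi <- .phi_factor(tn, p$alpha)
    out[nz] <- exp(1i * tn * p$delta -
                     abs(p$gamma * tn)^p$alpha *
                       (1 - 1i * p$beta * sign(tn) * phi))
  }
  out
}

# Quadrature inversion for skewed laws:
#   f(x) = (1/pi) Int_0^Inf Re[ phi(t) exp(-i x t) ] dt.
# Panels follow the dominant local oscillation frequency.
.stable_pdf_skew <- function(x, p) {
  alpha <- p$alpha
  tmax <- .stable_tmax(alpha) / p$gamma
  vapply(x, function(xi) {
    freq <- abs(xi - p$delta)
    if (alpha != 1) {
      freq <- freq + alpha * abs(p$beta * tan(pi * alpha / 2)) *
        p$gamma^alpha * tmax^(alpha - 1)
    } else {
      freq <- freq + (2 / pi) * p$gamma * (1 + abs(log(tmax)))
    }
    width <- min(pi / max(freq, 1e-12), tmax / 16)
    brk <- seq(0, tmax, by = width)
    if (brk[length(brk)] < tmax) brk <- c(brk, tmax)
    brk <- sort(unique(c(brk[2] * 2^seq(-24, -1), brk)))
    gl <- .gl_rule()
    h <- diff(brk)
    t <- as.vector(outer(gl$x, h) + rep(brk[-length(brk)], each = length(gl$x)))
    w <- as.vector(outer(gl$w, h))
    sum(w * Re(stable_cf(t, p) * exp(-1i * xi * t))) / pi
  }, numeric(1))
}

# FFT backend: trapezoid discretization of the full inverse transform on a
# uniform t-grid (spectrally accurate for the smooth, decaying integrand),
# followed by spline interpolation onto the requested abscissae.
.stable_pdf_fft <- function(x, p, n = 2^21L, dt_std = 6e-4) {
  dt <- dt_std / p$gamma
  k <- seq_len(n) - 1L
  tk <- (k - n / 2) * dt
  ph <- stable_cf(tk, p)
  f <- Re((-1)^k * stats::fft(ph * (-1)^k)) * (dt / (2 * pi))
  if (n %% 4L != 0L) f <- -f
  dx <- 2 * pi / (n * dt)
  xg <- (k - n / 2) * dx
  keep <- abs(xg - p$delta) <= min(600 * p$gamma, max(abs(xg)))
  stats::spline(xg[keep], f[keep], xout = x, method = "natural")$y
}

#' Stable probability density
#'
#' Numerically inverts the characteristic function to the density. The
#' `"quadrature"` backend integrates
#' \eqn{f(x) = (1/\pi)\int_0^\infty e^{-(\gamma t)^\alpha}\cos(xt)\,dt}
#' (symmetric case) with panel-wise Gauss-Legendre rules tied to the cosine
#' half-periods and switches to the asymptotic power-law series in the far
#' tail; the `"fft"` backend discretizes the full inverse Fourier transform
#' and serves as an independent cross-check. Skewed laws (`beta != 0`) are
#' supported for evaluation through the complex quadrature.
#'
#' @param x numeric vector of offsets (mm).
#' @param p a [stable_params()] object.
#' @param method `"quadrature"` (default) or `"fft"`.
#' @return Density values (1/mm), non-negative, integrating to 1.
#' @examples
#' dstable(0, stable_params(2))    # 1/(2*sqrt(pi))
#' dstable(0, stable_params(1))    # 1/pi (Cauchy)
#' @export
dstable <- function(x, p, method = c("quadrature", "fft")) {
  stopifnot(inherits(p, "stable_params"))
  method <- match.arg(method)
  if (any(!is.finite(x))) stop("`x` must be finite", call. = FALSE)
  if (method == "fft") return(pmax(.stable_pdf_fft(x, p), 0))
  if (is_symmetric_stable(p)) {
    .stable_pdf_std((x - p$delta) / p$gamma, p$alpha) / p$gamma
  } else {
    pmax(.stable_pdf_skew(x, p), 0)
  }
}

#' Closed-form stable densities
#'
#' The three members of the stable family with an elementary density:
#' Gaussian (`alpha = 2`, \eqn{\sigma = \gamma\sqrt2}), Lorentz/Cauchy
#' (`alpha = 1`) and the one-sided Levy law (`alpha = 1/2`, `beta = 1`,
#' support `x > 0`).
#'
#' @param x numeric vector of offsets (mm).
#' @param which `"gauss"`, `"lorentz"` or `"levy"`.
#' @param gamma scale (mm), > 0.
#' @return Density values (1/mm). For `"levy"`, 0 at and left of the support
#'   boundary `x = 0`.
#' @export
dstable_closed <- function(x, which = c("gauss", "lorentz", "levy"), gamma = 1) {
  which <- match.arg(which)
  if (!is.numeric(gamma) || length(gamma) != 1L || !is.finite(gamma) || gamma <= 0)
    stop("`gamma` must be > 0", call. = FALSE)
  switch(which,
    gauss = exp(-x^2 / (4 * gamma^2)) / (2 * gamma * sqrt(pi)),
    lorentz = gamma / (pi * (gamma^2 + x^2)),
    levy = ifelse(x > 0,
                  sqrt(gamma / (2 * pi)) * x^(-1.5) * exp(-gamma / (2 * x)),
                  0))
}

#' Density of the stable-plus-Gaussian dual model
#'
#' \eqn{(1-q)\,S(x;\alpha,\gamma_1) + q\,N(x;\sigma)}: the mixture of the
#' stable core and the normal background of a [dual_stable_model()].
#'
#' @param x numeric vector of offsets (mm).
#' @param m a [dual_stable_model()].
#' @return Density values (1/mm); integrates to 1.
#' @export
ddualstable <- function(x, m) {
  stopifnot(inherits(m, "dual_stable_model"))
  (1 - m$q) * dstable(x, symmetric_stable_params(m$alpha, m$gamma1)) +
    m$q * stats::dnorm(x, sd = m$sigma)
}

#' Combine scales of two same-shape stable laws
#'
#' Convolving two symmetric stable laws with a common shape `alpha` and scales
#' `gamma1`, `gamma2` yields a stable law with scale
#' \eqn{(\gamma_1^\alpha + \gamma_2^\alpha)^{1/\alpha}} — the closure property
#' used to fold the in-air source spread into the in-medium scale.
#'
#' @param gamma1,gamma2 scales (mm), >= 0 and not both 0.
#' @param alpha shared shape, in (0, 2].
#' @return Combined scale (mm); symmetric in its arguments and never smaller
#'   than either input.
#' @examples
#' combine_stable_scales(3, 4, alpha = 2)  # 5
#' @export
combine_stable_scales <- function(gamma1, gamma2, alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) ||
      alpha <= 0 || alpha > 2)
    stop("`alpha` must lie in (0, 2]", call. = FALSE)
  if (any(!is.finite(c(gamma1, gamma2))) || any(c(gamma1, gamma2) < 0) ||
      all(c(gamma1, gamma2) == 0))
    stop("scales must be >= 0 and not both 0", call. = FALSE)
  (gamma1^alpha + gamma2^alpha)^(1 / alpha)
}

# Evaluate `code` under a private RNG stream seeded by `seed`, restoring the
# caller's generator state afterwards.
.with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single finite number", call. = FALSE)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Draw symmetric stable variates (Chambers-Mallows-Stuck)
#'
#' Exact sampling of the symmetric zero-centered stable law by the
#' Chambers-Mallows-Stuck transform
#' \deqn{X = \gamma\,\frac{\sin(\alpha U)}{(\cos U)^{1/\alpha}}
#'       \left[\frac{\cos((1-\alpha)U)}{W}\right]^{(1-\alpha)/\alpha}}
#' with \eqn{U \sim \mathrm{Unif}(-\pi/2,\pi/2)}, \eqn{W \sim \mathrm{Exp}(1)}
#' (Cauchy shortcut \eqn{\gamma\tan U} at \eqn{\alpha = 1}). The seed is a
#' required argument; global RNG state is left untouched.
#'
#' @param n number of draws, >= 1.
#' @param p a symmetric [stable_params()] (beta = delta = 0).
#' @param seed integer seed; identical seeds give identical draws.
#' @return Numeric vector of `n` draws (mm).
#' @export
rstable_sym <- function(n, p, seed) {
  stopifnot(inherits(p, "stable_params"))
  if (!is_symmetric_stable(p))
    stop("sampling is implemented for symmetric zero-centered laws",
         call. = FALSE)
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stop("`n` must be >= 1", call. = FALSE)
  n <- as.integer(n)
  .with_seed(seed, {
    u <- stats::runif(n, -pi / 2, pi / 2)
    if (p$alpha == 1) {
      p$gamma * tan(u)
    } else {
      w <- stats::rexp(n)
      a <- p$alpha
      p$gamma * (sin(a * u) / cos(u)^(1 / a)) *
        (cos((1 - a) * u) / w)^((1 - a) / a)
    }
  })
}
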