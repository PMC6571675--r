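---
title: "Modelling proton pencil beams with stable distributions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling proton pencil beams with stable distributions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stabledose)
```

## The model

A scanned proton pencil beam entering water develops a *nuclear halo*: a
low-dose envelope of large-angle scattered protons and secondary particles
around the multiple-scattering core. Treatment planning systems usually model
the lateral dose profile at each depth as one or two Gaussians; the halo then
forces either extra Gaussian components or large parameter sets.

`stabledose` instead models the lateral profile at depth $z$ as a symmetric
alpha-stable distribution $S(r;\alpha(z),\gamma(z))$. Stable laws are the
closure of the central limit theorem with or without finite variance, so they
interpolate continuously between the Gaussian ($\alpha = 2$) and ever
heavier-tailed shapes — exactly the degrees of freedom the halo needs. Two
parameters take physical roles:

* $\alpha$ — *tailedness*; it tracks the relative halo contribution and dips
  below 2 mid-range, returning toward the Gaussian limit past the Bragg peak,
* $\gamma$ — *scale* (mm); it tracks beam divergence plus primary scatter.

Stable densities generally have no closed form (only the Gaussian, the
Lorentz/Cauchy at $\alpha = 1$, and the Lévy law at $\alpha = 1/2,\beta=1$
do), so everything is computed from the characteristic function
$$\varphi(t) = \exp[\,it\delta - |\gamma t|^\alpha(1 -
i\beta\,\mathrm{sgn}(t)\phi(t))\,],\qquad
\phi(t) = \tan(\pi\alpha/2)\ \text{or}\ -(2/\pi)\log|t|\ (\alpha = 1).$$

### Fourier convention

We use the self-consistent pair
$\varphi(t) = \int f(x)e^{ixt}\,dx$ and, for symmetric laws,
$f(x) = (1/\pi)\int_0^\infty \varphi(t)\cos(xt)\,dt$, so every density
integrates to one. Two related conventions that circulate in the applied
literature (a $1/2\pi$ on the forward transform together with an
unnormalized inverse) are mutually inconsistent; probabilistic semantics
forces the pair above. Two further normalization choices are documented
prominently because they are easy to get wrong:

* the Gaussian member has $\sigma = \gamma\sqrt{2}$, so the Gaussian
  background of the dual model (below) enters as a stable law with scale
  $\gamma_2 = \sigma/\sqrt{2}$, and
* the $\alpha = 1$ branch of $\phi$ must carry $\log|t|$, not $\log t$, for
  the characteristic function to be Hermitian.

### Numerical inversion

`dstable()` integrates the damped oscillation
$f(x) = (1/\pi)\int_0^{t_{\max}} e^{-(\gamma t)^\alpha}\cos(xt)\,dt$ with
panel-wise 10-point Gauss–Legendre rules: panels no wider than half a period
of $\cos(xt)$, geometric grading toward $t = 0$ (the integrand has a
$t^\alpha$ cusp there for non-integer $\alpha$), and
$t_{\max} = (-\ln\varepsilon)^{1/\alpha}/\gamma$ with
$\varepsilon = 10^{-16}$. Beyond $|x|/\gamma = 500$ the four-term asymptotic
series $f(x) \approx \frac1\pi\sum_k (-1)^{k+1}
\frac{\Gamma(k\alpha+1)}{k!}\sin(k\pi\alpha/2)\,\gamma^{k\alpha}
|x|^{-k\alpha-1}$ takes over; at the switch point both evaluations agree to
well below $10^{-9}$. An independent FFT backend (trapezoid discretization of
the full inverse transform, spectrally accurate for this smooth decaying
integrand) is kept as a cross-check; the two agree to $10^{-8}$ absolute,
and both match the Gaussian and Cauchy closed forms to better than
$10^{-9}$.

Repeated evaluation at a fixed shape (the dose engine queries thousands of
radii per depth slice) goes through a memoised natural-spline table of the
standardized density per *exact* $\alpha$ value. We deliberately do not
interpolate between tabulated $\alpha$ values at a fixed resolution: a
0.01-wide $\alpha$ grid would inject model error of the same order as the
fit-recovery tolerances, while lazy per-$\alpha$ splines are exact in
$\alpha$ and amortize equally well.

Skewed laws ($\beta \ne 0$) are supported in evaluation only, through the
complex form of the same quadrature; fitting is restricted to symmetric
zero-centered profiles (an optional centroid shift handles off-axis data —
location is a coordinate transform, never a fit parameter).

## Fitting per-depth profiles

`fit_stable()` estimates $(\alpha, \gamma)$ with the profile amplitude
profiled out analytically (it is a linear parameter). Two objectives are
available:

* `"ml"` (default) — the dose-weighted multinomial log-likelihood
  $\sum_i w_i\log p_i$, $w_i \propto S_i$, $p_i$ the model bin mass: the
  binned analogue of maximum likelihood on profile data;
* `"logchi2"` — direct minimization of the log10-space $\chi^2$ below.

Bounds and starts: $\alpha \in [0.3, 2]$ starting at 1.9, $\gamma$ starting
at half the FWHM estimate and bounded between a tenth of the grid spacing
and the grid width, optimized by L-BFGS-B on $(\alpha, \log\gamma)$.
Parameters pinned at a bound are flagged, as is optimizer non-convergence;
$\alpha = 2$ is a legitimate interior answer physically (a Gaussian beam)
even though it is the boundary of the family. On noiseless synthetic
profiles the recovery error is below $10^{-5}$ relative; under the 0.5%
multiplicative noise model of measured commissioning data it stays within
$\pm 0.01$ on $\alpha$ and 0.5% on $\gamma$ (the package's acceptance gates
are the looser $\pm 0.05$ / 2%).

### Goodness of fit in log space

Lateral profiles span four to five decades, so a linear reduced $\chi^2$ is
dominated by the peak. `log10_chi2()` implements
$$\chi^2 = \sum_i\left[\frac{\log_{10}S_i - \log_{10}\mathbf{S}_i}
{0.434\,\sigma_i'/S_i}\right]^2,\qquad
\sigma_i' = \max(\sigma_i, \mathrm{floor}\cdot S_i),$$
where $0.434 = 1/\ln 10$ is the error-propagation coefficient (computed at
full precision, never hard-coded). The relative error floor (default 5%)
exists for Monte-Carlo-type reference data whose high-dose voxels carry
unrealistically small statistical errors; for measured data with trusted
uncertainties it defaults to off in the fitting layer. Points with
non-positive dose or model are excluded from the log-space statistic and
reported; the degrees of freedom count included points only.

### The dual model for the high-energy halo

At the highest beam energies a single stable law underestimates the
mid-radius dose. The dual model adds a normally distributed background:
$$(1-q)\,S(r;\alpha,\gamma_1) + q\,N(r;\sigma),\qquad
\varphi(t) = (1-q)e^{-|\gamma_1 t|^\alpha} + q\,e^{-|\gamma_2 t|^2},$$
with $\gamma_2 = \sigma/\sqrt 2$. `fit_dual_stable()` follows the iterative
scheme: single stable fit as the starting point; Levenberg–Marquardt fit of
$(q, \sigma)$; stable refit against the profile minus the fitted background;
background refit; iterated to a $10^{-8}$ relative parameter tolerance
(at most 200 outer iterations). Because the amplitude is shared, the
refit-on-subtracted-data step is algebraically the same weighted residual
with $(q,\sigma)$ frozen, so the alternation is block coordinate descent on
one objective and its convergence is monotone. On strongly coupled mixtures
that descent can stall in a basin where $q$ sticks at its upper bound (the
background trades off against the core's tail index), so the result is
polished by a joint Levenberg–Marquardt refinement over all four parameters,
run from both the alternation result and the single-fit start; the better of
the two is returned together with both goodness-of-fit reports. On the
synthetic halo fixture the polish recovers the generating parameters to
machine precision, and the $\chi^2/\mathrm{NDF}$ ordering
dual < single stable < double Gaussian holds.

### The reference double Gaussian

`fit_double_gaussian()` fits the classical core-plus-halo mixture
$(1-q)N(0,\sigma_1) + qN(0,\sigma_2)$ by uncertainty-weighted
Levenberg–Marquardt, amplitude profiled, $\sigma_1 \le \sigma_2$ enforced by
swap. (The mixture is written as 1D densities; the areal 2D form differs
only in the amplitude convention, which is profiled out anyway.) Its role is
the robustness contrast: on a profile with a stable power-law tail the
fitted $\sigma_2$ chases whatever tail segment the detector window exposes
and moves by tens of percent as the window grows from 100 to 200 mm, while
the stable $\gamma$ moves by less than $10^{-4}$ relative. Note the contrast
requires a power-law tail — if the data genuinely contain a Gaussian
background (the dual fixture), $\sigma_2$ correctly locks onto it and is
window-stable; the package's robustness checks therefore use the
heavy-tailed single-stable fixture.

## Whole-beam parameterization and the dose engine

`parameterize_beam()` reduces a stack of per-depth profiles to three curves
$\alpha(z), \gamma(z), I_D(z)$ plus the range $\mathcal{R}$ — the complete
description of one nominal energy. $I_D$, the per-plane integral dose
(arbitrary dose·mm² units; only ratios matter downstream), is the fitted
amplitude times the shell normalization
$$V(\alpha,\gamma) = 2\pi\int_0^\infty r\,S(r;\alpha,\gamma)\,dr
= \gamma\,V(\alpha,1),$$
computed by direct quadrature plus the analytic integral of the asymptotic
tail (and cross-checked in the tests against the closed first absolute
moment $2\gamma\,\Gamma(1-1/\alpha)$). $V$ diverges for $\alpha \le 1$;
machine files with any tabulated $\alpha \le 1$ are rejected at load time
for that reason. During dose calculation $V$ comes from a precomputed
interpolation table (`precompute_V_table()`); $V$ is linear in $\gamma$, and
a 0.05-wide $\alpha$ grid keeps the bilinear error below 0.1% for
$\alpha \gtrsim 1.6$ (the engine's internal table uses 0.005).

The radial 2D kernel is $L(r;z) = S(r)/V$, normalized so
$2\pi\int r L\,dr = 1$, and the reconstructed dose is
$D(r;z) = I_D(z)\,L(r;z)$. `compute_dose_grid()` evaluates this per voxel:
depth along the beam axis and perpendicular radius from the axis, linear
interpolation of the three curves in depth (the interpolation order is our
choice; tabulated machine data do not prescribe one), voxel value = dose at
the voxel center, zero beyond the tabulated depth interval. An optional
in-air source spread $\sigma_{\rm air}$ is folded into $\gamma(z)$ by the
same-shape scale-combination rule
$\gamma = (\gamma_1^\alpha+\gamma_2^\alpha)^{1/\alpha}$ evaluated with the
surface shape $\alpha(0)$ (combining different $\alpha$ is not closed and is
out of scope). Axis-aligned beams hit exact per-slice depths; oblique beams
quantize depth to a quarter of the smallest voxel spacing only when the
number of distinct depths becomes large.

Verification is three-fold: per-slice dose sums conserve the interpolated
$I_D(z)$; a brute-force oracle re-computes the grid by $5^3$ sub-voxel
sampling with direct (non-table) $V$; and with $\alpha \equiv 2$ the engine
matches an independent closed-form Gaussian pencil-beam implementation to
0.1% pointwise above $10^{-4}$ of the maximum.

## Intermediate morphing and minimal commissioning

Beams at uncommissioned energies are synthesized by *intermediate morphing*:
both bracketing parameterizations are mapped onto the fractional-depth axis
$u = z/\mathcal{R}(E)$ (the only correspondence that aligns Bragg peaks;
equivalently $z_i = z_l\,\mathcal{R}(E_i)/\mathcal{R}(E_l)$), linearly
blended with weight $w = (E_i-E_l)/(E_u-E_l)$, and mapped back through
$\mathcal{R}(E_i)$. The common $u$-grid is the union of both source node
sets merged with a uniform 512-point grid, so machines tabulated on a shared
fractional-depth grid morph *exactly* — morphing is then exact by
construction on any family affine in $E$ at fixed $u$, which the tests
exploit. No extrapolation outside the bracketing interval is permitted.
The range model is either a commissioning table (always preferred) or the
Bragg–Kleeman power law $\mathcal{R}\,[\mathrm{cm}] = 0.0022\,E^{1.77}$ with
standard literature water coefficients — an implementation convenience, not
a measured fact.

`validate_morph()` scores a prediction against a reference curve by the
maximum relative deviations of $\gamma$ (threshold 1%), $\alpha$ (3%), $I_D$
relative to the curve maximum (1%) and the Bragg-peak position (1 mm). The
dose criterion is applied as a max-relative over the curve plus a separate
peak-position shift, since a single "1% dose and 1 mm position" statement
does not distinguish the two. `minimal_commissioning_set()` then greedily
keeps the endpoint energies and adds the worst threshold violator until
every omitted energy morphs within tolerance. On a machine linear in $E$
only the endpoints survive; on the mildly curved 21-energy fixture the kept
fraction is 3/21, comfortably inside a one-in-five commissioning budget.

## What the synthetic fixtures emulate — and what they do not

All tests run on generated data; no external measurements are shipped.

* **Profiles** (`make_profile()`, `make_halo_profile()`): exact model curves
  times $(1+\eta)$, $\eta \sim N(0, 0.005)$ — the order of the measurement
  error of pin-point chamber profile data; the sigma column carries the true
  noise sd. Seeds are mandatory arguments; there is no hidden global state.
* **Machines** (`machine_recipe()`, `make_machine()`): smooth parametric
  curves on the fractional-depth axis. The default shape curve
  $\alpha(u) = 2 - 0.2\sin^2(\pi u)$ (floored at 1.5) reproduces the
  qualitative dip-and-return of commissioned beams without claiming their
  values. The scale curve is a quadrature sum of an energy-dependent in-air
  spot ($\sigma_0$ of a few mm, narrowing with energy like a scanning
  nozzle) and a multiple-scattering term growing like $u^{1.7}$ to ~2.1% of
  the range — Highland-like growth. The depth-dose is a rising entrance
  plateau plus a Gaussian Bragg peak at $u = 0.96$ of width 5 mm, with the
  plateau switched off distally. The broad-spot variant
  ($\sigma_0 = 8$ mm at 70 MeV) used in the engine-oracle comparisons and
  the small-spot variant ($\sigma_0 = 2.5$ mm) used in the conservation
  check are both plausible nozzles; the two are needed because sub-voxel
  averaging error scales like $1/\sigma^2$ while out-of-grid tail mass
  scales like $\gamma^\alpha$, pulling the geometry in opposite directions.
* **Not emulated**: nuclear interaction physics, neutron/δ-ray transport,
  beam asymmetry, heterogeneous media, and the machine-specific parameter
  values of any real facility. Passing tests therefore demonstrate the
  correctness and self-consistency of the numerics and the pipeline, not
  agreement with any particular machine's commissioning data.

## Numerical choices and problem sizes

Profile fits use 201-point grids over ±100 mm (or 0–200 mm radial) — the
lateral extent of a typical scanned-beam commissioning scan. The engine
checks use a 50×50×80 mm³ water grid at 1 mm voxels (the classical
simulation geometry at reduced size) for the oracle comparisons, and a
±480 mm, 2 mm-voxel grid for slice conservation: with the shape dipping to
$\alpha = 1.8$, the power-law tail mass outside radius $R$ falls off only
like $R^{1-\alpha}$, so capturing 99.5% of a plane genuinely requires
half-metre lateral coverage — an instructive, physically real feature of
heavy-tailed beam models. Degenerate inputs are rejected loudly (non
increasing radii, $\alpha \le 1$ machine entries, non-overlapping morph
intervals); ties at optimizer bounds are flagged on the result rather than
silently accepted.

## Known limitations

* Fitting is symmetric-only; $\beta \ne 0$ is evaluation-only, and
  the far-tail series is implemented for symmetric laws.
* Combining stable laws with *different* $\alpha$ (elliptical spots) has no
  closed form and is out of scope.
* The dose engine assumes a homogeneous water medium; no radiological depth.
* $\chi^2/\mathrm{NDF}$ is used descriptively, with no significance
  testing.
* The spot-size and Bragg-curve shapes of the fixtures are qualitative
  emulations; none of their parameter values should be read as a
  commissioning claim.
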