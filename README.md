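# stabledose

Stable-distribution modelling of proton pencil beams in water.

## The problem

A scanned proton pencil beam is not a Gaussian. Large-angle scattered
protons and secondary particles deposit a *nuclear halo* of low dose far
from the central axis, and treatment-planning dose engines that model the
lateral profile with one or two Gaussians either miss that halo or pay for
it with many extra parameters whose values depend on the detector window
used to measure them.

`stabledose` models the lateral dose profile at each depth *z* as a
symmetric **alpha-stable distribution** S(r; α(z), γ(z)): the family closed
under addition of independent variables, spanning the Gaussian (α = 2)
through ever heavier power-law tails as α decreases. Two parameters carry
the physics — α tracks the halo ("tailedness"), γ the width — and a whole
beam of nominal energy E collapses to three depth curves plus its range:

    α(z; E),   γ(z; E),   I_D(z; E),   ℛ(E)

where I_D is the integral dose in the transverse plane at depth z. Voxel
dose is then the product of a depth factor and a lateral kernel,

    D(r; z) = I_D(z) · S(r; α(z), γ(z)) / V(α(z), γ(z)),
    V(α, γ) = 2π ∫₀^∞ r S(r; α, γ) dr         (shell normalization),

and beams at uncommissioned energies are synthesized by *intermediate
morphing*: range-scaled linear interpolation of the three curves between two
bracketing commissioned energies.

Stable densities have no closed form in general, so everything is evaluated
from the characteristic function φ(t) = exp(−|γt|^α) by panel-wise
Gauss–Legendre inversion with an asymptotic tail series (an FFT backend
serves as an independent cross-check). Goodness of fit uses a reduced χ² in
log10 space, χ² = Σ[(log₁₀Sᵢ − log₁₀𝐒ᵢ)/(0.434 σᵢ/Sᵢ)]², with an optional
5% relative error floor for Monte-Carlo-type reference data.

The package is aimed at medical-physics researchers prototyping analytic
dose engines and beam-model commissioning workflows; every input it needs
can be generated by its own synthetic fixture module, so the full pipeline
runs and is tested without any external data.

## Worked example

```r
library(stabledose)

# a noisy synthetic commissioning profile: alpha = 1.8, gamma = 2.5 mm,
# 0.5% multiplicative noise
grid <- evaluation_grid(seq(-100, 100, by = 1))
prof <- make_profile(symmetric_stable_params(alpha = 1.8, gamma = 2.5), grid,
                     noise_model(relative_sd = 0.005, seed = 7),
                     amplitude = 1000, depth = 100, energy = 176)
fit_stable(prof)
#> stable_fit: alpha=1.7997 gamma=2.5007 mm amplitude=998.28 chi2/NDF=0.9368

# the high-energy halo regime: stable core + Gaussian background
halo <- dual_stable_model(alpha = 1.85, gamma1 = 2.7, q = 0.1, sigma = 20)
hp <- make_halo_profile(halo, evaluation_grid(seq(0, 200, by = 1)),
                        noise_model(0.005, seed = 3))
fit_dual_stable(hp)
#> dual_stable_fit: alpha=1.8499 gamma1=2.7006 q=0.10003 sigma=20.004 |
#>   chi2/NDF dual=0.9825 single=9.462e+04 (19 iter)

# a three-energy synthetic machine and a 3D dose grid
mach <- make_machine(machine_recipe(c(70, 95, 120),
                                    sigma0_ref_mm = 8, e_ref = 70))
dose <- compute_dose_grid(mach, beam_spec(95, entry = c(24.5, 24.5, 0)),
                          grid_spec(c(50, 50, 80), 1, origin = c(0, 0, 0.5)))
dose
#> dose_grid: 50x50x80 voxels, spacing 1x1x1 mm, max dose 0.0038118
which.max(dose$values[25, 25, ])  # central-axis Bragg peak at z = 66.5 mm
```

The single fit recovers the generating parameters to 0.02% and its reduced
χ² of 0.94 says the model matches the data within the stated 0.5% errors.
The dual fit pulls the background fraction q = 0.100 and spread σ = 20.0 mm
out of the noisy halo profile, and its χ²/NDF of 0.98 against 9.5 × 10⁴ for
the single-stable fit quantifies how much the background matters at high
energy. In the dose grid, the central-axis maximum sits at 66.5 mm — the
Bragg peak of the 95 MeV beam, at 96% of its 69.7 mm range.

Command-line use (same pipeline over CSV/JSON files):

```sh
Rscript inst/cli/stabledose synth profile --noise 0.005 --seed 7 --out prof.csv
Rscript inst/cli/stabledose fit prof.csv --out fit.json
Rscript inst/cli/stabledose synth machine --energies 90,100,110 --out machine.json
Rscript inst/cli/stabledose dose machine.json --energy 100 --grid 50x50x80 \
        --voxel 1 --out dose.raw
```

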