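Package: stabledose
Title: Stable-Distribution Modelling of Proton Pencil Beams
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Characterizes the lateral dose profile of scanned proton pencil
    beams in a medium with alpha-stable distributions. Evaluates stable
    densities numerically from the characteristic function (panel-wise
    Gauss-Legendre inversion with an asymptotic tail series and an FFT
    cross-check), fits single-stable, stable-plus-Gaussian-background and
    reference double-Gaussian models to per-depth lateral profiles with a
    log10-space reduced chi-square goodness of fit, parameterizes whole beams
    as depth curves of shape alpha(z), scale gamma(z) and integral dose
    I_D(z), interpolates uncommissioned energies by range-scaled intermediate
    morphing, selects minimal commissioning sets, and reconstructs 3D dose
    grids in water with a shell-formula 2D normalization. Ships a synthetic
    fixture generator (noisy profiles, halo profiles, multi-energy machine
    libraries, brute-force reference dose grids) so the whole pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    jsonlite,
    minpack.lm,
    pracma
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
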