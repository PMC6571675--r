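# Shared fixtures, all generated in code.

std_grid <- function(rmax = 100, step = 1, signed = TRUE)
  evaluation_grid(if (signed) seq(-rmax, rmax, by = step)
                  else seq(0, rmax, by = step))

# the standard halo model of the high-energy regime
halo_model <- function() dual_stable_model(1.85, 2.7, q = 0.1, sigma = 20)

# machine recipes used across beam-model and morphing tests
linear_recipe <- function(energies, n_depths = 60L)
  machine_recipe(energies, n_depths = n_depths,
    alpha_fun = function(u, E) 1.7 + 0.2 * pmin(u, 1) + 5e-4 * E * (1 - pmin(u, 1)),
    gamma_fun = function(u, E) (1.5 + 2 * u^1.3) * (1 + 0.002 * (E - 120)),
    id_fun = function(u, E) (0.3 + 0.7 * exp(-(u - 0.96)^2 / 0.005)) *
      (1 + 0.001 * (E - 120)))

mild_recipe <- function(energies, curvature = 2e-6, n_depths = 60L)
  machine_recipe(energies, n_depths = n_depths,
    gamma_fun = function(u, E) (1.5 + 2 * u^1.3) *
      (1 + 0.002 * (E - 150) + curvature * (E - 150)^2),
    id_fun = function(u, E) 0.3 + 0.7 * exp(-(u - 0.96)^2 / 0.005))
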