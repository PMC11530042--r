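# Shared helpers: small grids and independent numerical oracles.

uniform_grid <- function(n, dx = 1, D = 1, A = 1, name = "medium") {
  grid_1d(layer_spec(name, n * dx, D), dx, A)
}

# Exponential integral E1 by numerical quadrature (oracle for the 2-D
# continuous point-source solution), independent of the solver.
E1_quad <- function(x) {
  stats::integrate(function(u) exp(-u) / u, x, Inf, rel.tol = 1e-10)$value
}

# Fraction released by a slab into a sink, early-time closed form.
slab_early_time <- function(Dt_over_L2) 2 * sqrt(Dt_over_L2 / pi)

# Fast coarse bone-plate config for scenario/sensitivity tests.
coarse_plate_config <- function(overrides = list()) {
  base <- list(geometry = list(tissue_dx_mm = 0.3),
               run = list(t_end = 24, record_every = 1))
  default_config("human_bone_plate", vancoelute:::.merge_lists(base, overrides))
}
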