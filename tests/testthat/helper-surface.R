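# Shared fixtures built once per test run.
#
# The shared response surface uses the spec'd gamma and depth grids but a
# coarse mesh (edge 45 um): generator and inference interpolate the same
# surface, so closed-loop recovery tests are about the inference machinery,
# not mesh accuracy (which has its own convergence test).

.fixture_env <- new.env(parent = emptyenv())

test_surface <- function() {
  if (is.null(.fixture_env$surface)) {
    .fixture_env$surface <- response_surface(
      gammas = seq(0.02, 0.45, length.out = 12),
      depths = seq(0.40, 0.65, by = 0.05),
      target_edge_length = 45
    )
  }
  .fixture_env$surface
}

test_material <- function() cg_material()

# Coarse single solves for mechanics tests.
quick_solve <- function(gamma, depth, edge = 45, radius = 225, exponent = 2,
                        material = cg_material()) {
  mesh <- incised_disk_mesh(radius, depth, target_edge_length = edge)
  solve_equilibrium(mesh, material,
                    stress_profile(gamma, exponent = exponent,
                                   reference_radius = radius))
}
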