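# Shared fixtures, built once per test run and cached. Everything is
# generated in code from seeds; the reduced resolution (K = 4, np = 2,
# 100 BDF steps) keeps single simulations around a quarter second.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- builder()
  .fixture_cache[[key]]
}

reduced_mesh <- function() cached("mesh42", function() build_mesh(4, 2, 0.1))

reduced_solver <- function() solver_config(n_steps = 100)

# six-experiment benchmark at reduced resolution, 2% noise, seed 1
bench_small <- function() cached("bench_small", function()
  benchmark_dataset(truth_spec(), seed = 1, mesh = reduced_mesh(),
                    solver = reduced_solver()))

# noiseless variant for exactness checks
bench_noiseless <- function() cached("bench_noiseless", function()
  benchmark_dataset(truth_spec(noise_sd = 0), seed = 1, mesh = reduced_mesh(),
                    solver = reduced_solver()))

# one mechanistic trajectory on the first training experiment
mech_trajectory <- function() cached("mech_traj", function() {
  bd <- bench_small()
  bdf_integrate(bd$models[[1]])
})

# tiny instance for gradient verification: K = 2, np = 2, 10 steps
tiny_setup <- function() cached("tiny", function() {
  mesh <- build_mesh(2, 2, 0.1)
  sv <- solver_config(max_order = 5, newton_tol = 1e-13, n_steps = 10)
  bd <- benchmark_dataset(truth_spec(), seed = 3, mesh = mesh, solver = sv)
  list(bd = bd, prep = prepare_experiment(bd$experiments[[1]], bd$models[[1]]))
})

# deterministic small network with both hidden units active over part of the
# feature range (so every parameter carries gradient signal)
tiny_theta <- function() {
  th <- init_network(network_config(1, 2, init_seed = 11))
  th$layers[[1]]$W <- matrix(c( 0.010, -0.02, 0.03, 0.01, -0.01, 0.02, 0.015,
                               -0.012,  0.03, 0.02, -0.02, 0.02, -0.01, 0.020),
                             2, 7, byrow = TRUE)
  th$layers[[1]]$b <- c(0.2, 0.5)
  th$layers[[2]]$W <- matrix(c(0.05, -0.04, 0.03, 0.06, -0.02, 0.04), 3, 2)
  th$layers[[2]]$b <- chromsol:::softplus_inv(1) + c(0.02, -0.03, 0.05)
  th
}

# Table-3-patterned parameter set used in pointwise SDM oracles
table3_components <- function() list(
  component_params("W", 6.08, 7.38e-5, 29.17, 2.89e-7),
  component_params("P", 7.70, 7.31e-6, 12.49, 4.49e-10),
  component_params("S", 12.63, 8.15e-9, 0, 1.56e-12))
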