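# Synthetic benchmark: printed design layout, observation model, determinism.

test_that("the six printed experiments are laid out with 1:1 roles", {
  exps <- make_programs(truth_spec())
  expect_length(exps, 6)
  roles <- vapply(exps, `[[`, character(1), "role")
  expect_equal(sum(roles == "train"), 3)
  expect_equal(sum(roles == "test"), 3)
  labels <- vapply(exps, `[[`, character(1), "label")
  expect_true(all(c("Load15_GL6p5", "Load7p5_GL6p5", "Load15_GL8p5",
                    "Load15_GL4p6", "Load22p5_GL6p5", "Load22p5_GL8p5")
                  %in% labels))
  # Load22p5_GL8p5: 150% of the 15 g/L benchmark load, 130% gradient length
  ex <- exps[[match("Load22p5_GL8p5", labels)]]
  bench <- exps[[match("Load15_GL6p5", labels)]]
  load_cv <- function(e) e$program$steps[[2]]$duration_cv
  grad_cv <- function(e) e$program$steps[[4]]$duration_cv
  expect_equal(load_cv(ex) / load_cv(bench), 1.5)
  expect_equal(grad_cv(ex) / grad_cv(bench), 8.5 / 6.5)
  # every gradient runs 30 -> 100 %B; the five-step structure is fixed
  for (e in exps) {
    kinds <- vapply(e$program$steps, `[[`, character(1), "kind")
    expect_equal(kinds, c("equilibration", "load", "wash", "gradient", "strip"))
    g <- e$program$steps[[4]]
    expect_equal(c(g$percentB_start, g$percentB_end), c(30, 100))
    expect_equal(ms_to_cmh(g$velocity), 200)
  }
})

test_that("observations are deterministic in the seed", {
  truth <- truth_spec()
  mesh <- reduced_mesh(); sv <- reduced_solver()
  a <- generate_observations(truth, make_programs(truth)[2], seed = 7,
                             mesh = mesh, solver = sv)
  b <- generate_observations(truth, make_programs(truth)[2], seed = 7,
                             mesh = mesh, solver = sv)
  expect_identical(a[[1]]$observations, b[[1]]$observations)
  c <- generate_observations(truth, make_programs(truth)[2], seed = 8,
                             mesh = mesh, solver = sv)
  expect_false(identical(a[[1]]$observations, c[[1]]$observations))
})

test_that("noiseless identity-truth observations equal the mechanistic run", {
  truth <- truth_spec(noise_sd = 0, correction = correction_identity())
  mesh <- reduced_mesh(); sv <- reduced_solver()
  exps <- generate_observations(truth, make_programs(truth)[1], seed = 1,
                                mesh = mesh, solver = sv)
  ex <- exps[[1]]
  model <- chrom_model(ex$program, truth$components, mesh = mesh, solver = sv)
  pred <- simulate_experiment(experiment(ex$label, ex$program, "train"),
                              model, fraction_cv = truth$fraction_cv)
  expect_equal(chromsol:::obs_matrix(ex$observations),
               chromsol:::obs_matrix(pred), tolerance = 1e-12)
})

test_that("doubling the fraction volume halves the fraction count (+-1)", {
  pr <- make_programs(truth_spec())[[1]]$program
  n1 <- nrow(fraction_windows(pr, 0.25))
  n2 <- nrow(fraction_windows(pr, 0.5))
  expect_lte(abs(n1 - 2 * n2), 2)
  # windows tile the gradient step exactly
  w <- fraction_windows(pr, 0.25)
  expect_equal(w$cv0[1], pr$cv_bounds[4])
  expect_equal(w$cv1[nrow(w)], pr$cv_bounds[5])
  expect_equal(w$cv0[-1], w$cv1[-nrow(w)])
})

test_that("the supplied ground truth reproduces its own benchmark exactly", {
  bd <- bench_noiseless()
  preps <- mapply(chromsol:::prepare_experiment, bd$experiments[1:3],
                  bd$models[1:3], SIMPLIFY = FALSE)
  l <- chromsol:::study_loss(preps, correction = bd$truth$correction)$loss
  expect_lt(l, 1e-10)
  # while the uncorrected model misfits the same data measurably
  expect_gt(chromsol:::study_loss(preps)$loss, 1e-3)
})

test_that("benchmark files round-trip through the text formats", {
  bd <- bench_small()
  dir <- tempfile()
  write_benchmark(bd$experiments[1:2], bd$truth$components, dir)
  back <- read_benchmark(dir)
  expect_length(back, 2)
  expect_equal(back[[1]]$label, bd$experiments[[1]]$label)
  expect_equal(back[[1]]$role, bd$experiments[[1]]$role)
  expect_equal(chromsol:::obs_matrix(back[[1]]$observations),
               chromsol:::obs_matrix(bd$experiments[[1]]$observations))
  expect_equal(back[[1]]$program$t_bounds,
               bd$experiments[[1]]$program$t_bounds)
  comps <- read_benchmark_components(dir)
  expect_equal(comps, bd$truth$components)
})
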