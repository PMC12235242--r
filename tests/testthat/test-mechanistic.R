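# SDM kinetics and the assembled right-hand side: pointwise rate law,
# displacement bookkeeping, steady states, decoupling, conservation.

test_that("SDM rate vanishes on an empty column and at detailed balance", {
  comps <- table3_components()
  W <- comps[[1]]
  # empty column at rest
  expect_equal(sdm_rate(0, matrix(0, 1, 3), cm = 50, W, ligand = 100,
                        all_params = comps), 0)
  # detailed balance: choose q_W so that forward and backward terms cancel
  q <- c(0.2, 0.1, 0.05); cm <- 3
  S <- 100 - sum(vapply(comps, function(p) p$charge_nu + p$sigma, numeric(1)) * q)
  c_eq <- q[1] * cm^W$charge_nu / (W$keq * S^W$charge_nu)
  expect_equal(sdm_rate(c_eq, matrix(q, 1), cm, W, 100, comps), 0,
               tolerance = 1e-12)
})

test_that("SDM rate matches the hand-evaluated Table-3-style case", {
  comps <- table3_components()
  # frozen hand arithmetic: Lambda = 100, q = (0.5, 0.3, 0.1), c_W = 0.01,
  # cm = 40; availability 100 - 17.625 - 6.057 - 1.263 = 75.055
  r <- sdm_rate(0.01, matrix(c(0.5, 0.3, 0.1), 1), cm = 40, comps[[1]],
                ligand = 100, all_params = comps)
  expect_equal(r, -9518477487690232, tolerance = 1e-10)
  expect_error(sdm_rate(0.01, matrix(c(10, 10, 10), 1), 40, comps[[1]],
                        ligand = 100, all_params = comps), "overload")
  expect_error(sdm_rate(0.01, matrix(0, 1, 3), -5, comps[[1]],
                        ligand = 100, all_params = comps), "positive")
})

test_that("stationary modifier rate is minus the charge-weighted rate sum", {
  expect_equal(modifier_stationary_rate(matrix(0, 1, 3), c(1, 2, 3)), 0)
  expect_equal(modifier_stationary_rate(matrix(c(1, 1, 1), 1), c(1, 2, 3)), -6)
  expect_equal(modifier_stationary_rate(matrix(c(1, 0, 0), 1),
                                        c(6.08, 7.70, 12.63)), -6.08)
  expect_error(modifier_stationary_rate(matrix(1, 1, 2), c(1, 2, 3)),
               "mismatch")
})

test_that("an equilibrated column is a steady state of the assembled rhs", {
  bd <- bench_noiseless()
  model <- bd$models[[1]]
  y <- initial_state(model)
  r <- chromsol:::chrom_rhs(y, 1, model)
  expect_lt(max(abs(r)), 1e-10)
})

test_that("a non-binding component decouples into pure transport", {
  bd <- bench_noiseless()
  ex <- bd$experiments[[1]]
  comps <- bd$truth$components
  comps[[1]] <- component_params("W", comps[[1]]$charge_nu, keq = 0,
                                 sigma = comps[[1]]$sigma,
                                 kkin = comps[[1]]$kkin)
  model <- chrom_model(ex$program, comps, mesh = reduced_mesh(),
                       solver = reduced_solver())
  y <- initial_state(model)
  set.seed(4)
  y[, 2] <- abs(rnorm(model$n))          # tracer profile; q_W = 0 so dq_W = 0
  t <- mean(ex$program$t_bounds[2:3])
  r <- chromsol:::chrom_rhs(y, t, model)
  ref <- dg_convection_diffusion(model$mesh, y[, 2],
                                 u = ex$program$steps[[2]]$velocity,
                                 Dapp = apparent_dispersion(
                                   ex$program$steps[[2]]$velocity,
                                   ex$program$column),
                                 eps_t = model$eps_t,
                                 inlet_value = inlet_profile(ex$program, t)$feed[[1]])
  expect_equal(r[, 2], ref, tolerance = 1e-12)
})

test_that("the stationary modifier column always recomputes from the rates", {
  bd <- bench_noiseless()
  model <- bd$models[[1]]
  y <- initial_state(model)
  set.seed(5)
  y[, 2:4] <- abs(matrix(rnorm(model$n * 3, sd = 0.1), model$n))
  y[, 6:8] <- abs(matrix(rnorm(model$n * 3, sd = 0.5), model$n))
  r <- chromsol:::chrom_rhs(y, 10, model)
  expect_equal(r[, 5], -as.vector(r[, 6:8] %*% model$nu), tolerance = 1e-12)
  # identical inputs give bit-identical outputs
  expect_identical(r, chromsol:::chrom_rhs(y, 10, model))
})

test_that("qm + sum(nu q) is conserved along a full simulated program", {
  bd <- bench_small()
  traj <- mech_trajectory()
  model <- bd$models[[1]]
  cons <- vapply(traj$states, function(y)
    max(abs(y[, 5] + as.vector(y[, 6:8] %*% model$nu) - model$Lambda)),
    numeric(1))
  expect_lt(max(cons) / model$Lambda, 1e-8)
})

test_that("analytic state Jacobian of the rhs matches finite differences", {
  bd <- bench_noiseless()
  model <- bd$models[[1]]
  traj <- mech_trajectory()
  y <- traj$states[[60]]                      # mid-load, surface partly laden
  t <- traj$times[60]
  for (corr in list(NULL, bd$truth$correction)) {
    J <- chromsol:::chrom_jac(y, t, model, corr = corr)
    f0 <- as.vector(chromsol:::chrom_rhs(y, t, model, corr = corr))
    set.seed(6)
    for (rep in 1:5) {                        # random directional derivatives
      d <- rnorm(length(y)); d <- d / sqrt(sum(d^2))
      hh <- 1e-6
      yp <- y + hh * matrix(d, nrow(y))
      ym <- y - hh * matrix(d, nrow(y))
      fd <- (as.vector(chromsol:::chrom_rhs(yp, t, model, corr = corr)) -
             as.vector(chromsol:::chrom_rhs(ym, t, model, corr = corr))) / (2 * hh)
      expect_lt(max(abs(as.vector(J %*% d) - fd)) / max(1, max(abs(fd))), 1e-5)
    }
  }
})
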