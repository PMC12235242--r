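# Hybrid right-hand side, loss and goodness of fit.

test_that("a constant correction rescales exactly the adsorption channel", {
  bd <- bench_noiseless()
  model <- bd$models[[1]]
  traj <- mech_trajectory()
  y <- traj$states[[60]]; t <- traj$times[60]
  r0 <- chromsol:::chrom_rhs(y, t, model)
  corr <- correction_function(function(X) {
    out <- matrix(1, nrow(X), 3); out[, 1] <- 2; out
  })
  r2 <- chromsol:::chrom_rhs(y, t, model, corr = corr)
  # dqW doubles; the coupling into cW and qm follows the corrected rate
  expect_equal(r2[, 6], 2 * r0[, 6])
  expect_equal(r2[, 7:8], r0[, 7:8])
  expect_equal(r2[, 2] - r0[, 2], -model$phase_ratio * r0[, 6])
  expect_equal(r2[, 5], -as.vector(r2[, 6:8] %*% model$nu))
  # transport-only fields are untouched
  expect_equal(r2[, 1], r0[, 1])
})

test_that("identity-initialized network gives exactly the mechanistic rhs", {
  bd <- bench_noiseless()
  model <- bd$models[[1]]
  y <- initial_state(model)
  y[, 2:4] <- 0.05
  th <- init_network(network_config(2, 14, init_seed = 2))
  expect_identical(
    chromsol:::chrom_rhs(y, 5, model, corr = correction_network(th)),
    chromsol:::chrom_rhs(y, 5, model))
})

test_that("loss is the normalized squared chromatogram distance", {
  set.seed(13)
  C <- cbind(runif(10, 30, 100), matrix(abs(rnorm(30)), 10))
  cinj <- c(0.1, 0.888, 0.012)
  expect_equal(chrom_loss(C, C, cinj), 0)
  expect_equal(chrom_loss(C * 0, C, cinj), 1)
  expect_equal(chrom_loss(2 * C, C, cinj), 1)
  expect_error(chrom_loss(C, C * 0, cinj), "zero")
  expect_error(chrom_loss(C[1:5, ], C, cinj), "shapes")
})

test_that("loss is invariant to jointly rescaling units and feed", {
  set.seed(14)
  C <- cbind(runif(8, 30, 100), matrix(abs(rnorm(24)), 8))
  P <- C * (1 + 0.05 * matrix(rnorm(32), 8))
  cinj <- c(0.1, 0.888, 0.012)
  l0 <- chrom_loss(P, C, cinj)
  scl <- c(1, 1000, 1, 0.5)   # e.g. W in mg/L, S in different batch units
  expect_equal(chrom_loss(sweep(P, 2, scl, "*"), sweep(C, 2, scl, "*"),
                          cinj * scl[2:4]), l0)
})

test_that("R2 has its textbook anchor points and a hand-checked value", {
  cinj <- c(1, 1, 1)
  set.seed(15)
  C <- cbind(runif(6, 30, 100), matrix(abs(rnorm(18)) + 0.2, 6))
  expect_equal(r_squared(C, C, cinj, "overall"), 1)
  r2c <- r_squared(C, C, cinj, "per_component")
  expect_equal(unname(r2c), rep(1, 4))
  # predicting the per-column observation mean gives R2 = 0 per component
  M <- C; for (j in 1:4) M[, j] <- mean(C[, j])
  expect_equal(unname(r_squared(M, C, cinj, "per_component")), rep(0, 4))
  # 3-point series, manual sums: C = (1,2,3), pred = (1.5, 2, 2.5)
  Cm <- cbind(c(50, 50, 50), c(1, 2, 3), c(1, 1, 1) * 2, c(0.5, 0.4, 0.3))
  Pm <- Cm; Pm[, 2] <- c(1.5, 2, 2.5)
  # SS_res = 0.25 + 0 + 0.25 = 0.5; SS_tot = 1 + 0 + 1 = 2 -> R2 = 0.75
  expect_equal(r_squared(Pm, Cm, cinj, "per_component")[["W"]], 0.75)
  # zero-variance observations report NA
  expect_true(is.na(r_squared(Pm, Cm, cinj, "per_component")[["P"]]))
})

test_that("simulate_experiment with nothing injected elutes nothing", {
  bd <- bench_noiseless()
  ex <- bd$experiments[[1]]
  # feed scaled to a trace: adsorbate outlet ~ 0, modifier still ramps
  tiny_feed <- c(W = 1e-10, P = 1e-10, S = 1e-10)
  pr <- chromsol:::benchmark_program(15, 6.5, bd$truth$column, tiny_feed)
  ex0 <- experiment("zeroload", pr, role = "train")
  model <- chrom_model(pr, bd$truth$components, mesh = reduced_mesh(),
                       solver = reduced_solver())
  pred <- simulate_experiment(ex0, model)
  expect_lt(max(pred$c_W, pred$c_P, pred$c_S), 1e-8)
  expect_gt(max(pred$modifier_percentB), 50)
  expect_gt(min(diff(pred$modifier_percentB)), 0)   # delayed, dispersed ramp
})

test_that("eluted mass balances injected mass for a non-retained tracer", {
  bd <- bench_noiseless()
  ex <- bd$experiments[[2]]                  # smallest load: fastest run
  comps <- bd$truth$components
  comps[[1]] <- component_params("W", comps[[1]]$charge_nu, keq = 0,
                                 sigma = 0, kkin = comps[[1]]$kkin)
  model <- chrom_model(ex$program, comps, mesh = reduced_mesh(),
                       solver = reduced_solver())
  traj <- bdf_integrate(model)
  out <- outlet_series(traj, model$mesh)
  # volumetric flow per snapshot (m^3/s): u * cross-section
  area <- pi * (ex$program$column$inner_diameter / 2)^2
  u <- vapply(out$time_s, function(t)
    ex$program$steps[[chromsol:::program_step_at(ex$program, t)]]$velocity,
    numeric(1))
  flow <- u * area * 1000                    # L/s
  rate <- out$c_W * flow                     # g/s leaving the column
  eluted <- sum(diff(out$time_s) * (rate[-1] + rate[-length(rate)]) / 2)
  load_step <- ex$program$steps[[2]]
  injected <- load_step$feed[["W"]] *
    load_step$duration_cv * ex$program$column$length * area * 1000 /
    1 # CV * V_col, feed in g/L -> grams
  expect_lt(abs(eluted - injected) / injected, 0.01)
})
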