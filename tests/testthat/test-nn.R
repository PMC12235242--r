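# Correction network: identity initialization, forward pass, normalization,
# node-wise locality, positivity, parameter archive round trip.

test_that("a fresh network is the exact identity correction", {
  th <- init_network(network_config(2, 14, init_seed = 5))
  set.seed(9)
  X <- cbind(runif(20, 0, 100), matrix(runif(20 * 6, 0, 30), 20))
  expect_equal(nn_forward(th, X), matrix(1, 20, 3))
  # softplus^-1(1) = log(e - 1) closes the loop to round-off
  expect_equal(chromsol:::softplus(chromsol:::softplus_inv(1)), 1)
  # same seed twice gives identical parameters
  th2 <- init_network(network_config(2, 14, init_seed = 5))
  expect_identical(chromsol:::theta_to_vec(th),
                   chromsol:::theta_to_vec(th2))
  # different seed changes the hidden layers
  th3 <- init_network(network_config(2, 14, init_seed = 6))
  expect_false(identical(chromsol:::theta_to_vec(th),
                         chromsol:::theta_to_vec(th3)))
})

test_that("forward pass matches a hand-computed 1-hidden-node case", {
  th <- init_network(network_config(1, 1, init_seed = 1))
  th$layers[[1]]$W <- matrix(c(0.1, -0.2, 0.3, 0.05, -0.05, 0.2, -0.1), 1, 7)
  th$layers[[1]]$b <- 0.3
  th$layers[[2]]$W <- matrix(c(0.5, -0.4, 0.2), 3, 1)
  th$layers[[2]]$b <- c(0.1, 0.2, -0.3)
  out <- nn_forward(th, matrix(c(2, 0.5, 1.5, 0.2, 3, 1, 0.4), 1))
  # frozen manual matrix arithmetic: hidden pre-activation 0.87,
  # softplus(c(0.535, -0.148, -0.126))
  expect_equal(as.vector(out),
               c(0.996006583276016, 0.62188268532159, 0.632130369200935),
               tolerance = 1e-12)
  expect_error(nn_forward(th, matrix(1, 1, 5)), "width")
})

test_that("feature normalization divides by injection concentrations", {
  y <- matrix(0, 1, 8)
  y[1, ] <- c(42, 0.5, 4.44, 0.12, 99, 1, 8.88, 0.012)
  X <- normalize_features(y, c(1, 8.88, 0.12))
  expect_equal(as.vector(X), c(42, 0.5, 0.5, 1.0, 1, 1, 0.1))
  # qm (column 5) is excluded by construction
  y2 <- y; y2[1, 5] <- -7
  expect_equal(normalize_features(y2, c(1, 8.88, 0.12)), X)
  expect_equal(as.vector(normalize_features(matrix(0, 1, 8), c(1, 2, 3))),
               rep(0, 7))
  expect_error(normalize_features(y, c(0, 1, 1)), "positive")
})

test_that("the network acts node-wise: permutation equivariance, positivity", {
  th <- init_network(network_config(2, 8, init_seed = 3))
  v <- chromsol:::theta_to_vec(th)
  set.seed(10)
  th <- chromsol:::vec_to_theta(v + rnorm(length(v), sd = 0.3), th)
  X <- cbind(runif(30, 0, 100), matrix(rnorm(30 * 6, sd = 5), 30))
  out <- nn_forward(th, X)
  p <- sample(30)
  expect_equal(nn_forward(th, X[p, ]), out[p, ])
  expect_true(all(out > 0))                 # Softplus range
})

test_that("input Jacobian and parameter gradients match finite differences", {
  th <- tiny_theta()
  X <- matrix(c(55, 1.2, 3.5, 0.4, 2, 8, 30,
                40, 0.1, 0.2, 0.05, 1, 2, 5), 2, 7, byrow = TRUE)
  fw <- nn_forward(th, X, cache = TRUE)
  J <- chromsol:::nn_input_jac(th, fw)
  for (f in 1:7) {
    hh <- 1e-6 * (1 + abs(X[, f]))
    Xp <- X; Xp[, f] <- X[, f] + hh
    Xm <- X; Xm[, f] <- X[, f] - hh
    fd <- (nn_forward(th, Xp) - nn_forward(th, Xm)) / (2 * hh)
    expect_equal(J[, , f], fd, tolerance = 1e-6)
  }
  # parameter VJP against FD on a scalar contraction sum(G * out)
  set.seed(11)
  G <- matrix(rnorm(6), 2, 3)
  g <- chromsol:::grad_to_vec(chromsol:::nn_vjp_params(th, fw, G))
  v <- chromsol:::theta_to_vec(th)
  fd <- vapply(seq_along(v), function(i) {
    hh <- 1e-6 * (1 + abs(v[i]))
    vp <- v; vp[i] <- v[i] + hh
    vm <- v; vm[i] <- v[i] - hh
    (sum(G * nn_forward(chromsol:::vec_to_theta(vp, th), X)) -
       sum(G * nn_forward(chromsol:::vec_to_theta(vm, th), X))) / (2 * hh)
  }, numeric(1))
  expect_equal(g, fd, tolerance = 1e-6)
})

test_that("parameter archives round-trip through the text format", {
  th <- init_network(network_config(2, 5, init_seed = 8))
  v <- chromsol:::theta_to_vec(th)
  set.seed(12)
  th <- chromsol:::vec_to_theta(v + rnorm(length(v)), th)
  path <- tempfile(fileext = ".csv")
  save_network(th, path)
  th2 <- load_network(path)
  expect_equal(th2$config, th$config)
  expect_equal(chromsol:::theta_to_vec(th2), chromsol:::theta_to_vec(th))
})
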