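# Method program: inlet profile, unit plumbing, dispersion from plate count.

table1_program <- function(load_cv = 15, gradient_cv = 6.5) {
  column <- column_spec(0.1, 0.0046, 0.54, 5000, 2000)
  method_program(list(
    method_step("equilibration", 30, velocity = cmh_to_ms(400), duration_cv = 3),
    method_step("load", 30, velocity = cmh_to_ms(300), duration_cv = load_cv,
                feed = c(W = 0.1, P = 0.888, S = 0.012)),
    method_step("wash", 30, velocity = cmh_to_ms(150), duration_cv = 2),
    method_step("gradient", 30, 100, velocity = cmh_to_ms(200),
                duration_cv = gradient_cv),
    method_step("strip", 100, velocity = cmh_to_ms(150), duration_cv = 2)),
    column)
}

test_that("inlet profile is piecewise: constant steps, linear gradient ramp", {
  pr <- table1_program()
  tb <- pr$t_bounds
  # inside equilibration: 30 %B, nothing fed
  p <- inlet_profile(pr, tb[2] / 2)
  expect_equal(p$percentB, 30)
  expect_equal(unname(p$feed), c(0, 0, 0))
  # during load: feed on, modifier still 30
  p <- inlet_profile(pr, mean(tb[2:3]))
  expect_equal(unname(p$feed), c(0.1, 0.888, 0.012))
  expect_equal(p$percentB, 30)
  # gradient midpoint of the 30 -> 100 ramp: 65 %B
  p <- inlet_profile(pr, mean(tb[4:5]))
  expect_equal(p$percentB, 65)
  # exact end of the gradient: 100 %B, nothing fed
  p <- inlet_profile(pr, tb[5])
  expect_equal(p$percentB, 100)
  expect_equal(unname(p$feed), c(0, 0, 0))
  expect_error(inlet_profile(pr, max(tb) + 1), "span")
  expect_error(inlet_profile(pr, -1), "span")
})

test_that("inlet %B stays within the program's endpoint range", {
  pr <- table1_program()
  ts <- seq(0, program_span(pr), length.out = 400)
  pb <- vapply(ts, function(t) inlet_profile(pr, t)$percentB, numeric(1))
  expect_true(all(pb >= 30 - 1e-12 & pb <= 100 + 1e-12))
})

test_that("apparent dispersion follows u L / (2 eps_t N)", {
  col <- column_spec(1, 0.01, 0.5, 1, 100)
  expect_equal(apparent_dispersion(1, col), 0.01)
  # homogeneous of degree 1 in u
  expect_equal(apparent_dispersion(2e-3, col) / apparent_dispersion(1e-3, col), 2)
  # hand-evaluated value: 300 cm/h on a 0.1 m column, eps_t 0.54, N 2000
  col2 <- column_spec(0.1, 0.0046, 0.54, 5000, 2000)
  expect_equal(apparent_dispersion(cmh_to_ms(300), col2),
               3.85802469135803e-08, tolerance = 1e-12)
  # degree 1 in L as well
  col3 <- column_spec(0.2, 0.0046, 0.54, 5000, 2000)
  expect_equal(apparent_dispersion(cmh_to_ms(300), col3) /
                 apparent_dispersion(cmh_to_ms(300), col2), 2)
})

test_that("CV/time conversion is a piecewise flow accounting and invertible", {
  col <- column_spec(0.1, 0.0046, 0.5, 100, 500)
  pr <- method_program(list(
    method_step("load", 30, velocity = 1e-3, duration_cv = 2,
                feed = c(W = 1, P = 0, S = 0)),
    method_step("gradient", 30, 100, velocity = 2e-3, duration_cv = 3)), col)
  expect_equal(cv_to_time(pr, 0), 0)
  # 1 CV at u = 1e-3 m/s on a 0.1 m column takes L/u = 100 s
  expect_equal(cv_to_time(pr, 1), 100)
  # hand-computed cumulative schedule across the velocity change:
  # 2 CV @ 100 s + 1.5 CV @ 50 s = 275 s
  expect_equal(cv_to_time(pr, 3.5), 275)
  # round trip is the identity; conversion strictly monotone
  v <- seq(0, 5, by = 0.25)
  expect_equal(time_to_cv(pr, cv_to_time(pr, v)), v)
  expect_true(all(diff(cv_to_time(pr, v)) > 0))
  expect_error(cv_to_time(pr, -0.5), "nonnegative")
})

test_that("constructors enforce the physical invariants", {
  expect_error(column_spec(0.1, 0.0046, 1.2, 100, 500))
  expect_error(component_params("W", -1, 1, 0, 1))
  expect_error(method_step("wash", 30, 50, velocity = 1e-3, duration_cv = 1),
               "constant")
  expect_error(method_step("wash", 30, velocity = 1e-3, duration_cv = 1,
                           feed = c(W = 1, P = 0, S = 0)), "feed")
  col <- column_spec(0.1, 0.0046, 0.5, 100, 500)
  expect_error(method_program(list(
    method_step("wash", 30, velocity = 1e-3, duration_cv = 1)), col),
    "gradient")
})

test_that("configuration files round-trip through YAML", {
  pr <- table1_program()
  comps <- table3_components()
  path <- tempfile(fileext = ".yml")
  write_config(pr$column, comps, pr, path)
  cfg <- read_config(path)
  expect_equal(cfg$column, pr$column)
  expect_equal(cfg$components, comps)
  expect_equal(cfg$program$t_bounds, pr$t_bounds)
  expect_equal(cfg$program$steps[[4]]$percentB_end, 100)
  expect_equal(unname(cfg$program$steps[[2]]$feed), c(0.1, 0.888, 0.012))
})
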