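# Fixed-step BDF time integration (operator SOL). Orders 1-5 with an order
# ramp at start-up, Newton iteration on the implicit relation with an LU-
# factorized Jacobian, and solver step boundaries aligned with method-step
# boundaries so the discontinuous forcing (step velocities, feed switches) is
# never integrated across. The integrator records a tape of converged states
# so that reverse-mode gradients can be propagated through every step.

#' Solver configuration
#'
#' @param step_fraction fraction of the total simulated time per BDF step
#'   (default 5 per-mille, i.e. 200 steps over the program)
#' @param max_order maximum BDF order (1-5). The default stops at 3: orders
#'   4-5 lose A-stability near the imaginary axis, where the eigenvalues of
#'   the upwind-DG convection operator sit, and can develop growing
#'   oscillations on fine meshes at the fixed step sizes used here
#' @param newton_tol relative Newton increment tolerance
#' @param newton_max_iter maximum Newton iterations per step
#' @param n_steps optional explicit total step count, overriding
#'   `step_fraction` (used for deliberately coarse runs, e.g. gradient
#'   verification on tiny instances)
#' @return object of class `solver_config`
#' @export
solver_config <- function(step_fraction = 0.005, max_order = 3,
                          newton_tol = 1e-10, newton_max_iter = 25,
                          n_steps = NULL) {
  stopifnot(step_fraction > 0, step_fraction <= 0.05,
            max_order >= 1, max_order <= 5)
  if (!is.null(n_steps)) stopifnot(n_steps >= 1)
  structure(list(step_fraction = step_fraction, max_order = as.integer(max_order),
                 newton_tol = newton_tol,
                 newton_max_iter = as.integer(newton_max_iter),
                 n_steps = n_steps),
            class = "solver_config")
}

# normalized BDF coefficients: y_n + sum_j a[j] y_{n-j} = h * beta * f(y_n)
bdf_coefs <- function(s) {
  switch(s,
    list(a = c(-1), beta = 1),
    list(a = c(-4, 1) / 3, beta = 2 / 3),
    list(a = c(-18, 9, -2) / 11, beta = 6 / 11),
    list(a = c(-48, 36, -16, 3) / 25, beta = 12 / 25),
    list(a = c(-300, 300, -200, 75, -12) / 137, beta = 60 / 137),
    stopf("BDF order must be 1-5, got %d", s))
}

# dense finite-difference Jacobian (fallback for user-supplied rhs callables)
num_jac <- function(fn, y) {
  f0 <- fn(y)
  J <- matrix(0, length(f0), length(y))
  for (j in seq_along(y)) {
    h <- 1e-7 * (1 + abs(y[j]))
    yp <- y; yp[j] <- y[j] + h
    J[, j] <- (fn(yp) - f0) / h
  }
  J
}

#' One implicit BDF step
#'
#' Solves the s-th order BDF relation `y_n + sum_j a_j y_(n-j) = h beta
#' f(y_n)` for the next state by Newton iteration; each iteration solves the
#' linearized system `(I - h beta J) dy = -residual` by LU factorization.
#'
#' @param history list of recent states, most recent first (length >= order)
#' @param rhs callable `f(y)` returning the time derivative
#' @param h step size (> 0)
#' @param order BDF order s (1-5)
#' @param jac optional callable returning the dense Jacobian of `rhs`; a
#'   finite-difference Jacobian is used when absent
#' @param newton_tol relative Newton increment tolerance
#' @param max_iter maximum Newton iterations
#' @return the next state (same shape as the history entries)
#' @export
bdf_step <- function(history, rhs, h, order, jac = NULL,
                     newton_tol = 1e-10, max_iter = 25) {
  stopifnot(h > 0, length(history) >= order)
  cf <- bdf_coefs(order)
  shape <- history[[1]]
  yv <- as.vector(shape)
  ysum <- Reduce(`+`, lapply(seq_len(order), function(j)
    cf$a[j] * as.vector(history[[j]])))
  fwrap <- function(v) as.vector(rhs(`dim<-`(v, dim(shape))))
  Jfun <- if (is.null(jac)) function(v) num_jac(fwrap, v)
          else function(v) jac(`dim<-`(v, dim(shape)))
  y <- yv
  A <- diag(length(yv)) - h * cf$beta * Jfun(y)
  Ainv <- solve(A)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    r <- y + ysum - h * cf$beta * fwrap(y)
    dy <- as.vector(Ainv %*% r)
    y <- y - dy
    if (max(abs(dy) / (1 + abs(y))) < newton_tol) { converged <- TRUE; break }
    if (it == ceiling(max_iter / 2)) {   # refresh stale Jacobian and retry
      A <- diag(length(yv)) - h * cf$beta * Jfun(y)
      Ainv <- solve(A)
    }
  }
  if (!converged)
    stopf("BDF Newton iteration failed to converge (order %d, h = %g)",
          order, h)
  `dim<-`(y, dim(shape))
}

# plan the solver grid: per method step, the number of sub-steps and step
# size so that segment boundaries coincide with method-step boundaries
plan_segments <- function(program, step_fraction, n_steps = NULL) {
  total <- program_span(program)
  n_total <- if (!is.null(n_steps)) n_steps else max(1, round(1 / step_fraction))
  durs <- diff(program$t_bounds)
  nseg <- pmax(1L, round(n_total * durs / total))
  data.frame(seg = seq_along(durs), t0 = program$t_bounds[-length(program$t_bounds)],
             n = nseg, h = durs / nseg)
}

#' Integrate the column model over its method program
#'
#' Fixed-step BDF integration of the (hybrid) semi-discrete model over the
#' full method program. The step size is `step_fraction` of the total
#' simulated time, redistributed so that solver step boundaries align with
#' method-step boundaries; the order ramps 1 up to `max_order` after every
#' such boundary. When a `correction` is supplied the adsorption rates are
#' multiplied node-wise by its output inside every implicit solve (the
#' solver-in-the-loop hybrid forward map); with the identity correction the
#' trajectory is bit-identical to the purely mechanistic run.
#'
#' @param model a [chrom_model()]
#' @param correction optional `chrom_correction`
#' @param y0 initial state, default [initial_state()]
#' @param config a [solver_config()], default taken from the model
#' @return object of class `chrom_trajectory`: snapshot times, states and the
#'   per-step tape (order, step size, segment) used for backpropagation
#' @export
bdf_integrate <- function(model, correction = NULL, y0 = initial_state(model),
                          config = model$solver) {
  plan <- plan_segments(model$program, config$step_fraction, config$n_steps)
  n_snap <- 1L + sum(plan$n)
  states <- vector("list", n_snap)
  times <- numeric(n_snap)
  step_order <- integer(n_snap); step_h <- numeric(n_snap)
  step_seg <- integer(n_snap)
  states[[1]] <- y0; times[1] <- 0
  m <- 1L
  cache <- new.env(parent = emptyenv())  # Newton-matrix reuse across steps
  for (k in seq_len(nrow(plan))) {
    seg_start <- m                      # snapshot index of segment's IC
    h <- plan$h[k]
    for (j in seq_len(plan$n[k])) {
      t_new <- plan$t0[k] + j * h
      s <- min(config$max_order, j)     # order ramp within the segment
      res <- bdf_step_model(states, m, seg_start, s, h, t_new, model,
                            correction, config, cache)
      if (is.null(res)) {               # one order-reduction retry
        if (s > 1)
          res <- bdf_step_model(states, m, seg_start, s - 1L, h, t_new,
                                model, correction, config, cache)
        if (is.null(res))
          stopf("BDF step failed at t = %g s (segment %d, order %d)",
                t_new, k, s)
        s <- max(1L, s - 1L)
      }
      m <- m + 1L
      states[[m]] <- res
      times[m] <- t_new
      step_order[m] <- s; step_h[m] <- h; step_seg[m] <- k
    }
  }
  structure(list(times = times, states = states, order = step_order,
                 h = step_h, seg = step_seg,
                 seg_start = c(1L, 1L + cumsum(plan$n))[seq_len(nrow(plan))],
                 plan = plan),
            class = "chrom_trajectory")
}

# internal step working on the snapshot store; returns NULL on Newton
# failure. The factored Newton matrix is reused across steps (modified
# Newton) as long as the step key (order, h, method segment) is unchanged
# and convergence stays fast; only the residual uses the exact RHS, so the
# converged state - and hence the adjoint - is unaffected by the reuse.
bdf_step_model <- function(states, m, seg_start, s, h, t_new, model,
                           correction, config, cache = new.env()) {
  cf <- bdf_coefs(s)
  ysum <- Reduce(`+`, lapply(seq_len(s), function(j)
    cf$a[j] * as.vector(states[[m - j + 1L]])))
  y_prev <- states[[m]]
  y <- as.vector(y_prev)
  dims <- dim(y_prev)
  N <- length(y)
  key <- c(s, h, program_step_at(model$program, t_new))
  rebuild <- function(y_at) {
    J <- chrom_jac(`dim<-`(y_at, dims), t_new, model, corr = correction)
    A <- -h * cf$beta * J
    A[seq.int(1L, N * N, by = N + 1L)] <- A[seq.int(1L, N * N, by = N + 1L)] + 1
    Ainv <- try(solve(A), silent = TRUE)
    if (inherits(Ainv, "try-error")) return(NULL)
    cache$Ainv <- Ainv; cache$key <- key
    Ainv
  }
  cached <- !is.null(cache$key) && identical(cache$key, key)
  Ainv <- if (cached) cache$Ainv else rebuild(y)
  if (is.null(Ainv)) return(NULL)
  # iterations since the matrix was last built: whenever the error fails to
  # contract by ~3x per iteration the matrix is refreshed at the current
  # iterate, degrading gracefully from modified to full Newton
  it_since <- if (cached) 99L else 0L
  err_prev <- Inf
  resid <- function(v) {
    f <- chrom_rhs(`dim<-`(v, dims), t_new, model, corr = correction)
    v + ysum - h * cf$beta * as.vector(f)
  }
  r <- resid(y)
  for (it in seq_len(config$newton_max_iter)) {
    dy <- as.vector(Ainv %*% r)
    # cap wildly large updates so strongly nonlinear steps approach the
    # solution steadily instead of overshooting
    rel <- max(abs(dy) / (1 + abs(y)))
    if (rel > 1) dy <- dy / rel
    # backtracking line search on the residual norm
    rn0 <- sum(r^2)
    lam <- 1
    for (ls in 1:5) {
      y_try <- y - lam * dy
      r_try <- resid(y_try)
      if (sum(r_try^2) <= rn0 || ls == 5) break
      lam <- lam / 2
    }
    y <- y_try; r <- r_try
    err <- lam * max(abs(dy) / (1 + abs(y)))
    if (err < config$newton_tol)
      return(check_state(`dim<-`(y, dims), model))
    if ((err > 0.3 * err_prev || lam < 1) && it_since >= 1L) {
      Ainv <- rebuild(y)
      if (is.null(Ainv)) return(NULL)
      it_since <- 0L
    } else {
      it_since <- it_since + 1L
    }
    err_prev <- err
  }
  NULL
}

#' @export
print.chrom_trajectory <- function(x, ...) {
  cat(sprintf("<chrom_trajectory> %d snapshots over [0, %g] s\n",
              length(x$times), max(x$times)))
  invisible(x)
}

#' Outlet concentration series of a trajectory
#'
#' Extracts the four mobile-phase fields (modifier, W, P, S) at the column
#' outlet node for each requested time, interpolating linearly between solver
#' snapshots.
#'
#' @param traj a [bdf_integrate()] trajectory
#' @param mesh the [build_mesh()] the trajectory was computed on
#' @param times sample times (s); default: the solver snapshot times
#' @return tibble with columns `time_s`, `modifier_percentB`, `c_W`, `c_P`,
#'   `c_S`
#' @export
outlet_series <- function(traj, mesh, times = traj$times) {
  OUT <- outlet_matrix(traj, mesh)
  W <- pwlinear_interp_weights(traj$times, times)
  vals <- W %*% OUT
  tibble::tibble(time_s = times,
                 modifier_percentB = vals[, 1],
                 c_W = vals[, 2], c_P = vals[, 3], c_S = vals[, 4])
}

# snapshot-by-field matrix of outlet-node mobile concentrations
outlet_matrix <- function(traj, mesh) {
  n <- mesh$n_nodes
  t(vapply(traj$states, function(y) y[n, 1:4], numeric(4)))
}
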