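# Model context: column + components + method program + DG mesh, with the
# per-step transport operators precomputed, plus the full semi-discrete
# right-hand side (operator F), its analytic state Jacobian (for the implicit
# solver and the adjoint) and its parameter derivatives.

#' Assemble a column model
#'
#' Binds a method program, the three-component SDM parameter set and a DG
#' mesh into a simulation-ready model. The affine transport operator and the
#' flow-dependent apparent dispersion coefficient are precomputed per method
#' step (dispersion follows `Dapp = u L / (2 eps_t N)`, so it changes with
#' the step velocity).
#'
#' @param program a [method_program()]; its load step defines the injection
#'   concentrations used for feature and loss normalization
#' @param components list of three [component_params()] in W, P, S order
#' @param mesh a [build_mesh()]; default `build_mesh(7, 3, L)`
#' @param solver a [solver_config()]
#' @return an object of class `chrom_model`
#' @export
chrom_model <- function(program, components, mesh = NULL,
                        solver = solver_config()) {
  stopifnot(inherits(program, "method_program"), length(components) == 3)
  col <- program$column
  if (is.null(mesh)) mesh <- build_mesh(7, 3, col$length)
  if (abs(mesh$L - col$length) > 1e-12)
    stopf("mesh length (%g) does not match the column (%g)", mesh$L, col$length)
  nu <- vapply(components, function(p) p$charge_nu, numeric(1))
  sigma <- vapply(components, function(p) p$sigma, numeric(1))
  load_idx <- which(vapply(program$steps, function(s) s$kind == "load",
                           logical(1)))
  cinj <- if (length(load_idx)) program$steps[[load_idx[1]]]$feed
          else c(W = 0, P = 0, S = 0)
  ops <- lapply(program$steps, function(s) {
    v <- s$velocity / col$total_porosity       # interstitial velocity
    Dapp <- apparent_dispersion(s$velocity, col)
    c(list(v = v, Dapp = Dapp), dg_transport_operator(mesh, v, Dapp))
  })
  # linear scatter indices of the node-local Jacobian blocks: entry [k]
  # of pair (row field rf, column field xf) sits at J[(rf-1)n+k, (xf-1)n+k]
  n <- mesh$n_nodes; N <- 8L * n; ii <- seq_len(n)
  jac_idx <- lapply(1:8, function(rf) lapply(1:8, function(xf)
    ((xf - 1L) * n + ii - 1L) * N + (rf - 1L) * n + ii))
  structure(
    list(program = program, components = components, mesh = mesh,
         solver = solver, column = col,
         eps_t = col$total_porosity,
         phase_ratio = (1 - col$total_porosity) / col$total_porosity,
         Lambda = col$ligand_density,
         nu = nu, sigma = sigma, nusig = nu + sigma,
         keq = vapply(components, function(p) p$keq, numeric(1)),
         kkin = vapply(components, function(p) p$kkin, numeric(1)),
         cinj = cinj, n = mesh$n_nodes, ops = ops, jac_idx = jac_idx),
    class = "chrom_model")
}

#' @export
print.chrom_model <- function(x, ...) {
  cat(sprintf("<chrom_model> %d-node DG mesh (K = %d, np = %d), %d method steps\n",
              x$n, x$mesh$K, x$mesh$np, length(x$program$steps)))
  invisible(x)
}

# update the SDM parameter vectors in the context (used by calibration)
model_set_params <- function(ctx, nu = ctx$nu, keq = ctx$keq,
                             sigma = ctx$sigma, kkin = ctx$kkin) {
  ctx$nu <- nu; ctx$keq <- keq; ctx$sigma <- sigma; ctx$kkin <- kkin
  ctx$nusig <- nu + sigma
  ctx$components <- lapply(1:3, function(i)
    component_params(ctx$components[[i]]$name, nu[i], keq[i], sigma[i], kkin[i]))
  ctx
}

#' Initial state of a regenerated, equilibrated column
#'
#' Mobile phase at the equilibration inlet composition (first-step %B, no
#' adsorbates), empty adsorbate stationary phase, and `qm = Lambda` so that
#' the displacement bookkeeping `qm + sum(nu_j q_j)` starts from the ligand
#' density and is conserved along any trajectory.
#'
#' @param model a [chrom_model()]
#' @return a `[n_nodes x 8]` state matrix
#' @export
initial_state <- function(model) {
  y <- matrix(0, model$n, 8, dimnames = list(NULL, FIELD_NAMES))
  y[, 1] <- model$program$steps[[1]]$percentB_start
  y[, 5] <- model$Lambda
  y
}

#' Normalize a state into neural-network features
#'
#' Builds the 7-wide feature rows `(cm, c~W, c~P, c~S, q~W, q~P, q~S)` where
#' tilde marks division by the component's injection concentration; the
#' modifier passes through unscaled and `qm` is excluded.
#'
#' @param state a `[n x 8]` state matrix (or a single row)
#' @param injection_concentrations positive vector of the three adsorbate
#'   feed concentrations (g/L)
#' @return a `[n x 7]` feature matrix
#' @export
normalize_features <- function(state, injection_concentrations) {
  if (any(injection_concentrations <= 0))
    stopf("injection concentrations must be strictly positive")
  y <- if (is.matrix(state)) state else matrix(state, 1)
  a <- injection_concentrations
  cbind(y[, 1],
        y[, 2] / a[1], y[, 3] / a[2], y[, 4] / a[3],
        y[, 6] / a[1], y[, 7] / a[2], y[, 8] / a[3])
}

# ---- corrections -----------------------------------------------------------

#' Corrections applied to the adsorption rates
#'
#' A correction multiplies the three SDM adsorption rates node-wise by
#' strictly positive factors computed from the local features. The identity
#' correction leaves the mechanistic model untouched; `correction_function`
#' wraps an arbitrary smooth positive function (used e.g. as the ground truth
#' of the synthetic benchmark); the trained neural network is wrapped by
#' [correction_network()].
#'
#' @param fn function mapping a `[n x 7]` feature matrix to a `[n x 3]`
#'   matrix of positive multipliers
#' @param jac_fn optional function returning the `[n x 3 x 7]` array of
#'   multiplier-feature derivatives; a central finite difference is used
#'   when absent
#' @return an object of class `chrom_correction`
#' @export
correction_function <- function(fn, jac_fn = NULL) {
  structure(list(kind = "function", fn = fn, jac_fn = jac_fn),
            class = "chrom_correction")
}

#' @rdname correction_function
#' @export
correction_identity <- function() {
  correction_function(function(X) matrix(1, nrow(X), 3),
                      function(X) array(0, c(nrow(X), 3, 7)))
}

# evaluate multipliers; returns list(gamma = n x 3, cache)
corr_eval <- function(corr, X) {
  if (is.null(corr)) return(list(gamma = NULL, cache = NULL))
  if (corr$kind == "network") {
    fw <- nn_forward(corr$theta, X, cache = TRUE)
    list(gamma = fw$out, cache = fw)
  } else {
    list(gamma = corr$fn(X), cache = X)
  }
}

# multiplier-feature Jacobian [n x 3 x 7]
corr_input_jac <- function(corr, X, cache = NULL) {
  if (is.null(corr)) return(NULL)
  if (corr$kind == "network") {
    if (is.null(cache)) cache <- nn_forward(corr$theta, X, cache = TRUE)
    return(nn_input_jac(corr$theta, cache))
  }
  if (!is.null(corr$jac_fn)) return(corr$jac_fn(X))
  J <- array(0, c(nrow(X), 3, 7))
  for (f in 1:7) {
    h <- 1e-6 * (1 + abs(X[, f]))
    Xp <- X; Xp[, f] <- X[, f] + h
    Xm <- X; Xm[, f] <- X[, f] - h
    J[, , f] <- (corr$fn(Xp) - corr$fn(Xm)) / (2 * h)
  }
  J
}

# ---- right-hand side -------------------------------------------------------

# internal fast path; `corr` NULL -> purely mechanistic. Returns the rates
# matrix; with `want_core = TRUE` also the SDM intermediates and multipliers.
chrom_rhs <- function(y, t, ctx, corr = NULL, want_core = FALSE) {
  i <- program_step_at(ctx$program, t)
  op <- ctx$ops[[i]]
  inl <- inlet_profile(ctx$program, t)
  core <- sdm_core(y, ctx)
  gamma <- NULL; ccache <- NULL
  R <- core$r
  if (!is.null(corr)) {
    X <- normalize_features(y, ctx$cinj)
    ev <- corr_eval(corr, X)
    gamma <- ev$gamma; ccache <- ev$cache
    R <- gamma * core$r
  }
  dy <- matrix(0, nrow(y), 8)
  dy[, 1:4] <- op$A %*% y[, 1:4, drop = FALSE] +
    outer(op$g, c(inl$percentB, inl$feed))
  dy[, MOBILE_ADS] <- dy[, MOBILE_ADS] - ctx$phase_ratio * R
  dy[, 5] <- -as.vector(R %*% ctx$nu)
  dy[, STAT_ADS] <- R
  if (want_core)
    attr(dy, "core") <- list(core = core, gamma = gamma, ccache = ccache,
                             step = i, op = op)
  dy
}

#' Semi-discrete right-hand side of the column model
#'
#' Operator F: maps a full column state to its time derivative. Adsorbate
#' mobile fields combine DG transport with the adsorption coupling
#' `-(1-eps_t)/eps_t dq/dt`; the modifier mobile field is transport only;
#' stationary fields follow the SDM kinetics and the modifier displacement
#' balance. Inlet values come from the method program at time `t`.
#'
#' @param state `[n x 8]` state matrix
#' @param t time (s)
#' @param program a [method_program()]
#' @param components list of three [component_params()]
#' @param mesh a [build_mesh()]
#' @param correction optional [correction_function()] applied to the
#'   adsorption rates (the hybrid right-hand side)
#' @return `[n x 8]` matrix of time derivatives
#' @export
assemble_rhs <- function(state, t, program, components, mesh,
                         correction = NULL) {
  ctx <- chrom_model(program, components, mesh)
  if (!is.matrix(state) || nrow(state) != ctx$n || ncol(state) != 8)
    stopf("state must be a [%d x 8] matrix for this mesh", ctx$n)
  chrom_rhs(state, t, ctx, corr = correction)
}

# ---- state Jacobian --------------------------------------------------------

# dense [8n x 8n] Jacobian of chrom_rhs w.r.t. vec(y) (column-major fields).
# Exact for NULL and network corrections; for function corrections exact up
# to the quality of their jac_fn / finite differences (only used inside
# Newton, where an approximate Jacobian does not affect the converged state).
chrom_jac <- function(y, t, ctx, corr = NULL) {
  n <- ctx$n; N <- 8L * n
  i <- program_step_at(ctx$program, t)
  op <- ctx$ops[[i]]
  core <- sdm_core(y, ctx)
  cj <- sdm_core_jac(core, ctx)
  gamma <- matrix(1, n, 3); Jin <- NULL
  if (!is.null(corr)) {
    X <- normalize_features(y, ctx$cinj)
    ev <- corr_eval(corr, X)
    gamma <- ev$gamma
    Jin <- corr_input_jac(corr, X, ev$cache)
  }
  J <- matrix(0, N, N)
  idx <- function(f) ((f - 1L) * n + 1L):(f * n)
  for (f in 1:4) J[idx(f), idx(f)] <- op$A
  # local derivative of the corrected rate R_i w.r.t. state field x:
  #   dR_i/dx = gamma_i dr_i/dx + r_i dgamma_i/dx
  # x runs over cm (feature 1, unit scale) and the six adsorbate fields
  # (features 2..7, scaled by 1/cinj)
  xfields <- c(1L, 2L, 3L, 4L, 6L, 7L, 8L)
  xfeat <- 1:7
  xscale <- c(1, 1 / ctx$cinj, 1 / ctx$cinj)
  dR <- array(0, c(n, 3, 7))
  for (i3 in 1:3) {
    for (k in 1:7) {
      x <- xfields[k]
      drdx <-
        if (x == 1) cj$dr_dcm[, i3]
        else if (x == i3 + 1) cj$dr_dc[, i3]
        else if (x >= 6) {
          j3 <- x - 5L
          -cj$Schan[, i3] * ctx$nusig[j3] -
            (if (j3 == i3) core$cmpow[, i3] / ctx$kkin[i3] else 0)
        } else 0
      val <- gamma[, i3] * drdx
      if (!is.null(Jin))
        val <- val + core$r[, i3] * Jin[, i3, xfeat[k]] * xscale[k]
      dR[, i3, k] <- val
    }
  }
  for (k in 1:7) {
    xf <- xfields[k]
    dqm <- numeric(n)
    for (i3 in 1:3) {
      v <- dR[, i3, k]
      J[ctx$jac_idx[[5L + i3]][[xf]]] <- v                           # q_i row
      lin <- ctx$jac_idx[[1L + i3]][[xf]]
      J[lin] <- J[lin] - ctx$phase_ratio * v                         # c_i row
      dqm <- dqm - ctx$nu[i3] * v
    }
    lin <- ctx$jac_idx[[5L]][[xf]]
    J[lin] <- J[lin] + dqm                                           # qm row
  }
  J
}
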