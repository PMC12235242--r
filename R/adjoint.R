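# Reverse-mode differentiation through the unrolled BDF integration
# (discretize-then-optimize). Each implicit step solves
#   R(y_n) = y_n + sum_j a_j y_{n-j} - h b f(y_n, p) = 0,
# so by the implicit function theorem, with A_n = I - h b J_f(y_n),
#   A_n dy_n = -sum_j a_j dy_{n-j} + h b (df/dp) dp.
# The reverse sweep therefore solves A_n^T w = ybar_n per step, scatters
# -a_j w into the history adjoints and contracts h b w against df/dtheta
# (network parameters) or df/dp (SDM parameters). The gradients are exact up
# to the Newton tolerance of the forward solve, and match finite differences.

# precompute everything reused across epochs for one experiment
prepare_experiment <- function(exp, model, include_modifier = TRUE) {
  if (is.null(exp$observations))
    stopf("experiment %s carries no observations", exp$label)
  obs <- obs_matrix(exp$observations)
  windows <- data.frame(t0 = exp$observations$t_start_s,
                        t1 = exp$observations$t_end_s)
  plan <- plan_segments(model$program, model$solver$step_fraction,
                        model$solver$n_steps)
  # solver snapshot grid is fixed by the program + solver config, so the
  # fraction-averaging weights can be frozen here
  times <- c(0, unlist(lapply(seq_len(nrow(plan)), function(k)
    plan$t0[k] + seq_len(plan$n[k]) * plan$h[k])))
  Wq <- fraction_weight_matrix(times, windows)
  scale <- loss_scales(model$cinj, include_modifier)
  obs_n <- sweep(obs, 2, scale, "*")
  list(exp = exp, model = model, obs = obs, obs_n = obs_n, scale = scale,
       denom = sum(obs_n^2), Wq = Wq, snap_times = times)
}

# forward + loss (+ optionally reverse sweep) for one prepared experiment.
# Exactly one of `theta` (network-parameter gradient) or `mech_grad = TRUE`
# (SDM-parameter gradient) drives the gradient contraction.
experiment_loss <- function(prep, theta = NULL, correction = NULL,
                            want_grad = FALSE, mech_grad = FALSE) {
  model <- prep$model
  if (is.null(correction) && !is.null(theta))
    correction <- correction_network(theta)
  traj <- bdf_integrate(model, correction = correction)
  OUT <- outlet_matrix(traj, model$mesh)
  pred_n <- sweep(prep$Wq %*% OUT, 2, prep$scale, "*")
  resid <- pred_n - prep$obs_n
  loss <- sum(resid^2) / prep$denom
  if (!want_grad)
    return(list(loss = loss, traj = traj))
  # adjoint of the snapshot outlet values
  dPred <- 2 * resid / prep$denom
  dOUT <- sweep(t(prep$Wq) %*% dPred, 2, prep$scale, "*")
  sweep_res <- adjoint_sweep(traj, model, correction, dOUT,
                             theta = if (mech_grad) NULL else theta,
                             mech_grad = mech_grad)
  c(list(loss = loss, traj = traj), sweep_res)
}

# reverse sweep over the tape; returns list(grad_theta=..., grad_mech=...)
adjoint_sweep <- function(traj, model, correction, dOUT,
                          theta = NULL, mech_grad = FALSE) {
  n <- model$n
  M <- length(traj$states)
  nodeset <- seq_len(n)
  out_idx <- (0:3) * n + n          # vec indices of outlet mobile fields
  ybar <- vector("list", M)
  for (m in seq_len(M)) {
    if (any(dOUT[m, ] != 0)) {
      v <- numeric(8L * n)
      v[out_idx] <- dOUT[m, ]
      ybar[[m]] <- v
    }
  }
  gtheta <- if (!is.null(theta))
    lapply(theta$layers, function(l) list(W = l$W * 0, b = l$b * 0))
  gmech <- if (mech_grad) numeric(12) else NULL   # (nu, keq, sigma, kkin) x 3
  for (m in M:2) {
    yb <- ybar[[m]]
    if (is.null(yb)) next
    s <- traj$order[m]; h <- traj$h[m]
    cf <- bdf_coefs(s)
    y <- traj$states[[m]]; t <- traj$times[m]
    J <- chrom_jac(y, t, model, corr = correction)
    A <- diag(8L * n) - h * cf$beta * J
    w <- as.vector(solve(t(A), yb))
    for (j in seq_len(s)) {
      tgt <- m - j
      if (tgt >= 1) {
        if (is.null(ybar[[tgt]])) ybar[[tgt]] <- numeric(8L * n)
        ybar[[tgt]] <- ybar[[tgt]] - cf$a[j] * w
      }
    }
    wmat <- matrix(w, n, 8)
    # adjoint weight of the corrected rate R_i at each node: R_i feeds q_i
    # directly, c_i through -phase_ratio, and qm through -nu_i
    core <- sdm_core(y, model)
    omega <- matrix(0, n, 3)
    for (i in 1:3)
      omega[, i] <- wmat[, 5 + i] - model$phase_ratio * wmat[, 1 + i] -
        model$nu[i] * wmat[, 5]
    hb <- h * cf$beta
    if (!is.null(theta)) {
      X <- normalize_features(y, model$cinj)
      fw <- nn_forward(theta, X, cache = TRUE)
      Gbar <- core$r * omega            # dR/dgamma = r (uncorrected rate)
      g <- nn_vjp_params(theta, fw, Gbar)
      for (l in seq_along(gtheta)) {
        gtheta[[l]]$W <- gtheta[[l]]$W + hb * g[[l]]$W
        gtheta[[l]]$b <- gtheta[[l]]$b + hb * g[[l]]$b
      }
    }
    if (mech_grad)
      gmech <- gmech + hb * mech_param_vjp(core, model, omega, wmat[, 5],
                                           correction, y)
  }
  list(grad_theta = gtheta, grad_mech = gmech)
}

# contraction of the rate adjoints against the SDM parameter derivatives.
# Returns d(loss)/d(nu_1..3, keq_1..3, sigma_1..3, kkin_1..3) contributions
# of one time step (before the h*beta factor).
mech_param_vjp <- function(core, ctx, omega, w_qm, correction, y) {
  gamma <- matrix(1, nrow(y), 3)
  if (!is.null(correction))
    gamma <- corr_eval(correction, normalize_features(y, ctx$cinj))$gamma
  Aw <- omega * gamma                     # adjoint of the uncorrected rate r_i
  logS <- ifelse(core$S > 0, log(core$S), 0)
  logcm <- log(core$cm)
  cj <- sdm_core_jac(core, ctx)
  # shared channel through the surface availability S: sum_l Aw_l * Schan_l
  B <- rowSums(Aw * cj$Schan)
  g <- numeric(12)
  for (i in 1:3) {
    Rcorr <- gamma[, i] * core$r[, i]
    # d r_i / d nu_i explicit (power-law exponents)
    dr_dnu <- (ctx$keq[i] * core$Spow[, i] * logS * core$cads[, i] -
                 core$q[, i] * core$cmpow[, i] * logcm) / ctx$kkin[i]
    g[i] <- sum(Aw[, i] * dr_dnu) - sum(w_qm * Rcorr) - sum(B * core$q[, i])
    g[3 + i] <- sum(Aw[, i] * core$Spow[, i] * core$cads[, i] / ctx$kkin[i])
    g[6 + i] <- -sum(B * core$q[, i])
    g[9 + i] <- -sum(Aw[, i] * core$r[, i] / ctx$kkin[i])
  }
  g
}

# mean loss (and gradients) over a list of prepared experiments
study_loss <- function(preps, theta = NULL, correction = NULL,
                       want_grad = FALSE, mech_grad = FALSE) {
  res <- lapply(preps, experiment_loss, theta = theta,
                correction = correction, want_grad = want_grad,
                mech_grad = mech_grad)
  losses <- vapply(res, `[[`, numeric(1), "loss")
  out <- list(loss = mean(losses), per_experiment = losses)
  if (want_grad && !mech_grad && !is.null(theta)) {
    gs <- lapply(res, `[[`, "grad_theta")
    acc <- gs[[1]]
    if (length(gs) > 1) for (k in 2:length(gs)) {
      for (l in seq_along(acc)) {
        acc[[l]]$W <- acc[[l]]$W + gs[[k]][[l]]$W
        acc[[l]]$b <- acc[[l]]$b + gs[[k]][[l]]$b
      }
    }
    for (l in seq_along(acc)) {
      acc[[l]]$W <- acc[[l]]$W / length(gs)
      acc[[l]]$b <- acc[[l]]$b / length(gs)
    }
    out$grad_theta <- acc
  }
  if (want_grad && mech_grad) {
    gm <- Reduce(`+`, lapply(res, `[[`, "grad_mech")) / length(res)
    out$grad_mech <- gm
  }
  out
}
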