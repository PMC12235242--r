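# Simplified stoichiometric displacement model (SDM) kinetics and the full
# semi-discrete right-hand side coupling transport to adsorption.
#
# State layout: a [n_nodes x 8] matrix with columns
#   (cm, cW, cP, cS, qm, qW, qP, qS)
# mobile concentrations in g/L (adsorbates) / %B (modifier), stationary
# concentrations q in model units per liter stationary phase.

FIELD_NAMES <- c("cm", "cW", "cP", "cS", "qm", "qW", "qP", "qS")
MOBILE_ADS <- 2:4    # cW, cP, cS columns
STAT_ADS <- 6:8      # qW, qP, qS columns

#' Adsorption rate of the stoichiometric displacement model
#'
#' Pointwise kinetic rate `dq_i/dt = (1/kkin) * (keq * (Lambda - sum_j
#' (nu_j + sigma_j) q_j)^nu * c_i - q_i * cm^nu)`: binding of one solute
#' molecule displaces `nu` modifier equivalents and shields `sigma` further
#' ligand sites. All arguments are vectorized over mesh nodes.
#'
#' @param c_i mobile-phase concentration of the component (g/L)
#' @param q_all matrix (nodes x n components) of stationary concentrations
#' @param cm modifier concentration (%B), strictly positive
#' @param params a [component_params()] for the component
#' @param ligand ligand density Lambda
#' @param all_params list of [component_params()] for every component (for
#'   the shared surface-availability term); defaults to `list(params)`
#' @return vector of rates dq_i/dt
#' @export
sdm_rate <- function(c_i, q_all, cm, params, ligand, all_params = list(params)) {
  q_all <- as.matrix(q_all)
  nusig <- vapply(all_params, function(p) p$charge_nu + p$sigma, numeric(1))
  S <- ligand - as.vector(q_all %*% nusig)
  if (any(S < 0)) stopf("surface overload: available ligand term is negative")
  if (any(cm <= 0)) stopf("modifier concentration must be positive (cm^nu term)")
  i <- which(vapply(all_params, function(p) identical(p$name, params$name),
                    logical(1)))[1]
  (params$keq * S^params$charge_nu * c_i - q_all[, i] * cm^params$charge_nu) /
    params$kkin
}

#' Stationary-phase modifier rate
#'
#' The modifier bookkeeping on the stationary phase: each adsorbing solute
#' displaces `nu` modifier equivalents, so `dqm/dt = -sum_j nu_j dq_j/dt`.
#'
#' @param dq_rates matrix (nodes x n) or vector of component adsorption rates
#' @param charges vector of characteristic charges nu, one per component
#' @return vector of dqm/dt
#' @export
modifier_stationary_rate <- function(dq_rates, charges) {
  dq_rates <- as.matrix(dq_rates)
  if (ncol(dq_rates) != length(charges))
    stopf("length mismatch: %d rate columns vs %d charges",
          ncol(dq_rates), length(charges))
  -as.vector(dq_rates %*% charges)
}

# ---- internal vectorized SDM core -----------------------------------------

# uncorrected rates r (n x 3) plus the shared terms reused by the Jacobian.
# The surface-availability term is clamped at zero so that the residual is
# defined for the transient Newton iterates; accepted solver states are
# validated separately (see check_state).
sdm_core <- function(y, ctx) {
  q <- y[, STAT_ADS, drop = FALSE]
  cm <- pmax(y[, 1], 1e-12)
  S <- pmax(ctx$Lambda - as.vector(q %*% ctx$nusig), 0)
  n <- nrow(y)
  cads <- y[, MOBILE_ADS, drop = FALSE]
  r <- matrix(0, n, 3)
  Spow <- matrix(0, n, 3)   # S^nu_i
  cmpow <- matrix(0, n, 3)  # cm^nu_i
  for (i in 1:3) {
    nu <- ctx$nu[i]
    Spow[, i] <- S^nu
    cmpow[, i] <- cm^nu
    r[, i] <- (ctx$keq[i] * Spow[, i] * cads[, i] -
                 q[, i] * cmpow[, i]) / ctx$kkin[i]
  }
  list(r = r, S = S, Spow = Spow, cmpow = cmpow, cm = cm, q = q, cads = cads)
}

# physical-state validation applied to accepted solver states (converged
# steps), not to transient Newton iterates
check_state <- function(y, ctx) {
  S <- ctx$Lambda - as.vector(y[, STAT_ADS, drop = FALSE] %*% ctx$nusig)
  if (min(S) < -1e-6 * ctx$Lambda)
    stopf("surface overload: available ligand term is negative (min %g)",
          min(S))
  if (min(y[, 1]) <= 0)
    stopf("modifier concentration must be positive inside the column (min %g)",
          min(y[, 1]))
  invisible(y)
}

# derivatives of the uncorrected rates w.r.t. the local state:
# returns per-component n-vectors; d r_i / d q_j assembles as
#   -Schan_i * (nu_j + sigma_j) - delta_ij * cm^nu_i / kkin_i
sdm_core_jac <- function(core, ctx) {
  n <- length(core$S)
  dr_dc <- matrix(0, n, 3)    # d r_i / d c_i
  dr_dcm <- matrix(0, n, 3)   # d r_i / d cm
  Schan <- matrix(0, n, 3)    # keq_i nu_i S^(nu_i - 1) c_i / kkin_i
  for (i in 1:3) {
    nu <- ctx$nu[i]
    dr_dc[, i] <- ctx$keq[i] * core$Spow[, i] / ctx$kkin[i]
    dr_dcm[, i] <- -core$q[, i] * nu * core$cm^(nu - 1) / ctx$kkin[i]
    Spm1 <- ifelse(core$S > 0, core$Spow[, i] / core$S, 0)
    Schan[, i] <- ctx$keq[i] * nu * Spm1 * core$cads[, i] / ctx$kkin[i]
  }
  list(dr_dc = dr_dc, dr_dcm = dr_dcm, Schan = Schan)
}
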