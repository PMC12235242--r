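# Mechanistic calibration: gradient-based fit of the SDM parameters to
# training chromatograms through the differentiable simulator, on
# log-transformed parameters (which keeps them strictly positive). Uses the
# same loss, normalization and data partitioning as the hybrid training; the
# calibrated parameters are then frozen while the correction network trains.

PARAM_NAMES <- c(t(outer(c("nu", "keq", "sigma", "kkin"),
                         c("W", "P", "S"), paste, sep = "_")))

params_to_vec <- function(ctx) c(ctx$nu, ctx$keq, ctx$sigma, ctx$kkin)

models_with_params <- function(models, p) {
  lapply(models, model_set_params,
         nu = p[1:3], keq = p[4:6], sigma = p[7:9], kkin = p[10:12])
}

#' Calibration configuration
#'
#' @param free character vector naming the parameters to fit, from
#'   `nu_W, nu_P, nu_S, keq_W, ..., kkin_S`; all twelve by default except the
#'   shielding factors of components whose initial sigma is zero (a zero
#'   sigma cannot be log-parameterized)
#' @param maxit maximum optimizer iterations
#' @param scan_multipliers optional multipliers for a coarse one-dimensional
#'   pre-scan of each free parameter (in order) before the gradient descent;
#'   `NULL` disables the scan
#' @param include_modifier include the modifier column in the loss
#' @return object of class `calibration_config`
#' @export
calibration_config <- function(free = NULL, maxit = 50,
                               scan_multipliers = NULL,
                               include_modifier = TRUE) {
  structure(list(free = free, maxit = maxit,
                 scan_multipliers = scan_multipliers,
                 include_modifier = include_modifier),
            class = "calibration_config")
}

#' Calibrate the mechanistic model on training chromatograms
#'
#' Minimizes the normalized chromatogram loss over log-transformed SDM
#' parameters by L-BFGS, with exact gradients obtained by backpropagating
#' through every BDF step of the mechanistic simulation (the same adjoint
#' used to train the correction network, contracted against the parameter
#' derivatives of the adsorption rates instead of the network weights).
#'
#' @param experiments training [experiment()]s with observations
#' @param models parallel [chrom_model()]s carrying the initial parameter
#'   guess
#' @param config a [calibration_config()]
#' @return list of class `chrom_calibration`: fitted `components`, updated
#'   `models`, initial and final `loss`, the optimizer `history` and the
#'   fitted parameter vector
#' @export
calibrate <- function(experiments, models, config = calibration_config()) {
  p0 <- params_to_vec(models[[1]])
  names(p0) <- PARAM_NAMES
  free <- config$free
  if (is.null(free)) free <- PARAM_NAMES[p0 > 0]
  if (!length(free)) stopf("at least one parameter must be free")
  if (any(p0[free] <= 0))
    stopf("free parameters must be strictly positive for log-scaling: %s",
          paste(free[p0[free] <= 0], collapse = ", "))
  obj_env <- new.env()
  obj_env$history <- numeric(0)
  eval_at <- function(lp, want_grad = TRUE) {
    p <- p0
    p[free] <- exp(lp)
    ms <- models_with_params(models, p)
    preps <- mapply(prepare_experiment, experiments, ms,
                    MoreArgs = list(include_modifier = config$include_modifier),
                    SIMPLIFY = FALSE)
    sl <- try(study_loss(preps, want_grad = want_grad, mech_grad = want_grad),
              silent = TRUE)
    if (inherits(sl, "try-error"))
      return(list(loss = 1e6, grad = rep(0, length(free))))
    g <- if (want_grad) (sl$grad_mech * p)[match(free, PARAM_NAMES)] else NULL
    list(loss = sl$loss, grad = g)
  }
  lp <- log(p0[free])
  if (!is.null(config$scan_multipliers)) {
    for (k in seq_along(free)) {
      cand <- lp[k] + log(config$scan_multipliers)
      losses <- vapply(cand, function(v) {
        lpk <- lp; lpk[k] <- v
        eval_at(lpk, want_grad = FALSE)$loss
      }, numeric(1))
      lp[k] <- cand[which.min(losses)]
    }
  }
  last <- new.env()   # L-BFGS calls fn and gr at the same point: cache one
  fn <- function(lpv) {
    r <- eval_at(lpv)
    last$lp <- lpv; last$r <- r
    obj_env$history <- c(obj_env$history, r$loss)
    r$loss
  }
  gr <- function(lpv) {
    if (!is.null(last$lp) && isTRUE(all.equal(last$lp, lpv, tolerance = 0)))
      return(last$r$grad)
    eval_at(lpv)$grad
  }
  initial_loss <- eval_at(lp, want_grad = FALSE)$loss
  opt <- stats::optim(lp, fn, gr, method = "L-BFGS-B",
                      control = list(maxit = config$maxit))
  # keep the best point seen (optim returns its own best, but guard anyway)
  lp_best <- if (opt$value <= initial_loss) opt$par else lp
  p <- p0; p[free] <- exp(lp_best)
  ms <- models_with_params(models, p)
  structure(
    list(components = ms[[1]]$components, models = ms,
         params = stats::setNames(p, PARAM_NAMES),
         initial_loss = initial_loss,
         loss = min(opt$value, initial_loss),
         history = obj_env$history, free = free,
         convergence = opt$convergence),
    class = "chrom_calibration")
}

#' @export
print.chrom_calibration <- function(x, ...) {
  cat(sprintf("<chrom_calibration> loss %.3e -> %.3e (%d free parameters)\n",
              x$initial_loss, x$loss, length(x$free)))
  invisible(x)
}
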