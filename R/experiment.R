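# Experiments: a labelled method program with (optionally) fraction-averaged
# chromatogram observations, plus the observation model shared by simulation
# and loss: outlet concentrations averaged over consecutive fraction-collector
# windows spanning the gradient step.

#' Create an experiment
#'
#' @param label experiment label, e.g. `"Load15_GL6p5"`
#' @param program a [method_program()] (the load step carries the feed)
#' @param role `"train"` or `"test"`
#' @param observations optional chromatogram tibble as returned by
#'   [generate_observations()] / [read_experiment()]
#' @return object of class `chrom_experiment`
#' @export
experiment <- function(label, program, role = c("train", "test"),
                       observations = NULL) {
  role <- match.arg(role)
  if (!is.null(observations)) {
    if (any(observations$t_start_s < -1e-9) ||
        any(observations$t_end_s > program_span(program) + 1e-6))
      stopf("observation windows outside the program span")
  }
  structure(list(label = label, program = program, role = role,
                 observations = observations),
            class = "chrom_experiment")
}

#' @export
print.chrom_experiment <- function(x, ...) {
  cat(sprintf("<chrom_experiment> %s (%s), %s\n", x$label, x$role,
              if (is.null(x$observations)) "no observations"
              else sprintf("%d fractions", nrow(x$observations))))
  invisible(x)
}

#' Fraction-collector windows over the gradient step
#'
#' Consecutive windows of `fraction_cv` column volumes covering the gradient
#' step of the program (a trailing partial fraction is kept). Times follow
#' the per-step flow through [cv_to_time()].
#'
#' @param program a [method_program()]
#' @param fraction_cv fraction volume (CV)
#' @return data.frame with columns `cv0`, `cv1`, `t0`, `t1`, `mid_cv`, `mid_t`
#' @export
fraction_windows <- function(program, fraction_cv = 0.25) {
  stopifnot(fraction_cv > 0)
  gi <- which(vapply(program$steps, function(s) s$kind == "gradient",
                     logical(1)))[1]
  cv0 <- program$cv_bounds[gi]; cv1 <- program$cv_bounds[gi + 1]
  edges <- seq(cv0, cv1, by = fraction_cv)
  if (cv1 - edges[length(edges)] > 1e-9) edges <- c(edges, cv1)
  lo <- edges[-length(edges)]; hi <- edges[-1]
  data.frame(cv0 = lo, cv1 = hi,
             t0 = cv_to_time(program, lo), t1 = cv_to_time(program, hi),
             mid_cv = (lo + hi) / 2,
             mid_t = cv_to_time(program, (lo + hi) / 2))
}

# weight matrix mapping snapshot outlet values -> fraction averages
fraction_weight_matrix <- function(times, windows) {
  t(vapply(seq_len(nrow(windows)), function(i)
    pwlinear_average_weights(times, windows$t0[i], windows$t1[i]),
    numeric(length(times))))
}

# assemble a chromatogram tibble from fraction-averaged values
chromatogram_tibble <- function(windows, vals) {
  tibble::tibble(time_s = windows$mid_t, volume_cv = windows$mid_cv,
                 t_start_s = windows$t0, t_end_s = windows$t1,
                 modifier_percentB = vals[, 1],
                 c_W = vals[, 2], c_P = vals[, 3], c_S = vals[, 4])
}

obs_matrix <- function(chrom) {
  cbind(chrom$modifier_percentB, chrom$c_W, chrom$c_P, chrom$c_S)
}

#' Simulate an experiment
#'
#' Integrates the mechanistic (`theta = NULL`, no `correction`) or hybrid
#' model over the experiment's full method program and returns the outlet
#' chromatogram averaged over the experiment's fraction windows, matching the
#' observation model of the benchmark.
#'
#' @param exp a [experiment()]
#' @param model a [chrom_model()] built on the experiment's program
#' @param theta optional [init_network()] parameters (hybrid simulation)
#' @param correction optional explicit `chrom_correction` (overrides `theta`)
#' @param fraction_cv fraction volume used when the experiment carries no
#'   observations
#' @return chromatogram tibble (one row per fraction)
#' @export
simulate_experiment <- function(exp, model, theta = NULL, correction = NULL,
                                fraction_cv = 0.25) {
  if (is.null(correction) && !is.null(theta))
    correction <- correction_network(theta)
  traj <- bdf_integrate(model, correction = correction)
  windows <- if (!is.null(exp$observations))
    data.frame(cv0 = NA, cv1 = NA,
               t0 = exp$observations$t_start_s, t1 = exp$observations$t_end_s,
               mid_cv = exp$observations$volume_cv,
               mid_t = exp$observations$time_s)
  else fraction_windows(exp$program, fraction_cv)
  Wq <- fraction_weight_matrix(traj$times, windows)
  chromatogram_tibble(windows, Wq %*% outlet_matrix(traj, model$mesh))
}

# ---- loss and goodness of fit ---------------------------------------------

# per-column scales turning raw chromatogram matrices into normalized ones:
# adsorbates divided by their injection concentration; the modifier needs no
# data-driven normalization - carried in %B it maps to its fractional 0-1
# scale so all four normalized columns are O(1)
loss_scales <- function(cinj, include_modifier = TRUE) {
  s <- c(if (include_modifier) 1 / 100 else 0, 1 / cinj)
  if (any(!is.finite(s))) stopf("injection concentrations must be positive")
  s
}

#' Normalized squared-error loss between chromatograms
#'
#' `L = ||Chat - C||^2 / ||C||^2` over the four normalized columns of the
#' fraction chromatogram (adsorbates scaled by their injection
#' concentrations; the modifier needs no data-driven normalization and
#' enters on its fractional 0-1 scale). This is the training loss; across
#' several experiments the arithmetic mean of per-experiment losses is used.
#'
#' @param pred predicted chromatogram (tibble or `[nt x 4]` matrix ordered
#'   modifier, W, P, S)
#' @param obs observed chromatogram, same layout
#' @param cinj the three adsorbate injection concentrations (g/L)
#' @param include_modifier include the modifier column in the loss
#' @return scalar loss
#' @export
chrom_loss <- function(pred, obs, cinj, include_modifier = TRUE) {
  P <- if (is.data.frame(pred)) obs_matrix(pred) else as.matrix(pred)
  C <- if (is.data.frame(obs)) obs_matrix(obs) else as.matrix(obs)
  if (!all(dim(P) == dim(C))) stopf("chromatogram shapes do not match")
  s <- loss_scales(cinj, include_modifier)
  Pn <- sweep(P, 2, s, "*"); Cn <- sweep(C, 2, s, "*")
  denom <- sum(Cn^2)
  if (denom == 0) stopf("observations are all zero: loss normalization undefined")
  sum((Pn - Cn)^2) / denom
}

#' Coefficient of determination of a chromatogram fit
#'
#' `R^2 = 1 - SS_res / SS_tot` on the normalized concentrations, per
#' component and pooled over the three adsorbate columns (`overall`).
#' Zero-variance observation columns yield `NA`.
#'
#' @inheritParams chrom_loss
#' @param scope `"per_component"` or `"overall"`
#' @return named numeric vector (per component) or scalar (overall)
#' @export
r_squared <- function(pred, obs, cinj, scope = c("overall", "per_component")) {
  scope <- match.arg(scope)
  P <- if (is.data.frame(pred)) obs_matrix(pred) else as.matrix(pred)
  C <- if (is.data.frame(obs)) obs_matrix(obs) else as.matrix(obs)
  s <- loss_scales(cinj, include_modifier = TRUE)
  Pn <- sweep(P, 2, s, "*"); Cn <- sweep(C, 2, s, "*")
  r2_one <- function(p, c) {
    sst <- sum((c - mean(c))^2)
    if (sst == 0) return(NA_real_)
    1 - sum((p - c)^2) / sst
  }
  if (scope == "per_component") {
    out <- vapply(1:4, function(j) r2_one(Pn[, j], Cn[, j]), numeric(1))
    names(out) <- c("modifier", "W", "P", "S")
    out
  } else {
    p <- as.vector(Pn[, 2:4]); c <- as.vector(Cn[, 2:4])
    r2_one(p, c)
  }
}
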