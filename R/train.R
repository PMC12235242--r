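# Training of the solver-in-the-loop hybrid model: full-batch Adam on the
# network parameters only (the calibrated SDM parameters stay frozen), one
# epoch = one full forward simulation of every training experiment plus
# backpropagation of the mean loss through all solver steps.

#' Training configuration
#'
#' @param learning_rate Adam learning rate alpha
#' @param epochs maximum number of epochs
#' @param seed RNG seed (controls network initialization when no explicit
#'   `theta0` is given to [train_correction()])
#' @param record_history keep the per-epoch loss history
#' @param include_modifier include the modifier column in the loss
#' @param target_loss optional early-exit threshold: training stops once the
#'   epoch loss drops to or below this value
#' @return object of class `train_config`
#' @export
train_config <- function(learning_rate = 1e-3, epochs = 100, seed = 1L,
                         record_history = TRUE, include_modifier = TRUE,
                         target_loss = NULL) {
  stopifnot(learning_rate > 0, epochs >= 1)
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 seed = as.integer(seed), record_history = record_history,
                 include_modifier = include_modifier,
                 target_loss = target_loss),
            class = "train_config")
}

# Adam with the framework-recommended moments (0.9, 0.999, eps 1e-8)
adam_state <- function(nparam) {
  list(m = numeric(nparam), v = numeric(nparam), t = 0L,
       beta1 = 0.9, beta2 = 0.999, eps = 1e-8)
}

adam_update <- function(st, g, lr) {
  st$t <- st$t + 1L
  st$m <- st$beta1 * st$m + (1 - st$beta1) * g
  st$v <- st$beta2 * st$v + (1 - st$beta2) * g^2
  mhat <- st$m / (1 - st$beta1^st$t)
  vhat <- st$v / (1 - st$beta2^st$t)
  list(state = st, step = -lr * mhat / (sqrt(vhat) + st$eps))
}

#' Train the hybrid correction network
#'
#' Full-batch Adam gradient descent on the correction-network parameters,
#' with gradients backpropagated through every BDF step of every training
#' experiment. The mechanistic parameters inside `models` remain frozen. The
#' epoch with the lowest training loss is retained as the fit.
#'
#' @param experiments list of training [experiment()]s (with observations)
#' @param models list of [chrom_model()]s parallel to `experiments`
#' @param theta0 initial parameters; default: identity-initialized network
#'   from `net_config`
#' @param net_config a [network_config()] used when `theta0` is absent
#' @param config a [train_config()]
#' @return object of class `chrom_fit`: best parameters, loss history,
#'   per-experiment contributions
#' @export
train_correction <- function(experiments, models,
                             theta0 = NULL,
                             net_config = network_config(),
                             config = train_config()) {
  stopifnot(length(experiments) >= 1, length(experiments) == length(models))
  if (is.null(theta0)) {
    net_config$init_seed <- config$seed
    theta0 <- init_network(net_config)
  }
  preps <- mapply(prepare_experiment, experiments, models,
                  MoreArgs = list(include_modifier = config$include_modifier),
                  SIMPLIFY = FALSE)
  theta <- theta0
  vec <- theta_to_vec(theta)
  ad <- adam_state(length(vec))
  history <- numeric(0)
  per_exp <- NULL
  best <- list(loss = Inf, theta = theta, epoch = 0L)
  for (epoch in seq_len(config$epochs)) {
    sl <- study_loss(preps, theta = theta, want_grad = TRUE)
    if (!is.finite(sl$loss))
      stopf("non-finite training loss at epoch %d", epoch)
    history <- c(history, sl$loss)
    per_exp <- rbind(per_exp, sl$per_experiment)
    if (sl$loss < best$loss)
      best <- list(loss = sl$loss, theta = theta, epoch = epoch)
    if (!is.null(config$target_loss) && sl$loss <= config$target_loss) break
    upd <- adam_update(ad, grad_to_vec(sl$grad_theta), config$learning_rate)
    ad <- upd$state
    vec <- vec + upd$step
    theta <- vec_to_theta(vec, theta)
  }
  colnames(per_exp) <- vapply(experiments, `[[`, character(1), "label")
  structure(
    list(theta = best$theta, best_loss = best$loss, best_epoch = best$epoch,
         initial_loss = history[1], history = history,
         per_experiment = per_exp, config = config,
         net_config = theta0$config, n_params = n_params(theta0)),
    class = "chrom_fit")
}

#' @export
print.chrom_fit <- function(x, ...) {
  cat(sprintf("<chrom_fit> %d epochs, initial loss %.3e, best %.3e (epoch %d)\n",
              length(x$history), x$initial_loss, x$best_loss, x$best_epoch))
  invisible(x)
}

#' Evaluate a correction (or the mechanistic model) on experiments
#'
#' Simulates every experiment and reports the normalized loss and the
#' per-component and overall R-squared against its observations.
#'
#' @param experiments list of [experiment()]s with observations
#' @param models parallel list of [chrom_model()]s
#' @param theta optional network parameters; `NULL` evaluates the purely
#'   mechanistic model
#' @param include_modifier include the modifier column in the loss
#' @return tibble with one row per experiment (label, role, loss, R2 columns)
#' @export
evaluate_experiments <- function(experiments, models, theta = NULL,
                                 include_modifier = TRUE) {
  rows <- lapply(seq_along(experiments), function(i) {
    ex <- experiments[[i]]
    pred <- simulate_experiment(ex, models[[i]], theta = theta)
    obs <- ex$observations
    cinj <- models[[i]]$cinj
    r2c <- r_squared(pred, obs, cinj, scope = "per_component")
    tibble::tibble(
      label = ex$label, role = ex$role,
      loss = chrom_loss(pred, obs, cinj, include_modifier),
      r2_overall = r_squared(pred, obs, cinj, scope = "overall"),
      r2_W = r2c[["W"]], r2_P = r2c[["P"]], r2_S = r2c[["S"]])
  })
  dplyr::bind_rows(rows)
}

#' Hyperparameter grid search
#'
#' Trains the hybrid model for a small number of epochs in every cell of the
#' (layers x nodes x learning-rate) grid, each cell starting from the same
#' identity-initialized network (shared layer-init seed), and summarizes the
#' empirical distribution of the resulting losses. Ties at the optimum are
#' broken toward fewer parameters, then toward the smaller learning rate.
#'
#' @param experiments training [experiment()]s
#' @param models parallel [chrom_model()]s
#' @param n_layers integer vector of hidden-layer counts
#' @param n_nodes integer vector of nodes per layer
#' @param learning_rates numeric vector of Adam learning rates
#' @param epochs epochs per cell (default 20)
#' @param seed shared layer-initialization seed
#' @param include_modifier include the modifier column in the loss
#' @return object of class `chrom_grid`: tibble of cells (`n_layers`,
#'   `n_nodes`, `learning_rate`, `loss`, `n_params`, `runtime_s`), the
#'   selected configuration, the mechanistic baseline loss and the fraction
#'   of cells beating it
#' @export
grid_search <- function(experiments, models,
                        n_layers = 1:3, n_nodes = seq(3, 21),
                        learning_rates = c(1e-4, 1e-3, 1e-2, 1e-1),
                        epochs = 20, seed = 1L, include_modifier = TRUE) {
  preps <- mapply(prepare_experiment, experiments, models,
                  MoreArgs = list(include_modifier = include_modifier),
                  SIMPLIFY = FALSE)
  baseline <- study_loss(preps, theta = NULL)$loss
  cells <- expand.grid(n_layers = n_layers, n_nodes = n_nodes,
                       learning_rate = learning_rates)
  res <- lapply(seq_len(nrow(cells)), function(i) {
    nc <- network_config(cells$n_layers[i], cells$n_nodes[i], init_seed = seed)
    t0 <- proc.time()[["elapsed"]]
    fit <- try(train_correction(
      experiments, models, theta0 = init_network(nc),
      config = train_config(learning_rate = cells$learning_rate[i],
                            epochs = epochs, seed = seed,
                            include_modifier = include_modifier)),
      silent = TRUE)
    rt <- proc.time()[["elapsed"]] - t0
    if (inherits(fit, "try-error"))
      tibble::tibble(loss = NA_real_, n_params = n_params(init_network(nc)),
                     runtime_s = rt, failed = TRUE)
    else
      tibble::tibble(loss = fit$best_loss, n_params = fit$n_params,
                     runtime_s = rt, failed = FALSE)
  })
  tab <- dplyr::bind_cols(tibble::as_tibble(cells), dplyr::bind_rows(res))
  ok <- which(!tab$failed & is.finite(tab$loss))
  sel <- ok[order(tab$loss[ok], tab$n_params[ok], tab$learning_rate[ok])][1]
  structure(
    list(table = tab, selected = tab[sel, ],
         baseline_loss = baseline,
         beat_fraction = mean(tab$loss[ok] < baseline)),
    class = "chrom_grid")
}

#' @export
print.chrom_grid <- function(x, ...) {
  cat(sprintf("<chrom_grid> %d cells; best loss %.3e at nL=%d, nl=%d, alpha=%g\n",
              nrow(x$table), x$selected$loss, x$selected$n_layers,
              x$selected$n_nodes, x$selected$learning_rate))
  cat(sprintf("  mechanistic baseline %.3e beaten by %.0f%% of cells\n",
              x$baseline_loss, 100 * x$beat_fraction))
  invisible(x)
}
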