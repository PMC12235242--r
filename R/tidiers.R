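# broom-style tidiers and ggplot2 autoplot methods for the fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a hybrid-training fit
#'
#' @param x a `chrom_fit` from [train_correction()]
#' @param ... unused
#' @return tibble with one row per epoch: `epoch`, `loss` and one
#'   `loss_<label>` column per training experiment
#' @export
tidy.chrom_fit <- function(x, ...) {
  out <- tibble::tibble(epoch = seq_along(x$history), loss = x$history)
  pe <- tibble::as_tibble(as.data.frame(x$per_experiment))
  names(pe) <- paste0("loss_", names(pe))
  dplyr::bind_cols(out, pe)
}

#' @rdname tidy.chrom_fit
#' @export
glance.chrom_fit <- function(x, ...) {
  tibble::tibble(initial_loss = x$initial_loss, best_loss = x$best_loss,
                 best_epoch = x$best_epoch, epochs = length(x$history),
                 n_params = x$n_params,
                 n_hidden_layers = x$net_config$n_hidden_layers,
                 nodes_per_layer = x$net_config$nodes_per_layer,
                 learning_rate = x$config$learning_rate)
}

#' @rdname tidy.chrom_fit
#' @export
autoplot.chrom_fit <- function(object, ...) {
  d <- tidy.chrom_fit(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$epoch, y = .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = d[object$best_epoch, ], colour = "red") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "epoch", y = "training loss",
                  title = "Hybrid training loss",
                  subtitle = sprintf("best %.3g at epoch %d",
                                     object$best_loss, object$best_epoch)) +
    ggplot2::theme_minimal()
}

#' Tidy a hyperparameter grid search
#'
#' @param x a `chrom_grid` from [grid_search()]
#' @param ... unused
#' @return the cell table as a tibble
#' @export
tidy.chrom_grid <- function(x, ...) x$table

#' @rdname tidy.chrom_grid
#' @export
glance.chrom_grid <- function(x, ...) {
  tibble::tibble(n_cells = nrow(x$table),
                 best_loss = x$selected$loss,
                 n_layers = x$selected$n_layers,
                 n_nodes = x$selected$n_nodes,
                 learning_rate = x$selected$learning_rate,
                 baseline_loss = x$baseline_loss,
                 beat_fraction = x$beat_fraction)
}

#' @rdname tidy.chrom_grid
#' @export
autoplot.chrom_grid <- function(object, ...) {
  d <- object$table
  ggplot2::ggplot(d, ggplot2::aes(x = .data$n_nodes, y = .data$n_layers,
                                  fill = log10(.data$loss))) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~learning_rate, labeller = ggplot2::label_both) +
    ggplot2::scale_fill_viridis_c(name = "log10 loss") +
    ggplot2::labs(x = "nodes per layer", y = "hidden layers",
                  title = "Hyperparameter grid search") +
    ggplot2::theme_minimal()
}

#' Tidy a mechanistic calibration
#'
#' @param x a `chrom_calibration` from [calibrate()]
#' @param ... unused
#' @return tibble with one row per SDM parameter: `parameter`, `value`,
#'   `free`
#' @export
tidy.chrom_calibration <- function(x, ...) {
  tibble::tibble(parameter = names(x$params), value = unname(x$params),
                 free = names(x$params) %in% x$free)
}

#' @rdname tidy.chrom_calibration
#' @export
glance.chrom_calibration <- function(x, ...) {
  tibble::tibble(initial_loss = x$initial_loss, loss = x$loss,
                 n_free = length(x$free), evaluations = length(x$history),
                 convergence = x$convergence)
}

#' Plot a simulated chromatogram against observations
#'
#' Adsorbate outlet concentrations over elution volume, with the modifier
#' gradient on a secondary axis; observations (if given) as points.
#'
#' @param pred predicted chromatogram tibble from [simulate_experiment()]
#' @param obs optional observed chromatogram (same layout)
#' @param normalized plot concentrations normalized by the injection
#'   concentrations `cinj` (requires `cinj`)
#' @param cinj injection concentrations for normalization
#' @return a ggplot object
#' @export
plot_chromatogram <- function(pred, obs = NULL, normalized = FALSE,
                              cinj = NULL) {
  shape_long <- function(d, what) {
    out <- tidyr::pivot_longer(
      dplyr::select(d, "volume_cv", "c_W", "c_P", "c_S"),
      cols = c("c_W", "c_P", "c_S"),
      names_to = "component", values_to = "concentration")
    out$component <- sub("^c_", "", out$component)
    if (normalized) {
      if (is.null(cinj)) stopf("normalized plots need cinj")
      out$concentration <- out$concentration /
        cinj[match(out$component, c("W", "P", "S"))]
    }
    out$what <- what
    out
  }
  d <- shape_long(pred, "model")
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$volume_cv,
                                       y = .data$concentration,
                                       colour = .data$component)) +
    ggplot2::geom_line()
  if (!is.null(obs))
    p <- p + ggplot2::geom_point(data = shape_long(obs, "observed"),
                                 size = 1.2, alpha = 0.8)
  p + ggplot2::labs(x = "elution volume (CV)",
                    y = if (normalized) "c / c_inj" else "outlet conc. (g/L)",
                    colour = NULL) +
    ggplot2::theme_minimal()
}
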