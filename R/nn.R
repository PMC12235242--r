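# Node-wise fully connected correction network: 7 features in, 3 strictly
# positive multipliers out (ReLU hidden activations, Softplus output). The
# same parameters act independently at every mesh node, so all operations are
# batched over nodes. Forward, input-Jacobian and parameter-VJP are written
# out explicitly: training gradients flow through these by hand-rolled
# reverse mode.

#' Network architecture configuration
#'
#' @param n_hidden_layers number of hidden layers (>= 1)
#' @param nodes_per_layer nodes per hidden layer (>= 1; the hyperparameter
#'   search explores 3 and up, but narrower layers are valid networks)
#' @param init_seed RNG seed for layer initialization
#' @return object of class `network_config`
#' @export
network_config <- function(n_hidden_layers = 2, nodes_per_layer = 14,
                           init_seed = 1L) {
  stopifnot(n_hidden_layers >= 1, nodes_per_layer >= 1)
  structure(list(n_hidden_layers = n_hidden_layers,
                 nodes_per_layer = nodes_per_layer,
                 input_width = 7L, output_width = 3L,
                 init_seed = as.integer(init_seed)),
            class = "network_config")
}

#' Initialize correction-network parameters
#'
#' Hidden layers are Kaiming-initialized (zero-mean normal weights with
#' variance `2/fan_in`, zero biases). The output layer is initialized at the
#' identity-correction point: zero weights and bias `softplus^-1(1) =
#' log(e - 1)`, so a freshly initialized network multiplies every adsorption
#' rate by exactly 1 and the hybrid model coincides with the calibrated
#' mechanistic model it starts from.
#'
#' @param config a [network_config()]
#' @return parameter list of class `nn_theta`: per layer `W` (out x in) and `b`
#' @export
init_network <- function(config) {
  widths <- c(config$input_width,
              rep(config$nodes_per_layer, config$n_hidden_layers),
              config$output_width)
  nlayers <- length(widths) - 1L
  layers <- with_seed(config$init_seed, {
    lapply(seq_len(nlayers), function(l) {
      fan_in <- widths[l]; fan_out <- widths[l + 1]
      if (l < nlayers) {
        W <- matrix(stats::rnorm(fan_out * fan_in, sd = sqrt(2 / fan_in)),
                    fan_out, fan_in)
        list(W = W, b = numeric(fan_out))
      } else {
        list(W = matrix(0, fan_out, fan_in),
             b = rep(softplus_inv(1), fan_out))
      }
    })
  })
  structure(list(layers = layers, config = config), class = "nn_theta")
}

#' Forward pass of the correction network
#'
#' @param theta parameters from [init_network()]
#' @param X `[n x 7]` feature matrix
#' @param cache keep intermediate activations (needed for backpropagation)
#' @return `[n x 3]` matrix of positive multipliers; with `cache = TRUE`, a
#'   list with elements `out`, `Xs` (per-layer inputs) and `Ys`
#'   (pre-activations)
#' @export
nn_forward <- function(theta, X, cache = FALSE) {
  if (!is.matrix(X)) X <- matrix(X, 1)
  if (ncol(X) != theta$config$input_width)
    stopf("feature width %d does not match the network input width %d",
          ncol(X), theta$config$input_width)
  L <- length(theta$layers)
  Xs <- vector("list", L)   # input to layer l
  Ys <- vector("list", L)   # pre-activation of layer l
  A <- X
  for (l in seq_len(L)) {
    Xs[[l]] <- A
    Y <- A %*% t(theta$layers[[l]]$W) +
      matrix(theta$layers[[l]]$b, nrow(A), length(theta$layers[[l]]$b),
             byrow = TRUE)
    Ys[[l]] <- Y
    A <- if (l < L) relu(Y) else softplus(Y)
  }
  if (cache) list(out = A, Xs = Xs, Ys = Ys) else A
}

# Jacobian of the outputs w.r.t. the inputs, batched: [n x 3 x 7]
nn_input_jac <- function(theta, fw) {
  L <- length(theta$layers)
  n <- nrow(fw$out)
  J <- array(0, c(n, 3, theta$config$input_width))
  sp <- softplus_prime(fw$Ys[[L]])
  for (k in 1:3) {
    G <- outer(sp[, k], theta$layers[[L]]$W[k, ])   # n x width(L-1)
    if (L > 1) for (l in (L - 1):1) {
      G <- (G * (fw$Ys[[l]] > 0)) %*% theta$layers[[l]]$W
    }
    J[, k, ] <- G
  }
  J
}

# vector-Jacobian product into the parameters: Gbar is the [n x 3] adjoint of
# the outputs; returns a gradient with the same shape as theta$layers
nn_vjp_params <- function(theta, fw, Gbar) {
  L <- length(theta$layers)
  grad <- vector("list", L)
  dY <- Gbar * softplus_prime(fw$Ys[[L]])
  for (l in L:1) {
    grad[[l]] <- list(W = t(dY) %*% fw$Xs[[l]], b = colSums(dY))
    if (l > 1) {
      dX <- dY %*% theta$layers[[l]]$W
      dY <- dX * (fw$Ys[[l - 1]] > 0)
    }
  }
  grad
}

#' Wrap network parameters as a rate correction
#'
#' @param theta parameters from [init_network()]
#' @return a `chrom_correction` usable by [simulate_experiment()] and the
#'   training loop
#' @export
correction_network <- function(theta) {
  stopifnot(inherits(theta, "nn_theta"))
  structure(list(kind = "network", theta = theta), class = "chrom_correction")
}

# ---- parameter vector packing ---------------------------------------------

theta_to_vec <- function(theta) {
  unlist(lapply(theta$layers, function(l) c(as.vector(l$W), l$b)),
         use.names = FALSE)
}

vec_to_theta <- function(v, theta) {
  pos <- 0L
  for (l in seq_along(theta$layers)) {
    W <- theta$layers[[l]]$W
    nw <- length(W); nb <- length(theta$layers[[l]]$b)
    theta$layers[[l]]$W <- matrix(v[pos + seq_len(nw)], nrow(W), ncol(W))
    pos <- pos + nw
    theta$layers[[l]]$b <- v[pos + seq_len(nb)]
    pos <- pos + nb
  }
  theta
}

grad_to_vec <- function(grad) {
  unlist(lapply(grad, function(l) c(as.vector(l$W), l$b)), use.names = FALSE)
}

n_params <- function(theta) length(theta_to_vec(theta))

#' Save / load network parameters
#'
#' Parameters are written as a flat named-parameter text archive (one row per
#' scalar: layer, kind, row, col, value) with the architecture echoed in a
#' header comment, portable across sessions.
#'
#' @param theta parameters from [init_network()]
#' @param path file path
#' @return `save_network` returns `path` invisibly; `load_network` the
#'   reconstructed `nn_theta`
#' @export
save_network <- function(theta, path) {
  cfg <- theta$config
  rows <- do.call(rbind, lapply(seq_along(theta$layers), function(l) {
    W <- theta$layers[[l]]$W
    rbind(
      data.frame(layer = l, kind = "W",
                 row = as.vector(row(W)), col = as.vector(col(W)),
                 value = as.vector(W)),
      data.frame(layer = l, kind = "b",
                 row = seq_along(theta$layers[[l]]$b), col = 0L,
                 value = theta$layers[[l]]$b))
  }))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# network_config n_hidden_layers=%d nodes_per_layer=%d init_seed=%d",
                     cfg$n_hidden_layers, cfg$nodes_per_layer, cfg$init_seed),
             con)
  utils::write.csv(rows, con, row.names = FALSE)
  invisible(path)
}

#' @rdname save_network
#' @export
load_network <- function(path) {
  hdr <- readLines(path, n = 1)
  m <- regmatches(hdr, regexec(
    "n_hidden_layers=(\\d+) nodes_per_layer=(\\d+) init_seed=(-?\\d+)", hdr))[[1]]
  if (length(m) != 4) stopf("not a chromsol network archive: %s", path)
  cfg <- network_config(as.integer(m[2]), as.integer(m[3]), as.integer(m[4]))
  theta <- init_network(cfg)
  rows <- utils::read.csv(path, comment.char = "#")
  for (l in seq_along(theta$layers)) {
    w <- rows[rows$layer == l & rows$kind == "W", ]
    theta$layers[[l]]$W[cbind(w$row, w$col)] <- w$value
    b <- rows[rows$layer == l & rows$kind == "b", ]
    theta$layers[[l]]$b[b$row] <- b$value
  }
  theta
}
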