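# Internal helpers: unit conversions, numerically safe activations, seeded RNG.
# Internal units are SI (m, s) with concentrations in g/L and modifier in %B;
# configuration accepts cm/h and CV as printed on instrument methods.

#' Convert a superficial velocity from cm/h to m/s
#' @param x velocity in cm/h
#' @return velocity in m/s
#' @export
cmh_to_ms <- function(x) x / 360000

#' Convert a superficial velocity from m/s to cm/h
#' @param x velocity in m/s
#' @return velocity in cm/h
#' @export
ms_to_cmh <- function(x) x * 360000

# softplus with overflow guard: log(1+exp(x)) -> x for large x
softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))

# d/dx softplus = logistic
softplus_prime <- function(x) stats::plogis(x)

# inverse softplus; softplus_inv(1) = log(e - 1)
softplus_inv <- function(y) ifelse(y > 30, y, log(expm1(y)))

relu <- function(x) pmax(x, 0)

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# weights of the average of the piecewise-linear interpolant over [ta, tb],
# as a row vector over the knot values at `times` (strictly increasing).
pwlinear_average_weights <- function(times, ta, tb) {
  n <- length(times)
  if (ta < times[1] - 1e-9 || tb > times[n] + 1e-9 || tb <= ta)
    stopf("averaging window [%g, %g] outside trajectory span [%g, %g]",
          ta, tb, times[1], times[n])
  ta <- max(ta, times[1]); tb <- min(tb, times[n])
  w <- numeric(n)
  # integrate the hat-function basis over [ta, tb] segment by segment
  for (k in seq_len(n - 1)) {
    t0 <- times[k]; t1 <- times[k + 1]
    lo <- max(t0, ta); hi <- min(t1, tb)
    if (hi <= lo) next
    dt <- t1 - t0
    # on [t0,t1]: c(t) = c_k (t1-t)/dt + c_{k+1} (t-t0)/dt
    # integral of each basis over [lo,hi]
    w[k]     <- w[k]     + ((t1 - lo)^2 - (t1 - hi)^2) / (2 * dt)
    w[k + 1] <- w[k + 1] + ((hi - t0)^2 - (lo - t0)^2) / (2 * dt)
  }
  w / (tb - ta)
}

# linear-interpolation weight matrix: rows map knot values -> values at `at`
pwlinear_interp_weights <- function(times, at) {
  n <- length(times)
  W <- matrix(0, length(at), n)
  if (n == 1L) {
    if (any(abs(at - times) > 1e-9))
      stopf("requested time outside trajectory span")
    W[, 1] <- 1
    return(W)
  }
  for (i in seq_along(at)) {
    t <- at[i]
    if (t < times[1] - 1e-9 || t > times[n] + 1e-9)
      stopf("requested time %g outside trajectory span [%g, %g]",
            t, times[1], times[n])
    t <- min(max(t, times[1]), times[n])
    k <- findInterval(t, times, rightmost.closed = TRUE)
    k <- min(max(k, 1L), n - 1L)
    a <- (t - times[k]) / (times[k + 1] - times[k])
    W[i, k] <- 1 - a
    W[i, k + 1] <- a
  }
  W
}
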