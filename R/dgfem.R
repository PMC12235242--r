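# Nodal discontinuous Galerkin discretization of the 1-D column.
#
# Each of the K uniform elements carries a degree-np Lagrange basis on
# Legendre-Gauss-Lobatto (LGL) nodes. Convection uses an upwind numerical
# flux; diffusion uses a local-DG first-order system with central fluxes.
# The Danckwerts (Robin) inlet and Neumann outlet conditions enter weakly
# through the boundary fluxes. z = 0 is the inlet, z = L the outlet.

# Legendre polynomial P_n and derivative at x (recurrence); n >= 0
legendre_eval <- function(n, x) {
  p0 <- rep(1, length(x))
  if (n == 0) return(list(p = p0, dp = rep(0, length(x))))
  p1 <- x
  if (n >= 2) {
    for (k in 2:n) {
      p2 <- ((2 * k - 1) * x * p1 - (k - 1) * p0) / k
      p0 <- p1
      p1 <- p2
    }
  }
  # derivative from P_n, P_{n-1}: (x^2-1)/n P_n' = x P_n - P_{n-1}
  dp <- ifelse(abs(x) < 1 - 1e-14,
               n * (x * p1 - p0) / (x^2 - 1),
               # endpoint limit: P_n'(+-1) = (+-1)^(n-1) n(n+1)/2
               sign(x)^(n - 1) * n * (n + 1) / 2)
  list(p = p1, dp = dp)
}

# LGL nodes on [-1, 1]: roots of (1-x^2) P'_np(x), by Newton iteration from
# Chebyshev-Lobatto starting values
lgl_nodes <- function(np) {
  if (np == 1) return(c(-1, 1))
  x <- -cos(pi * (0:np) / np)
  for (it in 1:100) {
    # q(x) = (1-x^2) P'_np(x); interior roots only
    xi <- x[2:np]
    le <- legendre_eval(np, xi)
    # q'(x) = -np(np+1) P_np(x)  (Legendre ODE)
    dx <- (1 - xi^2) * le$dp / (np * (np + 1) * le$p)
    xi <- xi + dx
    x[2:np] <- xi
    if (max(abs(dx)) < 1e-15) break
  }
  x
}

# orthonormal Legendre Vandermonde and its derivative on nodes x
legendre_vandermonde <- function(np, x) {
  V <- matrix(0, length(x), np + 1)
  Vr <- matrix(0, length(x), np + 1)
  for (j in 0:np) {
    le <- legendre_eval(j, x)
    nrm <- sqrt((2 * j + 1) / 2)
    V[, j + 1] <- le$p * nrm
    Vr[, j + 1] <- le$dp * nrm
  }
  list(V = V, Vr = Vr)
}

#' Build a discontinuous Galerkin mesh of the column
#'
#' Partitions `[0, L]` into `K` uniform elements, each carrying a nodal
#' Lagrange basis of degree `np` on Legendre-Gauss-Lobatto points, and
#' precomputes the reference differentiation matrix, inverse mass matrix and
#' node coordinates. Differentiation is exact for polynomials up to degree
#' `np` within each element.
#'
#' @param K number of elements (>= 1)
#' @param np polynomial order per element (>= 1)
#' @param L column length (m)
#' @return an object of class `dg_mesh`
#' @export
build_mesh <- function(K, np, L) {
  stopifnot(K >= 1, np >= 1, L > 0)
  r <- lgl_nodes(np)                      # reference nodes on [-1, 1]
  vd <- legendre_vandermonde(np, r)
  Dr <- vd$Vr %*% solve(vd$V)             # reference differentiation matrix
  Minv_ref <- vd$V %*% t(vd$V)            # inverse reference mass matrix
  h <- L / K
  J <- h / 2                              # affine map Jacobian
  nodes <- as.vector(vapply(seq_len(K), function(k) {
    (k - 1) * h + (r + 1) * J
  }, numeric(np + 1)))
  structure(
    list(K = K, np = np, L = L, n_per = np + 1L, n_nodes = K * (np + 1L),
         r = r, Dr = Dr, Minv = Minv_ref / J, rx = 1 / J, nodes = nodes),
    class = "dg_mesh")
}

#' @export
print.dg_mesh <- function(x, ...) {
  cat(sprintf("<dg_mesh> K = %d elements, order np = %d, %d nodes on [0, %g m]\n",
              x$K, x$np, x$n_nodes, x$L))
  invisible(x)
}

# apply the nodal derivative d/dz element-wise (exact to degree np)
mesh_derivative <- function(mesh, field) {
  F <- matrix(field, mesh$n_per, mesh$K)
  as.vector(mesh$rx * (mesh$Dr %*% F))
}

# DG gradient with central interface fluxes; boundary closures use the
# interior trace (suitable for the LDG auxiliary variable)
dg_gradient <- function(mesh, c) {
  npn <- mesh$n_per; K <- mesh$K
  Cm <- matrix(c, npn, K)
  s <- mesh$rx * (mesh$Dr %*% Cm)
  # interface values: right trace of element k is Cm[npn,k], left trace of
  # element k+1 is Cm[1,k+1]; central flux = mean
  if (K > 1) {
    cr <- Cm[npn, 1:(K - 1)]        # minus side of interior faces
    cl <- Cm[1, 2:K]                # plus side
    chat <- (cr + cl) / 2
    # right face of element k: n = +1, correction Minv e_np (chat - c-)
    s[, 1:(K - 1)] <- s[, 1:(K - 1)] +
      outer(mesh$Minv[, npn], (chat - cr))
    # left face of element k+1: n = -1
    s[, 2:K] <- s[, 2:K] - outer(mesh$Minv[, 1], (chat - cl))
  }
  # domain boundary faces: chat = interior trace -> zero correction
  as.vector(s)
}

# semi-discrete convection-diffusion operator with Danckwerts inlet / Neumann
# outlet, as an affine map rhs = A %*% c + g * c_in. v = interstitial
# velocity (m/s), D = apparent dispersion (m^2/s). Returns dc/dt nodal vector.
dg_transport_apply <- function(mesh, c, v, D, c_in) {
  npn <- mesh$n_per; K <- mesh$K
  s <- if (D > 0) dg_gradient(mesh, c) else numeric(mesh$n_nodes)
  Fm <- matrix(v * c - D * s, npn, K)
  Cm <- matrix(c, npn, K)
  Sm <- matrix(s, npn, K)
  rhs <- -mesh$rx * (mesh$Dr %*% Fm)
  if (K > 1) {
    # interior faces: upwind convection (v > 0 -> left/minus trace),
    # central diffusion
    fr <- v * Cm[npn, 1:(K - 1)] - D * (Sm[npn, 1:(K - 1)] + Sm[1, 2:K]) / 2
    # right face of element k (n = +1): + Minv e (F- - Fhat)
    rhs[, 1:(K - 1)] <- rhs[, 1:(K - 1)] +
      outer(mesh$Minv[, npn], (Fm[npn, 1:(K - 1)] - fr))
    # left face of element k+1 (n = -1): - Minv e (F- - Fhat)
    rhs[, 2:K] <- rhs[, 2:K] - outer(mesh$Minv[, 1], (Fm[1, 2:K] - fr))
  }
  # inlet face (n = -1): Danckwerts total flux Fhat = v * c_in
  rhs[, 1] <- rhs[, 1] - mesh$Minv[, 1] * (Fm[1, 1] - v * c_in)
  # outlet face (n = +1): Neumann, Fhat = v c- (zero dispersive flux)
  rhs[, K] <- rhs[, K] + mesh$Minv[, npn] * (Fm[npn, K] - v * Cm[npn, K])
  as.vector(rhs)
}

#' Semi-discrete convection-diffusion right-hand side
#'
#' Applies the DG transport operator `-(u/eps_t) d/dz + Dapp d2/dz2` to a
#' nodal field, with the Danckwerts (Robin) inlet condition and Neumann
#' outlet condition imposed weakly through the boundary fluxes.
#'
#' @param mesh a [build_mesh()] object
#' @param field nodal vector of length `mesh$n_nodes`
#' @param u superficial velocity (m/s)
#' @param Dapp apparent dispersion coefficient (m^2/s)
#' @param eps_t total porosity
#' @param inlet_value inlet concentration entering the Danckwerts flux
#' @return nodal vector of time derivatives
#' @export
dg_convection_diffusion <- function(mesh, field, u, Dapp, eps_t, inlet_value) {
  if (length(field) != mesh$n_nodes)
    stopf("field length %d does not match mesh (%d nodes)",
          length(field), mesh$n_nodes)
  dg_transport_apply(mesh, field, u / eps_t, Dapp, inlet_value)
}

# materialize the affine transport operator: list(A = n x n matrix,
# g = inlet weight vector) with rhs = A c + g * c_in
dg_transport_operator <- function(mesh, v, D) {
  n <- mesh$n_nodes
  A <- matrix(0, n, n)
  z <- numeric(n)
  for (j in seq_len(n)) {
    e <- z; e[j] <- 1
    A[, j] <- dg_transport_apply(mesh, e, v, D, 0)
  }
  g <- dg_transport_apply(mesh, z, v, D, 1)
  list(A = A, g = g)
}
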