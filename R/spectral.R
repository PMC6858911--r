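#' Evaluate a Legendre polynomial by Bonnet's recursion
#'
#' Three-term recursion `(j+1) L_{j+1}(x) = (2j+1) x L_j(x) - j L_{j-1}(x)`
#' with `L_0 = 1`, `L_1 = x`.
#'
#' @param j Degree (single non-negative integer).
#' @param x Numeric vector of points in `[-1, 1]` (the recursion itself is
#'   valid for any real `x`).
#' @return Numeric vector `L_j(x)`.
#' @export
legendre_eval <- function(j, x) {
  stopifnot(length(j) == 1L, j >= 0, j == as.integer(j))
  if (j == 0L) return(rep(1, length(x)))
  if (j == 1L) return(as.numeric(x))
  Lm1 <- rep(1, length(x)); L <- as.numeric(x)
  for (k in 1:(j - 1)) {
    Lp1 <- ((2 * k + 1) * x * L - k * Lm1) / (k + 1)
    Lm1 <- L; L <- Lp1
  }
  L
}

# All degrees 0..(N-1) at once: length(x) x N matrix.
legendre_matrix <- function(N, x) {
  V <- matrix(0, length(x), N)
  V[, 1] <- 1
  if (N >= 2) V[, 2] <- x
  if (N >= 3) for (k in 1:(N - 2))
    V[, k + 2] <- ((2 * k + 1) * x * V[, k + 1] - k * V[, k]) / (k + 1)
  V
}

#' Legendre derivative expansion matrix
#'
#' Row `j` (0-based degree) holds the coefficients of `L_j'` expanded in the
#' Legendre basis: for even `j = 2m`, `L_j' = sum_{v=0}^{m-1} (4v+3)
#' L_{2v+1}`; for odd `j = 2m+1`, `L_j' = sum_{v=0}^{m} (4v+1) L_{2v}`.  The
#' matrix is strictly lower triangular in degree.
#'
#' @param N Number of degrees (rows/columns), degrees `0..N-1`.
#' @return An `N x N` matrix `D` with `L_j' = sum_k D[j+1, k+1] L_k`.
#' @export
legendre_deriv_matrix <- function(N) {
  stopifnot(N >= 1)
  D <- matrix(0, N, N)
  for (j in seq_len(N) - 1L) {
    if (j == 0L) next
    if (j %% 2L == 0L) {
      v <- 0:(j %/% 2L - 1L)
      D[j + 1L, 2L * v + 2L] <- 4 * v + 3   # odd degrees 2v+1
    } else {
      v <- 0:((j - 1L) %/% 2L)
      D[j + 1L, 2L * v + 1L] <- 4 * v + 1   # even degrees 2v
    }
  }
  D
}

#' Shifted-Legendre basis on the normalized maturity interval
#'
#' Basis functions `e_j(xi) = L_j(2 xi - 1) / sqrt(w)` on `[0, 1]`,
#' orthogonal in the weighted inner product `<f, g>_w = w int_0^1 f g dxi`
#' with `||e_j||_w^2 = 1/(2j+1)`.  The record carries the boundary
#' evaluations `e_j(0) = (-1)^j / sqrt(w)`, `e_j(1) = 1 / sqrt(w)`, and the
#' derivative expansion `d/dxi e_j = sum_k Dxi[j+1, k+1] e_k`.
#'
#' @param N Basis size (degrees `0..N-1`), default 15.
#' @param width Width `w` of the physical maturity interval (days).
#' @return An object of class `"legendre_basis"`.
#' @export
spectral_basis <- function(N = 15, width) {
  stopifnot(N >= 1, width > 0)
  j <- seq_len(N) - 1L
  structure(
    list(N = N, w = width, degrees = j,
         norm2 = 1 / (2 * j + 1),
         e0 = (-1)^j / sqrt(width),
         e1 = rep(1 / sqrt(width), N),
         Dxi = 2 * legendre_deriv_matrix(N)),
    class = "legendre_basis"
  )
}

#' Discrete delta representer at the inflow boundary
#'
#' The unique element `delta_N` of the span with `<delta_N, phi>_w = phi(0)`
#' for every `phi` in the span: coefficient vector `e_j(0) / ||e_j||_w^2`.
#' It carries the boundary influx into the Galerkin ODE system.
#'
#' @param basis A [spectral_basis()] object.
#' @return Numeric coefficient vector of length `N`.
#' @export
delta_representer <- function(basis) basis$e0 / basis$norm2

# Gauss-Legendre nodes/weights on [a, b] (pracma does the Golub-Welsch work).
gauss_rule <- function(n, a, b) {
  g <- pracma::gaussLegendre(n, a, b)
  list(x = g$x, w = g$w)
}

#' Galerkin projection of a function onto the basis span
#'
#' Coefficients `<f, e_j>_w / ||e_j||_w^2` computed with composite
#' Gauss-Legendre quadrature on `[0, 1]`, subdivided at any supplied
#' discontinuity locations so each panel integrates a smooth function; the
#' rule order makes polynomial integrands up to degree `2N` exact.
#'
#' @param f Function of the normalized maturity `xi` in `[0, 1]`,
#'   vectorized.
#' @param basis A [spectral_basis()] object.
#' @param breaks Optional interior break points in `(0, 1)` where `f` is
#'   not smooth (e.g. an indicator edge).
#' @return Numeric coefficient vector of length `N`.
#' @export
project_fn <- function(f, basis, breaks = NULL) {
  N <- basis$N
  edges <- sort(unique(c(0, breaks[breaks > 0 & breaks < 1], 1)))
  nq <- max(N + 2, 24)
  co <- numeric(N)
  for (k in seq_len(length(edges) - 1)) {
    g <- gauss_rule(nq, edges[k], edges[k + 1])
    fv <- f(g$x)
    if (length(fv) != length(g$x)) stop("'f' must be vectorized", call. = FALSE)
    if (any(!is.finite(fv))) stop("quadrature failure: non-finite integrand",
                                  call. = FALSE)
    V <- legendre_matrix(N, 2 * g$x - 1)        # L_j at the nodes
    co <- co + drop(crossprod(V, g$w * fv))
  }
  # <f,e_j>_w = sqrt(w) * int f L_j ; divide by ||e_j||^2 = 1/(2j+1)
  co * sqrt(basis$w) / basis$norm2
}

#' Reconstruct a density from its Galerkin coefficients
#'
#' @param coef Coefficient vector (length `N`).
#' @param basis A [spectral_basis()] object.
#' @param xi Normalized maturities in `[0, 1]`.
#' @return Numeric vector of density values.
#' @export
reconstruct_density <- function(coef, basis, xi) {
  V <- legendre_matrix(basis$N, 2 * xi - 1)
  drop(V %*% coef) / sqrt(basis$w)
}

# Projection matrix of the neocytolysis indicator window against the basis:
# entries (2i+1) * int_{xihat} L_i L_j dxi over the window in xi coordinates.
neo_window_matrix <- function(basis, xi_lo, xi_hi) {
  N <- basis$N
  if (xi_hi <= xi_lo) return(matrix(0, N, N))
  g <- gauss_rule(2 * N, max(0, xi_lo), min(1, xi_hi))
  V <- legendre_matrix(N, 2 * g$x - 1)
  M <- crossprod(V, g$w * V)            # int L_i L_j over the window
  M * (2 * (seq_len(N) - 1) + 1)        # scale rows by 1/||e_i||^2 (w cancels)
}

#' Assemble the Galerkin operator matrix for one cell class
#'
#' Matrix of the approximating operator `A_N(E) phi = -(v(E)/w) phi' +
#' P_N(kappa(h(.); E) phi) - delta_N phi(0)` in the shifted-Legendre basis,
#' together with the influx representer `d`.  For classes 1-4 the reaction
#' coefficient is constant in maturity so the projection term is
#' `kappa(E) I`; for the erythrocyte class the age-windowed neocytolysis
#' term is assembled from the window projection matrix (exact quadrature,
#' split at the window edge).
#'
#' @param i Class index 1..5.
#' @param E EPO concentration (single value, U/l).
#' @param p Patient parameter record.
#' @param basis A [spectral_basis()] whose width matches class `i`; if
#'   missing it is built with `N = 15`.
#' @param N Basis size used when `basis` is missing.
#' @return List with `A` (N x N), `d` (influx vector), `basis`.
#' @export
assemble_operator <- function(i, E, p, basis = NULL, N = 15) {
  if (!i %in% 1:5) stop("invalid class index", call. = FALSE)
  geom <- class_geometry(p)
  w <- geom$width[i]
  if (is.null(basis)) basis <- spectral_basis(N, w)
  stopifnot(abs(basis$w - w) < 1e-12)
  d <- delta_representer(basis)
  v <- velocity(i, E, p)
  A <- -(v / w) * t(basis$Dxi) - outer(d, basis$e0)
  if (i == 5L) {
    diag(A) <- diag(A) - p$alpha5_0
    m <- neo_excess(E, p)
    if (m > 0) {
      Mw <- neo_window_matrix(basis, p$neo_window[1] / w, p$neo_window[2] / w)
      A <- A - m * Mw
    }
  } else {
    kap <- switch(i, p$beta1, p$beta2 - alpha2(E, p), p$beta3, -p$alpha4)
    diag(A) <- diag(A) + kap
  }
  list(A = A, d = d, basis = basis)
}

#' Steady state of one class under fixed EPO and influx
#'
#' Solves the time-invariant Galerkin system `0 = A(E) y + g d` for the
#' equilibrium coefficient vector of a single class.
#'
#' @inheritParams assemble_operator
#' @param g Constant boundary influx for this class.
#' @return Coefficient vector of length `N`.
#' @export
steady_state_class <- function(i, E, g, p, basis = NULL, N = 15) {
  op <- assemble_operator(i, E, p, basis, N)
  out <- try(solve(op$A, -g * op$d), silent = TRUE)
  if (inherits(out, "try-error"))
    stop("singular steady-state system for class ", i, call. = FALSE)
  out
}

#' Uncontrolled (fixed-EPO) equilibrium of the full five-class system
#'
#' Chains the per-class steady states 1 -> 5, passing each class's upper
#' boundary density through [boundary_influx()].  Used as the initial
#' condition of simulations and as the calibration probe.
#'
#' @param p Patient parameter record.
#' @param E Fixed EPO concentration (U/l); defaults to the endogenous level.
#' @param N Basis size.
#' @return List with `coef` (N x 5 coefficient matrix, cell counts scaled by
#'   10^8), `P` (total RBC count, cells), `hgb` (g/dl), `E`.
#' @export
steady_state <- function(p, E = p$E_end, N = 15) {
  geom <- class_geometry(p)
  coef <- matrix(0, N, 5)
  upstream <- NA_real_
  for (i in 1:5) {
    b <- spectral_basis(N, geom$width[i])
    g <- boundary_influx(i, upstream, E, p)
    coef[, i] <- steady_state_class(i, E, g, p, b)
    upstream <- sum(coef[, i] * b$e1)   # density at the class's upper bound
  }
  P <- total_population(coef[, 5], geom$width[5])
  list(coef = coef, P = P, hgb = hgb(P, p$c_tbv, p$MCH), E = E)
}

#' Total RBC population from erythrocyte-class coefficients
#'
#' Only the degree-0 basis function has non-zero integral, so the population
#' is `sqrt(w5)` times the first coefficient (times the internal 10^8 cell
#' scaling).
#'
#' @param coef5 Erythrocyte-class coefficient vector (10^8-cell scaling).
#' @param w5 Erythrocyte maturity width = RBC lifespan (days).
#' @return Total RBC count in cells.
#' @export
total_population <- function(coef5, w5) {
  if (is.matrix(coef5)) coef5 <- coef5[, 5]
  1e8 * sqrt(w5) * coef5[1]
}
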