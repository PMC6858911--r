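#' Twice continuously differentiable regularized Heaviside function
#'
#' A piecewise-polynomial smoothing of the Heaviside step: exactly 0 for
#' `s <= 0`, exactly 1 for `s >= eps`, and the sixth-degree polynomial
#' `s^4/eps^6 * (10 s^2 - 24 eps s + 15 eps^2)` in between.  The first and
#' second derivatives vanish at both joins, so the function is C^2 on the
#' whole real line.
#'
#' @param s Numeric vector of evaluation points.
#' @param eps Regularization width (a single positive number).
#' @return Numeric vector of values in `[0, 1]`.
#' @seealso [smooth_min()], [alpha5_reg()]
#' @export
heaviside_reg <- function(s, eps) {
  stopifnot(is.numeric(s), length(eps) == 1L, is.finite(eps))
  if (eps <= 0) stop("'eps' must be > 0", call. = FALSE)
  out <- numeric(length(s))
  out[s >= eps] <- 1
  mid <- s > 0 & s < eps
  if (any(mid)) {
    sm <- s[mid]
    out[mid] <- sm^4 / eps^6 * (10 * sm^2 - 24 * eps * sm + 15 * eps^2)
  }
  out
}

#' Derivative of the regularized Heaviside function
#'
#' Equals `60 s^3 (s - eps)^2 / eps^6` on `(0, eps)` and 0 elsewhere.
#'
#' @inheritParams heaviside_reg
#' @return Numeric vector.
#' @keywords internal
heaviside_reg_d <- function(s, eps) {
  out <- numeric(length(s))
  mid <- s > 0 & s < eps
  if (any(mid)) {
    sm <- s[mid]
    out[mid] <- 60 * sm^3 * (sm - eps)^2 / eps^6
  }
  out
}

#' Smooth approximation of min(s, tau)
#'
#' `F_eps(s, tau) = (s - tau) * H_eps(tau - s) + tau`, built on the
#' regularized Heaviside [heaviside_reg()].  Exactly equals `min(s, tau)`
#' outside the transition band `tau - eps < s < tau`.
#'
#' @param s Numeric vector.
#' @param tau Threshold (single number).
#' @param eps Regularization width (> 0).
#' @return Numeric vector.
#' @export
smooth_min <- function(s, tau, eps) {
  stopifnot(length(tau) == 1L)
  (s - tau) * heaviside_reg(tau - s, eps) + tau
}

#' Partial derivative of [smooth_min()] with respect to s
#' @inheritParams smooth_min
#' @keywords internal
smooth_min_ds <- function(s, tau, eps) {
  heaviside_reg(tau - s, eps) - (s - tau) * heaviside_reg_d(tau - s, eps)
}

#' EPO-dependent CFU-E apoptosis rate
#'
#' Decreasing sigmoid `alpha2(E) = mu1 / (1 + exp(mu2 * E - mu3))`: high EPO
#' suppresses apoptosis of CFU-E progenitors.  Takes the value `mu1 / 2` at
#' the midpoint `E = mu3 / mu2` and tends to 0 as `E -> Inf`.
#'
#' @param E Plasma EPO concentration (U/l model units), numeric vector.
#' @param p A patient parameter record, see [patient_params()].
#' @return Apoptosis rate in 1/day.
#' @export
alpha2 <- function(E, p) {
  mu <- p$mu
  mu[1] / (1 + exp(mu[2] * E - mu[3]))
}

#' @rdname alpha2
#' @details `alpha2_d()` is the derivative with respect to `E`.
#' @keywords internal
alpha2_d <- function(E, p) {
  mu <- p$mu
  z <- exp(mu[2] * E - mu[3])
  -mu[1] * mu[2] * z / (1 + z)^2
}

#' EPO-dependent maturation velocity of marrow reticulocytes
#'
#' Increasing sigmoid `nu(E) = (mu4 - mu5) / (1 + exp(-mu6 * E + mu7)) + mu5`,
#' bounded between the baseline velocity `mu5` and the maximal velocity
#' `mu4` (requires `mu4 > mu5`): high EPO accelerates the release of
#' reticulocytes from the marrow into circulation.
#'
#' @inheritParams alpha2
#' @return Maturation velocity (maturity-days per day), always positive.
#' @export
nu_rate <- function(E, p) {
  mu <- p$mu
  (mu[4] - mu[5]) / (1 + exp(-mu[6] * E + mu[7])) + mu[5]
}

#' @rdname nu_rate
#' @keywords internal
nu_rate_d <- function(E, p) {
  mu <- p$mu
  z <- exp(-mu[6] * E + mu[7])
  (mu[4] - mu[5]) * mu[6] * z / (1 + z)^2
}

#' Neocytolysis excess mortality (regularized)
#'
#' The smooth excess mortality applied to young erythrocytes when EPO falls
#' below the neocytolysis threshold `tau_E`:
#' `m(E) = H_eps(tau_E - E) * F_epsR(mu8 / E^mu9, mu10)`.
#' It vanishes identically for `E >= tau_E` and approaches
#' `min(mu8 / E^mu9, mu10)` away from the regularization bands; the
#' threshold factor uses the E-scale width `epsilon`, the smooth min the
#' rate-scale width `epsilon_R`.  `mu8 / E^mu9` is evaluated in log-space
#' so small `E` with large `mu9` cannot overflow.
#'
#' @inheritParams alpha2
#' @return Excess mortality rate (1/day), >= 0.
#' @keywords internal
neo_excess <- function(E, p) {
  mu <- p$mu
  q <- exp(log(mu[8]) - mu[9] * log(E))
  heaviside_reg(p$tau_E - E, p$epsilon) * smooth_min(q, mu[10], p$epsilon_R)
}

#' @rdname neo_excess
#' @keywords internal
neo_excess_d <- function(E, p) {
  mu <- p$mu
  q <- exp(log(mu[8]) - mu[9] * log(E))
  dq <- -mu[9] * q / E
  H <- heaviside_reg(p$tau_E - E, p$epsilon)
  dH <- -heaviside_reg_d(p$tau_E - E, p$epsilon)
  Fv <- smooth_min(q, mu[10], p$epsilon_R)
  dF <- smooth_min_ds(q, mu[10], p$epsilon_R) * dq
  dH * Fv + H * dF
}

#' Regularized erythrocyte mortality rate
#'
#' `alpha5_reg(x, E) = alpha5_0 + chi_[neo_window](x) * m(E)` where `m` is the
#' regularized neocytolysis excess [neo_excess()].  Outside the neocytolysis
#' age window, or whenever `E >= tau_E`, the rate equals the baseline
#' mortality `alpha5_0`.
#'
#' @param x Erythrocyte age in days (vector), within `[0, rbc_lifespan]`.
#' @inheritParams alpha2
#' @return Mortality rate in 1/day.
#' @export
alpha5_reg <- function(x, E, p) {
  stopifnot(length(E) == 1L)
  inwin <- x >= p$neo_window[1] & x <= p$neo_window[2]
  p$alpha5_0 + as.numeric(inwin) * neo_excess(E, p)
}

#' Reaction coefficient kappa_i(x; E) = beta_i - alpha_i
#'
#' Class-wise net proliferation-minus-death coefficient of the transport
#' equations: `beta1` (BFU-E), `beta2 - alpha2(E)` (CFU-E), `beta3`
#' (erythroblasts), `-alpha4` (marrow reticulocytes) and `-alpha5_reg(x; E)`
#' (erythrocytes; the only age-dependent one).
#'
#' @param i Class index 1..5.
#' @param x Maturity (days), used only for class 5.
#' @inheritParams alpha2
#' @return Numeric vector of rates (1/day).
#' @export
kappa_rate <- function(i, x, E, p) {
  switch(i,
    rep(p$beta1, length(x)),
    rep(p$beta2 - alpha2(E, p), length(x)),
    rep(p$beta3, length(x)),
    rep(-p$alpha4, length(x)),
    -alpha5_reg(x, E, p)
  )
}

#' Maturation velocity v_i(E)
#'
#' Equals [nu_rate()] for the marrow reticulocyte class (i = 4) and 1
#' (one maturity-day per day) for all other classes.
#'
#' @inheritParams kappa_rate
#' @return Positive scalar velocity.
#' @export
velocity <- function(i, E, p) {
  if (i == 4L) nu_rate(E, p) else 1
}

#' Boundary influx g_i into class i
#'
#' The flux entering class `i` at its lower maturity bound: the committed
#' stem-cell influx `S0` for class 1; the upstream boundary density for
#' classes 2 and 3; the upstream density divided by the maturation velocity
#' `nu(E)` for class 4 (cells slow down or speed up on entry); and
#' `nu(E)` times the upstream density for class 5 (release into blood).
#'
#' @param i Class index 1..5.
#' @param upstream_value Boundary density `y_{i-1}(t, xbar_{i-1})` (ignored
#'   for `i = 1`).
#' @inheritParams alpha2
#' @return Influx (cells x 10^8 per day per maturity-day).
#' @export
boundary_influx <- function(i, upstream_value, E, p) {
  if (!i %in% 1:5) stop("class index must be in 1..5", call. = FALSE)
  if (i == 1L) return(p$S0)
  if (i == 4L) {
    nv <- nu_rate(E, p)
    if (nv <= 0) stop("maturation velocity must be positive", call. = FALSE)
    return(upstream_value / nv)
  }
  if (i == 5L) return(nu_rate(E, p) * upstream_value)
  upstream_value
}
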