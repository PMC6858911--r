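#' Piecewise-constant EPO administration schedule
#'
#' A schedule of non-negative EPO rates (U/day), each held constant over an
#' interval of length `period` days.  Interval `j` is the half-open
#' `[t0 + (j-1) * period, t0 + j * period)`.
#'
#' @param rates Numeric vector of administration rates (U/day).
#' @param period Length of each constant-rate interval in days (> 0).
#' @param t0 Start time of the schedule (days), default 0.
#' @param u_max Upper box bound on the rates (U/day), default 1000.
#' @return An object of class `"epo_schedule"`: list with `rates`,
#'   `breaks` (the `length(rates) + 1` interval boundaries), `period`,
#'   `u_max`.
#' @examples
#' sch <- control_schedule(rep(500, 28), period = 1)
#' @export
control_schedule <- function(rates, period, t0 = 0, u_max = 1000) {
  stopifnot(is.numeric(rates), length(rates) >= 1L, period > 0, u_max > 0)
  if (any(!is.finite(rates))) stop("rates must be finite", call. = FALSE)
  if (any(rates < -1e-12) || any(rates > u_max + 1e-9))
    stop("rates must lie in [0, u_max]", call. = FALSE)
  structure(
    list(rates = pmin(pmax(rates, 0), u_max),
         breaks = t0 + period * (0:length(rates)),
         period = period, u_max = u_max),
    class = "epo_schedule"
  )
}

#' @export
print.epo_schedule <- function(x, ...) {
  cat(sprintf("<epo_schedule> %d intervals of %g d on [%g, %g], u_max = %g U/day\n",
              length(x$rates), x$period, x$breaks[1],
              x$breaks[length(x$breaks)], x$u_max))
  invisible(x)
}

#' EPO plasma distribution volume (liters)
#'
#' EPO concentrations are carried in U/l, so the single-compartment
#' elimination model uses the blood volume in liters.
#'
#' @param p Patient parameter record.
#' @return Volume in liters.
#' @keywords internal
epo_volume <- function(p) p$c_tbv / 1000

#' Plasma EPO concentration under a piecewise-constant rate schedule
#'
#' Closed-form solution of the one-compartment elimination model
#' `dE_ex/dt = u(t)/V - lambda * E_ex`, `E_ex(t0) = E_ex0`, added to the
#' constant endogenous level: `E(t) = E_end + exp(-lambda (t - t0)) E_ex0 +`
#' convolution of the piecewise-constant rates with the exponential kernel.
#' `lambda = log(2) / T_half` is the degradation rate and `V` the
#' distribution volume in liters.  All exponentials are arranged with
#' non-positive arguments, so the evaluation is stable for arbitrarily long
#' horizons.
#'
#' @param t Numeric vector of evaluation times (days), inside the schedule
#'   span `[breaks[1], breaks[n_u + 1]]`.
#' @param schedule An [control_schedule()] object.
#' @param p Patient parameter record ([patient_params()]).
#' @param Eex0 Exogenous EPO concentration at the schedule start (U/l);
#'   defaults to the patient's `E_ex0`.
#' @return Numeric vector `E(t)` in U/l; always `>= E_end`.
#' @export
epo_concentration <- function(t, schedule, p, Eex0 = p$E_ex0) {
  br <- schedule$breaks
  n_u <- length(schedule$rates)
  if (any(t < br[1] - 1e-9) || any(t > br[n_u + 1] + 1e-9))
    stop("evaluation time outside the schedule span", call. = FALSE)
  lam <- p$lambda
  vol <- epo_volume(p)
  s <- t - br[1]
  sb <- br - br[1]
  j <- pmin(pmax(findInterval(t, br, rightmost.closed = TRUE), 1L), n_u)
  Eex <- exp(-lam * s) * Eex0
  # cumulative contribution of completed intervals 1..j-1, plus the running one
  for (i in seq_len(n_u)) {
    ui <- schedule$rates[i]
    if (ui == 0) next
    done <- j > i
    run  <- j == i
    if (any(done)) {
      sd <- s[done]
      Eex[done] <- Eex[done] +
        ui / (vol * lam) * (exp(-lam * (sd - sb[i + 1])) - exp(-lam * (sd - sb[i])))
    }
    if (any(run)) {
      sr <- s[run]
      Eex[run] <- Eex[run] + ui / (vol * lam) * (1 - exp(-lam * (sr - sb[i])))
    }
  }
  p$E_end + Eex
}

#' Sensitivity of the EPO concentration to the administration rates
#'
#' The gradient of `E(t; u)` with respect to the rate vector is independent
#' of `u` (the exogenous kinetics are linear in the rates; the Hessian is
#' zero).  Component `l` is `(exp(-lambda (t - t_{l+1})) -
#' exp(-lambda (t - t_l))) / (V lambda)` for completed intervals `l < j(t)`,
#' `(1 - exp(-lambda (t - t_j))) / (V lambda)` for the running interval, and
#' 0 for intervals after the one containing `t`.
#'
#' @inheritParams epo_concentration
#' @return If `t` has length 1, a numeric vector of length `n_u`; otherwise
#'   a `length(t) x n_u` matrix with one row per time.
#' @export
epo_gradient <- function(t, schedule, p) {
  br <- schedule$breaks
  n_u <- length(schedule$rates)
  if (any(t < br[1] - 1e-9) || any(t > br[n_u + 1] + 1e-9))
    stop("evaluation time outside the schedule span", call. = FALSE)
  lam <- p$lambda
  vol <- epo_volume(p)
  s <- t - br[1]
  sb <- br - br[1]
  j <- pmin(pmax(findInterval(t, br, rightmost.closed = TRUE), 1L), n_u)
  G <- matrix(0, length(t), n_u)
  for (i in seq_len(n_u)) {
    done <- j > i
    run  <- j == i
    if (any(done)) {
      sd <- s[done]
      G[done, i] <- (exp(-lam * (sd - sb[i + 1])) - exp(-lam * (sd - sb[i]))) /
        (vol * lam)
    }
    if (any(run)) {
      sr <- s[run]
      G[run, i] <- (1 - exp(-lam * (sr - sb[i]))) / (vol * lam)
    }
  }
  if (length(t) == 1L) drop(G) else G
}

#' Advance the exogenous EPO level over one constant-rate interval
#'
#' Exact one-step update `E_ex(t + tau) = exp(-lambda tau) E_ex(t) +
#' u (1 - exp(-lambda tau)) / (V lambda)`; used by the closed-loop plant so
#' arbitrarily long runs never evaluate large exponentials.
#'
#' @param Eex Exogenous concentration at interval start (U/l).
#' @param rate Constant administration rate over the interval (U/day).
#' @param tau Interval length (days).
#' @param p Patient parameter record.
#' @return Exogenous concentration at interval end (U/l).
#' @keywords internal
epo_advance <- function(Eex, rate, tau, p) {
  lam <- p$lambda
  exp(-lam * tau) * Eex + rate * (1 - exp(-lam * tau)) / (epo_volume(p) * lam)
}
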