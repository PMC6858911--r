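#' Hemoglobin concentration from the total RBC count
#'
#' `Hgb = P * MCH / (c_tbv * 1e10)` g/dl, with `P` in cells, the mean
#' corpuscular hemoglobin `MCH` in pg and the total blood volume in ml.
#'
#' @param P Total RBC count (cells), >= 0.
#' @param c_tbv Total blood volume (ml), > 0.
#' @param MCH Mean corpuscular hemoglobin (pg), default 29.
#' @return Hgb in g/dl.
#' @export
hgb <- function(P, c_tbv, MCH = 29) {
  if (any(c_tbv <= 0)) stop("c_tbv must be > 0", call. = FALSE)
  P * MCH / (c_tbv * 1e10)
}

#' Precompute the EPO-independent operator blocks
#'
#' Assembles, once per patient, every Galerkin block that does not depend on
#' the EPO concentration: the constant class operators (BFU-E,
#' erythroblasts), the advection/influx/reaction splits of the EPO-dependent
#' classes, the neocytolysis window projection matrix, and the influx and
#' boundary-evaluation vectors.  The time steppers rebuild only the
#' E-dependent parts from these blocks.
#'
#' @param p Patient parameter record.
#' @param N Basis size (default 15).
#' @return A list consumed by the C++ kernels and by
#'   [step_implicit_euler()].
#' @export
operator_precompute <- function(p, N = 15) {
  geom <- class_geometry(p)
  bas <- lapply(geom$width, function(w) spectral_basis(N, w))
  dmat <- vapply(bas, delta_representer, numeric(N))
  bmat <- vapply(bas, function(b) b$e1, numeric(N))
  adv <- function(i) -t(bas[[i]]$Dxi) / geom$width[i]
  del <- function(i) -outer(dmat[, i], bas[[i]]$e0)
  A1 <- adv(1) + diag(p$beta1, N) + del(1)
  K2base <- adv(2) + del(2)                       # kappa2(E) I added per step
  A3 <- adv(3) + diag(p$beta3, N) + del(3)
  V4adv <- adv(4)                                 # scaled by nu(E) per step
  A4const <- diag(-p$alpha4, N) + del(4)
  B5 <- adv(5) + diag(-p$alpha5_0, N) + del(5)
  w5 <- geom$width[5]
  Xneo <- -neo_window_matrix(bas[[5]], p$neo_window[1] / w5,
                             p$neo_window[2] / w5)
  list(N = N, A1 = A1, K2base = K2base, A3 = A3, V4adv = V4adv,
       A4const = A4const, B5 = B5, Xneo = Xneo, d = dmat, b = bmat,
       S0 = p$S0, tau_E = p$tau_E, epsilon = p$epsilon,
       epsilon_R = p$epsilon_R, beta2 = p$beta2,
       mu = p$mu, sqrtw5 = sqrt(w5), bases = bas)
}

#' One implicit-Euler step of the coupled five-class system
#'
#' Reference implementation in plain R of the sequential scheme: each class
#' solves `(I - dt A_i(E)) y_i(t+dt) = y_i(t) + dt g_i(t+dt) d_i` in the
#' order 1 to 5, with the boundary influx `g_i` taken from the already
#' updated upstream class at `t + dt` and the EPO concentration evaluated
#' at the step end.  The compiled production stepper follows the identical
#' recursion; this function exists as its readable cross-check and for
#' single-step experiments.
#'
#' @param state `N x 5` coefficient matrix at time `t`.
#' @param E EPO concentration at `t + dt` (U/l).
#' @param p Patient parameter record.
#' @param dt Step size (days), > 0.
#' @param prec Optional [operator_precompute()] result.
#' @return `N x 5` coefficient matrix at `t + dt`.
#' @export
step_implicit_euler <- function(state, E, p, dt, prec = NULL) {
  stopifnot(dt > 0, is.matrix(state), ncol(state) == 5)
  if (is.null(prec)) prec <- operator_precompute(p, nrow(state))
  N <- prec$N
  y <- state
  kap2 <- p$beta2 - alpha2(E, p)
  nuv <- nu_rate(E, p)
  mE <- neo_excess(E, p)
  Ms <- list(
    diag(N) - dt * prec$A1,
    diag(N) - dt * (prec$K2base + diag(kap2, N)),
    diag(N) - dt * prec$A3,
    diag(N) - dt * (prec$A4const + nuv * prec$V4adv),
    diag(N) - dt * (prec$B5 + mE * prec$Xneo)
  )
  g <- p$S0
  for (i in 1:5) {
    if (i > 1) g <- boundary_influx(i, sum(y[, i - 1] * prec$b[, i - 1]), E, p)
    y[, i] <- solve(Ms[[i]], y[, i] + dt * g * prec$d[, i])
  }
  y
}

# E(t) on the fine grid inside one constant-rate interval, stepping from a
# known exogenous level (stable for arbitrarily long runs).
interval_Evec <- function(Eex0, rate, nstep, dt, p) {
  k <- seq_len(nstep)
  decay <- exp(-p$lambda * dt * k)
  p$E_end + decay * Eex0 + rate * (1 - decay) / (epo_volume(p) * p$lambda)
}

#' Simulate the erythropoiesis model under an EPO schedule
#'
#' Integrates the coupled Galerkin system with the implicit Euler method on
#' a uniform fine grid, the plasma EPO concentration evaluated from the
#' closed-form pharmacokinetics at each step end.  Cell counts are carried
#' with a 10^8 internal scaling; all returned observables are unscaled.
#'
#' @param p Patient parameter record.
#' @param schedule An [control_schedule()]; its span defines the horizon.
#' @param y0 Initial `N x 5` coefficient matrix; default is the
#'   uncontrolled steady state at `E_end` (so with zero rates the
#'   trajectory is stationary).
#' @param Eex0 Exogenous EPO at the horizon start (U/l).
#' @param dt Time step (days), default 0.01.
#' @param N Basis size, default 15.
#' @param keep_states Keep the full coefficient trajectory (memory ~
#'   `N * 5 * nstep` doubles)?
#' @param prec Optional precomputed operator blocks.
#' @return An object of class `"epo_trajectory"`: a list with `table`
#'   (data.frame: `time`, `E`, `P`, `hgb`, `rate`), `final` (coefficients at
#'   the horizon end), `Eex_final`, and optionally `states`.
#' @export
simulate_traj <- function(p, schedule, y0 = NULL, Eex0 = p$E_ex0, dt = 0.01,
                          N = 15, keep_states = FALSE, prec = NULL) {
  stopifnot(inherits(schedule, "epo_schedule"))
  if (is.null(prec)) prec <- operator_precompute(p, N)
  if (is.null(y0)) y0 <- steady_state(p, N = prec$N)$coef
  n_u <- length(schedule$rates)
  per_steps <- round(schedule$period / dt)
  if (abs(per_steps * dt - schedule$period) > 1e-9)
    stop("'period' must be an integer multiple of dt", call. = FALSE)
  K <- n_u * per_steps
  Evec <- numeric(K)
  Eex <- Eex0
  for (j in seq_len(n_u)) {
    idx <- (j - 1) * per_steps + seq_len(per_steps)
    Evec[idx] <- interval_Evec(Eex, schedule$rates[j], per_steps, dt, p)
    Eex <- epo_advance(Eex, schedule$rates[j], schedule$period, p)
  }
  sim <- cpp_simulate(y0, Evec, prec, dt, keep_states)
  tgrid <- schedule$breaks[1] + dt * (0:K)
  P <- 1e8 * sim$P
  out <- list(
    table = data.frame(
      time = tgrid,
      E = c(p$E_end + Eex0, Evec),
      P = P,
      hgb = hgb(P, p$c_tbv, p$MCH),
      rate = c(schedule$rates[1], rep(schedule$rates, each = per_steps))),
    final = sim$final, Eex_final = Eex, dt = dt, schedule = schedule)
  if (keep_states) out$states <- sim$states
  class(out) <- "epo_trajectory"
  out
}

#' @export
print.epo_trajectory <- function(x, ...) {
  tb <- x$table
  cat(sprintf(paste0("<epo_trajectory> t in [%g, %g] d, dt = %g\n",
                     "  Hgb: start %.2f -> end %.2f g/dl\n"),
              min(tb$time), max(tb$time), x$dt,
              tb$hgb[1], tb$hgb[nrow(tb)]))
  invisible(x)
}

#' Export a trajectory as a delimited table
#'
#' @param traj An `"epo_trajectory"`.
#' @param path Output file path (tab-separated).
#' @return `path`, invisibly.
#' @export
export_trajectory <- function(traj, path) {
  utils::write.table(traj$table, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Apply an instantaneous bleeding event to a model state
#'
#' Scales the circulating-erythrocyte coefficient vector uniformly so the
#' Hgb drops to `target_hgb`; the marrow classes (1-4) are untouched --
#' bleeding removes circulating cells only, not marrow precursors.
#'
#' @param state `N x 5` coefficient matrix.
#' @param target_hgb Post-bleed Hgb (g/dl); must not exceed the current Hgb.
#' @param p Patient parameter record.
#' @return The shocked `N x 5` coefficient matrix.
#' @export
apply_bleed <- function(state, target_hgb, p) {
  w5 <- class_geometry(p)$width[5]
  cur <- hgb(total_population(state[, 5], w5), p$c_tbv, p$MCH)
  if (target_hgb > cur + 1e-12)
    stop(sprintf("bleed target %.2f g/dl above current Hgb %.2f", target_hgb,
                 cur), call. = FALSE)
  state[, 5] <- state[, 5] * target_hgb / cur
  state
}
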