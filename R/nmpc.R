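#' Desired total RBC population for a Hgb target
#'
#' Inverse of the Hgb formula: `P^d = target * c_tbv * 1e10 / MCH` cells.
#'
#' @param target_hgb Hgb target (g/dl), > 0.
#' @param p Patient parameter record.
#' @return Cell count.
#' @export
desired_population <- function(target_hgb, p) {
  if (target_hgb < 0) stop("target must be >= 0", call. = FALSE)
  target_hgb * p$c_tbv * 1e10 / p$MCH
}

#' Receding-horizon (NMPC) configuration
#'
#' The constant-rate period `Delta_t` fixes both the rate-update frequency
#' and, through the horizon rule, the prediction horizon: 4 weeks for
#' periods of 1 or 7 days, 6 weeks for 14 or 21 days, 8 weeks for 28 days
#' (longer periods need a longer look-ahead to cover the ~2-week marrow
#' transit delay with at least two decision intervals).
#'
#' @param period Constant-rate period in days; one of 1, 7, 14, 21, 28 for
#'   the horizon rule, other divisors of the horizon are accepted with an
#'   explicit `horizon`.
#' @param T_total Total closed-loop duration (days), default 168.
#' @param horizon Prediction horizon in days; default by the horizon rule.
#' @param c_gamma Control-cost constant, default 0.1.
#' @param u_max Dose cap (U/day), default 1000.
#' @param target_hgb Setpoint (g/dl), default 10.5.
#' @param dt Plant integration step (days), default 0.01.
#' @param pred_dt Controller-internal integration step for the open-loop
#'   predictions (days), default 0.05: the optimizer needs only
#'   control-grade accuracy from its forward model, and a coarser
#'   first-order grid there buys a several-fold speedup; the plant always
#'   advances on the fine grid.
#' @param N Basis size, default 15.
#' @param ol_pgtol,ol_maxit Inner optimizer controls for the per-step
#'   open-loop solves.
#' @return An object of class `"epo_nmpc_config"`.
#' @export
nmpc_config <- function(period = 1, T_total = 168, horizon = NULL,
                        c_gamma = 0.1, u_max = 1000, target_hgb = 10.5,
                        dt = 0.01, pred_dt = 0.05, N = 15, ol_pgtol = 1e-3,
                        ol_maxit = 60) {
  if (is.null(horizon)) {
    horizon <- if (period <= 7) 28 else if (period <= 21) 42 else 56
  }
  M <- horizon / period
  if (abs(M - round(M)) > 1e-9)
    stop("'horizon' must be a multiple of 'period'", call. = FALSE)
  M <- as.integer(round(M))
  L <- T_total / period
  if (abs(L - round(L)) > 1e-9)
    stop("'T_total' must be a multiple of 'period'", call. = FALSE)
  structure(list(period = period, T_total = T_total, horizon = horizon,
                 M = M, L = as.integer(round(L)), c_gamma = c_gamma,
                 u_max = u_max, target_hgb = target_hgb, dt = dt,
                 pred_dt = pred_dt, N = N,
                 ol_pgtol = ol_pgtol, ol_maxit = ol_maxit),
            class = "epo_nmpc_config")
}

#' Scenario events unknown to the controller in advance
#'
#' @param bleeds Data frame with columns `day` and `target_hgb`: at the
#'   start of `day` the plant's circulating RBCs are cut so Hgb drops to
#'   `target_hgb`; the controller only learns of it through the next state
#'   measurement.
#' @param missed Integer vector of days with complete failure to administer
#'   EPO (actuator outputs 0 regardless of the command).
#' @param overrides Data frame with columns `day` and `rate`: on those days
#'   the given rate is applied instead of the command (dosing errors; may
#'   exceed the cap).
#' @return An object of class `"epo_scenario"`.
#' @export
scenario_events <- function(bleeds = NULL, missed = integer(), overrides = NULL) {
  if (!is.null(bleeds)) stopifnot(all(c("day", "target_hgb") %in% names(bleeds)))
  if (!is.null(overrides)) stopifnot(all(c("day", "rate") %in% names(overrides)))
  structure(list(bleeds = bleeds, missed = as.integer(missed),
                 overrides = overrides), class = "epo_scenario")
}

#' Run the NMPC closed loop
#'
#' The receding-horizon loop: at each decision time `t0 = 0, Delta_t,
#' 2 Delta_t, ...` solve the open-loop problem on `[t0, t0 + M Delta_t]`
#' from the measured plant state (perfect measurement, including any
#' post-bleed state), apply only the first component of the optimal rate
#' vector to the plant over `[t0, t0 + Delta_t]` -- with actuator events
#' (missed doses, overrides) imposed day by day -- advance the plant, shift
#' the horizon, and warm-start the next solve with the shifted previous
#' optimum (last value padded).
#'
#' @param p Calibrated patient parameter record.
#' @param config An [nmpc_config()].
#' @param scenario Optional [scenario_events()].
#' @param y0 Initial plant state; default the uncontrolled steady state.
#' @param verbose Print per-step progress?
#' @return An object of class `"epo_nmpc_result"`: list with `days`
#'   (per-day table: `day`, `commanded`, `applied`, `hgb` at day start,
#'   `E` at day start), `fine` (fine-grid trajectory table), `total_dose`
#'   (U), `solves` (per-decision diagnostics), `events`, `config`.
#' @export
run_closed_loop <- function(p, config = nmpc_config(), scenario = NULL,
                            y0 = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "epo_nmpc_config"))
  if (!isTRUE(attr(p, "calibrated")))
    warning("patient record is not calibrated")
  prec <- operator_precompute(p, config$N)
  cfg <- cost_config(p, M = config$M, period = config$period,
                     c_gamma = config$c_gamma, u_max = config$u_max,
                     target_hgb = config$target_hgb, dt = config$pred_dt)
  if (is.null(y0)) y0 <- steady_state(p, N = config$N)$coef
  state <- y0
  Eex <- p$E_ex0
  dt <- config$dt
  steps_day <- round(1 / dt)
  if (abs(steps_day * dt - 1) > 1e-9)
    stop("dt must divide one day", call. = FALSE)
  w5 <- class_geometry(p)$width[5]
  bleeds <- if (!is.null(scenario)) scenario$bleeds
  missed <- if (!is.null(scenario)) scenario$missed else integer()
  overrides <- if (!is.null(scenario)) scenario$overrides
  n_days <- config$T_total
  day_tab <- data.frame(day = 0:(n_days - 1), commanded = NA_real_,
                        applied = NA_real_, hgb = NA_real_, E = NA_real_)
  fine_t <- fine_E <- fine_hgb <- fine_rate <- vector("list", n_days)
  solves <- vector("list", config$L)
  events <- list()
  warm <- NULL
  Hwarm <- NULL
  for (l in seq_len(config$L)) {
    t0 <- (l - 1) * config$period
    sol <- solve_open_loop(state, Eex, cfg, p, warm_start = warm, prec = prec,
                           pgtol = config$ol_pgtol, maxit = config$ol_maxit,
                           H0 = Hwarm)
    if (identical(sol$flag, "linesearch_failure") && sol$iterations == 0L)
      stop("open-loop solve failed at step ", l, " (t0 = ", t0, ")",
           call. = FALSE)
    solves[[l]] <- data.frame(t0 = t0, cost = sol$cost, pgnorm = sol$pgnorm,
                              iterations = sol$iterations,
                              converged = sol$converged)
    u_apply <- sol$u[1]
    warm <- c(sol$u[-1], sol$u[cfg$M])    # shift, pad with last value
    M <- cfg$M                            # shift the curvature estimate too
    Hwarm <- sol$H
    Hwarm[-M, -M] <- Hwarm[-1, -1]
    Hwarm[M, ] <- Hwarm[, M] <- 0
    Hwarm[M, M] <- Hwarm[M - 1, M - 1]
    if (verbose)
      message(sprintf("t0 = %5.0f  u = %7.2f  it = %3d  pg = %.2e",
                      t0, u_apply, sol$iterations, sol$pgnorm))
    for (d in t0:(t0 + config$period - 1)) {
      if (!is.null(bleeds) && d %in% bleeds$day) {
        tgt <- bleeds$target_hgb[match(d, bleeds$day)]
        state <- apply_bleed(state, tgt, p)
        events <- c(events, list(list(kind = "bleed", day = d,
                                      target_hgb = tgt)))
      }
      rate_d <- u_apply
      if (d %in% missed) {
        rate_d <- 0
        events <- c(events, list(list(kind = "missed", day = d)))
      } else if (!is.null(overrides) && d %in% overrides$day) {
        rate_d <- overrides$rate[match(d, overrides$day)]
        events <- c(events, list(list(kind = "override", day = d,
                                      rate = rate_d)))
      }
      P0 <- total_population(state[, 5], w5)
      day_tab[d + 1, ] <- c(d, u_apply, rate_d, hgb(P0, p$c_tbv, p$MCH),
                            p$E_end + Eex)
      E_start <- p$E_end + Eex
      Evec <- interval_Evec(Eex, rate_d, steps_day, dt, p)
      sim <- cpp_simulate(state, Evec, prec, dt, FALSE)
      state <- sim$final
      Eex <- epo_advance(Eex, rate_d, 1, p)
      Pf <- 1e8 * sim$P
      fine_t[[d + 1]] <- d + dt * (0:steps_day)
      fine_E[[d + 1]] <- c(E_start, Evec)
      fine_hgb[[d + 1]] <- hgb(Pf, p$c_tbv, p$MCH)
      fine_rate[[d + 1]] <- rep(rate_d, steps_day + 1)
    }
  }
  fine <- data.frame(time = unlist(fine_t), E = unlist(fine_E),
                     hgb = unlist(fine_hgb), rate = unlist(fine_rate))
  structure(list(days = day_tab, fine = fine,
                 total_dose = sum(day_tab$applied),
                 solves = do.call(rbind, solves),
                 events = events, config = config,
                 final_state = state, Eex_final = Eex),
            class = "epo_nmpc_result")
}

#' @export
print.epo_nmpc_result <- function(x, ...) {
  cat(sprintf(paste0("<epo_nmpc_result> %g d, period %g d, c_gamma = %g\n",
                     "  total dose %.0f U | final Hgb %.2f g/dl | ",
                     "mean Hgb (last 28 d) %.2f\n"),
              x$config$T_total, x$config$period, x$config$c_gamma,
              x$total_dose, x$fine$hgb[nrow(x$fine)],
              mean_hgb(x, x$config$T_total - 28, x$config$T_total)))
  invisible(x)
}

#' Closed-loop summary metrics
#'
#' `mean_hgb()`/`min_hgb()`/`max_hgb()` summarize the fine-grid Hgb trace
#' on a time window; `time_in_range()` is the fraction of the window spent
#' inside `[lower, upper]`; `oscillation_amplitude()` is the maximal
#' absolute deviation from the setpoint on the window (taken after the
#' correction transient when comparing rate-update frequencies).
#'
#' @param res An `"epo_nmpc_result"`.
#' @param from,to Window bounds in days.
#' @param lower,upper Target range bounds (g/dl).
#' @param target Setpoint (g/dl); defaults to the run's configured target.
#' @return A scalar.
#' @export
mean_hgb <- function(res, from, to) {
  h <- res$fine
  mean(h$hgb[h$time >= from & h$time <= to])
}

#' @rdname mean_hgb
#' @export
min_hgb <- function(res, from, to) {
  h <- res$fine
  min(h$hgb[h$time >= from & h$time <= to])
}

#' @rdname mean_hgb
#' @export
max_hgb <- function(res, from, to) {
  h <- res$fine
  max(h$hgb[h$time >= from & h$time <= to])
}

#' @rdname mean_hgb
#' @export
time_in_range <- function(res, lower = 10, upper = 12, from = 56,
                          to = res$config$T_total) {
  h <- res$fine
  sel <- h$time >= from & h$time <= to
  mean(h$hgb[sel] >= lower & h$hgb[sel] <= upper)
}

#' @rdname mean_hgb
#' @export
oscillation_amplitude <- function(res, from = 56, to = res$config$T_total,
                                  target = res$config$target_hgb) {
  h <- res$fine
  sel <- h$time >= from & h$time <= to
  max(abs(h$hgb[sel] - target))
}

#' Run a grid of closed-loop experiments
#'
#' Sweeps control-cost constants and constant-rate periods over one or more
#' patients and tabulates per-run summary metrics.  Per-cell failures are
#' recorded (column `ok`) and the grid continues.
#'
#' @param patients A single patient record or a named list of records.
#' @param c_gamma Vector of control-cost constants.
#' @param periods Vector of constant-rate periods (days).
#' @param T_total Run length (days).
#' @param transient_end Day separating the correction transient from the
#'   evaluation window, default 56.
#' @param ... Further arguments to [nmpc_config()].
#' @return Data frame with one row per (patient, c_gamma, period) cell:
#'   total dose, mean/min/max Hgb and time-in-range on the evaluation
#'   window, oscillation amplitude, maximum applied rate.
#' @export
run_experiment_grid <- function(patients, c_gamma = c(0.1, 1, 10),
                                periods = 1, T_total = 168,
                                transient_end = 56, ...) {
  if (inherits(patients, "epo_patient")) patients <- list(patient = patients)
  rows <- list()
  for (pn in names(patients)) {
    for (cg in c_gamma) {
      for (per in periods) {
        res <- try(run_closed_loop(
          patients[[pn]],
          nmpc_config(period = per, T_total = T_total, c_gamma = cg, ...)),
          silent = TRUE)
        ok <- !inherits(res, "try-error")
        rows[[length(rows) + 1L]] <- if (ok) data.frame(
          patient = pn, c_gamma = cg, period = per, ok = TRUE,
          total_dose = res$total_dose,
          mean_hgb = mean_hgb(res, transient_end, T_total),
          min_hgb = min_hgb(res, transient_end, T_total),
          max_hgb = max_hgb(res, transient_end, T_total),
          time_in_range = time_in_range(res, from = transient_end),
          oscillation = oscillation_amplitude(res, from = transient_end),
          max_rate = max(res$days$applied)
        ) else data.frame(
          patient = pn, c_gamma = cg, period = per, ok = FALSE,
          total_dose = NA_real_, mean_hgb = NA_real_, min_hgb = NA_real_,
          max_hgb = NA_real_, time_in_range = NA_real_,
          oscillation = NA_real_, max_rate = NA_real_)
      }
    }
  }
  do.call(rbind, rows)
}
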