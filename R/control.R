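#' Cost-functional configuration for the open-loop dose problem
#'
#' The horizon cost is
#' `J(u) = 1/2 sum_j gamma_j u_j^2
#'        + sigma_O/2 int (r (P(t) - P^d))^2 dt
#'        + sigma_f/2 (r (P(t_f) - P^d))^2`,
#' where the scale factor r = 2 MCH / (c_tbv 1e10) converts populations to
#' the Hgb scale (so
#' r (P - P^d) is twice the Hgb deviation in g/dl), `sigma_O = 1e4 / (M
#' Delta_t)`, `sigma_f = 1e3`, and `gamma_j = c_gamma Delta_t / (M
#' Delta_t)`: for longer constant-rate periods the control weight is
#' multiplied by the days per period so control costs are penalized alike
#' across update frequencies.  `c_gamma` is the only individualized knob.
#'
#' @param p Patient parameter record.
#' @param M Number of control intervals in the prediction horizon.
#' @param period Constant-rate period `Delta_t` (days).
#' @param c_gamma Control-cost constant, default 0.1.
#' @param u_max Dose-rate cap (U/day), default 1000.
#' @param target_hgb Hgb setpoint (g/dl), default 10.5.
#' @param dt Integration step (days), default 0.01.
#' @return An object of class `"epo_cost_config"`.
#' @export
cost_config <- function(p, M = 28, period = 1, c_gamma = 0.1, u_max = 1000,
                        target_hgb = 10.5, dt = 0.01) {
  stopifnot(M >= 1, period > 0, c_gamma > 0, u_max > 0, target_hgb > 0)
  per_steps <- round(period / dt)
  if (abs(per_steps * dt - period) > 1e-9)
    stop("'period' must be an integer multiple of dt", call. = FALSE)
  horizon <- M * period
  r <- 2 * p$MCH / (p$c_tbv * 1e10)
  Pd <- desired_population(target_hgb, p)
  w5 <- class_geometry(p)$width[5]
  structure(list(
    M = M, period = period, horizon = horizon, dt = dt,
    per_steps = per_steps, K = M * per_steps,
    c_gamma = c_gamma, gamma = c_gamma * period / horizon,
    sigma_O = 1e4 / horizon, sigma_f = 1e3,
    u_max = u_max, target_hgb = target_hgb, Pd = Pd, r = r,
    a = r * 1e8 * sqrt(w5),      # model coefficient -> r * P (cells)
    h0 = r * Pd
  ), class = "epo_cost_config")
}

# E(t) on the fine grid over the horizon for a rate vector u, plus (once per
# solve) the K x M sensitivity matrix dE/du -- independent of u since the
# exogenous kinetics are linear in the rates (zero Hessian).
horizon_Evec <- function(u, Eex0, cfg, p) {
  Evec <- numeric(cfg$K)
  Eex <- Eex0
  for (j in seq_len(cfg$M)) {
    idx <- (j - 1) * cfg$per_steps + seq_len(cfg$per_steps)
    Evec[idx] <- interval_Evec(Eex, u[j], cfg$per_steps, cfg$dt, p)
    Eex <- epo_advance(Eex, u[j], cfg$period, p)
  }
  Evec
}

horizon_dEdu <- function(cfg, p) {
  lam <- p$lambda
  vol <- epo_volume(p)
  s <- cfg$dt * seq_len(cfg$K)              # step-end times from t0
  sb <- cfg$period * (0:cfg$M)              # interval boundaries
  j <- findInterval(s - 1e-12, sb)          # running interval of each step
  G <- matrix(0, cfg$K, cfg$M)
  for (l in seq_len(cfg$M)) {
    done <- j > l
    run <- j == l
    G[done, l] <- (exp(-lam * (s[done] - sb[l + 1])) -
                   exp(-lam * (s[done] - sb[l]))) / (vol * lam)
    G[run, l] <- (1 - exp(-lam * (s[run] - sb[l]))) / (vol * lam)
  }
  G
}

#' Open-loop cost and adjoint gradient
#'
#' `ol_cost()` evaluates the horizon cost for a rate vector; `ol_gradient()`
#' returns its exact gradient, computed by the discrete adjoint of the
#' sequential implicit-Euler scheme: one forward sweep storing the states,
#' one backward sweep (classes 5 to 1) for the adjoint states, then
#' assembly through the EPO sensitivities `dE/du`.  Because the gradient is
#' that of the fully discretized cost, it agrees with finite differences of
#' [ol_cost()] to solver precision.
#'
#' @param u Rate vector of length `cfg$M` (U/day).
#' @param state Initial `N x 5` coefficient matrix at the horizon start.
#' @param Eex0 Exogenous EPO at the horizon start (U/l).
#' @param cfg An [cost_config()] object.
#' @param p Patient parameter record.
#' @param prec Optional [operator_precompute()] blocks.
#' @return `ol_cost()`: scalar cost.  `ol_gradient()`: gradient vector of
#'   length `cfg$M`.
#' @export
ol_cost <- function(u, state, Eex0, cfg, p, prec = NULL) {
  if (is.null(prec)) prec <- operator_precompute(p)
  Evec <- horizon_Evec(u, Eex0, cfg, p)
  res <- cpp_cost_grad(state, Evec, prec, cfg$dt, cfg$sigma_O, cfg$sigma_f,
                       cfg$a, cfg$h0, FALSE)
  0.5 * cfg$gamma * sum(u^2) + res$J
}

#' @rdname ol_cost
#' @export
ol_gradient <- function(u, state, Eex0, cfg, p, prec = NULL) {
  if (is.null(prec)) prec <- operator_precompute(p)
  Evec <- horizon_Evec(u, Eex0, cfg, p)
  res <- cpp_cost_grad(state, Evec, prec, cfg$dt, cfg$sigma_O, cfg$sigma_f,
                       cfg$a, cfg$h0, TRUE)
  cfg$gamma * u + drop(crossprod(horizon_dEdu(cfg, p), res$gE))
}

#' Projected BFGS with Armijo line search under box constraints
#'
#' Quasi-Newton minimization over a box: search directions use the inverse
#' BFGS approximation on the epsilon-free variables and steepest descent on
#' the epsilon-active ones (variables within a small distance of a bound
#' with the gradient pushing outward), steps are projected onto the box and
#' accepted under an Armijo sufficient-decrease condition (parameter 1e-4,
#' quadratic-interpolation backtracking with safeguard factors between
#' 0.1 and 0.5, at most 40 backtracks).  The approximation is Shanno-scaled
#' at the first update and reset only when a direction fails the descent
#' test.  Termination on the projected
#' gradient: `max |x - proj(x - g)| <= pgtol * max(1, pg0)` with `pg0` the
#' projected-gradient norm at the start point -- relative to the initial
#' stationarity violation, with an absolute floor so an already-stationary
#' start exits immediately.
#'
#' @param fg Function of `x` returning `list(value = f, gradient = g)`.
#' @param x0 Start point (clipped into the box).
#' @param lower,upper Box bounds (scalars or vectors).
#' @param pgtol Relative projected-gradient tolerance, default 1e-6.
#' @param maxit Iteration cap, default 200.
#' @param H0 Optional initial inverse-Hessian approximation (e.g. carried
#'   over from a closely related previous solve, as the receding-horizon
#'   loop does); default identity with Shanno scaling at the first update.
#' @return List with `par`, `value`, `gradient`, `iterations`, `pgnorm`,
#'   `converged`, `flag` (`"converged"`, `"maxit"` or
#'   `"linesearch_failure"`), and `history` (per-iteration cost, step and
#'   projected-gradient norm).
#' @export
projected_bfgs <- function(fg, x0, lower = -Inf, upper = Inf, pgtol = 1e-6,
                           maxit = 200, H0 = NULL) {
  n <- length(x0)
  lower <- rep_len(lower, n); upper <- rep_len(upper, n)
  clip <- function(x) pmin(pmax(x, lower), upper)
  x <- clip(x0)
  ev <- fg(x); f <- ev$value; g <- ev$gradient
  if (is.null(H0)) { H <- diag(n); scaled <- FALSE } else {
    H <- H0; scaled <- TRUE                 # curvature carried over
  }
  hist <- matrix(NA_real_, 0, 3,
                 dimnames = list(NULL, c("cost", "step", "pgnorm")))
  flag <- "maxit"
  it <- 0L
  pgnorm <- max(abs(x - clip(x - g)))
  thr <- pgtol * max(1, pgnorm)
  while (it < maxit) {
    if (pgnorm <= thr) { flag <- "converged"; break }
    it <- it + 1L
    # epsilon-active set: variables at (or within eps of) a bound with a
    # gradient pushing outward are frozen for this iteration
    epsa <- min(1e-3 * pmax(upper - lower, 1), pgnorm)
    act <- (x <= lower + epsa & g > 0) | (x >= upper - epsa & g < 0)
    d <- numeric(n)
    free <- !act
    if (any(free)) d[free] <- -drop(H[free, free, drop = FALSE] %*% g[free])
    d[act] <- -g[act]
    if (sum(g * d) >= -1e-14 * sum(abs(g))) {
      d <- -g; H <- diag(n); scaled <- FALSE
    }
    # Armijo backtracking with quadratic interpolation on the projected arc
    tstep <- 1; ok <- FALSE
    for (bt in 0:40) {
      xc <- clip(x + tstep * d)
      pred <- sum(g * (xc - x))
      if (pred < 0) {
        fc <- fg(xc)
        if (fc$value <= f + 1e-4 * pred) { ok <- TRUE; break }
        tq <- -0.5 * pred * tstep / (fc$value - f - pred)
        tstep <- if (is.finite(tq)) min(max(tq, 0.1 * tstep), 0.5 * tstep) else
          0.5 * tstep
      } else tstep <- 0.5 * tstep
    }
    if (!ok) {
      if (scaled) { H <- diag(n); scaled <- FALSE; next }  # retry steepest
      flag <- "linesearch_failure"; break
    }
    svec <- xc - x; yvec <- fc$gradient - g
    sy <- sum(svec * yvec)
    if (sy > 1e-10 * sqrt(sum(svec^2) * sum(yvec^2))) {
      if (!scaled) {                  # Shanno scaling after each reset
        H <- diag(sy / sum(yvec^2), n)
        scaled <- TRUE
      }
      rho <- 1 / sy
      Hy <- H %*% yvec
      H <- H - rho * (outer(svec, drop(Hy)) + outer(drop(Hy), svec)) +
        rho * (rho * sum(yvec * Hy) + 1) * outer(svec, svec)
    }
    x <- xc; f <- fc$value; g <- fc$gradient
    pgnorm <- max(abs(x - clip(x - g)))
    hist <- rbind(hist, c(f, tstep, pgnorm))
  }
  list(par = x, value = f, gradient = g, iterations = it, pgnorm = pgnorm,
       converged = identical(flag, "converged"), flag = flag, history = hist,
       H = H)
}

#' Solve the open-loop dose-optimization problem on one horizon
#'
#' Minimizes the horizon cost of [cost_config()] over admissible rate
#' vectors `0 <= u <= u_max` with [projected_bfgs()] and the discrete
#' adjoint gradient.  Controls are internally rescaled to `[0, 1]` (divide
#' by `u_max`) for quasi-Newton conditioning.  A line-search failure
#' returns the best iterate with an explicit flag, never silently.
#'
#' @inheritParams ol_cost
#' @param warm_start Optional admissible starting rate vector (length
#'   `cfg$M`); default all-zero.
#' @param pgtol,maxit,H0 Optimizer controls, see [projected_bfgs()].
#' @return List with `u` (optimal rates), `cost`, `pgnorm`, `iterations`,
#'   `converged`, `flag`, `history`, `H` (final inverse-Hessian
#'   approximation, reusable as `H0` for a nearby solve).
#' @export
solve_open_loop <- function(state, Eex0, cfg, p, warm_start = NULL,
                            prec = NULL, pgtol = 1e-6, maxit = 200,
                            H0 = NULL) {
  if (is.null(prec)) prec <- operator_precompute(p)
  u0 <- if (is.null(warm_start)) rep(0, cfg$M) else rep_len(warm_start, cfg$M)
  dEdu <- horizon_dEdu(cfg, p)
  um <- cfg$u_max
  fg <- function(v) {
    u <- v * um
    Evec <- horizon_Evec(u, Eex0, cfg, p)
    res <- cpp_cost_grad(state, Evec, prec, cfg$dt, cfg$sigma_O, cfg$sigma_f,
                         cfg$a, cfg$h0, TRUE)
    list(value = 0.5 * cfg$gamma * sum(u^2) + res$J,
         gradient = um * (cfg$gamma * u + drop(crossprod(dEdu, res$gE))))
  }
  opt <- projected_bfgs(fg, u0 / um, lower = 0, upper = 1, pgtol = pgtol,
                        maxit = maxit, H0 = H0)
  list(u = opt$par * um, cost = opt$value, pgnorm = opt$pgnorm,
       iterations = opt$iterations, converged = opt$converged,
       flag = opt$flag, history = opt$history, H = opt$H)
}
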