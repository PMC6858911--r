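#' Patient parameter record
#'
#' Bundles every patient-specific constant of the erythropoiesis model.  No
#' clinical reference parameter set ships with the package: defaults are
#' synthetic, chosen to satisfy the published physiological constraints
#' (RBC lifespan 37.7-115.8 days, uncontrolled Hgb below 10 g/dl,
#' neocytolysis threshold `tau_E = 80`), and every record is expected to
#' pass [calibrate_patient()].
#'
#' @param mu Vector of 10 positive shape parameters: `mu1..mu3` the CFU-E
#'   apoptosis sigmoid ([alpha2()]), `mu4..mu7` the reticulocyte maturation
#'   velocity sigmoid ([nu_rate()]), `mu8..mu10` the neocytolysis excess
#'   mortality (`min(mu8 / E^mu9, mu10)`).
#' @param S0 Committed stem-cell influx (cells x 10^8 per day).
#' @param beta1,beta2,beta3 Proliferation rates (1/day) of BFU-E, CFU-E and
#'   erythroblasts.
#' @param alpha4 Marrow-reticulocyte apoptosis rate (1/day).
#' @param alpha5_0 Baseline erythrocyte mortality (1/day).
#' @param E_end Endogenous EPO concentration (U/l), > 0.
#' @param c_tbv Total blood volume (ml), > 0.
#' @param rbc_lifespan Maximal erythrocyte age (days).
#' @param E_ex0 Exogenous EPO concentration at time 0 (U/l), >= 0.
#' @param T_half EPO half-life (days); the degradation rate
#'   `lambda = log(2) / T_half` is derived and exposed read-only.
#' @param tau_E Neocytolysis EPO threshold (U/l), default 80.
#' @param neo_window Closed age subinterval of the erythrocyte class where
#'   neocytolysis acts, default `c(0, 14)` days (neocytes are young RBCs).
#' @param MCH Mean corpuscular hemoglobin (pg), default 29.
#' @param epsilon Regularization width of the smoothed Heaviside threshold
#'   `H_eps(tau_E - E)` (EPO-concentration units), default 1.
#' @param epsilon_R Regularization width of the smoothed
#'   `min(mu8/E^mu9, mu10)` (mortality-rate units, 1/day), default 0.02.
#'   The two regularizations act on quantities three orders of magnitude
#'   apart, so they carry separate widths.
#' @return An object of class `"epo_patient"` (a validated list); the
#'   element `lambda` is derived from `T_half`.
#' @export
patient_params <- function(mu, S0, beta1, beta2, beta3, alpha4, alpha5_0,
                           E_end, c_tbv, rbc_lifespan, E_ex0 = 0,
                           T_half = 0.3, tau_E = 80, neo_window = c(0, 14),
                           MCH = 29, epsilon = 1, epsilon_R = 0.02) {
  p <- list(mu = as.numeric(mu), S0 = S0, beta1 = beta1, beta2 = beta2,
            beta3 = beta3, alpha4 = alpha4, alpha5_0 = alpha5_0,
            E_end = E_end, c_tbv = c_tbv, rbc_lifespan = rbc_lifespan,
            E_ex0 = E_ex0, T_half = T_half, tau_E = tau_E,
            neo_window = as.numeric(neo_window), MCH = MCH,
            epsilon = epsilon, epsilon_R = epsilon_R)
  p$lambda <- log(2) / T_half
  validate_patient(p)
  structure(p, class = "epo_patient")
}

validate_patient <- function(p) {
  with(p, {
    if (length(mu) != 10 || any(!is.finite(mu)) || any(mu <= 0))
      stop("'mu' must be 10 positive reals", call. = FALSE)
    if (mu[4] <= mu[5])
      stop("mu4 must exceed mu5 (velocity sigmoid range)", call. = FALSE)
    if (!is.finite(E_end) || E_end <= 0) stop("E_end must be > 0", call. = FALSE)
    if (!is.finite(c_tbv) || c_tbv <= 0) stop("c_tbv must be > 0", call. = FALSE)
    if (S0 < 0) stop("S0 must be >= 0", call. = FALSE)
    if (E_ex0 < 0) stop("E_ex0 must be >= 0", call. = FALSE)
    if (T_half <= 0) stop("T_half must be > 0 (lambda = log(2)/T_half)",
                          call. = FALSE)
    if (rbc_lifespan <= 0) stop("rbc_lifespan must be > 0", call. = FALSE)
    if (any(c(beta1, beta2, beta3) <= 0)) stop("beta rates must be > 0",
                                               call. = FALSE)
    if (alpha4 < 0 || alpha5_0 <= 0) stop("mortality rates invalid", call. = FALSE)
    if (epsilon <= 0 || epsilon_R <= 0)
      stop("regularization widths must be > 0", call. = FALSE)
    if (length(neo_window) != 2 || neo_window[1] < 0 ||
        neo_window[2] <= neo_window[1] || neo_window[2] >= rbc_lifespan)
      stop("neo_window must be a non-empty interval inside [0, rbc_lifespan)",
           call. = FALSE)
    if (tau_E <= 0) stop("tau_E must be > 0", call. = FALSE)
  })
  invisible(p)
}

#' @export
print.epo_patient <- function(x, ...) {
  cat(sprintf(paste0(
    "<epo_patient>%s\n",
    "  E_end = %.1f U/l | RBC lifespan = %.1f d | c_tbv = %.0f ml\n",
    "  S0 = %.3g x1e8 cells/d | T_half = %.2f d | tau_E = %g\n"),
    if (isTRUE(attr(x, "calibrated"))) " (calibrated)" else "",
    x$E_end, x$rbc_lifespan, x$c_tbv, x$S0, x$T_half, x$tau_E))
  invisible(x)
}

#' Maturity interval geometry of the five cell classes
#'
#' Fixed marrow class boundaries 0, 3, 8, 13, 15.5 days (BFU-E, CFU-E,
#' erythroblasts, marrow reticulocytes); the erythrocyte class spans
#' `[0, rbc_lifespan]` since circulating age restarts at release.
#'
#' @param p Patient parameter record.
#' @return List with `lower`, `upper`, `width` (numeric vectors, length 5).
#' @export
class_geometry <- function(p) {
  lower <- c(0, 3, 8, 13, 0)
  upper <- c(3, 8, 13, 15.5, p$rbc_lifespan)
  list(lower = lower, upper = upper, width = upper - lower)
}

#' Default synthetic patient
#'
#' A fully documented synthetic parameter set: endogenous EPO below the
#' neocytolysis threshold (anemic hemodialysis patient), mid-range RBC
#' lifespan, and rate parameters calibrated by [calibrate_patient()] so the
#' uncontrolled steady-state Hgb is 8.25 g/dl and sustained maximum-rate
#' dosing can raise it above 12 g/dl.
#'
#' @param target_hgb_uncontrolled Uncontrolled steady-state Hgb (g/dl) the
#'   calibration scales `S0` to; default 8.25.
#' @return A calibrated `"epo_patient"` record.
#' @export
default_patient <- function(target_hgb_uncontrolled = 8.25) {
  E_end <- 50
  p <- patient_params(
    mu = c(0.2, 0.025, 0.025 * (E_end + 40),   # alpha2 midpoint at E_end + 40
           1.8, 1.0, 0.03, 0.03 * (E_end + 50),# nu midpoint at E_end + 50
           160, 2, 0.4),
    S0 = 1, beta1 = 0.8, beta2 = 0.35, beta3 = 0.9,
    alpha4 = 0.05, alpha5_0 = 0.01,
    E_end = E_end, c_tbv = 5000, rbc_lifespan = 76
  )
  calibrate_patient(p, target_hgb_uncontrolled)
}

#' Calibrate a patient record by two steady-state solves
#'
#' Substitute ground truth for the absent clinical parameter sets: (a) the
#' uncontrolled steady-state Hgb (at `E = E_end`) must lie in the anemic
#' band `[7, 9.5]` g/dl -- `S0` is rescaled exactly (the state system is
#' linear in the influx) to hit `target_hgb` when supplied, otherwise the
#' band is only checked; (b) sustained dosing at `u_max` (steady EPO level
#' `E_end + u_max / (V lambda)`) must raise the steady-state Hgb above
#' 12 g/dl (controllability).  Violations raise errors naming the criterion;
#' nothing is adjusted silently.
#'
#' @param p Patient parameter record.
#' @param target_hgb Optional uncontrolled Hgb (g/dl) in `[7, 9.5]` to scale
#'   `S0` to.
#' @param u_max Reference dosing cap (U/day) for the controllability check.
#' @param N Basis size for the steady-state solves.
#' @return The calibrated record, with attribute `calibrated = TRUE`.
#' @export
calibrate_patient <- function(p, target_hgb = NULL, u_max = 1000, N = 15) {
  stopifnot(inherits(p, "epo_patient"))
  if (p$S0 <= 0)
    stop("calibration failed: S0 <= 0, no cell influx so any positive Hgb ",
         "target is unreachable", call. = FALSE)
  ss0 <- steady_state(p, E = p$E_end, N = N)
  if (!is.finite(ss0$hgb) || ss0$hgb <= 0)
    stop("calibration failed: degenerate uncontrolled steady state",
         call. = FALSE)
  if (!is.null(target_hgb)) {
    if (target_hgb < 7 || target_hgb > 9.5)
      stop("target uncontrolled Hgb must lie in [7, 9.5] g/dl", call. = FALSE)
    p$S0 <- p$S0 * target_hgb / ss0$hgb   # exact by linearity in S0
    ss0 <- steady_state(p, E = p$E_end, N = N)
  }
  if (ss0$hgb < 7 - 1e-6 || ss0$hgb > 9.5 + 1e-6)
    stop(sprintf(paste0("calibration failed: uncontrolled steady-state Hgb ",
                        "%.2f g/dl outside [7, 9.5]"), ss0$hgb), call. = FALSE)
  E_max <- p$E_end + u_max / (epo_volume(p) * p$lambda)
  ss1 <- steady_state(p, E = E_max, N = N)
  if (ss1$hgb <= 12)
    stop(sprintf(paste0("calibration failed: steady-state Hgb at maximum ",
                        "dosing is %.2f g/dl (needs > 12; patient not ",
                        "controllable)"), ss1$hgb), call. = FALSE)
  attr(p, "calibrated") <- TRUE
  p
}

#' Generate a calibrated synthetic patient
#'
#' Samples a parameter record from documented physiological ranges and
#' passes it through [calibrate_patient()].  The endogenous EPO level is
#' drawn per profile -- `high_Eend` in 200-300 U/l (far above the
#' neocytolysis threshold), `near_threshold` in 60-80, `low_Eend` in 20-60 --
#' and the RBC lifespan uniformly in the published hemodialysis range
#' 37.7-115.8 days.  The sigmoid midpoints are placed relative to the
#' patient's own endogenous level (as individualized estimates would be),
#' which keeps every profile responsive to exogenous EPO.  Draws are
#' retried a bounded number of times on calibration failure; the generator
#' is a deterministic function of `seed` and leaves the caller's RNG state
#' untouched.
#'
#' @param seed Integer seed fixing the pseudo-random stream.
#' @param profile One of `"high_Eend"`, `"near_threshold"`, `"low_Eend"`.
#' @param max_tries Bounded number of redraws before an explicit error.
#' @return A calibrated `"epo_patient"` record.
#' @export
generate_patient <- function(seed,
                             profile = c("high_Eend", "near_threshold",
                                         "low_Eend"),
                             max_tries = 20) {
  profile <- match.arg(profile)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  last_err <- NULL
  for (try_i in seq_len(max_tries)) {
    E_end <- switch(profile,
      high_Eend      = stats::runif(1, 200, 300),
      near_threshold = stats::runif(1, 60, 80),
      low_Eend       = stats::runif(1, 20, 60))
    mu2 <- stats::runif(1, 0.02, 0.03)
    mu6 <- stats::runif(1, 0.025, 0.035)
    mu9 <- stats::runif(1, 1.5, 2.5)
    p <- try(patient_params(
      mu = c(stats::runif(1, 0.15, 0.3),                   # mu1
             mu2, mu2 * (E_end + stats::runif(1, 30, 50)), # alpha2 midpoint
             stats::runif(1, 1.6, 2.0), stats::runif(1, 0.9, 1.1),
             mu6, mu6 * (E_end + stats::runif(1, 40, 60)), # nu midpoint
             stats::runif(1, 0.05, 0.15) * 40^mu9,         # mu8: ~0.1/d at E=40
             mu9, stats::runif(1, 0.3, 0.5)),
      S0 = 1,
      beta1 = stats::runif(1, 0.6, 0.9),
      beta2 = stats::runif(1, 0.3, 0.5),
      beta3 = stats::runif(1, 0.7, 1.0),
      alpha4 = stats::runif(1, 0.03, 0.08),
      alpha5_0 = stats::runif(1, 0.008, 0.02),
      E_end = E_end,
      c_tbv = stats::runif(1, 4000, 6500),
      rbc_lifespan = stats::runif(1, 37.7, 115.8),
      T_half = stats::runif(1, 0.25, 0.4)
    ), silent = TRUE)
    if (!inherits(p, "try-error")) {
      cal <- try(calibrate_patient(p, target_hgb = stats::runif(1, 7.5, 9.2)),
                 silent = TRUE)
      if (!inherits(cal, "try-error")) return(cal)
      last_err <- attr(cal, "condition")
    } else last_err <- attr(p, "condition")
  }
  stop("could not generate a calibrated patient after ", max_tries,
       " tries: ", conditionMessage(last_err), call. = FALSE)
}

#' Default five-patient synthetic cohort
#'
#' One patient far above the neocytolysis threshold, two just below, two
#' clearly below, with fixed seeds -- the package's stand-in study cohort.
#' Each record carries a recommended control-cost constant (attribute
#' `c_gamma`) chosen by [recommend_c_gamma()], since the penalization must
#' be tuned on a per-patient level so that control costs do not block the
#' controller from reaching the target range.
#'
#' @param seeds Integer seeds, one per patient.
#' @return Named list of five calibrated patients.
#' @export
default_cohort <- function(seeds = 1:5) {
  profiles <- c("high_Eend", "near_threshold", "near_threshold",
                "low_Eend", "low_Eend")
  stopifnot(length(seeds) == length(profiles))
  out <- Map(generate_patient, seed = seeds, profile = profiles)
  out <- lapply(out, function(p) {
    attr(p, "c_gamma") <- recommend_c_gamma(p)
    p
  })
  names(out) <- sprintf("patient%d_%s", seq_along(out), profiles)
  out
}

#' Recommend a control-cost constant for a patient
#'
#' The control weight must not block the controller from holding the Hgb
#' target: at the maintenance dose `u*` (the constant rate whose steady
#' state sits at the target Hgb, found by bisection on the fixed-EPO
#' equilibrium), the marginal control cost `gamma u*` competes with the
#' tracking gradient and shifts the closed-loop equilibrium below the
#' setpoint.  Patients with a high maintenance dose therefore get the
#' weaker penalization: `c_gamma = 0.1` for `u* <= 300` U/day and `0.01`
#' above.
#'
#' @param p Calibrated patient record.
#' @param target_hgb Setpoint (g/dl), default 10.5.
#' @param u_max Dose cap (U/day), default 1000.
#' @return A control-cost constant (0.1 or 0.01).
#' @export
recommend_c_gamma <- function(p, target_hgb = 10.5, u_max = 1000) {
  u_star <- maintenance_dose(p, target_hgb, u_max)
  if (is.na(u_star) || u_star > 300) 0.01 else 0.1
}

#' @rdname recommend_c_gamma
#' @details `maintenance_dose()` returns the constant rate whose fixed-EPO
#'   steady state has Hgb equal to `target_hgb` (`NA` if the cap cannot
#'   reach it), by bisection over the admissible steady EPO range.
#' @export
maintenance_dose <- function(p, target_hgb = 10.5, u_max = 1000) {
  vol_lam <- epo_volume(p) * p$lambda
  f <- function(u) steady_state(p, E = p$E_end + u / vol_lam)$hgb - target_hgb
  if (f(0) >= 0) return(0)
  if (f(u_max) <= 0) return(NA_real_)
  stats::uniroot(f, c(0, u_max), tol = 0.5)$root
}

PATIENT_SCHEMA_VERSION <- "1"

#' Write / read a patient record as a flat key-value file
#'
#' Human-readable `key = value` serialization (Debian-control style) with a
#' schema version field.  Numeric values are written with 17 significant
#' digits, so a write/read round trip reproduces the record bit-exactly.
#'
#' @param p Patient parameter record.
#' @param path File path.
#' @return `read_patient()` returns an `"epo_patient"`; `write_patient()`
#'   returns `path` invisibly.
#' @export
write_patient <- function(p, path) {
  stopifnot(inherits(p, "epo_patient"))
  num <- function(x) paste(sprintf("%.17g", x), collapse = " ")
  fields <- c(
    schema = PATIENT_SCHEMA_VERSION,
    mu = num(p$mu), S0 = num(p$S0),
    beta1 = num(p$beta1), beta2 = num(p$beta2), beta3 = num(p$beta3),
    alpha4 = num(p$alpha4), alpha5_0 = num(p$alpha5_0),
    E_end = num(p$E_end), c_tbv = num(p$c_tbv),
    rbc_lifespan = num(p$rbc_lifespan), E_ex0 = num(p$E_ex0),
    T_half = num(p$T_half), tau_E = num(p$tau_E),
    neo_window = num(p$neo_window), MCH = num(p$MCH),
    epsilon = num(p$epsilon), epsilon_R = num(p$epsilon_R),
    calibrated = if (isTRUE(attr(p, "calibrated"))) "TRUE" else "FALSE"
  )
  writeLines(paste(names(fields), "=", fields), path)
  invisible(path)
}

#' @rdname write_patient
#' @export
read_patient <- function(path) {
  ln <- readLines(path)
  ln <- ln[nzchar(trimws(ln))]
  kv <- regmatches(ln, regexec("^\\s*([A-Za-z0-9_]+)\\s*=\\s*(.*)$", ln))
  keys <- vapply(kv, `[`, "", 2)
  vals <- vapply(kv, `[`, "", 3)
  names(vals) <- keys
  if (!identical(unname(vals["schema"]), PATIENT_SCHEMA_VERSION))
    stop("unsupported patient schema version: ", vals["schema"], call. = FALSE)
  num <- function(k) as.numeric(strsplit(trimws(vals[[k]]), "\\s+")[[1]])
  p <- patient_params(
    mu = num("mu"), S0 = num("S0"), beta1 = num("beta1"),
    beta2 = num("beta2"), beta3 = num("beta3"), alpha4 = num("alpha4"),
    alpha5_0 = num("alpha5_0"), E_end = num("E_end"), c_tbv = num("c_tbv"),
    rbc_lifespan = num("rbc_lifespan"), E_ex0 = num("E_ex0"),
    T_half = num("T_half"), tau_E = num("tau_E"),
    neo_window = num("neo_window"), MCH = num("MCH"),
    epsilon = num("epsilon"), epsilon_R = num("epsilon_R"))
  if (identical(unname(vals["calibrated"]), "TRUE"))
    attr(p, "calibrated") <- TRUE
  p
}
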