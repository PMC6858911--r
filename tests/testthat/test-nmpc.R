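test_that("the horizon rule maps constant periods to prediction horizons", {
  expect_equal(nmpc_config(period = 1)$horizon, 28)
  expect_equal(nmpc_config(period = 7)$horizon, 28)
  expect_equal(nmpc_config(period = 14)$horizon, 42)
  expect_equal(nmpc_config(period = 21)$horizon, 42)
  expect_equal(nmpc_config(period = 28)$horizon, 56)
  expect_equal(nmpc_config(period = 7)$M, 4L)
  expect_equal(nmpc_config(period = 28)$M, 2L)
  expect_error(nmpc_config(period = 5), "multiple")
  expect_error(nmpc_config(period = 1, T_total = 100.5), "multiple")
})

test_that("control weights follow the horizon scaling rules", {
  p <- test_patient
  # gamma multiplies by the days per constant period; sigma_O by 1/horizon
  cfg1 <- cost_config(p, M = 28, period = 1, c_gamma = 0.1)
  cfg7 <- cost_config(p, M = 4, period = 7, c_gamma = 0.1)
  expect_equal(cfg1$gamma, 0.1 / 28)
  expect_equal(cfg7$gamma, 0.1 * 7 / 28)
  expect_equal(cfg1$sigma_O * cfg1$horizon, 1e4)
  expect_equal(cfg1$sigma_f, 1e3)
  expect_equal(cfg1$r, 2 * p$MCH / (p$c_tbv * 1e10))
})

test_that("scenario containers validate their fields", {
  expect_error(scenario_events(bleeds = data.frame(day = 3)), "target_hgb")
  expect_error(scenario_events(overrides = data.frame(day = 3)), "rate")
  sc <- scenario_events(bleeds = data.frame(day = 10, target_hgb = 7.5),
                        missed = c(4, 5), overrides = NULL)
  expect_s3_class(sc, "epo_scenario")
})

test_that("closed-loop runs are deterministic and respect the dose cap", {
  p <- test_patient
  cfgn <- nmpc_config(T_total = 10)
  r1 <- run_closed_loop(p, cfgn)
  r2 <- run_closed_loop(p, cfgn)
  expect_identical(r1$days, r2$days)
  expect_identical(r1$fine$hgb, r2$fine$hgb)
  expect_true(all(r1$days$applied >= 0 & r1$days$applied <= cfgn$u_max))
  expect_equal(r1$total_dose, sum(r1$days$applied))
})

test_that("a dominant control penalty reproduces the uncontrolled trajectory", {
  p <- test_patient
  r <- run_closed_loop(p, nmpc_config(T_total = 14, c_gamma = 1e4 * 0.1))
  expect_lt(max(r$days$applied), 2)
  expect_lt(max(abs(r$fine$hgb - test_ss$hgb)), 0.05)
})

test_that("with no events the plant follows the controller's own prediction", {
  # plant = model: the one-interval-ahead open-loop prediction must match
  # the plant state reached by applying the first control
  p <- test_patient
  prec <- operator_precompute(p)
  config <- nmpc_config(T_total = 4, pred_dt = 0.01)  # matched grids
  cfg <- cost_config(p, M = config$M, period = 1, c_gamma = 0.1, dt = 0.01)
  sol <- solve_open_loop(test_ss$coef, 0, cfg, p, prec = prec, pgtol = 1e-4,
                         maxit = 60)
  Evec <- epodose:::interval_Evec(0, sol$u[1], 100, 0.01, p)
  pred <- epodose:::cpp_simulate(test_ss$coef, Evec, prec, 0.01, FALSE)
  r <- run_closed_loop(p, config)
  plant_day1 <- r$fine$hgb[abs(r$fine$time - 1) < 1e-9][1]
  expect_equal(hgb(1e8 * pred$P[101], p$c_tbv, p$MCH), plant_day1,
               tolerance = 1e-6)
})

test_that("missed administrations force zero applied rate and are logged", {
  p <- test_patient
  sc <- scenario_events(missed = c(2, 3))
  r <- run_closed_loop(p, nmpc_config(T_total = 6), scenario = sc)
  expect_equal(r$days$applied[r$days$day %in% c(2, 3)], c(0, 0))
  expect_true(all(r$days$applied[!r$days$day %in% c(2, 3)] ==
                    r$days$commanded[!r$days$day %in% c(2, 3)]))
  kinds <- vapply(r$events, `[[`, "", "kind")
  expect_equal(sum(kinds == "missed"), 2)
})

test_that("override events may exceed the cap and are applied verbatim", {
  p <- test_patient
  sc <- scenario_events(overrides = data.frame(day = 1, rate = 1500))
  r <- run_closed_loop(p, nmpc_config(T_total = 3), scenario = sc)
  expect_equal(r$days$applied[r$days$day == 1], 1500)
})

test_that("a mid-run bleed triggers cap-level dosing then recovery", {
  p <- test_patient
  sc <- scenario_events(bleeds = data.frame(day = 28, target_hgb = 7.5))
  r <- cached_run("bleed56", run_closed_loop(p, nmpc_config(T_total = 56),
                                             scenario = sc))
  h <- r$fine
  # the drop is visible at day 28
  expect_lt(h$hgb[abs(h$time - 28.01) < 1e-9][1], 8)
  # the controller responds with (near-)maximal rates shortly after
  expect_gt(max(r$days$applied[r$days$day %in% 28:35]), 0.95 * 1000)
  # and the Hgb recovers towards the target without exceeding 12
  expect_gt(max(h$hgb[h$time > 28]), 9.5)
  expect_lt(max(h$hgb), 12)
})

test_that("the experiment grid returns one tidy row per cell", {
  p <- test_patient
  tab <- run_experiment_grid(p, c_gamma = c(0.1, 10), periods = 7,
                             T_total = 28, transient_end = 14)
  expect_equal(nrow(tab), 2)
  expect_true(all(tab$ok))
  expect_true(all(c("total_dose", "mean_hgb", "time_in_range",
                    "oscillation", "max_rate") %in% names(tab)))
  expect_gte(tab$total_dose[1], tab$total_dose[2])  # stronger penalty: less drug
})
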