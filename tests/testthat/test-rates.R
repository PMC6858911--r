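test_that("regularized Heaviside has exact plateaus and the printed mid value", {
  for (eps in c(0.5, 1, 2)) {
    expect_identical(heaviside_reg(0, eps), 0)
    expect_identical(heaviside_reg(-3, eps), 0)
    expect_identical(heaviside_reg(eps, eps), 1)
    expect_identical(heaviside_reg(eps + 2, eps), 1)
    # s^4/eps^6 (10 s^2 - 24 eps s + 15 eps^2) at s = eps/2 is 11/32
    expect_equal(heaviside_reg(eps / 2, eps), 0.34375)
    expect_true(all(diff(heaviside_reg(seq(0, eps, length = 50), eps)) >= 0))
  }
})

test_that("regularized Heaviside joins are C^2 (derivatives vanish at 0 and eps)", {
  eps <- 1
  h <- 1e-4
  num_d <- function(s) (heaviside_reg(s + h, eps) - heaviside_reg(s - h, eps)) / (2 * h)
  num_d2 <- function(s) (heaviside_reg(s + h, eps) - 2 * heaviside_reg(s, eps) +
                           heaviside_reg(s - h, eps)) / h^2
  # central differences at the joins see only the O(h^2)/O(h) truncation of
  # the (discontinuous) third derivative, not a genuine kink
  expect_lt(abs(num_d(0)), 1e-6)
  expect_lt(abs(num_d(eps)), 1e-6)
  expect_lt(abs(num_d2(0)), 1e-2)
  expect_lt(abs(num_d2(eps)), 1e-2)
  # analytic derivative matches finite differences inside the band
  s <- seq(0.05, 0.95, by = 0.1)
  expect_equal(heaviside_reg_d(s, eps), num_d(s), tolerance = 1e-6)
})

test_that("smooth_min equals min outside the band and interpolates inside", {
  eps <- 0.5; tau <- 2
  expect_equal(smooth_min(c(2, 2.5, 10), tau, eps), rep(tau, 3))
  s_lo <- c(-1, 0, 1.5)
  expect_equal(smooth_min(s_lo, tau, eps), s_lo)
  mid <- smooth_min(tau - eps / 2, tau, eps)
  expect_gt(mid, min(tau - eps / 2, tau) - 1e-12)
  expect_lt(mid, tau)
})

test_that("alpha2 and nu are sigmoids with the expected midpoints and limits", {
  p <- test_patient
  expect_equal(alpha2(p$mu[3] / p$mu[2], p), p$mu[1] / 2)
  expect_equal(nu_rate(p$mu[7] / p$mu[6], p), (p$mu[4] + p$mu[5]) / 2)
  expect_lt(alpha2(1e6, p), 1e-10)
  expect_equal(nu_rate(1e6, p), p$mu[4])
  E <- seq(5, 400, by = 5)
  expect_true(all(diff(alpha2(E, p)) < 0))        # strictly decreasing
  expect_true(all(diff(nu_rate(E, p)) > 0))       # strictly increasing
  expect_true(all(alpha2(E, p) > 0 & alpha2(E, p) < p$mu[1]))
  expect_true(all(nu_rate(E, p) > p$mu[5] & nu_rate(E, p) < p$mu[4]))
})

test_that("regularized erythrocyte mortality collapses to baseline as required", {
  p <- test_patient
  x_in <- 5; x_out <- p$neo_window[2] + 5
  # above threshold, or outside the age window: exactly alpha5_0
  expect_identical(alpha5_reg(x_in, p$tau_E, p), p$alpha5_0)
  expect_identical(alpha5_reg(x_in, p$tau_E + 40, p), p$alpha5_0)
  expect_identical(alpha5_reg(x_out, 30, p), p$alpha5_0)
  # far from both regularization bands: exactly the unregularized formula
  E <- 40
  stopifnot(E <= p$tau_E - p$epsilon,
            p$mu[8] / E^p$mu[9] <= p$mu[10] - p$epsilon_R)
  expect_equal(alpha5_reg(x_in, E, p), p$alpha5_0 + p$mu[8] / E^p$mu[9])
  # below the cap region the rate is capped near mu10
  E_small <- 5
  expect_lte(alpha5_reg(x_in, E_small, p), p$alpha5_0 + p$mu[10] + 1e-12)
})

test_that("alpha5 regularization converges pointwise as widths shrink", {
  p <- test_patient
  E <- seq(20, 120, by = 0.5)
  exact <- p$alpha5_0 +
    ifelse(E < p$tau_E, pmin(p$mu[8] / E^p$mu[9], p$mu[10]), 0)
  err <- function(eps) {
    q <- p; q$epsilon <- eps; q$epsilon_R <- eps / 50
    max(abs(sapply(E, function(e) alpha5_reg(5, e, q)) - exact))
  }
  errs <- vapply(c(1, 0.3, 0.1, 0.03), err, numeric(1))
  expect_true(all(diff(errs) <= 1e-12))
  expect_lt(errs[length(errs)], 0.01)
})

test_that("rate functions stay finite and smooth over the admissible range", {
  p <- test_patient
  E <- seq(p$E_end * 0.1, 10 * p$tau_E, length.out = 400)
  vals <- c(alpha2(E, p), nu_rate(E, p),
            vapply(E, function(e) neo_excess(e, p), numeric(1)))
  expect_true(all(is.finite(vals)))
})

test_that("boundary influx follows the class-coupling rules", {
  p <- test_patient
  E <- 60
  expect_identical(boundary_influx(1, 123, E, p), p$S0)
  expect_identical(boundary_influx(1, NA, 999, p), p$S0)
  expect_equal(boundary_influx(2, 7, E, p), 7)
  expect_equal(boundary_influx(3, 7, E, p), 7)
  expect_equal(boundary_influx(4, 7, E, p), 7 / nu_rate(E, p))
  expect_equal(boundary_influx(4, 0, E, p), 0)
  expect_equal(boundary_influx(5, 7, E, p), 7 * nu_rate(E, p))
  expect_error(boundary_influx(6, 1, E, p), "class index")
})

test_that("class-4 transport conserves throughput when apoptosis is off", {
  # cells/day leaving class 3 equal cells/day entering class 5 for alpha4 = 0
  p <- test_patient
  p$alpha4 <- 0
  for (E in c(45, 90)) {
    ss <- steady_state(p, E = E)
    b3 <- spectral_basis(15, 5)
    b4 <- spectral_basis(15, 2.5)
    out3 <- sum(ss$coef[, 3] * b3$e1)             # y3 at its upper bound
    in5 <- nu_rate(E, p) * sum(ss$coef[, 4] * b4$e1)
    expect_equal(in5, out3, tolerance = 1e-8)
  }
})
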