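test_that("Legendre recursion reproduces the closed forms and symmetries", {
  x <- seq(-1, 1, by = 0.1)
  expect_equal(legendre_eval(2, 0), -0.5)
  expect_equal(legendre_eval(2, x), (3 * x^2 - 1) / 2)
  expect_equal(legendre_eval(3, x), (5 * x^3 - 3 * x) / 2)
  expect_equal(legendre_eval(4, x), (35 * x^4 - 30 * x^2 + 3) / 8)
  for (j in 0:14) {
    expect_equal(legendre_eval(j, 1), 1)
    expect_equal(legendre_eval(j, -x), (-1)^j * legendre_eval(j, x))
  }
})

test_that("derivative expansion matrix reconstructs L_j'", {
  D <- legendre_deriv_matrix(15)
  expect_identical(D[1, ], rep(0, 15))            # L0' = 0
  expect_equal(D[2, ], c(1, rep(0, 14)))          # L1' = L0
  expect_true(all(D[upper.tri(D, diag = TRUE)] == 0))  # strictly lower
  x <- seq(-0.95, 0.95, by = 0.05)
  h <- 1e-6
  V <- sapply(0:14, function(j) legendre_eval(j, x))
  for (j in 2:14) {
    num <- (legendre_eval(j, x + h) - legendre_eval(j, x - h)) / (2 * h)
    expect_lt(max(abs(V %*% D[j + 1, ] - num)), 1e-8)
  }
})

test_that("shifted basis satisfies the norm and boundary identities", {
  for (w in c(3, 5, 76)) {
    b <- spectral_basis(15, w)
    j <- 0:14
    expect_equal(b$norm2, 1 / (2 * j + 1))
    expect_equal(b$e1, rep(w^(-1 / 2), 15))
    expect_equal(b$e0, (-1)^j * w^(-1 / 2))
    # orthogonality under the weighted inner product, by exact quadrature
    g <- pracma::gaussLegendre(32, 0, 1)
    V <- sapply(j, function(k) legendre_eval(k, 2 * g$x - 1)) / sqrt(w)
    G <- w * crossprod(V, g$w * V)
    expect_lt(max(abs(G - diag(1 / (2 * j + 1)))), 1e-12)
  }
})

test_that("delta representer reproduces evaluation at the inflow boundary", {
  b <- spectral_basis(15, 5)
  dlt <- delta_representer(b)
  # <delta, e0>_w = e0(0)
  expect_equal(sum(dlt * 1 * b$norm2 * c(1, rep(0, 14))) / 1, b$e0[1] * b$norm2[1] / b$norm2[1],
               tolerance = 1e-12)
  set.seed(5)
  for (rep in 1:20) {
    co <- stats::rnorm(15)
    lhs <- sum(dlt * co * b$norm2)          # <delta, phi>_w
    rhs <- reconstruct_density(co, b, 0)    # phi(0)
    expect_equal(lhs, rhs, tolerance = 1e-12 * max(1, abs(rhs)))
  }
  b1 <- spectral_basis(1, 5)
  expect_equal(delta_representer(b1), b1$e0[1] / b1$norm2[1])
})

test_that("projection is the identity on the span and exact for constants", {
  b <- spectral_basis(15, 5)
  set.seed(9)
  co <- stats::rnorm(15)
  back <- project_fn(function(xi) reconstruct_density(co, b, xi), b)
  expect_equal(back, co, tolerance = 1e-10)
  cc <- project_fn(function(xi) rep(4.2, length(xi)), b)
  expect_equal(cc, c(4.2 * sqrt(5), rep(0, 14)), tolerance = 1e-12)
})

test_that("projection of an indicator matches analytic Legendre integrals", {
  # int_0^a L_j(2xi-1) dxi = (P_{j+1}(c) - P_{j-1}(c)) / (2(2j+1)) at c = 2a-1,
  # measured from the lower end; antiderivative of L_j is
  # (L_{j+1} - L_{j-1}) / (2j+1) / ... on [-1, 1] with dx = 2 dxi.
  b <- spectral_basis(10, 2)
  a <- 0.37
  co <- project_fn(function(xi) as.numeric(xi <= a), b, breaks = a)
  c1 <- 2 * a - 1
  analytic <- numeric(10)
  analytic[1] <- a                                   # degree 0
  for (j in 1:9) {
    analytic[j + 1] <- (legendre_eval(j + 1, c1) - legendre_eval(j - 1, c1)) /
      (2 * (2 * j + 1))
  }
  expected <- analytic * sqrt(2) / b$norm2
  expect_equal(co, expected, tolerance = 1e-10)
})

test_that("assembled operator matches its defining action on the span", {
  p <- test_patient
  geom <- class_geometry(p)
  set.seed(13)
  for (i in c(2L, 4L, 5L)) {
    w <- geom$width[i]
    b <- spectral_basis(12, w)
    E <- 58
    op <- assemble_operator(i, E, p, b)
    co <- stats::rnorm(12)
    # direct evaluation of -(v/w) phi' + P(kappa phi) - delta phi(0)
    v <- velocity(i, E, p)
    phi0 <- reconstruct_density(co, b, 0)
    adv <- -(v / w) * drop(t(b$Dxi) %*% co)
    reac <- project_fn(function(xi)
      kappa_rate(i, geom$lower[i] + w * xi, E, p) *
        reconstruct_density(co, b, xi), b,
      breaks = if (i == 5L) p$neo_window / w)
    dlt <- -delta_representer(b) * phi0
    direct <- adv + reac + dlt
    expect_lt(max(abs(drop(op$A %*% co) - direct)) / max(abs(direct)), 1e-10)
  }
})

test_that("class-1 operator is EPO-independent; class-5 loses the neo term at high EPO", {
  p <- test_patient
  A_a <- assemble_operator(1, 20, p)$A
  A_b <- assemble_operator(1, 300, p)$A
  expect_identical(A_a, A_b)
  # at E >= tau_E the erythrocyte operator equals the baseline-mortality one
  A5 <- assemble_operator(5, p$tau_E + 5, p)$A
  q <- p; q$mu[10] <- 1e-12                # kill the neocytolysis term
  A5_base <- assemble_operator(5, 40, q)$A
  expect_equal(A5, A5_base, tolerance = 1e-12)
})

test_that("class-1 steady state converges spectrally to S0 exp(beta1 x)", {
  p <- test_patient
  xi <- seq(0, 1, length.out = 401)
  exact <- p$S0 * exp(p$beta1 * 3 * xi)
  relerr <- function(N) {
    b <- spectral_basis(N, 3)
    y <- steady_state_class(1, p$E_end, p$S0, p, b)
    approxv <- reconstruct_density(y, b, xi)
    sqrt(mean((approxv - exact)^2) / mean(exact^2))
  }
  errs <- vapply(c(4, 8, 12, 15), relerr, numeric(1))
  expect_true(all(diff(log(errs)) < 0))            # monotone decay
  expect_lt(errs[4], 1e-6)
  # decay is faster than any fixed polynomial rate: successive ratios shrink
  rates <- diff(log(errs)) / diff(log(c(4, 8, 12, 15)))
  expect_lt(rates[3], rates[1])
})

test_that("steady state is linear in the stem-cell influx", {
  p <- test_patient
  ss1 <- steady_state(p)
  p2 <- p; p2$S0 <- 2 * p$S0
  ss2 <- steady_state(p2)
  expect_equal(ss2$coef, 2 * ss1$coef, tolerance = 1e-12)
  expect_equal(ss2$P, 2 * ss1$P, tolerance = 1e-12)
})

test_that("total population identity: first coefficient equals the quadrature", {
  p <- test_patient
  ss <- steady_state(p)
  w5 <- class_geometry(p)$width[5]
  b5 <- spectral_basis(15, w5)
  g <- pracma::gaussLegendre(64, 0, 1)
  quad <- w5 * sum(g$w * reconstruct_density(ss$coef[, 5], b5, g$x))
  expect_equal(ss$P / 1e8, sqrt(w5) * ss$coef[1, 5], tolerance = 1e-12)
  expect_equal(quad, sqrt(w5) * ss$coef[1, 5], tolerance = 1e-10)
})

test_that("singular steady-state systems are reported", {
  # with a single basis function the class-1 operator is beta1 - 1/w,
  # singular exactly at beta1 = 1/w
  q <- test_patient
  q$beta1 <- (1 / sqrt(3))^2     # floating-point-exact match of the delta term
  b1 <- spectral_basis(1, 3)
  expect_error(steady_state_class(1, q$E_end, q$S0, q, b1), "singular")
})
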