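# Longitudinal trajectory, hazard and conditional survival.

test_that("natural-spline basis matches splines::ns and its analytic
          derivative matches finite differences", {
  k <- c(0.1, 0.5, 4); b <- c(0, 7)
  x <- c(seq(0, 7, length.out = 31), -0.5, 7.5, 9)
  expect_equal(nsBasis(x, k, b),
               unclass(splines::ns(x, knots = k, Boundary.knots = b)),
               ignore_attr = TRUE, tolerance = 1e-12)
  h <- 1e-6
  fd <- (nsBasis(x + h, k, b) - nsBasis(x - h, k, b)) / (2 * h)
  expect_equal(nsBasis(x, k, b, deriv = 1), fd, tolerance = 1e-6)
})

test_that("trajectory handles the zero and linear special cases and rejects
          mismatched random effects", {
  sp0 <- longitudinalSpec(beta = rep(0, 7), D = diag(3), sigma = 0.3)
  tr <- psaTrajectory(sp0, age = 70, b = rep(0, 3), t = c(0.5, 3))
  expect_equal(tr$value, c(0, 0))
  expect_equal(tr$velocity, c(0, 0))

  lin <- longitudinalSpec(beta = c(1, 2), D = matrix(1), sigma = 0.1,
                          include_age = FALSE, fixed_time_basis = "linear",
                          random_time_basis = "none")
  tr2 <- psaTrajectory(lin, age = 70, b = 0, t = 3)
  expect_equal(tr2$value, 7)
  expect_equal(tr2$velocity, 2)

  expect_error(psaTrajectory(sp0, age = 70, b = rep(0, 2), t = 1),
               "random design")
})

test_that("trajectory velocity agrees with a central finite difference for
          random specs", {
  set.seed(42)
  for (rep in 1:5) {
    sp <- longitudinalSpec(beta = rnorm(7), D = diag(3), sigma = 0.3)
    b <- rnorm(3)
    age <- runif(1, 55, 75)
    tt <- runif(6, 0.05, 6.9)
    h <- 1e-5
    fd <- (psaTrajectory(sp, age, b, tt + h)$value -
             psaTrajectory(sp, age, b, tt - h)$value) / (2 * h)
    expect_equal(psaTrajectory(sp, age, b, tt)$velocity, fd,
                 tolerance = 1e-6)
  }
})

test_that("hazard has the Weibull closed form when associations vanish", {
  p <- fullParams()
  rk <- riskSpec(gamma = c(0, 0), alpha_value = 0, alpha_velocity = 0,
                 baseline = weibullHazard(3, 5), form = "value")
  expect_equal(hazardRate(rk, p$long, 70, rep(0, 3), 2.5),
               (3 / 5) * (2.5 / 5)^2)
  expect_equal(hazardRate(rk, p$long, 70, rep(0, 3), 2.5), 0.15)
  expect_error(hazardRate(rk, p$long, 70, rep(0, 3), -1), "t must be")
})

test_that("piecewise-constant baseline with constant trajectory gives a
          constant hazard", {
  lin <- longitudinalSpec(beta = c(2, 0), D = matrix(1), sigma = 0.1,
                          include_age = FALSE, fixed_time_basis = "linear",
                          random_time_basis = "none")
  rk <- riskSpec(gamma = c(0, 0), alpha_value = 0.4, alpha_velocity = 0,
                 baseline = piecewiseHazard(numeric(), 0.7), form = "value")
  hs <- hazardRate(rk, lin, 70, 0, c(0.5, 2, 8))
  expect_equal(hs, rep(0.7 * exp(0.4 * 2), 3))
})

test_that("a 0.2 velocity increase multiplies the hazard by 2.05 at the
          default association", {
  p <- fullParams()
  a2 <- p$risk$alpha_velocity
  lin <- longitudinalSpec(beta = c(2, 0), D = diag(2), sigma = 0.1,
                          include_age = FALSE, fixed_time_basis = "linear",
                          random_time_basis = "linear")
  rk <- riskSpec(gamma = c(0, 0), alpha_value = 0, alpha_velocity = a2,
                 baseline = weibullHazard(3, 5))
  h_slow <- hazardRate(rk, lin, 70, c(0, -0.06), 2)
  h_fast <- hazardRate(rk, lin, 70, c(0, 0.14), 2)
  expect_equal(h_fast / h_slow, 2.05, tolerance = 1e-10)
})

test_that("conditional survival matches the Weibull closed form and a dense
          trapezoid oracle", {
  p <- fullParams()
  rk0 <- riskSpec(gamma = c(0, 0), alpha_value = 0, alpha_velocity = 0,
                  baseline = weibullHazard(1.5, 4), form = "value")
  for (tt in list(c(0, 2), c(1, 4), c(0.5, 9))) {
    expect_equal(conditionalSurvival(rk0, p$long, 70, rep(0, 3),
                                     tt[1], tt[2]),
                 exp(-((tt[2] / 4)^1.5 - (tt[1] / 4)^1.5)),
                 tolerance = 1e-8)
  }
  expect_equal(conditionalSurvival(rk0, p$long, 70, rep(0, 3), 3, 3), 1)
  expect_error(conditionalSurvival(rk0, p$long, 70, rep(0, 3), 3, 2),
               "t0 <= t1")

  ## time-varying trajectory in the hazard: compare to dense trapezoid
  set.seed(7)
  b <- drop(rnorm(3) %*% chol(p$long$D))
  g <- seq(0.5, 6, length.out = 1e5)
  hz <- hazardRate(p$risk, p$long, 66, b, g)
  expect_equal(conditionalSurvival(p$risk, p$long, 66, b, 0.5, 6),
               exp(-trapz(g, hz)), tolerance = 1e-6)
})

test_that("conditional survival is multiplicative and non-increasing", {
  p <- fullParams()
  set.seed(8)
  for (rep in 1:3) {
    b <- drop(rnorm(3) %*% chol(p$long$D))
    s01 <- conditionalSurvival(p$risk, p$long, 66, b, 0.5, 2)
    s12 <- conditionalSurvival(p$risk, p$long, 66, b, 2, 5)
    s02 <- conditionalSurvival(p$risk, p$long, 66, b, 0.5, 5)
    expect_equal(s02, s01 * s12, tolerance = 1e-8)
    expect_lte(s02, s01 + 1e-12)
  }
})

test_that("hazard is invariant to shifting the trajectory intercept when the
          value association is compensated through the age covariate", {
  p <- fullParams()
  cshift <- 0.8
  lg2 <- p$long
  lg2$beta[1] <- lg2$beta[1] + cshift
  ## at age 71, w = (1, 1): absorb -alpha1 * c into gamma1
  rk2 <- p$risk
  rk2$gamma[1] <- rk2$gamma[1] - p$risk$alpha_value * cshift
  b <- c(0.2, -0.1, 0.3)
  expect_equal(hazardRate(p$risk, p$long, 71, b, c(1, 3, 6)),
               hazardRate(rk2, lg2, 71, b, c(1, 3, 6)),
               tolerance = 1e-10)
})

test_that("parameter bundles round-trip through the YAML serialization", {
  p <- fullParams()
  f <- tempfile(fileext = ".yml")
  writeModelParameters(p, f)
  p2 <- readModelParameters(f)
  expect_equal(p2$long$beta, p$long$beta, tolerance = 1e-12)
  expect_equal(p2$long$D, p$long$D, tolerance = 1e-12)
  expect_equal(p2$risk$alpha_velocity, p$risk$alpha_velocity)
  expect_equal(p2$risk$baseline$scale, p$risk$baseline$scale)
  pc <- modelParameters(p$long,
                        riskSpec(baseline = piecewiseHazard(c(1, 3),
                                                            c(0.1, 0.2, 0.3))))
  writeModelParameters(pc, f)
  expect_equal(readCohortSafe <- readModelParameters(f)$risk$baseline$rates,
               c(0.1, 0.2, 0.3))
  unlink(f)
})

test_that("invalid specifications are rejected", {
  expect_error(longitudinalSpec(beta = rep(0, 7), D = diag(c(1, -1, 1)),
                                sigma = 0.3), "positive-definite")
  expect_error(longitudinalSpec(beta = rep(0, 6), D = diag(3), sigma = 0.3),
               "length")
  expect_error(longitudinalSpec(beta = rep(0, 7), D = diag(3), sigma = -1),
               "sigma")
  expect_error(weibullHazard(-1, 2), "> 0")
  expect_error(piecewiseHazard(c(2, 1), c(1, 1, 1)), "increasing")
  expect_error(riskSpec(alpha_value = NA), "finite")
})
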