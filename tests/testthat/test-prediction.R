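# Posterior of the random effects and the predictive reclassification-time
# distribution.

test_that("with no information the posterior of b equals its prior", {
  ## huge residual scale and t = 0: likelihood is flat
  prm <- toyParams(sigma = 1e4, D0 = 0.49)
  hist <- patientHistory(psaTimes = c(0, 0.5, 1), psa = c(5, 6, 5.5),
                         age = 66, lastBiopsy = 0)
  pp <- posteriorRandomEffects(hist, prm, nDraws = 4000, seed = 1,
                               method = "mcmc")
  m <- sum(pp$weights * pp$draws[, 1])
  v <- sum(pp$weights * pp$draws[, 1]^2) - m^2
  expect_lt(abs(m), 3 * sqrt(0.49 / 1000))
  expect_equal(v, 0.49, tolerance = 0.1)
})

test_that("1-D posterior moments match dense-grid integration for both
          samplers", {
  prm <- toyParams(sigma = 0.25, D0 = 0.4, alpha_value = 0.4)
  tt <- seq(0, 2, by = 0.25)
  set.seed(5)
  psa <- 2^(2 + 0.1 * tt + 0.6 + 0.25 * rt(length(tt), 3))
  hist <- patientHistory(tt, psa, age = 66, lastBiopsy = 2)
  gp <- gridPosterior1D(hist, prm, seq(-4, 4, length.out = 4001))
  for (meth in c("mcmc", "laplace_is")) {
    pp <- posteriorRandomEffects(hist, prm, nDraws = 4000, seed = 11,
                                 method = meth)
    m <- sum(pp$weights * pp$draws[, 1])
    v <- sum(pp$weights * pp$draws[, 1]^2) - m^2
    expect_lt(abs(m - gp$mean), 0.01 * max(1, abs(gp$mean)))
    expect_lt(abs(v - gp$var), 0.05 * gp$var)
  }
})

test_that("conditioning on surviving a late biopsy lowers the posterior
          hazard relative to the PSA-only posterior", {
  prm <- toyParams(sigma = 0.25, D0 = 0.4, alpha_value = 0.8,
                   baseline = weibullHazard(1.5, 4))
  tt <- seq(0, 1, by = 0.25)
  psa <- 2^(2 + 0.1 * tt)
  bgrid <- seq(-4, 4, length.out = 2001)
  g_y <- gridPosterior1D(patientHistory(tt, psa, 66, lastBiopsy = 0),
                         prm, bgrid)
  g_yt <- gridPosterior1D(patientHistory(tt, psa, 66, lastBiopsy = 6),
                          prm, bgrid)
  h_at <- function(w) sum(w * vapply(bgrid, function(b)
    hazardRate(prm$risk, prm$long, 66, b, 6), numeric(1)))
  expect_lt(h_at(g_yt$w), h_at(g_y$w))
})

test_that("dynamic survival is 1 at t, non-increasing, and matches the grid
          oracle on the 1-D toy", {
  prm <- toyParams(sigma = 0.25, D0 = 0.4, alpha_value = 0.4)
  tt <- seq(0, 1.5, by = 0.25)
  psa <- 2^(2 + 0.1 * tt + 0.3)
  hist <- patientHistory(tt, psa, age = 66, lastBiopsy = 1.5)
  pp <- posteriorRandomEffects(hist, prm, nDraws = 2000, seed = 3,
                               method = "mcmc")
  expect_equal(dynamicSurvival(pp, pp$t), 1)
  grid <- seq(pp$t, 18, length.out = 40)
  piv <- dynamicSurvival(pp, grid)
  expect_true(all(diff(piv) <= 1e-12))
  expect_error(dynamicSurvival(pp, pp$t - 0.5), ">=")

  ## grid oracle: integrate S(t -> u | b) against the exact posterior
  bgrid <- seq(-4, 4, length.out = 801)
  gp <- gridPosterior1D(hist, prm, bgrid)
  for (u in c(3, 6, 10)) {
    Lg <- persched:::cumHazDraws(prm$risk, prm$long, 66, matrix(bgrid),
                                 persched:::panelEdges(pp$t, u))
    oracle <- sum(gp$w * exp(-Lg[, ncol(Lg)]))
    Ld <- persched:::cumHazDraws(prm$risk, prm$long, 66, pp$draws,
                                 persched:::panelEdges(pp$t, u))
    sdraw <- exp(-Ld[, ncol(Ld)])
    mcse <- 3 * sd(sdraw) / sqrt(length(sdraw))
    expect_lt(abs(dynamicSurvival(pp, u) - oracle), max(mcse, 0.02))
  }
})

test_that("the exponential toy has closed-form moments and median", {
  pp <- exponentialPP(t = 2, rate = 1)
  expect_equal(expectedGRTime(pp), 3, tolerance = 1e-5)
  expect_equal(varianceGRTime(pp), 1, tolerance = 1e-4)
  expect_equal(quantileGRTime(pp, 0.5), 2 + log(2), tolerance = 1e-4)
})

test_that("quadrature moments match a dense trapezoid oracle on a simulated
          predictive distribution", {
  p <- fullParams()
  cfg <- simConfig(n_patients = 2, train_fraction = 0, seed = 21)
  co <- simulateCohort(cfg, p)
  li <- co$longitudinal[co$longitudinal$id == 1, ]
  keep <- li$time <= 1.01
  hist <- patientHistory(li$time[keep], li$psa[keep],
                         age = co$events$age[1], lastBiopsy = 1)
  pp <- posteriorRandomEffects(hist, p, nDraws = 50, seed = 5,
                               method = "laplace_is")
  g <- seq(pp$t, pp$horizon, length.out = 2e4 + 1)
  piv <- piDense(pp, g)
  I1 <- trapz(g, piv)
  I2 <- trapz(g, (g - pp$t) * piv)
  expect_equal(expectedGRTime(pp), pp$t + I1, tolerance = 1e-5)
  expect_equal(varianceGRTime(pp), 2 * I2 - I1^2, tolerance = 1e-4)
})

test_that("a near-point-mass predictive distribution has E = T0 and zero
          variance", {
  ## hazard jumps from 0 to a huge rate at T0 = 6
  long <- longitudinalSpec(beta = 0, D = matrix(1e-8, 1, 1), sigma = 0.1,
                          include_age = FALSE, fixed_time_basis = "none",
                          random_time_basis = "none")
  risk <- riskSpec(gamma = c(0, 0), alpha_value = 0, alpha_velocity = 0,
                   baseline = piecewiseHazard(6, c(0, 1e4)), form = "value")
  pp <- posteriorPredictive(matrix(0, 1, 1), 1, modelParameters(long, risk),
                            age = 70, t = 2, s = 2)
  expect_equal(expectedGRTime(pp), 6, tolerance = 5e-3)
  expect_lt(varianceGRTime(pp), 1e-4)
})

test_that("quantiles invert the survival curve and flag censoring beyond the
          horizon", {
  pp <- exponentialPP(t = 1, rate = 0.8)
  for (prob in seq(0.1, 0.9, by = 0.2)) {
    qv <- quantileGRTime(pp, prob)
    expect_equal(dynamicSurvival(pp, qv), 1 - prob, tolerance = 1e-3)
  }
  slow <- exponentialPP(t = 1, rate = 0.005)   # pi(H) ~ 0.91
  med <- quantileGRTime(slow, 0.5)
  expect_equal(as.numeric(med), slow$horizon)
  expect_true(isTRUE(attr(med, "censored")))
})

test_that("conditioning on a later negative biopsy shrinks the predictive
          SD (common PSA information)", {
  ## the comparison isolates the conditioning: same PSA history, only the
  ## latest-negative-biopsy time moves
  p <- fullParams()
  cfg <- simConfig(n_patients = 25, subgroup_weibulls = list(c(3, 5)),
                   train_fraction = 0, seed = 31)
  co <- simulateCohort(cfg, p)
  ok <- 0; tot <- 0
  for (i in head(which(co$events$true_gr_time > 4), 12)) {
    li <- co$longitudinal[co$longitudinal$id == i, ]
    keep <- li$time <= 4.01
    sds <- sapply(c(1, 2, 4), function(tb) {
      hist <- patientHistory(li$time[keep], li$psa[keep],
                             age = co$events$age[i], lastBiopsy = tb)
      pp <- posteriorRandomEffects(hist, p, nDraws = 400,
                                   seed = 100 + i, method = "laplace_is")
      sqrt(varianceGRTime(pp))
    })
    tot <- tot + 1
    if (all(diff(sds) < 0.05)) ok <- ok + 1
  }
  expect_gte(ok / tot, 0.9)
})
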