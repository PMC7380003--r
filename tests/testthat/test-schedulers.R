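# Decision-theoretic proposals, the biopsy-timing algorithm, PSA doubling
# time and the fixed comparator grids.

test_that("PSA doubling time is the inverse log2 regression slope", {
  expect_equal(computePsaDT(c(0, 1, 2), c(4, 8, 16)), 1)
  expect_equal(computePsaDT(c(0, 1, 2), c(6, 6, 6)), Inf)
  ## hand least-squares oracle: slope of (1.0, 1.1, 1.4) on t = 0,1,2 is 0.2
  expect_equal(computePsaDT(c(0, 1, 2), 2^c(1.0, 1.1, 1.4)), 5,
               tolerance = 1e-10)
  expect_error(computePsaDT(1, 5), "2 distinct")
})

test_that("proposals have closed forms on the exponential toy", {
  pp <- exponentialPP(t = 2, rate = 1)
  expect_equal(proposeBiopsyTime(scheduler("median"), pp), 2 + log(2),
               tolerance = 1e-3)
  expect_equal(proposeBiopsyTime(scheduler("expected"), pp), 3,
               tolerance = 1e-3)
  ## multilinear loss: minimum at pi^-1(kappa); kappa = e^-1 -> u = t + 1
  expect_equal(proposeBiopsyTime(scheduler("dyn_risk", kappa = exp(-1)), pp),
               3, tolerance = 1e-3)
})

test_that("the hybrid rule uses the central rule when the spread is small
          and the risk rule when it is large", {
  ## tight: exponential with a fast rate -> spread under 3 years
  tight <- exponentialPP(t = 1, rate = 3)
  sch <- scheduler("hybrid", kappa = 0.9)
  expect_equal(proposeBiopsyTime(sch, tight),
               proposeBiopsyTime(scheduler("median"), tight),
               tolerance = 1e-6)
  ## diffuse: slow rate -> spread over 3 years -> dynamic-risk time
  wide <- exponentialPP(t = 1, rate = 0.2)
  expect_equal(proposeBiopsyTime(sch, wide),
               proposeBiopsyTime(scheduler("dyn_risk", kappa = 0.9), wide),
               tolerance = 1e-6)
  expect_lt(proposeBiopsyTime(sch, wide),
            proposeBiopsyTime(scheduler("median"), wide))
})

test_that("proposed times minimize the posterior expected loss against
          Monte-Carlo draws of the reclassification time", {
  set.seed(77)
  p <- fullParams()
  cfg <- simConfig(n_patients = 6, train_fraction = 0, seed = 21)
  co <- simulateCohort(cfg, p)
  for (i in 1:3) {
    li <- co$longitudinal[co$longitudinal$id == i, ]
    keep <- li$time <= 1.01
    hist <- patientHistory(li$time[keep], li$psa[keep],
                           age = co$events$age[i], lastBiopsy = 1)
    pp <- posteriorRandomEffects(hist, p, nDraws = 300, seed = 40 + i,
                                 method = "mcmc")
    ## draws of T* from the predictive distribution (truncated at horizon)
    idx <- sample.int(300, 3000, replace = TRUE, prob = pp$weights)
    Lh <- persched:::cumHazDraws(p$risk, p$long, pp$age, pp$draws,
                                 persched:::panelEdges(pp$t, pp$horizon,
                                                       0.1))
    edges <- persched:::panelEdges(pp$t, pp$horizon, 0.1)
    Ts <- vapply(seq_along(idx), function(j) {
      lam <- c(0, Lh[idx[j], ])
      tgt <- -log(runif(1))
      if (tgt >= lam[length(lam)]) return(pp$horizon)
      k <- which(lam >= tgt)[1]
      edges[k - 1] + (edges[k] - edges[k - 1]) *
        (tgt - lam[k - 1]) / (lam[k] - lam[k - 1])
    }, numeric(1))
    ug <- seq(pp$t, pp$horizon, by = 0.05)
    checkMin <- function(lossfun, proposal) {
      Lbar <- vapply(ug, function(u) mean(lossfun(Ts, u)), numeric(1))
      ## the proposal must attain (close to) the minimal MC expected loss
      Lprop <- mean(lossfun(Ts, proposal))
      expect_lte(Lprop, min(Lbar) + 3 * sd(lossfun(Ts, ug[which.min(Lbar)])) /
                   sqrt(length(Ts)))
    }
    checkMin(function(T, u) (T - u)^2,
             as.numeric(proposeBiopsyTime(scheduler("expected"), pp)))
    checkMin(function(T, u) abs(T - u),
             as.numeric(proposeBiopsyTime(scheduler("median"), pp)))
    for (kap in c(0.8, 0.9, 0.95)) {
      checkMin(function(T, u) ifelse(T > u, (1 - kap) * (T - u),
                                     kap * (u - T)),
               as.numeric(proposeBiopsyTime(scheduler("dyn_risk",
                                                      kappa = kap), pp)))
    }
  }
})

test_that("larger risk thresholds give earlier-or-equal proposals", {
  pp <- exponentialPP(t = 1, rate = 0.5)
  us <- vapply(c(0.5, 0.7, 0.9, 0.97), function(k)
    as.numeric(proposeBiopsyTime(scheduler("dyn_risk", kappa = k), pp)),
    numeric(1))
  expect_true(all(diff(us) <= 1e-6))
})

test_that("the timing algorithm postpones early proposals to t + 1 and
          defers proposals past the next visit", {
  ## proposal at 2.4 with latest biopsy at 2 -> biopsy at 3.0
  pp2 <- exponentialPP(t = 2, rate = log(2) / 0.4)    # median at 2.4
  d <- nextBiopsyDecision(scheduler("median"), pp2, s_nv = 3.5, s = 2.2)
  expect_equal(d$action, "biopsy")
  expect_equal(d$time, 3, tolerance = 1e-3)

  ## far proposal with an early next visit -> defer
  slow <- exponentialPP(t = 2, rate = 0.05)
  d2 <- nextBiopsyDecision(scheduler("median"), slow, s_nv = 4.5, s = 2.2)
  expect_equal(d2$action, "defer")
  expect_gt(d2$proposal, 10)

  ## boundary: proposal exactly t + 1 is allowed
  pp3 <- exponentialPP(t = 2, rate = log(2))          # median exactly 3
  d3 <- nextBiopsyDecision(scheduler("median"), pp3, s_nv = 3.2, s = 2.2)
  expect_equal(d3$action, "biopsy")
  expect_equal(d3$time, 3, tolerance = 1e-3)
})

test_that("fixed comparator grids follow the protocols", {
  expect_equal(fixedScheduleTimes("prias", horizon = 12), c(1, 4, 7, 10))
  expect_equal(fixedScheduleTimes("annual", horizon = 5), 1:5)
  expect_equal(fixedScheduleTimes("prias", horizon = 21),
               c(1, 4, 7, 10, 15, 20))
  ## doubling time of 2 years from entry -> annual from year 2
  tt <- seq(0, 12, by = 0.25)
  psa <- 4 * 2^(tt / 2)
  expect_equal(fixedScheduleTimes("prias", horizon = 8, psaTimes = tt,
                                  psa = psa), 1:8)
  ## non-rising PSA never triggers the switch
  expect_equal(fixedScheduleTimes("prias", horizon = 12,
                                  psaTimes = tt, psa = rep(6, length(tt))),
               c(1, 4, 7, 10))
})

test_that("every scheduler keeps consecutive biopsies at least one year
          apart", {
  p <- fullParams()
  cfg <- simConfig(n_patients = 12, train_fraction = 0, seed = 9)
  co <- simulateCohort(cfg, p)
  predP <- predictionParams(p, cfg)
  schs <- defaultSchedulers(kappa = 0.9)
  set.seed(5)
  for (i in 1:12) {
    li <- co$longitudinal[co$longitudinal$id == i, ]
    res <- persched:::evalSchedulesForPatient(
      list(psaTimes = li$time, psa = li$psa, age = co$events$age[i],
           trueT = co$events$true_gr_time[i]),
      schs, predP, schedControl(nDraws = 50))
    for (r in res)
      if (length(r$biopsies) > 1)
        expect_true(all(diff(r$biopsies) >= 1 - 1e-9))
  }
})

test_that("scheduler construction is validated", {
  expect_error(scheduler("dyn_risk"), "kappa")
  expect_error(scheduler("dyn_risk", kappa = 1.4), "0, 1")
  expect_error(scheduler("hybrid", kappa = 0.9,
                         hybrid_spread_threshold = -1), "> 0")
  expect_error(proposeBiopsyTime(scheduler("annual"),
                                 exponentialPP()), "fixed")
})
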