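# Schedule runs, pooled estimators, schedule choice.

test_that("fixed schedules produce the expected burden and offset on known
          true times", {
  ## annual: T* = 2.5 detected at 3.0 with 3 biopsies (offset 6 months)
  r <- runSchedule(scheduler("annual"), trueT = 2.5)
  expect_equal(r$N, 3L)
  expect_equal(r$detectionTime, 3)
  expect_equal(r$O, 0.5)

  ## PRIAS with non-rising PSA: T* = 5 detected at year 7 (N = 3, O = 24 mo)
  tt <- seq(0, 20, by = 0.5)
  r2 <- runSchedule(scheduler("prias"), psaTimes = tt,
                    psa = rep(6, length(tt)), trueT = 5)
  expect_equal(r2$N, 3L)
  expect_equal(r2$detectionTime, 7)
  expect_equal(r2$O, 2)

  ## never reached within the horizon -> censored flag
  r3 <- runSchedule(scheduler("annual"), trueT = Inf)
  expect_true(r3$censored)
  expect_true(is.na(r3$O))
})

test_that("offsets are non-negative and detection at/after the true time
          for every scheduler", {
  p <- fullParams()
  cfg <- simConfig(n_patients = 15, train_fraction = 0, seed = 51)
  co <- simulateCohort(cfg, p)
  predP <- predictionParams(p, cfg)
  set.seed(2)
  for (i in 1:15) {
    li <- co$longitudinal[co$longitudinal$id == i, ]
    res <- persched:::evalSchedulesForPatient(
      list(psaTimes = li$time, psa = li$psa, age = co$events$age[i],
           trueT = co$events$true_gr_time[i]),
      defaultSchedulers(kappa = 0.9), predP, schedControl(nDraws = 50))
    for (r in res) {
      if (!r$censored) {
        expect_gte(r$O, 0)
        expect_gte(r$detectionTime, co$events$true_gr_time[i])
        expect_equal(r$N, length(r$biopsies))
      }
    }
  }
})

test_that("engine proposals agree with the reference posterior pipeline", {
  p <- fullParams()
  cfg <- simConfig(n_patients = 4, train_fraction = 0, seed = 61)
  co <- simulateCohort(cfg, p)
  ctl <- schedControl(nDraws = 400)
  eng <- persched:::makeCurveEngine(p, ctl)
  for (i in 1:3) {
    li <- co$longitudinal[co$longitudinal$id == i, ]
    keep <- li$time <= 2.01
    hist <- patientHistory(li$time[keep], li$psa[keep],
                           age = co$events$age[i], lastBiopsy = 1)
    pp <- posteriorRandomEffects(hist, p, nDraws = 400, seed = 70 + i,
                                 method = "laplace_is")
    at <- persched:::engineAgeTerms(eng, co$events$age[i])
    crv <- persched:::engineCurve(eng, pp$draws, pp$weights, at, 1)
    for (sch in list(scheduler("median"), scheduler("expected"),
                     scheduler("dyn_risk", kappa = 0.9))) {
      expect_equal(persched:::engineProposal(sch, crv),
                   as.numeric(proposeBiopsyTime(sch, pp)),
                   tolerance = 0.02)
    }
  }
})

test_that("pooled estimators follow the weighted formulas", {
  ## hand-computed: (n=3, m=1, v=4) and (n=5, m=2, v=1)
  pe <- pooledEstimates(c(1, 2), c(4, 1), c(3, 5))
  expect_equal(pe$mean, 13 / 8)
  expect_equal(pe$variance, 2)

  ## identical datasets pool to themselves; single dataset passes through
  expect_equal(pooledEstimates(c(2, 2), c(3, 3), c(10, 10)),
               list(mean = 2, variance = 3))
  expect_equal(pooledEstimates(1.5, 0.7, 8),
               list(mean = 1.5, variance = 0.7))
  expect_error(pooledEstimates(1, 0, 1), "undefined")

  ## equal n_k: pooled mean equals the concatenated-sample mean exactly
  set.seed(1)
  xs <- replicate(4, rnorm(20), simplify = FALSE)
  pe2 <- pooledEstimates(vapply(xs, mean, 1), vapply(xs, var, 1),
                         rep(20, 4))
  expect_equal(pe2$mean, mean(unlist(xs)))
})

test_that("compound and constrained schedule choice match exhaustive
          enumeration", {
  tbl <- data.frame(schedule = c("a", "b", "c"),
                    E_N = c(5, 3, 2),
                    E_O = c(4, 8, 14),
                    q90_O = c(10, 11, 26))
  ## eta = (1, 0): minimize E_N alone
  expect_equal(chooseSchedule(tbl, weights = c(E_N = 1, E_O = 0)), "c")
  ## brute-force the compound score for mixed weights
  eta <- c(E_N = 0.7, E_O = 0.3)
  scores <- 0.7 * tbl$E_N + 0.3 * tbl$E_O
  expect_equal(chooseSchedule(tbl, weights = eta),
               tbl$schedule[which.min(scores)])
  ## constrained: fewest biopsies subject to q90 of the offset under 12
  expect_equal(chooseSchedule(tbl, constraints = list(
    list(criterion = "q90_O", max = 12)), target = "E_N"), "b")
  ## infeasible constraint set
  out <- chooseSchedule(tbl, constraints = list(
    list(criterion = "q90_O", max = 5)), target = "E_N")
  expect_true(is.na(out))
  expect_false(attr(out, "feasible"))
  expect_error(chooseSchedule(tbl, weights = c(bogus = 1)), "unknown")
})

test_that("a small schedule experiment emits the full summary layout and an
          inverse burden/offset relationship", {
  ex <- scheduleExperiment(nDatasets = 2, nTest = 40, seed = 7,
                           schedulers = defaultSchedulers(kappa = 0.9),
                           control = schedControl(nDraws = 40))
  tb <- ex$table
  expect_setequal(unique(tb$subgroup), c("all", "G1", "G2", "G3"))
  expect_setequal(unique(tb$schedule),
                  c("annual", "prias", "dyn_risk", "hybrid", "median",
                    "expected"))
  expect_true(all(c("E_N", "E_O_months", "SD_N", "SD_O_months") %in%
                    names(tb)))
  allt <- tb[tb$subgroup == "all", ]
  expect_true(all(allt$E_N >= 1))
  expect_true(all(allt$E_O_months > 0))
  ## inverse relationship between burden and delay across schedules
  expect_lt(cor(allt$E_N, allt$E_O_months, method = "spearman"), 0)
  ## annual offsets stay within a year
  ann <- ex$perDataset[ex$perDataset$schedule == "annual" &
                         !ex$perDataset$censored, ]
  expect_true(all(ann$O <= 1 + 1e-9))
})
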