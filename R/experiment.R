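#' The six benchmark schedulers
#'
#' Annual, PRIAS, dynamic-risk, hybrid (median + dynamic risk), median and
#' expected reclassification time — the schedule set compared by the
#' simulation experiment.
#'
#' @param kappa dynamic-risk threshold shared by the `dyn_risk` and `hybrid`
#'   schedulers (`"auto"` selects it by F1 score per biopsy time).
#' @return a named list of [scheduler()] objects.
#' @export
defaultSchedulers <- function(kappa = "auto") {
  list(annual = scheduler("annual"),
       prias = scheduler("prias"),
       dyn_risk = scheduler("dyn_risk", kappa = kappa),
       hybrid = scheduler("hybrid", kappa = kappa),
       median = scheduler("median"),
       expected = scheduler("expected"))
}

#' F1-selected dynamic-risk thresholds over a grid of biopsy times
#'
#' Simulates a reference cohort under the population model and selects, for
#' each latest-biopsy time on a grid, the threshold maximizing the F1 score
#' for predicting reclassification within the next year. Times where no
#' threshold is informative inherit the previous time's value (0.95 at the
#' start of the grid, a conservative low-risk cutoff).
#'
#' @param params population parameters (simulation truth).
#' @param predParams prediction-time parameters (marginal baseline).
#' @param config a [simConfig()] describing the population.
#' @param ts grid of latest-biopsy times (years).
#' @param nRef reference-cohort size.
#' @param seed integer seed.
#' @param nDraws posterior draws per reference patient.
#' @return a data.frame with columns `t`, `kappa`, `f1`, `nAtRisk`.
#' @export
kappaTable <- function(params, predParams, config, ts = 0:8, nRef = 300,
                       seed, nDraws = 100) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  refConfig <- config
  refConfig$n_patients <- nRef
  refConfig$train_fraction <- 0
  ref <- simulateCohort(refConfig, params, seed = seed)
  out <- data.frame(t = ts, kappa = NA_real_, f1 = NA_real_,
                    nAtRisk = NA_integer_)
  prev <- 0.95
  for (i in seq_along(ts)) {
    res <- tryCatch(
      kappaForCohort(ref, predParams, t = ts[i], dt = 1, nDraws = nDraws,
                     seed = seed + i),
      error = function(e) NULL)
    if (!is.null(res) && isTRUE(res$informative)) {
      out$kappa[i] <- res$kappa; out$f1[i] <- res$f1
      out$nAtRisk[i] <- res$nAtRisk
      prev <- res$kappa
    } else {
      out$kappa[i] <- prev; out$f1[i] <- 0
      out$nAtRisk[i] <- if (is.null(res)) 0L else res$nAtRisk
    }
  }
  out
}

kappaFunFromTable <- function(tab) {
  function(t) {
    i <- findInterval(t, tab$t)
    tab$kappa[max(1L, min(i, nrow(tab)))]
  }
}

#' Simulation experiment comparing biopsy schedules
#'
#' Generates test cohorts from the subgroup-mixture population, conducts
#' hypothetical biopsies under each scheduler, and reports the pooled mean
#' and standard deviation of the number of biopsies until detection and of
#' the detection offset (in months), overall and per progression subgroup.
#' Personalized schedules use the true population parameters with the
#' subgroup-mixture marginal baseline (subgroup membership is not revealed
#' to the scheduler).
#'
#' @param params population [modelParameters()] (simulation truth).
#' @param nDatasets number of replicated test datasets.
#' @param nTest test patients per dataset.
#' @param schedulers named list of [scheduler()]s.
#' @param seed integer seed.
#' @param control a [schedControl()].
#' @param config optional [simConfig()] template (patient count and train
#'   fraction are overridden).
#' @param kappaArgs list of settings forwarded to [kappaTable()] when any
#'   scheduler uses `kappa = "auto"`.
#' @return an object of class `"scheduleExperiment"`: list with `table`
#'   (pooled summaries), `perDataset`, `kappaTable` and the settings.
#' @export
scheduleExperiment <- function(params = priasParams(), nDatasets = 50,
                               nTest = 250,
                               schedulers = defaultSchedulers(),
                               seed = 1, control = schedControl(),
                               config = NULL,
                               kappaArgs = list(ts = 0:8, nRef = 300,
                                                nDraws = 100)) {
  if (is.null(config))
    config <- simConfig(n_patients = nTest, train_fraction = 0, seed = seed)
  config$n_patients <- nTest
  config$train_fraction <- 0
  predParams <- modelParameters(
    params$long,
    riskSpec(gamma = params$risk$gamma,
             alpha_value = params$risk$alpha_value,
             alpha_velocity = params$risk$alpha_velocity,
             baseline = marginalBaseline(config),
             form = params$risk$form))

  needAuto <- any(vapply(schedulers, function(s)
    identical(s$kappa, "auto"), logical(1)))
  ktab <- NULL
  kfun <- NULL
  if (needAuto) {
    ktab <- kappaTable(params, predParams, config,
                       ts = kappaArgs$ts, nRef = kappaArgs$nRef,
                       seed = seed + 777000L, nDraws = kappaArgs$nDraws)
    kfun <- kappaFunFromTable(ktab)
  }

  snames <- names(schedulers)
  engine <- makeCurveEngine(predParams, control)
  perDataset <- vector("list", nDatasets)
  for (k in seq_len(nDatasets)) {
    cohort <- simulateCohort(config, params, seed = seed + k)
    ev <- cohort$events
    set.seed(seed + 500000L + k)
    recs <- vector("list", nTest)
    for (i in seq_len(nTest)) {
      li <- cohort$longitudinal[cohort$longitudinal$id == ev$id[i], ]
      patient <- list(psaTimes = li$time, psa = li$psa, age = ev$age[i],
                      trueT = ev$true_gr_time[i])
      res <- evalSchedulesForPatient(patient, schedulers, predParams,
                                     control, kfun, engine = engine)
      recs[[i]] <- data.frame(
        dataset = k, id = ev$id[i], subgroup = ev$subgroup[i],
        schedule = snames,
        N = vapply(res, `[[`, numeric(1), "N"),
        O = vapply(res, `[[`, numeric(1), "O"),
        censored = vapply(res, `[[`, logical(1), "censored"))
    }
    perDataset[[k]] <- do.call(rbind, recs)
  }
  long <- do.call(rbind, perDataset)

  summarize <- function(df) {
    grp <- split(df, list(df$schedule, df$dataset), drop = TRUE)
    per <- do.call(rbind, lapply(grp, function(g) {
      gg <- g[!g$censored, ]
      data.frame(schedule = g$schedule[1], dataset = g$dataset[1],
                 n = nrow(gg), mN = mean(gg$N), vN = var(gg$N),
                 mO = mean(gg$O), vO = var(gg$O))
    }))
    do.call(rbind, lapply(split(per, per$schedule), function(p) {
      sc <- p$schedule[1]
      p <- p[p$n > 1, ]
      if (!nrow(p))
        return(data.frame(schedule = sc, E_N = NA_real_, SD_N = NA_real_,
                          E_O_months = NA_real_, SD_O_months = NA_real_,
                          nDetected = 0L))
      pn <- pooledEstimates(p$mN, p$vN, p$n)
      po <- pooledEstimates(p$mO, p$vO, p$n)
      data.frame(schedule = p$schedule[1],
                 E_N = pn$mean, SD_N = sqrt(pn$variance),
                 E_O_months = 12 * po$mean,
                 SD_O_months = 12 * sqrt(po$variance),
                 nDetected = sum(p$n))
    }))
  }

  tabs <- list(all = summarize(long))
  for (g in sort(unique(long$subgroup)))
    tabs[[paste0("G", g)]] <- summarize(long[long$subgroup == g, ])
  table <- do.call(rbind, Map(function(nm, tb) {
    tb$subgroup <- nm; tb
  }, names(tabs), tabs))
  rownames(table) <- NULL
  table <- table[order(match(table$subgroup, c("all", "G1", "G2", "G3")),
                       match(table$schedule, snames)),
                 c("subgroup", "schedule", "E_N", "E_O_months",
                   "SD_N", "SD_O_months", "nDetected")]

  structure(list(table = table, perDataset = long, kappaTable = ktab,
                 nDatasets = nDatasets, nTest = nTest, seed = seed,
                 control = control, censoredCount = sum(long$censored)),
            class = "scheduleExperiment")
}

#' @export
print.scheduleExperiment <- function(x, ...) {
  cat(sprintf(paste0("Schedule comparison: %d datasets x %d test patients ",
                     "(seed %d)\n"), x$nDatasets, x$nTest, x$seed))
  cat(paste0("Pooled mean/SD of number of biopsies until detection and ",
             "of the offset (months):\n\n"))
  tb <- x$table
  tb[c("E_N", "E_O_months", "SD_N", "SD_O_months")] <-
    lapply(tb[c("E_N", "E_O_months", "SD_N", "SD_O_months")], round, 2)
  print(tb, row.names = FALSE)
  if (x$censoredCount > 0)
    cat(sprintf("\n(%d patient-schedule runs censored at the horizon)\n",
                x$censoredCount))
  invisible(x)
}
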