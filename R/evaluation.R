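# Schedule evaluation: run biopsy rules against patients with known true
# reclassification times and summarize burden (number of biopsies N) and
# detection delay (offset O).

#' Control settings for schedule evaluation
#'
#' The evaluation driver re-conditions the patient's posterior at every PSA
#' visit, which is the dominant cost of the simulation experiments; these
#' settings trade Monte-Carlo precision for speed. The posterior draws use
#' the Laplace-with-importance-reweighting sampler by default, and the
#' dynamic survival curve is cached on a fixed grid (panel width `step`)
#' with per-draw interpolation of the cumulative hazard between grid points.
#'
#' @param nDraws posterior draws per re-conditioning.
#' @param method `"laplace_is"` or `"mcmc"`.
#' @param step curve panel width in years.
#' @param horizon administrative horizon (years).
#' @return a list of class `"schedControl"`.
#' @export
schedControl <- function(nDraws = 75, method = "laplace_is", step = 0.25,
                         horizon = 20) {
  structure(list(nDraws = nDraws, method = method, step = step,
                 horizon = horizon), class = "schedControl")
}

## -- per-patient schedule run -------------------------------------------------

#' Run a biopsy schedule against a patient with known true reclassification
#' time
#'
#' Walks the patient forward over the PSA visit grid, re-evaluating the
#' scheduler at every visit: biopsies conducted before the true time are
#' negative (the posterior is re-conditioned on them), and the first biopsy
#' at or after the true time detects reclassification. Returns the number of
#' biopsies `N` conducted through detection and the offset
#' `O = detection time - true time`.
#'
#' @param sch a [scheduler()].
#' @param psaTimes,psa the patient's PSA measurement grid and values (the
#'   full protocol series; values are revealed to the scheduler visit by
#'   visit). Optional for the `"annual"` comparator.
#' @param age entry age.
#' @param trueT true reclassification time (years; may be `Inf`).
#' @param params prediction-time [modelParameters()] (personalized kinds).
#' @param seed integer seed (personalized kinds; posterior draws are
#'   Monte-Carlo).
#' @param control a [schedControl()].
#' @param kappaFun optional function `t -> kappa` resolving an `"auto"`
#'   dynamic-risk threshold at the current biopsy time.
#' @return a list with `N`, `O` (years), `detectionTime`, `biopsies` (times
#'   conducted) and `censored` (`TRUE` when the schedule never reaches the
#'   true time within the horizon).
#' @export
runSchedule <- function(sch, psaTimes = NULL, psa = NULL, age = 66, trueT,
                        params = NULL, seed = NULL,
                        control = schedControl(), kappaFun = NULL) {
  stopifnot(inherits(sch, "scheduler"))
  personalized <- sch$kind %in% c("expected", "median", "dyn_risk", "hybrid")
  if (personalized) {
    if (is.null(params)) stop("personalized schedules need params", call. = FALSE)
    if (is.null(psa)) stop("personalized schedules need PSA data", call. = FALSE)
    if (is.null(seed)) stop("seed is mandatory for personalized schedules",
                            call. = FALSE)
    set.seed(as.integer(seed))
  }
  if (is.null(psaTimes))
    psaTimes <- c(seq(0, 2, by = 0.25), seq(2.5, control$horizon, by = 0.5))
  patient <- list(psaTimes = psaTimes, psa = psa, age = age, trueT = trueT)
  res <- evalSchedulesForPatient(patient, list(sch), params, control,
                                 kappaFun)
  res[[1]]
}

# Shared per-patient runner: evaluates several schedulers for one patient,
# memoizing the posterior and its survival curve across schedulers that are
# in the same (last-biopsy, visit) state. Uses the caller's RNG stream.
evalSchedulesForPatient <- function(patient, schedulers, params, control,
                                    kappaFun = NULL, engine = NULL) {
  visits <- patient$psaTimes[patient$psaTimes <= control$horizon]
  nv <- length(visits)
  memo <- new.env(parent = emptyenv())
  lg <- if (!is.null(params)) params$long else NULL

  ## precomputed observation designs for all visits (personalized kinds)
  personalizedAny <- any(vapply(schedulers, function(s)
    s$kind %in% c("expected", "median", "dyn_risk", "hybrid"), logical(1)))
  if (personalizedAny) {
    if (is.null(engine)) engine <- makeCurveEngine(params, control)
    at <- engineAgeTerms(engine, patient$age)
    y_all <- psaToOutcome(lg, patient$psa[seq_len(nv)])
    m0_all <- drop(fixedDesign(lg, visits, patient$age) %*% lg$beta)
    Z_all <- randomDesign(lg, visits)
  }

  getCurve <- function(t, vi) {
    key <- sprintf("%.6f|%d", t, vi)
    if (!is.null(memo[[key]])) return(memo[[key]])
    skey <- sprintf("surv|%.6f", t)
    sv <- memo[[skey]]
    if (is.null(sv)) {
      sv <- engineSurvData(engine, at, t)
      memo[[skey]] <- sv
    }
    idx <- seq_len(vi)
    dat <- enginePostData(engine, at, y_all[idx], m0_all[idx],
                          Z_all[idx, , drop = FALSE], t, survCache = sv)
    dr <- .posteriorDrawsCore(dat, lg$q, control$nDraws, control$method,
                              mode_start = memo$lastmode)
    memo$lastmode <- dr$diagnostics$mode
    crv <- engineCurve(engine, dr$draws, dr$weights, at, t)
    memo[[key]] <- crv
    crv
  }

  priasGrid <- c(1, 4, 7, 10, seq(15, max(15, ceiling(control$horizon)),
                                  by = 5))

  lapply(schedulers, function(sch) {
    personalized <- sch$kind %in% c("expected", "median", "dyn_risk", "hybrid")
    t <- 0; u_pv <- NULL; N <- 0L
    biopsies <- numeric()
    detected <- FALSE; detTime <- NA_real_
    fast <- FALSE                     # PRIAS faster-progressing flag (absorbing)
    for (vi in seq_len(nv)) {
      s <- visits[vi]
      s_nv <- if (vi < nv) visits[vi + 1L] else control$horizon
      if (personalized) {
        crv <- getCurve(t, vi)
        kap <- sch$kappa
        if (identical(kap, "auto")) {
          if (is.null(kappaFun))
            stop("kappa = \"auto\" requires kappaFun", call. = FALSE)
          kap <- kappaFun(t)
        }
        u <- engineProposal(sch, crv, kappa = kap)
        if (sch$proposal_update == "earliest" && !is.null(u_pv))
          u <- min(u, u_pv)
      } else if (sch$kind == "annual") {
        u <- t + 1
      } else {                                     # prias
        if (!fast && !is.null(patient$psa)) {
          dt_now <- psaDTWindowed(visits[seq_len(vi)],
                                  patient$psa[seq_len(vi)], s, sch$dt_window)
          fast <- is.finite(dt_now) && dt_now > 0 && dt_now <= 10
        }
        u <- if (fast) t + 1
             else suppressWarnings(min(priasGrid[priasGrid > t + 1e-9]))
      }
      if (u - t < 1) u <- t + 1
      if (u <= s_nv + 1e-9) {
        tau <- max(u, s)
        N <- N + 1L
        biopsies <- c(biopsies, tau)
        if (tau >= patient$trueT) { detected <- TRUE; detTime <- tau; break }
        t <- tau; u_pv <- NULL
      } else u_pv <- u
    }
    list(N = N, O = if (detected) detTime - patient$trueT else NA_real_,
         detectionTime = detTime, biopsies = biopsies,
         censored = !detected)
  })
}

## -- pooled estimators and schedule choice ------------------------------------

#' Pooled mean and variance across simulated datasets
#'
#' Sample-size weighted pooling of per-dataset summaries: the pooled mean is
#' `sum(n_k * m_k) / sum(n_k)` and the pooled variance is
#' `sum((n_k - 1) * v_k) / sum(n_k - 1)`.
#'
#' @param means per-dataset means.
#' @param vars per-dataset variances.
#' @param n per-dataset sample sizes.
#' @return a list with `mean` and `variance`.
#' @export
pooledEstimates <- function(means, vars, n) {
  stopifnot(length(means) == length(vars), length(means) == length(n))
  if (all(n <= 1)) stop("pooled variance undefined: all n_k <= 1",
                        call. = FALSE)
  list(mean = sum(n * means) / sum(n),
       variance = sum((n - 1) * vars) / sum(n - 1))
}

#' Choose a schedule by compound or constrained criteria
#'
#' Compound mode minimizes the weighted sum `sum(eta_r * R_r)` of criteria
#' (weights non-negative, summing to 1); constrained mode minimizes a target
#' criterion among the schedules satisfying all constraints `R_r < C_r`.
#'
#' @param tbl a data.frame with a `schedule` column and one numeric column
#'   per criterion.
#' @param weights named non-negative weights over criterion columns (compound
#'   mode), summing to 1.
#' @param constraints list of `list(criterion =, max =)` upper bounds
#'   (constrained mode).
#' @param target criterion column minimized in constrained mode.
#' @return the selected schedule id (character); `NA` with attribute
#'   `feasible = FALSE` when no schedule satisfies the constraints.
#' @export
chooseSchedule <- function(tbl, weights = NULL, constraints = NULL,
                           target = NULL) {
  stopifnot(is.data.frame(tbl), "schedule" %in% names(tbl))
  if (!is.null(weights)) {
    if (any(weights < 0) || abs(sum(weights) - 1) > 1e-8)
      stop("weights must be non-negative and sum to 1", call. = FALSE)
    miss <- setdiff(names(weights), names(tbl))
    if (length(miss))
      stop("unknown criterion: ", paste(miss, collapse = ", "), call. = FALSE)
    score <- as.matrix(tbl[names(weights)]) %*% weights
    return(tbl$schedule[which.min(score)])
  }
  if (is.null(target)) stop("constrained mode needs a target criterion",
                            call. = FALSE)
  if (!target %in% names(tbl))
    stop("unknown criterion: ", target, call. = FALSE)
  ok <- rep(TRUE, nrow(tbl))
  for (cn in constraints) {
    if (!cn$criterion %in% names(tbl))
      stop("unknown criterion: ", cn$criterion, call. = FALSE)
    ok <- ok & tbl[[cn$criterion]] < cn$max
  }
  if (!any(ok)) {
    out <- NA_character_; attr(out, "feasible") <- FALSE
    return(out)
  }
  sub <- tbl[ok, ]
  sub$schedule[which.min(sub[[target]])]
}
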