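#' F1 score of a dynamic-risk threshold
#'
#' A patient at risk at `t` is predicted to reclassify within the window
#' `(t, t + dt]` when the dynamic survival `pi_j(t + dt | t, s) <= kappa`.
#' Against the observed case/control status this yields a time-dependent true
#' positive rate (sensitivity) and positive predictive value (precision),
#' combined into `F1 = 2 * TPR * PPV / (TPR + PPV)` (0 when `TPR + PPV = 0`).
#'
#' @param piValues dynamic survival probabilities `pi_j(t + dt | t, s)` of the
#'   patients at risk at `t`.
#' @param isCase logical; `TRUE` when the patient reclassifies in
#'   `(t, t + dt]`.
#' @param kappa threshold in `[0, 1]`.
#' @return a list with `f1`, `tpr` and `ppv`.
#' @export
f1Score <- function(piValues, isCase, kappa) {
  if (length(piValues) == 0L)
    stop("no at-risk patients", call. = FALSE)
  stopifnot(length(piValues) == length(isCase))
  pred <- piValues <= kappa
  tp <- sum(pred & isCase)
  tpr <- if (sum(isCase) > 0L) tp / sum(isCase) else 0
  ppv <- if (sum(pred) > 0L) tp / sum(pred) else 0
  f1 <- if (tpr + ppv > 0) 2 * tpr * ppv / (tpr + ppv) else 0
  list(f1 = f1, tpr = tpr, ppv = ppv)
}

#' Select the dynamic-risk threshold by grid-searched F1 score
#'
#' Evaluates the F1 score over a grid of thresholds and returns the maximizer;
#' ties are broken toward the larger threshold (fewer biopsies at equal
#' accuracy).
#'
#' @inheritParams f1Score
#' @param grid candidate thresholds in `[0, 1]`.
#' @return a list with `kappa` (the selected threshold, `NA` when no
#'   threshold attains a positive F1), `f1`, `informative`, and the full
#'   `grid` / `f1grid` profile.
#' @export
selectKappa <- function(piValues, isCase, grid = seq(0, 1, by = 0.01)) {
  if (any(grid < 0 | grid > 1))
    stop("grid must lie in [0, 1]", call. = FALSE)
  f1grid <- vapply(grid, function(k) f1Score(piValues, isCase, k)$f1,
                   numeric(1))
  best <- max(f1grid)
  if (best <= 0)
    return(list(kappa = NA_real_, f1 = 0, informative = FALSE,
                grid = grid, f1grid = f1grid))
  kap <- max(grid[f1grid >= best - 1e-12])   # ties -> larger kappa
  list(kappa = kap, f1 = best, informative = TRUE,
       grid = grid, f1grid = f1grid)
}

#' Select the dynamic-risk threshold from a simulated cohort
#'
#' For every cohort patient still at risk at `t`, computes the dynamic
#' survival `pi_j(t + dt | t, s = t)` from the PSA accrued up to `t` (taking
#' the latest biopsy to be at `t`), labels the patient a case when the true
#' reclassification time falls in `(t, t + dt]`, and runs [selectKappa()].
#' In simulation the case/control status is taken from the known true times.
#'
#' @param cohort a simulated cohort (see [simulateCohort()]).
#' @param params prediction-time [modelParameters()].
#' @param t evaluation time (years, a biopsy time).
#' @param dt prediction window (years).
#' @param grid candidate thresholds.
#' @param nDraws,method posterior settings per patient.
#' @param seed integer seed.
#' @return the [selectKappa()] result, plus `t`, `dt` and `nAtRisk`.
#' @export
kappaForCohort <- function(cohort, params, t, dt = 1,
                           grid = seq(0, 1, by = 0.01),
                           nDraws = 100, method = "laplace_is", seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  set.seed(as.integer(seed))
  ev <- cohort$events
  atrisk <- which(ev$true_gr_time > t)
  if (!length(atrisk)) stop("no at-risk patients at t", call. = FALSE)
  piv <- numeric(length(atrisk)); case <- logical(length(atrisk))
  for (i in seq_along(atrisk)) {
    id <- ev$id[atrisk[i]]
    li <- cohort$longitudinal[cohort$longitudinal$id == id, ]
    keep <- li$time <= t + 1e-9
    if (!any(keep)) keep[1] <- TRUE
    hist <- patientHistory(li$time[keep], li$psa[keep],
                           age = ev$age[atrisk[i]], lastBiopsy = t)
    dat <- bPostData(hist, params)
    dr <- .posteriorDrawsCore(dat, params$long$q, nDraws, method)
    pp <- posteriorPredictive(dr$draws, dr$weights, params,
                              age = hist$age, t = t, s = hist$s)
    piv[i] <- dynamicSurvival(pp, t + dt)
    case[i] <- ev$true_gr_time[atrisk[i]] <= t + dt
  }
  res <- selectKappa(piv, case, grid)
  res$t <- t; res$dt <- dt; res$nAtRisk <- length(atrisk)
  res
}
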