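#' PSA doubling time
#'
#' The inverse of the least-squares slope of log2(PSA) regressed on time,
#' the quantity PRIAS uses to flag fast-progressing patients. A non-positive
#' slope (non-rising PSA) returns `Inf`.
#'
#' @param psaTimes measurement times (years).
#' @param psa raw PSA values (ng/mL).
#' @return doubling time in years (`Inf` if PSA is not rising).
#' @examples
#' computePsaDT(c(0, 1, 2), c(4, 8, 16))  # doubles every year -> 1
#' @export
computePsaDT <- function(psaTimes, psa) {
  keep <- is.finite(psaTimes) & is.finite(psa) & psa > 0
  psaTimes <- psaTimes[keep]; psa <- psa[keep]
  if (length(unique(psaTimes)) < 2L)
    stop("need at least 2 distinct time points", call. = FALSE)
  y <- log2(psa)
  tc <- psaTimes - mean(psaTimes)
  slope <- sum(tc * y) / sum(tc^2)
  if (slope <= 0) Inf else 1 / slope
}

#' Biopsy scheduler specification
#'
#' Defines the rule that maps a patient's posterior predictive distribution
#' (or fixed protocol) to the next biopsy time:
#' * `"expected"` — the expected reclassification time (minimizer of the
#'   posterior expected squared loss);
#' * `"median"` — the median (minimizer of the absolute loss);
#' * `"dyn_risk"` — the time `u` at which the dynamic survival drops to
#'   `kappa`, i.e. the dynamic risk of reclassification reaches `1 - kappa`
#'   (minimizer of the multilinear loss with `kappa = k1 / (k1 + k2)`);
#' * `"hybrid"` — the central rule (`hybrid_central`) when the predictive
#'   distribution is tight, the dynamic-risk rule when its spread (central
#'   value minus the 0.025 quantile) exceeds `hybrid_spread_threshold`;
#' * `"annual"`, `"prias"` — the fixed comparators.
#'
#' @param kind one of `"expected"`, `"median"`, `"dyn_risk"`, `"hybrid"`,
#'   `"annual"`, `"prias"`.
#' @param kappa dynamic-risk threshold in `[0, 1]`, or `"auto"` to select it
#'   by F1 score (resolved by the evaluation driver via [selectKappa()]).
#' @param hybrid_spread_threshold years; default 3, the largest possible
#'   detection delay of the PRIAS protocol in the first decade.
#' @param hybrid_central `"median"` or `"expected"`.
#' @param proposal_update how a new proposal interacts with the one made at
#'   the previous visit: `"recompute"` (use the new one) or `"earliest"`
#'   (keep the earlier of the two).
#' @param dt_window years of PSA entering the PRIAS doubling-time trigger
#'   (minimum 3 values); the default `Inf` uses all values since entry. Once
#'   the doubling time falls in (0, 10] the patient is classified as faster
#'   progressing and stays on the annual schedule thereafter.
#' @return an object of class `"scheduler"`.
#' @export
scheduler <- function(kind = c("expected", "median", "dyn_risk", "hybrid",
                               "annual", "prias"),
                      kappa = NULL, hybrid_spread_threshold = 3,
                      hybrid_central = c("median", "expected"),
                      proposal_update = c("recompute", "earliest"),
                      dt_window = Inf) {
  kind <- match.arg(kind)
  hybrid_central <- match.arg(hybrid_central)
  proposal_update <- match.arg(proposal_update)
  if (kind %in% c("dyn_risk", "hybrid")) {
    if (is.null(kappa))
      stop(sprintf("scheduler '%s' requires kappa (a value in [0,1] or \"auto\")",
                   kind), call. = FALSE)
    if (is.numeric(kappa) && (kappa < 0 || kappa > 1))
      stop("kappa must be in [0, 1]", call. = FALSE)
  }
  if (hybrid_spread_threshold <= 0)
    stop("hybrid_spread_threshold must be > 0", call. = FALSE)
  if (dt_window <= 0) stop("dt_window must be > 0", call. = FALSE)
  structure(list(kind = kind, kappa = kappa,
                 hybrid_spread_threshold = hybrid_spread_threshold,
                 hybrid_central = hybrid_central,
                 proposal_update = proposal_update,
                 dt_window = dt_window),
            class = "scheduler")
}

#' @export
print.scheduler <- function(x, ...) {
  cat(sprintf("Biopsy scheduler: %s", x$kind))
  if (x$kind %in% c("dyn_risk", "hybrid"))
    cat(sprintf(" (kappa = %s)", if (is.numeric(x$kappa))
      format(x$kappa) else x$kappa))
  if (x$kind == "hybrid")
    cat(sprintf(", central rule %s, spread threshold %g y",
                x$hybrid_central, x$hybrid_spread_threshold))
  cat("\n")
  invisible(x)
}

#' Personalized next-biopsy proposal
#'
#' Maps the posterior predictive distribution of the reclassification time to
#' the biopsy time that minimizes the scheduler's posterior expected loss:
#' the expected time (squared loss), the median (absolute loss), the inverse
#' dynamic survival at `kappa` (multilinear loss), or the hybrid combination.
#'
#' @param sch a [scheduler()] with a personalized `kind`.
#' @param pp a [posteriorPredictive()] for the patient, conditioned on the
#'   latest negative biopsy.
#' @param kappa optional numeric override of the scheduler's threshold (used
#'   when `kappa = "auto"` has been resolved externally).
#' @return proposed biopsy time in years (`>= pp$t`); carries attribute
#'   `censored = TRUE` when the rule's defining quantile lies beyond the
#'   horizon.
#' @export
proposeBiopsyTime <- function(sch, pp, kappa = NULL) {
  stopifnot(inherits(sch, "scheduler"), inherits(pp, "posteriorPredictive"))
  kind <- sch$kind
  if (kind %in% c("annual", "prias"))
    stop("fixed schedules do not use posterior proposals; see fixedScheduleTimes()",
         call. = FALSE)
  kap <- kappa %||% sch$kappa
  if (kind %in% c("dyn_risk", "hybrid") && !is.numeric(kap))
    stop("kappa must be resolved to a numeric value before proposing",
         call. = FALSE)
  u <- switch(kind,
    expected = expectedGRTime(pp),
    median = quantileGRTime(pp, 0.5),
    dyn_risk = quantileGRTime(pp, 1 - kap),
    hybrid = {
      central <- if (sch$hybrid_central == "median")
        quantileGRTime(pp, 0.5) else expectedGRTime(pp)
      q025 <- quantileGRTime(pp, 0.025)
      if ((as.numeric(central) - as.numeric(q025)) >
          sch$hybrid_spread_threshold)
        quantileGRTime(pp, 1 - kap)
      else central
    })
  cens <- isTRUE(attr(u, "censored"))
  u <- max(as.numeric(u), pp$t)
  if (cens) attr(u, "censored") <- TRUE
  u
}

#' One step of the biopsy-timing algorithm
#'
#' Applies the decision algorithm that turns a proposed time `u` into an
#' action at the current visit: proposals closer than 1 year to the latest
#' biopsy are postponed to `t + 1` (surveillance programs require at least a
#' 1-year gap between biopsies); a proposal due before the next PSA visit
#' leads to a biopsy at that time; otherwise the proposal is carried forward
#' and re-evaluated at the next visit.
#'
#' @param sch a [scheduler()].
#' @param pp a [posteriorPredictive()] (personalized kinds only).
#' @param u_pv the proposal made at the previous visit, or `NULL`.
#' @param s_nv time of the next PSA visit (years).
#' @param s current visit time (defaults to `pp$s`).
#' @param kappa optional numeric threshold override.
#' @return a list with `action` (`"biopsy"` or `"defer"`), `time` (the biopsy
#'   time if `action == "biopsy"`) and `proposal` (the adjusted proposal).
#' @export
nextBiopsyDecision <- function(sch, pp, u_pv = NULL, s_nv, s = pp$s,
                               kappa = NULL) {
  if (s_nv < s) stop("s_nv must be >= the current visit time", call. = FALSE)
  u <- proposeBiopsyTime(sch, pp, kappa = kappa)
  if (sch$proposal_update == "earliest" && !is.null(u_pv))
    u <- min(u, u_pv)
  t <- pp$t
  if (u - t < 1) u <- t + 1          # enforce the 1-year biopsy gap
  if (u <= s_nv) {
    list(action = "biopsy", time = max(u, s), proposal = u)
  } else {
    list(action = "defer", time = NA_real_, proposal = u)
  }
}

#' Fixed comparator schedules
#'
#' Biopsy time grids for the fixed protocols: `"annual"` biopsies every year,
#' and the `"prias"` protocol (biopsies at years 1, 4, 7, 10 and every 5
#' years thereafter, switching to annual spacing while the PSA doubling time
#' is in (0, 10] years).
#'
#' @param kind `"annual"` or `"prias"`.
#' @param horizon last follow-up year covered by the grid.
#' @param psaTimes,psa optional PSA history used to evaluate the doubling
#'   time at each scheduled biopsy (PRIAS only); when absent the PSA is
#'   treated as non-rising.
#' @param dt_window years of PSA entering the doubling-time regression
#'   (minimum 3 values); `Inf` uses all values since entry.
#' @return increasing vector of biopsy times, consecutive gaps always
#'   `>= 1` year.
#' @details A doubling time in (0, 10] classifies the patient as faster
#'   progressing: the schedule switches to annual spacing and stays annual
#'   from that point on.
#' @examples
#' fixedScheduleTimes("prias", horizon = 12)      # 1, 4, 7, 10
#' fixedScheduleTimes("annual", horizon = 5)      # 1..5
#' @export
fixedScheduleTimes <- function(kind = c("annual", "prias"), horizon,
                               psaTimes = NULL, psa = NULL, dt_window = Inf) {
  kind <- match.arg(kind)
  if (kind == "annual") return(seq_len(floor(horizon)))
  grid <- c(1, 4, 7, 10, seq(15, max(15, ceiling(horizon)), by = 5))
  ## first measurement time at which the doubling time falls in (0, 10]
  trig <- Inf
  if (!is.null(psaTimes)) {
    for (s in sort(psaTimes)) {
      dt <- psaDTWindowed(psaTimes, psa, s, dt_window)
      if (is.finite(dt) && dt > 0 && dt <= 10) { trig <- s; break }
    }
  }
  times <- numeric()
  t_last <- 0
  repeat {
    nx_grid <- suppressWarnings(min(grid[grid > t_last + 1e-9]))
    u <- if (trig <= t_last) t_last + 1
         else if (trig < nx_grid) max(t_last + 1, trig)
         else nx_grid
    if (!is.finite(u) || u > horizon + 1e-9) break
    times <- c(times, u)
    t_last <- u
  }
  times
}

# PRIAS doubling-time trigger: regression of log2(PSA) on time over the
# values observed in (now - window, now]; Inf (non-rising) when fewer than 3
# values are available.
psaDTWindowed <- function(psaTimes, psa, now, window = 2) {
  use <- psaTimes <= now + 1e-9 & psaTimes > now - window - 1e-9
  if (sum(use) < 3L || length(unique(psaTimes[use])) < 2L) return(Inf)
  computePsaDT(psaTimes[use], psa[use])
}
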