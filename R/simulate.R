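#' Simulation configuration for a PRIAS-like surveillance cohort
#'
#' The simulated population consists of subgroups with different Weibull
#' baseline hazards of Gleason reclassification (by default three equal-sized
#' subgroups with (shape, scale) = (1.5, 4), (3, 5), (4.5, 6), i.e. fast,
#' intermediate and slow progression), all sharing the same PSA trajectory
#' model and association structure. PSA is measured on the protocol grid
#' (every 3 months in the first 2 years, every 6 months thereafter), and
#' training patients are right-censored at a random, non-informative time.
#'
#' @param n_patients cohort size.
#' @param subgroup_weibulls list of `c(shape, scale)` pairs, one per subgroup.
#' @param subgroup_probs subgroup membership probabilities (sum to 1).
#' @param psa_visit_times protocol PSA measurement grid (years, strictly
#'   increasing, starting at 0).
#' @param train_fraction fraction of patients assigned to the training set.
#' @param censoring_max training censoring times are uniform on
#'   `(0, censoring_max)`.
#' @param horizon administrative horizon (years); true times beyond it are
#'   treated as right-censored at the horizon.
#' @param training_schedule biopsy protocol generating the observed
#'   reclassification intervals of training patients (`"prias"` or
#'   `"annual"`).
#' @param age_mean,age_sd,age_range entry-age distribution (normal,
#'   truncated).
#' @param seed integer seed; every simulated cohort is reproducible from it.
#' @return an object of class `"simConfig"`.
#' @export
simConfig <- function(n_patients = 1000,
                      subgroup_weibulls = list(c(1.5, 4), c(3, 5), c(4.5, 6)),
                      subgroup_probs = NULL,
                      psa_visit_times = c(seq(0, 2, by = 0.25),
                                          seq(2.5, 20, by = 0.5)),
                      train_fraction = 0.75,
                      censoring_max = 10,
                      horizon = 20,
                      training_schedule = c("prias", "annual"),
                      age_mean = 66, age_sd = 7, age_range = c(45, 85),
                      seed = 1L) {
  training_schedule <- match.arg(training_schedule)
  G <- length(subgroup_weibulls)
  if (is.null(subgroup_probs)) subgroup_probs <- rep(1 / G, G)
  if (abs(sum(subgroup_probs) - 1) > 1e-8)
    stop("subgroup_probs must sum to 1", call. = FALSE)
  for (w in subgroup_weibulls)
    if (length(w) != 2L || any(w <= 0))
      stop("each subgroup needs positive (shape, scale)", call. = FALSE)
  if (is.unsorted(psa_visit_times, strictly = TRUE) ||
      psa_visit_times[1] != 0)
    stop("psa_visit_times must be strictly increasing and start at 0",
         call. = FALSE)
  if (psa_visit_times[1] > horizon)
    stop("horizon shorter than the first visit", call. = FALSE)
  if (train_fraction < 0 || train_fraction > 1)
    stop("train_fraction must be in [0, 1]", call. = FALSE)
  structure(list(n_patients = n_patients,
                 subgroup_weibulls = subgroup_weibulls,
                 subgroup_probs = as.numeric(subgroup_probs),
                 psa_visit_times = as.numeric(psa_visit_times),
                 train_fraction = train_fraction,
                 censoring_max = censoring_max, horizon = horizon,
                 training_schedule = training_schedule,
                 age_mean = age_mean, age_sd = age_sd,
                 age_range = as.numeric(age_range),
                 seed = as.integer(seed)),
            class = "simConfig")
}

#' @export
print.simConfig <- function(x, ...) {
  cat(sprintf("Simulation config: %d patients, %d subgroups, seed %d\n",
              x$n_patients, length(x$subgroup_weibulls), x$seed))
  cat(sprintf("  train fraction %.2f, censoring U(0, %g), horizon %g y\n",
              x$train_fraction, x$censoring_max, x$horizon))
  invisible(x)
}

#' Sample a true reclassification time by inverse-transform sampling
#'
#' Solves `S(0 -> t* | b) = u` for `t*` by bracketing root-finding on the
#' cumulative hazard (closed form when the PSA-hazard association and the
#' age effects are all zero). Returns `Inf` when the subject survives the
#' administrative horizon at the drawn `u`.
#'
#' @inheritParams hazardRate
#' @param u uniform(0,1) draw.
#' @param horizon administrative horizon (years).
#' @param tol root tolerance (years).
#' @return the sampled time in years, or `Inf`.
#' @export
sampleGRTime <- function(risk, spec, age, b, u, horizon = 20, tol = 1e-6) {
  if (u <= 0 || u >= 1) stop("u must be in (0, 1)", call. = FALSE)
  target <- -log(u)
  if (risk$alpha_value == 0 && risk$alpha_velocity == 0) {
    w <- c(age - 70, (age - 70)^2)
    x <- target * exp(-sum(risk$gamma * w))    # solve H0(t*) = x
    bl <- risk$baseline
    t_star <- if (bl$kind == "weibull") {
      bl$scale * x^(1 / bl$shape)
    } else {
      edges <- c(0, bl$breaks)
      cums <- c(0, cumsum(bl$rates[seq_along(bl$breaks)] * diff(c(0, bl$breaks))))
      k <- findInterval(x, cums)
      if (k > length(bl$breaks) && bl$rates[k] == 0) Inf
      else edges[k] + (x - cums[k]) / bl$rates[k]
    }
    return(if (t_star > horizon) Inf else t_star)
  }
  edges <- panelEdges(0, horizon, step = 0.25)
  L <- c(0, drop(cumHazDraws(risk, spec, age, matrix(b, nrow = 1), edges)))
  if (L[length(L)] < target) return(Inf)
  k <- which(L >= target)[1]             # crossing in (edges[k-1], edges[k]]
  lo <- edges[k - 1]; hi <- edges[k]; Llo <- L[k - 1]
  f <- function(tt) {
    if (tt <= lo) return(Llo - target)
    Llo + drop(cumHazDraws(risk, spec, age, matrix(b, nrow = 1),
                           c(lo, tt))) - target
  }
  uniroot(f, lower = lo, upper = hi, tol = tol)$root
}

#' Simulate a surveillance cohort from the joint model
#'
#' Draws subgroup membership, entry age and subject random effects, samples
#' the true reclassification time from the subgroup-specific hazard by
#' inverse-transform sampling, measures PSA at the protocol visits with
#' t-distributed residuals, and (for training patients) constructs the
#' interval-censored observation `(l, r]` implied by the training biopsy
#' protocol truncated at a uniform non-informative censoring time.
#'
#' @param config a [simConfig()].
#' @param params population [modelParameters()]; the baseline hazard inside
#'   `params$risk` is replaced by the subgroup-specific Weibull for each
#'   simulated patient.
#' @param seed optional override of `config$seed`.
#' @return an object of class `"cohort"`: a list with `longitudinal`
#'   (id, time, psa), `events` (id, age, subgroup, train, l, r, event,
#'   censor_time, true_gr_time), the matrix `b` of true random effects, and
#'   the `config`/`params` used.
#' @export
simulateCohort <- function(config, params, seed = NULL) {
  stopifnot(inherits(config, "simConfig"), inherits(params, "modelParameters"))
  seed <- as.integer(seed %||% config$seed)
  set.seed(seed)
  n <- config$n_patients
  lg <- params$long
  G <- length(config$subgroup_weibulls)

  subgroup <- sample.int(G, n, replace = TRUE, prob = config$subgroup_probs)
  age <- pmin(pmax(rnorm(n, config$age_mean, config$age_sd),
                   config$age_range[1]), config$age_range[2])
  Rd <- chol(lg$D)
  B <- matrix(rnorm(n * lg$q), n, lg$q) %*% Rd
  uu <- runif(n)
  train <- rep(FALSE, n)
  if (config$train_fraction > 0)
    train[seq_len(round(n * config$train_fraction))] <- TRUE
  censor <- ifelse(train, runif(n, 0, config$censoring_max), Inf)

  risks <- lapply(config$subgroup_weibulls, function(w)
    riskSpec(gamma = params$risk$gamma,
             alpha_value = params$risk$alpha_value,
             alpha_velocity = params$risk$alpha_velocity,
             baseline = weibullHazard(w[1], w[2]),
             form = params$risk$form))

  visits <- config$psa_visit_times[config$psa_visit_times <= config$horizon]
  Zv <- randomDesign(lg, visits)

  trueT <- numeric(n)
  keep_list <- vector("list", n)
  psa_list <- vector("list", n)
  l <- r <- numeric(n); event <- logical(n)
  for (i in seq_len(n)) {
    rk <- risks[[subgroup[i]]]
    ti <- sampleGRTime(rk, lg, age[i], B[i, ], uu[i],
                       horizon = config$horizon)
    trueT[i] <- ti
    m <- drop(fixedDesign(lg, visits, age[i]) %*% lg$beta + Zv %*% B[i, ])
    y <- m + lg$sigma * rt(length(visits), df = lg$residual_df)
    psa <- outcomeToPsa(lg, y)

    if (train[i]) {
      bt <- fixedScheduleTimes(config$training_schedule,
                               horizon = min(censor[i], config$horizon),
                               psaTimes = visits, psa = psa)
      det <- bt[bt >= ti]
      if (length(det)) {
        r[i] <- det[1]; event[i] <- TRUE
        prev <- bt[bt < r[i]]
        l[i] <- if (length(prev)) max(prev) else 0
        keep <- visits <= r[i] + 1e-9
      } else {
        event[i] <- FALSE; r[i] <- Inf
        l[i] <- if (length(bt)) max(bt) else 0
        keep <- visits <= censor[i] + 1e-9
      }
    } else {
      l[i] <- NA_real_; r[i] <- NA_real_; event[i] <- NA
      keep <- rep(TRUE, length(visits))
    }
    keep_list[[i]] <- visits[keep]
    psa_list[[i]] <- psa[keep]
  }
  lens <- lengths(keep_list)

  structure(list(
    longitudinal = data.frame(id = rep.int(seq_len(n), lens),
                              time = unlist(keep_list, use.names = FALSE),
                              psa = unlist(psa_list, use.names = FALSE)),
    events = data.frame(id = seq_len(n), age = age, subgroup = subgroup,
                        train = train, l = l, r = r, event = event,
                        censor_time = ifelse(train, censor, NA_real_),
                        true_gr_time = ifelse(trueT > config$horizon,
                                              Inf, trueT)),
    b = B, config = config, params = params, seed = seed),
    class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  ev <- x$events
  cat(sprintf("Simulated surveillance cohort: %d patients (%d training, %d test), seed %d\n",
              nrow(ev), sum(ev$train), sum(!ev$train), x$seed))
  if (any(ev$train))
    cat(sprintf("  training events observed: %d of %d\n",
                sum(ev$event[ev$train]), sum(ev$train)))
  invisible(x)
}

#' Write / read a cohort as delimited text
#'
#' Two CSV tables: `<prefix>_long.csv` (id, time, psa) and
#' `<prefix>_events.csv` (id, l, r, age, subgroup, train, true_gr_time).
#' The true reclassification time is written for test patients only; the
#' training rows carry the interval-censored observation instead.
#'
#' @param cohort a [simulateCohort()] result.
#' @param prefix path prefix for the two files.
#' @return `writeCohort` returns the file paths invisibly; `readCohort`
#'   returns a `"cohort"` (without the unobservable random effects).
#' @export
writeCohort <- function(cohort, prefix) {
  ev <- cohort$events
  ev_out <- data.frame(id = ev$id, l = ev$l, r = ev$r, age = ev$age,
                       subgroup = ev$subgroup, train = ev$train,
                       true_gr_time = ifelse(ev$train, NA_real_,
                                             ev$true_gr_time))
  fl <- paste0(prefix, "_long.csv")
  fe <- paste0(prefix, "_events.csv")
  utils::write.csv(cohort$longitudinal, fl, row.names = FALSE)
  utils::write.csv(ev_out, fe, row.names = FALSE)
  invisible(c(fl, fe))
}

#' @rdname writeCohort
#' @export
readCohort <- function(prefix) {
  long <- utils::read.csv(paste0(prefix, "_long.csv"))
  ev <- utils::read.csv(paste0(prefix, "_events.csv"))
  ev$event <- ifelse(ev$train, is.finite(ev$r), NA)
  structure(list(longitudinal = long, events = ev, b = NULL,
                 config = NULL, params = NULL, seed = NA),
            class = "cohort")
}

#' Marginal baseline hazard of a subgroup mixture
#'
#' The population-level baseline hazard implied by a mixture of subgroup
#' Weibull baselines, `h(t) = sum_g p_g f_g(t) / sum_g p_g S_g(t)`,
#' discretized to a piecewise-constant hazard. This is the single baseline a
#' model fitted to the pooled population would see, and is what the
#' prediction machinery uses when subgroup membership is (realistically)
#' unknown.
#'
#' @param config a [simConfig()].
#' @param nIntervals number of discretization intervals up to the horizon.
#' @return a [piecewiseHazard()].
#' @export
marginalBaseline <- function(config, nIntervals = 80) {
  edges <- seq(0, config$horizon, length.out = nIntervals + 1L)
  mid <- (edges[-1] + edges[-length(edges)]) / 2
  p <- config$subgroup_probs
  num <- den <- numeric(length(mid))
  for (g in seq_along(p)) {
    w <- config$subgroup_weibulls[[g]]
    S <- exp(-(mid / w[2])^w[1])
    h <- (w[1] / w[2]) * (mid / w[2])^(w[1] - 1)
    num <- num + p[g] * h * S
    den <- den + p[g] * S
  }
  piecewiseHazard(breaks = edges[-c(1, length(edges))], rates = num / den)
}
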