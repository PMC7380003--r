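#' Observed history of a surveillance patient
#'
#' Collects the PSA measurements, the time of the latest negative biopsy and
#' the entry age of one patient, the inputs from which the posterior
#' predictive distribution of the reclassification time is computed.
#'
#' @param psaTimes measurement times (years since entry).
#' @param psa raw PSA values (ng/mL), same length as `psaTimes`.
#' @param age age at entry (years).
#' @param lastBiopsy time `t` of the latest negative biopsy (years; 0 for the
#'   diagnostic biopsy at entry).
#' @param prevBiopsies optional earlier negative biopsy times.
#' @return an object of class `"patientHistory"`.
#' @export
patientHistory <- function(psaTimes, psa, age, lastBiopsy = 0,
                           prevBiopsies = numeric()) {
  psaTimes <- as.numeric(psaTimes); psa <- as.numeric(psa)
  if (length(psaTimes) != length(psa))
    stop("psaTimes and psa must have the same length", call. = FALSE)
  if (lastBiopsy < 0) stop("lastBiopsy must be >= 0", call. = FALSE)
  o <- order(psaTimes)
  structure(list(psaTimes = psaTimes[o], psa = psa[o], age = age,
                 t = lastBiopsy, prevBiopsies = sort(prevBiopsies),
                 s = if (length(psaTimes)) max(psaTimes) else lastBiopsy),
            class = "patientHistory")
}

#' @export
print.patientHistory <- function(x, ...) {
  cat(sprintf("Patient history: %d PSA measurements up to %.2f y, age %.1f\n",
              length(x$psa), x$s, x$age))
  cat(sprintf("  latest negative biopsy at t = %.2f y\n", x$t))
  invisible(x)
}

# Precompute the flat data list consumed by the compiled log-target:
# observation designs, quadrature nodes for Lambda(0 -> t), prior precision.
bPostData <- function(history, params) {
  lg <- params$long; rk <- params$risk
  y <- psaToOutcome(lg, history$psa)
  tt <- history$psaTimes
  X <- fixedDesign(lg, tt, history$age)
  Z <- randomDesign(lg, tt)
  t <- history$t
  if (t > 0) {
    pn <- panelNodes(refineEdges(panelEdges(0, t), rk$baseline))
    Xn <- fixedDesign(lg, pn$nodes, history$age)
    Zn <- randomDesign(lg, pn$nodes)
    Xnv <- fixedDesign(lg, pn$nodes, history$age, deriv = 1L)
    Znv <- randomDesign(lg, pn$nodes, deriv = 1L)
    w <- c(history$age - 70, (history$age - 70)^2)
    logh0_eta <- logBaseHaz(rk$baseline, pn$nodes) + sum(rk$gamma * w)
    qw <- pn$wts
    m0_nod <- drop(Xn %*% lg$beta); m0v_nod <- drop(Xnv %*% lg$beta)
  } else {
    qw <- numeric(); logh0_eta <- numeric()
    m0_nod <- numeric(); m0v_nod <- numeric()
    Zn <- matrix(0, 0, lg$q); Znv <- matrix(0, 0, lg$q)
  }
  list(y = y, m0_obs = drop(X %*% lg$beta), Z_obs = Z,
       sigma = lg$sigma, nu = lg$residual_df,
       qw = qw, logh0_eta = logh0_eta,
       m0_nod = m0_nod, m0v_nod = m0v_nod, Z_nod = Zn, Zv_nod = Znv,
       a1 = rk$alpha_value, a2 = rk$alpha_velocity,
       Dinv = solve(lg$D))
}

#' Posterior of the random effects given history and latest negative biopsy
#'
#' Draws from `p(b | Y(s), T* > t, theta)`, which is proportional to the
#' product of the t-residual PSA likelihood, the survival probability through
#' the latest negative biopsy, and the normal random-effects prior. Draws are
#' obtained either by random-walk Metropolis (default) or by a Laplace
#' approximation at the posterior mode with importance reweighting; both use
#' the mode and curvature found by a damped Newton ascent.
#'
#' @param history a [patientHistory()].
#' @param params a [modelParameters()] bundle.
#' @param nDraws number of retained draws.
#' @param seed integer seed (mandatory: the draws are Monte-Carlo objects and
#'   every downstream quantity must be reproducible).
#' @param method `"mcmc"` (random-walk Metropolis) or `"laplace_is"`
#'   (Laplace proposal + importance weights).
#' @param horizon administrative horizon (years) used when integrating the
#'   predictive distribution.
#' @param burn,thin MCMC burn-in and thinning (ignored for `"laplace_is"`).
#' @return a `"posteriorPredictive"` object; see [posteriorPredictive()].
#' @export
posteriorRandomEffects <- function(history, params, nDraws = 500, seed,
                                   method = c("mcmc", "laplace_is"),
                                   horizon = 20, burn = 500, thin = 2) {
  stopifnot(inherits(history, "patientHistory"),
            inherits(params, "modelParameters"))
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  if (length(history$psa) < 1L)
    stop("history must contain at least one PSA measurement", call. = FALSE)
  method <- match.arg(method)
  set.seed(as.integer(seed))
  dat <- bPostData(history, params)
  res <- .posteriorDrawsCore(dat, params$long$q, nDraws, method, burn, thin)
  posteriorPredictive(draws = res$draws, weights = res$weights,
                      params = params, age = history$age, t = history$t,
                      s = history$s, horizon = horizon,
                      diagnostics = res$diagnostics, method = method,
                      seed = seed)
}

# Core sampler working on a precomputed data list; uses the current RNG
# stream (callers own the seed).
.posteriorDrawsCore <- function(dat, q, nDraws, method = "laplace_is",
                                burn = 500, thin = 2, mode_start = NULL) {
  md <- .cpp_b_mode(if (is.null(mode_start)) rep(0, q) else mode_start, dat)
  Hn <- -md$hessian
  R <- tryCatch(chol(solve(Hn)), error = function(e) {
    chol(solve(Hn + diag(1e-6, q)))
  })
  if (method == "laplace_is") {
    df <- 4
    Zm <- matrix(rnorm(nDraws * q), nDraws, q)
    u <- sqrt(df / rchisq(nDraws, df))
    B <- sweep(Zm %*% R * u, 2L, md$mode, "+")
    ## multivariate-t log density (constants cancel in the weights);
    ## the standardized quadratic form is u^2 * ||z||^2 by construction
    quad <- u^2 * rowSums(Zm^2)
    logprop <- -0.5 * (df + q) * log1p(quad / df)
    logw <- drop(.cpp_b_logtarget_mat(B, dat)) - logprop
    logw <- logw - max(logw)
    wts <- exp(logw); wts <- wts / sum(wts)
    list(draws = B, weights = wts,
         diagnostics = list(ess = 1 / sum(wts^2), mode = md$mode,
                            converged = md$converged))
  } else {
    scale <- 2.4 / sqrt(q)
    P <- R * scale
    niter <- burn + nDraws * thin
    B <- matrix(0, nDraws, q)
    b <- md$mode
    lp <- .cpp_b_logtarget(b, dat)
    acc <- 0L; k <- 0L
    prop_all <- matrix(rnorm(niter * q), niter, q) %*% P
    lu <- log(runif(niter))
    for (i in seq_len(niter)) {
      bn <- b + prop_all[i, ]
      lpn <- .cpp_b_logtarget(bn, dat)
      if (lu[i] < lpn - lp) { b <- bn; lp <- lpn; acc <- acc + 1L }
      if (i > burn && (i - burn) %% thin == 0L) { k <- k + 1L; B[k, ] <- b }
    }
    list(draws = B, weights = rep(1 / nDraws, nDraws),
         diagnostics = list(acceptance = acc / niter, mode = md$mode,
                            converged = md$converged))
  }
}

#' Monte-Carlo representation of the predictive reclassification-time
#' distribution
#'
#' Wraps weighted random-effect draws together with the model parameters into
#' an object from which the dynamic survival probability, moments and
#' quantiles of the time of Gleason reclassification can be computed.
#'
#' @param draws matrix of random-effect draws (rows are draws).
#' @param weights normalized draw weights.
#' @param params a [modelParameters()].
#' @param age entry age of the patient.
#' @param t time of the latest negative biopsy.
#' @param s time of the latest PSA measurement.
#' @param horizon administrative horizon (years); integrals over the
#'   predictive distribution are truncated there, i.e. the reported moments
#'   are those of `min(T*, horizon)`.
#' @param diagnostics,method,seed provenance of the draws.
#' @return an object of class `"posteriorPredictive"`.
#' @export
posteriorPredictive <- function(draws, weights = NULL, params, age, t, s = t,
                                horizon = 20, diagnostics = list(),
                                method = "manual", seed = NA) {
  draws <- as.matrix(draws)
  if (is.null(weights)) weights <- rep(1 / nrow(draws), nrow(draws))
  if (abs(sum(weights) - 1) > 1e-8)
    stop("weights must sum to 1", call. = FALSE)
  if (ncol(draws) != params$long$q)
    stop("draw dimension does not match the random design", call. = FALSE)
  structure(list(draws = draws, weights = as.numeric(weights),
                 params = params, age = age, t = t, s = s,
                 horizon = horizon, diagnostics = diagnostics,
                 method = method, seed = seed,
                 cache = new.env(parent = emptyenv())),
            class = "posteriorPredictive")
}

#' @export
print.posteriorPredictive <- function(x, ...) {
  cat(sprintf(paste0("Posterior predictive for time of Gleason ",
                     "reclassification\n  %d weighted draws (%s), latest ",
                     "biopsy t = %.2f y, PSA history to s = %.2f y\n"),
              nrow(x$draws), x$method, x$t, x$s))
  if (!is.null(x$diagnostics$ess))
    cat(sprintf("  importance-sampling ESS: %.1f\n", x$diagnostics$ess))
  if (!is.null(x$diagnostics$acceptance))
    cat(sprintf("  Metropolis acceptance rate: %.2f\n",
                x$diagnostics$acceptance))
  invisible(x)
}

#' Dynamic survival probability
#'
#' `pi(u | t, s) = Pr(T* >= u | T* > t, Y(s))`, the probability that the
#' patient remains free of Gleason reclassification at `u` given that the
#' latest biopsy at `t` was negative. Computed as the weighted Monte-Carlo
#' average of `S(t -> u | b)` over the posterior draws of the random effects.
#'
#' @param pp a [posteriorPredictive()] object.
#' @param u times (years), all `>= t`; vectorized.
#' @return survival probabilities in `[0, 1]`, non-increasing in `u`.
#' @export
dynamicSurvival <- function(pp, u) {
  stopifnot(inherits(pp, "posteriorPredictive"))
  if (any(u < pp$t - 1e-12))
    stop("u must be >= the latest biopsy time t", call. = FALSE)
  u <- pmax(u, pp$t)
  out <- numeric(length(u))
  out[u == pp$t] <- 1
  ui <- unique(u[u > pp$t])
  if (length(ui)) {
    ## each query uses its own panel rule so that pi(u) is a consistent
    ## function of u (required by the adaptive quadrature built on top)
    surv <- vapply(ui, function(uu) {
      L <- cumHazDraws(pp$params$risk, pp$params$long, pp$age, pp$draws,
                       panelEdges(pp$t, uu))
      sum(pp$weights * exp(-L[, ncol(L)]))
    }, numeric(1))
    out[u > pp$t] <- surv[match(u[u > pp$t], ui)]
  }
  out
}

#' Moments and quantiles of the predictive reclassification time
#'
#' The expected time is computed through
#' `E(T*) = t + integral_t^H pi(u | t, s) du` and the variance through
#' `var(T*) = 2 integral_t^H (u - t) pi(u) du - (integral_t^H pi(u) du)^2`,
#' both by adaptive Gauss-Kronrod quadrature with the upper limit truncated at
#' the administrative horizon `H` (so they are moments of `min(T*, H)`).
#' Quantiles invert the dynamic survival curve by monotone root-finding:
#' `quantileGRTime(pp, p)` solves `pi(u) = 1 - p`, so `p = 0.5` is the median.
#'
#' @param pp a [posteriorPredictive()] object.
#' @param p probability level in (0, 1).
#' @param tol root-finding tolerance in years.
#' @return years (`expectedGRTime`, `quantileGRTime`) or years^2
#'   (`varianceGRTime`). If the requested quantile lies beyond the horizon
#'   (`pi(H) > 1 - p`) the horizon is returned with attribute
#'   `censored = TRUE`.
#' @export
expectedGRTime <- function(pp) {
  ints <- ppMomentIntegrals(pp)
  pp$t + ints$I1
}

#' @rdname expectedGRTime
#' @export
varianceGRTime <- function(pp) {
  ints <- ppMomentIntegrals(pp)
  max(0, 2 * ints$I2 - ints$I1^2)
}

# Moment integrals by composite 15-point Gauss-Kronrod panels over [t, H],
# with panel edges aligned to any piecewise-constant baseline breakpoints so
# the integrand is smooth within every panel. The survival values at all
# quadrature nodes come from one cumulative-hazard sweep, so the curve is a
# single consistent function.
ppMomentIntegrals <- function(pp) {
  if (!is.null(pp$cache$moments)) return(pp$cache$moments)
  t <- pp$t; H <- pp$horizon
  edges <- refineEdges(panelEdges(t, H, step = 0.25),
                       pp$params$risk$baseline)
  pn <- panelNodes(edges, rule = .gk15)
  L <- cumHazDraws(pp$params$risk, pp$params$long, pp$age, pp$draws,
                   c(t, pn$nodes))
  piv <- drop(pp$weights %*% exp(-L))
  I1 <- sum(pn$wts * piv)
  I2 <- sum(pn$wts * (pn$nodes - t) * piv)
  pp$cache$moments <- list(I1 = I1, I2 = I2)
  pp$cache$moments
}

#' @rdname expectedGRTime
#' @export
quantileGRTime <- function(pp, p, tol = 1e-4) {
  stopifnot(p > 0, p < 1)
  target <- 1 - p
  piH <- dynamicSurvival(pp, pp$horizon)
  if (piH > target) {
    out <- pp$horizon
    attr(out, "censored") <- TRUE
    return(out)
  }
  if (target >= 1) return(pp$t)
  uniroot(function(u) dynamicSurvival(pp, u) - target,
          lower = pp$t, upper = pp$horizon, tol = tol)$root
}
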