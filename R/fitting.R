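#' Fit the joint model to an interval-censored training cohort
#'
#' Bayesian estimation of the joint model by Markov chain Monte Carlo: the
#' PSA likelihood (t residuals), the interval-censored survival likelihood
#' `S(0 -> l | b) - S(0 -> r | b)` (or `S(0 -> l | b)` for right-censored
#' patients), and the normal random-effects prior are combined with
#' weakly-informative zero-centred normal priors on the coefficients, an
#' inverse-Wishart prior on the random-effects covariance `D` (updated by a
#' conjugate Gibbs step), and a Weibull baseline hazard. All other
#' parameters use adaptive random-walk Metropolis updates; the per-patient
#' random effects are updated in blocks scaled by `chol(D)`.
#'
#' @param cohort a [simulateCohort()]/[readCohort()] cohort; only training
#'   rows (`events$train`) are used.
#' @param skeleton a [longitudinalSpec()] giving the model structure (knots,
#'   design; its coefficient values are ignored).
#' @param nIter,nBurn,thin chain length, burn-in and thinning.
#' @param seed integer seed.
#' @param priors list of prior scales: `sd_beta`, `sd_assoc` (gamma and
#'   alpha), `sd_logsigma`, `sd_logwb` (log Weibull parameters).
#' @return an object of class `"jointModelFit"` with posterior draws,
#'   posterior means (as a [modelParameters()] in `$params`), convergence
#'   diagnostics (split R-hat and effective sample size per parameter) and a
#'   data summary. Non-convergence (any R-hat > 1.1) sets
#'   `$diagnostics$converged = FALSE` with a warning.
#' @export
fitJointModel <- function(cohort, skeleton = priasParams()$long,
                          nIter = 3500, nBurn = 1750, thin = 2, seed,
                          priors = list(sd_beta = 10, sd_assoc = 10,
                                        sd_logsigma = 2, sd_logwb = 2)) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  set.seed(as.integer(seed))
  ev <- cohort$events[cohort$events$train, ]
  if (!nrow(ev)) stop("cohort has no training patients", call. = FALSE)
  long <- cohort$longitudinal[cohort$longitudinal$id %in% ev$id, ]
  n <- nrow(ev)
  q <- skeleton$q

  ## observation blocks, ordered by patient
  obs <- long[order(match(long$id, ev$id), long$time), ]
  pid <- match(obs$id, ev$id)
  y <- psaToOutcome(skeleton, obs$psa)
  ages_row <- ev$age[pid]
  X <- cbind(1, if (skeleton$include_age) cbind(ages_row - 70,
                                                (ages_row - 70)^2),
             timeBasis(skeleton$fixed_time_basis, obs$time,
                       skeleton$internal_knots, skeleton$boundary_knots))
  Z <- randomDesign(skeleton, obs$time)
  cnt <- tabulate(pid, n)
  obs_e <- cumsum(cnt); obs_s <- c(0L, obs_e[-n])

  ## quadrature blocks for Lambda(0 -> l) and Lambda(0 -> r)
  mkblock <- function(times) {
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      ti <- times[i]
      if (is.finite(ti) && ti > 0) {
        pn <- panelNodes(panelEdges(0, ti, step = 1))
        rows[[i]] <- data.frame(i = i, node = pn$nodes, w = pn$wts)
      }
    }
    df <- do.call(rbind, rows)
    if (is.null(df)) df <- data.frame(i = integer(), node = numeric(),
                                      w = numeric())
    cnt <- tabulate(df$i, n)
    e <- cumsum(cnt); s <- c(0L, e[-n])
    ages_n <- ev$age[df$i]
    Xn <- cbind(1, if (skeleton$include_age) cbind(ages_n - 70,
                                                   (ages_n - 70)^2),
                timeBasis(skeleton$fixed_time_basis, df$node,
                          skeleton$internal_knots, skeleton$boundary_knots))
    Xnv <- cbind(0, if (skeleton$include_age) cbind(0 * ages_n, 0 * ages_n),
                 timeBasis(skeleton$fixed_time_basis, df$node,
                           skeleton$internal_knots, skeleton$boundary_knots,
                           deriv = 1L))
    Zn <- randomDesign(skeleton, df$node)
    Znv <- randomDesign(skeleton, df$node, deriv = 1L)
    list(w = df$w, lognod = log(df$node), X = Xn, Z = Zn, Xv = Xnv,
         Zv = Znv, s = s, e = e)
  }
  Lb <- mkblock(ev$l)
  Rb <- mkblock(ifelse(ev$event, ev$r, NA_real_))

  dat <- list(y = y, X = X, Z = Z, obs_s = obs_s, obs_e = obs_e,
              wL = Lb$w, lognodL = Lb$lognod, XL = Lb$X, ZL = Lb$Z,
              XLv = Lb$Xv, ZLv = Lb$Zv, l_s = Lb$s, l_e = Lb$e,
              wR = Rb$w, lognodR = Rb$lognod, XR = Rb$X, ZR = Rb$Z,
              XRv = Rb$Xv, ZRv = Rb$Zv, r_s = Rb$s, r_e = Rb$e,
              event = as.integer(ev$event),
              W = cbind(ev$age - 70, (ev$age - 70)^2),
              n = n, p = skeleton$p, q = q, nu = skeleton$residual_df,
              sd_beta = priors$sd_beta, sd_assoc = priors$sd_assoc,
              sd_logsigma = priors$sd_logsigma, sd_logwb = priors$sd_logwb,
              ## least-squares-shaped proposal factors for the correlated
              ## coefficient blocks (ridged so degenerate designs still
              ## yield a valid, if uninformed, proposal shape)
              Lbeta = t(chol(solve(crossprod(X) / nrow(X) +
                                     diag(1e-3, ncol(X))))),
              Lgamma = t(chol(solve(crossprod(
                cbind(ev$age - 70, (ev$age - 70)^2)) / n + diag(1e-3, 2)))),
              Atr = reProjection(skeleton))

  beta0 <- qr.coef(qr(X), y)
  beta0[is.na(beta0)] <- 0
  sigma0 <- max(0.05, sd(y - X %*% beta0) * 0.7)
  scale0 <- if (any(ev$event)) max(1, stats::median(ev$r[ev$event])) else 5
  init <- list(beta = beta0, gamma = c(0, 0), a1 = 0, a2 = 0,
               sigma = sigma0, shape = 1.5, scale = scale0,
               b = matrix(0, n, q), D = diag(q))

  raw <- .cpp_fit_mcmc(dat, init, as.integer(nIter), as.integer(nBurn),
                       as.integer(thin))

  p <- skeleton$p
  cn <- c(paste0("beta", seq_len(p) - 1L), "gamma1", "gamma2",
          "alpha_value", "alpha_velocity", "log_sigma", "log_shape",
          "log_scale")
  theta <- raw$theta
  colnames(theta) <- cn
  ## transform the log-scale parameters to their natural scale for reporting
  draws <- as.data.frame(theta)
  draws$sigma <- exp(draws$log_sigma)
  draws$shape <- exp(draws$log_shape)
  draws$scale <- exp(draws$log_scale)

  rhat <- vapply(as.data.frame(theta), splitRhat, numeric(1))
  ess <- vapply(as.data.frame(theta), essChain, numeric(1))
  converged <- all(is.finite(rhat)) && max(rhat, na.rm = TRUE) <= 1.1
  if (!converged)
    warning("MCMC may not have converged: max split R-hat = ",
            round(max(rhat, na.rm = TRUE), 3), call. = FALSE)

  Dmean <- apply(raw$D, c(1, 2), mean)
  pm <- colMeans(theta)
  long_hat <- longitudinalSpec(
    beta = pm[seq_len(p)], D = Dmean, sigma = exp(pm["log_sigma"]),
    residual_df = skeleton$residual_df,
    internal_knots = skeleton$internal_knots,
    boundary_knots = skeleton$boundary_knots,
    re_internal_knots = skeleton$re_internal_knots,
    include_age = skeleton$include_age,
    fixed_time_basis = skeleton$fixed_time_basis,
    random_time_basis = skeleton$random_time_basis,
    psa_scale = skeleton$psa_scale)
  risk_hat <- riskSpec(gamma = pm[c("gamma1", "gamma2")],
                       alpha_value = pm["alpha_value"],
                       alpha_velocity = pm["alpha_velocity"],
                       baseline = weibullHazard(exp(pm["log_shape"]),
                                                exp(pm["log_scale"])))

  structure(list(draws = draws, D_draws = raw$D,
                 params = modelParameters(long_hat, risk_hat),
                 diagnostics = list(rhat = rhat, ess = ess,
                                    converged = converged,
                                    acc_theta = raw$acc_theta,
                                    acc_b = raw$acc_b),
                 data_summary = list(n = n, nEvents = sum(ev$event),
                                     nObs = length(y)),
                 seed = seed, nIter = nIter, nBurn = nBurn, thin = thin),
            class = "jointModelFit")
}

#' @export
print.jointModelFit <- function(x, ...) {
  cat(sprintf("Joint model fit: %d training patients (%d events, %d PSA obs)\n",
              x$data_summary$n, x$data_summary$nEvents, x$data_summary$nObs))
  cat(sprintf("  %d retained draws; max split R-hat %.3f; converged: %s\n",
              nrow(x$draws), max(x$diagnostics$rhat, na.rm = TRUE),
              x$diagnostics$converged))
  cat("\nPosterior means:\n")
  print(x$params)
  invisible(x)
}

#' Credible interval for a fitted parameter
#' @param fit a `jointModelFit`.
#' @param par a column of `fit$draws`.
#' @param level credibility level.
#' @return length-2 numeric vector.
#' @export
credInterval <- function(fit, par, level = 0.95) {
  a <- (1 - level) / 2
  unname(quantile(fit$draws[[par]], c(a, 1 - a)))
}

# split R-hat of a single chain (halves as pseudo-chains)
splitRhat <- function(x) {
  n <- floor(length(x) / 2)
  if (n < 4) return(NA_real_)
  h <- list(x[seq_len(n)], x[(length(x) - n + 1):length(x)])
  m <- vapply(h, mean, numeric(1))
  v <- vapply(h, var, numeric(1))
  Wv <- mean(v)
  Bv <- n * var(m)
  if (Wv <= 0) return(NA_real_)
  sqrt(((n - 1) / n * Wv + Bv / n) / Wv)
}

# effective sample size by the initial positive sequence estimator
essChain <- function(x) {
  n <- length(x)
  if (n < 10 || sd(x) == 0) return(NA_real_)
  ac <- acf(x, lag.max = min(n - 1, 200), plot = FALSE)$acf[-1]
  pos <- which(ac < 0)
  k <- if (length(pos)) pos[1] - 1 else length(ac)
  n / (1 + 2 * sum(ac[seq_len(k)]))
}

# Projection of the random-effects design onto the fixed design: the random
# natural-spline space (fewer knots, same boundary) is nested in the fixed
# one, so each random basis column is an exact linear combination of the
# intercept and the fixed spline columns. Used by the sampler's
# likelihood-invariant translation move.
reProjection <- function(skeleton) {
  grid <- seq(skeleton$boundary_knots[1], skeleton$boundary_knots[2],
              length.out = 101)
  Zg <- randomDesign(skeleton, grid)
  Fg <- cbind(1, timeBasis(skeleton$fixed_time_basis, grid,
                           skeleton$internal_knots,
                           skeleton$boundary_knots))
  co <- qr.coef(qr(Fg), Zg)            # (1 + nspline) x q
  co[is.na(co)] <- 0
  resid <- max(abs(Fg %*% co - Zg))
  if (resid > 1e-6)
    warning("random-effects basis not nested in the fixed design ",
            "(residual ", format(resid), "); translation move is approximate",
            call. = FALSE)
  A <- matrix(0, skeleton$p, skeleton$q)
  A[1, ] <- co[1, ]
  if (nrow(co) > 1) {
    off <- 1L + 2L * skeleton$include_age
    A[off + seq_len(nrow(co) - 1L), ] <- co[-1, , drop = FALSE]
  }
  A
}
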