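# Shared fixtures: small parameter sets and oracle helpers.

# full PRIAS-like parameter bundle (simulation truth)
fullParams <- function() priasParams()

# minimal 1-D toy: random intercept only, no age terms, linear time trend
toyParams <- function(sigma = 0.3, D0 = 0.5, slope = 0.1,
                      baseline = weibullHazard(1.5, 6),
                      alpha_value = 0.3, alpha_velocity = 0) {
  long <- longitudinalSpec(beta = c(2, slope), D = matrix(D0, 1, 1),
                          sigma = sigma, include_age = FALSE,
                          fixed_time_basis = "linear",
                          random_time_basis = "none")
  risk <- riskSpec(gamma = c(0, 0), alpha_value = alpha_value,
                   alpha_velocity = alpha_velocity, baseline = baseline,
                   form = if (alpha_velocity != 0) "value+velocity" else "value")
  modelParameters(long, risk)
}

# constant-hazard model whose predictive distribution is exactly
# exponential: pi(u | t) = exp(-rate * (u - t))
exponentialPP <- function(t = 2, rate = 1, horizon = 20) {
  long <- longitudinalSpec(beta = 0, D = matrix(1e-8, 1, 1), sigma = 0.1,
                          include_age = FALSE, fixed_time_basis = "none",
                          random_time_basis = "none")
  risk <- riskSpec(gamma = c(0, 0), alpha_value = 0, alpha_velocity = 0,
                   baseline = piecewiseHazard(numeric(), rate),
                   form = "value")
  posteriorPredictive(draws = matrix(0, 1, 1), weights = 1,
                      params = modelParameters(long, risk),
                      age = 70, t = t, s = t, horizon = horizon)
}

# dense dynamic-survival evaluation for trapezoid oracles, chunked over
# draws to bound memory
piDense <- function(pp, grid) {
  stopifnot(grid[1] >= pp$t)
  out <- numeric(length(grid))
  out[grid == pp$t] <- 1
  gpos <- grid[grid > pp$t]
  acc <- numeric(length(gpos))
  idx <- seq_len(nrow(pp$draws))
  for (ch in split(idx, ceiling(idx / 25))) {
    L <- persched:::cumHazDraws(pp$params$risk, pp$params$long, pp$age,
                                pp$draws[ch, , drop = FALSE], c(pp$t, gpos))
    acc <- acc + drop(pp$weights[ch] %*% exp(-L))
  }
  out[grid > pp$t] <- acc
  out
}

trapz <- function(x, y) sum((y[-1] + y[-length(y)]) / 2 * diff(x))

# grid-quadrature oracle for the 1-D random-intercept posterior
# p(b | Y, T* > t) on a fixed grid; returns normalized weights and moments.
# The survival factor is computed for all grid values in one vectorized
# cumulative-hazard sweep.
gridPosterior1D <- function(history, params, bgrid) {
  lg <- params$long; rk <- params$risk
  y <- persched:::psaToOutcome(lg, history$psa)
  loglik <- vapply(bgrid, function(b) {
    m <- y - (lg$beta[1] + lg$beta[2] * history$psaTimes + b)
    sum(dt(m / lg$sigma, df = lg$residual_df, log = TRUE) - log(lg$sigma))
  }, numeric(1))
  logsurv <- if (history$t > 0) {
    L <- persched:::cumHazDraws(rk, lg, history$age, matrix(bgrid),
                                persched:::panelEdges(0, history$t))
    -L[, ncol(L)]
  } else 0
  logprior <- dnorm(bgrid, 0, sqrt(lg$D[1, 1]), log = TRUE)
  lp <- loglik + logsurv + logprior
  w <- exp(lp - max(lp)); w <- w / sum(w)
  list(w = w, mean = sum(w * bgrid),
       var = sum(w * bgrid^2) - sum(w * bgrid)^2)
}

# prediction-time parameters for the mixture population: same coefficients,
# subgroup-mixture marginal baseline
predictionParams <- function(params, config) {
  modelParameters(params$long,
                  riskSpec(gamma = params$risk$gamma,
                           alpha_value = params$risk$alpha_value,
                           alpha_velocity = params$risk$alpha_velocity,
                           baseline = marginalBaseline(config),
                           form = params$risk$form))
}
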