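#' Subject-specific PSA trajectory and velocity
#'
#' Evaluates the error-free log-scale PSA level
#' `m(t) = x(t, age)' beta + z(t)' b` and its exact analytic time derivative
#' `m'(t)` (the PSA velocity), where `x` and `z` are the fixed- and
#' random-effects designs of the longitudinal sub-model.
#'
#' @param spec a [longitudinalSpec()].
#' @param age age at entry (years).
#' @param b random-effect vector for the subject (length `spec$q`).
#' @param t evaluation times (years); beyond the boundary knots the spline
#'   continues with its linear tails.
#' @return a list with numeric vectors `value` and `velocity`.
#' @examples
#' sp <- longitudinalSpec(beta = rep(0, 7), D = diag(3), sigma = 0.3)
#' psaTrajectory(sp, age = 65, b = c(0, 0, 0), t = c(1, 2))
#' @export
psaTrajectory <- function(spec, age, b, t) {
  stopifnot(inherits(spec, "longSpec"))
  b <- as.numeric(b)
  if (length(b) != spec$q)
    stop(sprintf("b has length %d but the random design has %d columns",
                 length(b), spec$q), call. = FALSE)
  X <- fixedDesign(spec, t, age)
  Z <- randomDesign(spec, t)
  Xd <- fixedDesign(spec, t, age, deriv = 1L)
  Zd <- randomDesign(spec, t, deriv = 1L)
  list(value = drop(X %*% spec$beta + Z %*% b),
       velocity = drop(Xd %*% spec$beta + Zd %*% b))
}

#' Hazard of Gleason reclassification
#'
#' `h(t) = h0(t) * exp(gamma' w + alpha_value * m(t) + alpha_velocity * m'(t))`
#' with baseline covariates `w = ((age - 70), (age - 70)^2)`.
#'
#' @param risk a [riskSpec()].
#' @param spec a [longitudinalSpec()].
#' @param age age at entry (years).
#' @param b subject random effects.
#' @param t positive times (years); vectorized.
#' @return hazard rates (1/year).
#' @export
hazardRate <- function(risk, spec, age, b, t) {
  stopifnot(inherits(risk, "riskSpec"))
  if (any(t < 0)) stop("t must be >= 0", call. = FALSE)
  traj <- psaTrajectory(spec, age, b, t)
  w <- c(age - 70, (age - 70)^2)
  eta <- sum(risk$gamma * w) + risk$alpha_value * traj$value +
    risk$alpha_velocity * traj$velocity
  baseHaz(risk$baseline, t) * exp(eta)
}

#' Conditional survival probability
#'
#' `S(t0 -> t1 | b) = exp(-int_{t0}^{t1} h(v) dv)`, the probability of
#' remaining free of Gleason reclassification over `(t0, t1]` given survival
#' to `t0`, for a subject with known random effects. The cumulative hazard is
#' computed by adaptive Gauss-Kronrod quadrature.
#'
#' @inheritParams hazardRate
#' @param t0,t1 interval endpoints, `0 <= t0 <= t1`.
#' @param rel.tol relative tolerance of the quadrature.
#' @return a probability in (0, 1].
#' @export
conditionalSurvival <- function(risk, spec, age, b, t0, t1,
                                rel.tol = 1e-9) {
  if (t1 < t0 || t0 < 0)
    stop("need 0 <= t0 <= t1", call. = FALSE)
  if (t1 == t0) return(1)
  ch <- integrate(function(v) hazardRate(risk, spec, age, b, v),
                  lower = t0, upper = t1,
                  rel.tol = rel.tol, abs.tol = 1e-12,
                  subdivisions = 200L)$value
  exp(-ch)
}
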