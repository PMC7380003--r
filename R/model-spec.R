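#' Longitudinal sub-model specification
#'
#' Describes the mixed-effects model for the log-scale PSA trajectory:
#' fixed effects are an intercept, optional centred-age terms `(age - 70)` and
#' `(age - 70)^2`, and a natural cubic spline in follow-up time; random effects
#' are a subject-level intercept plus a (smaller) natural spline in time. The
#' residual is t-distributed with `residual_df` degrees of freedom and scale
#' `sigma`, and is independent of the random effects.
#'
#' @param beta fixed-effect coefficient vector (length must match the implied
#'   fixed design).
#' @param D random-effects covariance matrix (symmetric positive-definite,
#'   dimension matching the implied random design).
#' @param sigma residual scale (> 0).
#' @param residual_df degrees of freedom of the t-distributed residual.
#' @param internal_knots internal knots of the fixed-effects time spline
#'   (years).
#' @param boundary_knots boundary knots (years); beyond them the spline
#'   continues linearly.
#' @param re_internal_knots internal knots of the random-effects time spline.
#' @param include_age include `(age - 70)` and `(age - 70)^2` fixed effects?
#' @param fixed_time_basis `"ns"` (natural spline), `"linear"` (a single
#'   column `t`) or `"none"`.
#' @param random_time_basis `"ns"`, `"linear"` or `"none"` (random intercept
#'   only).
#' @param psa_scale transformation linking raw PSA (ng/mL) to the modeled
#'   outcome: `"log2psa1"` for log2(PSA + 1) or `"log2psa"` for log2(PSA).
#' @return an object of class `"longSpec"`.
#' @export
longitudinalSpec <- function(beta, D, sigma, residual_df = 3,
                             internal_knots = c(0.1, 0.5, 4),
                             boundary_knots = c(0, 7),
                             re_internal_knots = 0.1,
                             include_age = TRUE,
                             fixed_time_basis = c("ns", "linear", "none"),
                             random_time_basis = c("ns", "linear", "none"),
                             psa_scale = c("log2psa1", "log2psa")) {
  fixed_time_basis <- match.arg(fixed_time_basis)
  random_time_basis <- match.arg(random_time_basis)
  psa_scale <- match.arg(psa_scale)
  beta <- as.numeric(beta)
  D <- as.matrix(D)
  if (!isTRUE(all.equal(D, t(D), tolerance = 1e-8)))
    stop("D must be symmetric", call. = FALSE)
  ev <- eigen(D, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0))
    stop("D must be positive-definite", call. = FALSE)
  if (!is.numeric(sigma) || sigma <= 0) stop("sigma must be > 0", call. = FALSE)
  if (residual_df <= 0) stop("residual_df must be > 0", call. = FALSE)
  stopifnot(length(boundary_knots) == 2L)

  p_time <- switch(fixed_time_basis,
                   ns = length(internal_knots) + 1L, linear = 1L, none = 0L)
  q_time <- switch(random_time_basis,
                   ns = length(re_internal_knots) + 1L, linear = 1L, none = 0L)
  p <- 1L + 2L * include_age + p_time
  q <- 1L + q_time
  if (length(beta) != p)
    stop(sprintf("beta has length %d but the fixed design has %d columns",
                 length(beta), p), call. = FALSE)
  if (nrow(D) != q)
    stop(sprintf("D is %dx%d but the random design has %d columns",
                 nrow(D), ncol(D), q), call. = FALSE)

  structure(list(beta = beta, D = D, sigma = sigma, residual_df = residual_df,
                 internal_knots = as.numeric(internal_knots),
                 boundary_knots = as.numeric(boundary_knots),
                 re_internal_knots = as.numeric(re_internal_knots),
                 include_age = include_age,
                 fixed_time_basis = fixed_time_basis,
                 random_time_basis = random_time_basis,
                 psa_scale = psa_scale, p = p, q = q),
            class = "longSpec")
}

#' @export
print.longSpec <- function(x, ...) {
  cat("Longitudinal sub-model (log-scale PSA trajectory)\n")
  cat(sprintf("  fixed design : intercept%s + %s time basis (%d coefficients)\n",
              if (x$include_age) " + (age-70) + (age-70)^2" else "",
              x$fixed_time_basis, x$p))
  cat(sprintf("  random design: intercept + %s time basis (q = %d)\n",
              x$random_time_basis, x$q))
  cat(sprintf("  residual     : t(df = %g), scale sigma = %.3g\n",
              x$residual_df, x$sigma))
  cat(sprintf("  outcome scale: %s\n",
              if (x$psa_scale == "log2psa1") "log2(PSA + 1)" else "log2(PSA)"))
  invisible(x)
}

## -- design matrices ---------------------------------------------------------

timeBasis <- function(kind, t, knots, boundary, deriv = 0L) {
  switch(kind,
         ns = nsBasis(t, knots, boundary, deriv),
         linear = matrix(if (deriv == 0L) t else if (deriv == 1L)
           rep(1, length(t)) else 0, ncol = 1L),
         none = matrix(0, length(t), 0L))
}

fixedDesign <- function(spec, t, age, deriv = 0L) {
  n <- length(t)
  icpt <- if (deriv == 0L) rep(1, n) else rep(0, n)
  agecols <- if (spec$include_age) {
    a <- age - 70
    if (deriv == 0L) cbind(rep(a, length.out = n), rep(a^2, length.out = n))
    else matrix(0, n, 2L)
  } else matrix(0, n, 0L)
  cbind(icpt, agecols,
        timeBasis(spec$fixed_time_basis, t, spec$internal_knots,
                  spec$boundary_knots, deriv))
}

randomDesign <- function(spec, t, deriv = 0L) {
  n <- length(t)
  icpt <- if (deriv == 0L) rep(1, n) else rep(0, n)
  cbind(icpt,
        timeBasis(spec$random_time_basis, t, spec$re_internal_knots,
                  spec$boundary_knots, deriv))
}

#' Raw PSA to the modeled outcome scale and back
#' @param spec a `longSpec`.
#' @param psa raw PSA values (ng/mL).
#' @return transformed values.
#' @keywords internal
psaToOutcome <- function(spec, psa) {
  if (spec$psa_scale == "log2psa1") log2(psa + 1) else log2(psa)
}

outcomeToPsa <- function(spec, y) {
  if (spec$psa_scale == "log2psa1") 2^y - 1 else 2^y
}

## -- baseline hazards ---------------------------------------------------------

#' Weibull baseline hazard
#'
#' `h0(t) = (shape/scale) * (t/scale)^(shape-1)`.
#'
#' @param shape,scale positive Weibull parameters.
#' @return an object of class `"baselineHazard"`.
#' @export
weibullHazard <- function(shape, scale) {
  if (shape <= 0 || scale <= 0) stop("shape and scale must be > 0", call. = FALSE)
  structure(list(kind = "weibull", shape = shape, scale = scale),
            class = "baselineHazard")
}

#' Piecewise-constant baseline hazard
#'
#' @param breaks strictly increasing interior breakpoints (years); the first
#'   interval starts at 0 and the last is open-ended.
#' @param rates non-negative rates, one per interval (`length(breaks) + 1`).
#' @return an object of class `"baselineHazard"`.
#' @export
piecewiseHazard <- function(breaks, rates) {
  breaks <- as.numeric(breaks)
  rates <- as.numeric(rates)
  if (length(breaks) && (is.unsorted(breaks, strictly = TRUE) || any(breaks <= 0)))
    stop("breaks must be strictly increasing and positive", call. = FALSE)
  if (length(rates) != length(breaks) + 1L)
    stop("need one rate per interval (length(breaks) + 1)", call. = FALSE)
  if (any(rates < 0)) stop("rates must be >= 0", call. = FALSE)
  structure(list(kind = "piecewise_constant", breaks = breaks, rates = rates),
            class = "baselineHazard")
}

#' @export
print.baselineHazard <- function(x, ...) {
  if (x$kind == "weibull")
    cat(sprintf("Weibull baseline hazard: shape %.3g, scale %.3g\n",
                x$shape, x$scale))
  else
    cat(sprintf("Piecewise-constant baseline hazard: %d intervals\n",
                length(x$rates)))
  invisible(x)
}

#' Baseline hazard and cumulative baseline hazard
#' @param bh a `baselineHazard`.
#' @param t non-negative times (years).
#' @return numeric vector.
#' @export
baseHaz <- function(bh, t) {
  if (any(t < 0)) stop("t must be >= 0", call. = FALSE)
  if (bh$kind == "weibull") {
    (bh$shape / bh$scale) * (t / bh$scale)^(bh$shape - 1)
  } else {
    bh$rates[findInterval(t, bh$breaks) + 1L]
  }
}

#' @rdname baseHaz
#' @export
baseCumHaz <- function(bh, t) {
  if (any(t < 0)) stop("t must be >= 0", call. = FALSE)
  if (bh$kind == "weibull") {
    (t / bh$scale)^bh$shape
  } else {
    edges <- c(0, bh$breaks)
    vapply(t, function(ti) {
      hi <- pmin(c(bh$breaks, Inf), ti)
      sum(pmax(hi - edges, 0) * bh$rates)
    }, numeric(1))
  }
}

logBaseHaz <- function(bh, t) {
  if (bh$kind == "weibull")
    log(bh$shape / bh$scale) + (bh$shape - 1) * log(t / bh$scale)
  else log(baseHaz(bh, t))
}

## -- relative-risk sub-model --------------------------------------------------

#' Relative-risk sub-model specification
#'
#' Hazard of Gleason reclassification:
#' `h(t) = h0(t) * exp(gamma1*(age-70) + gamma2*(age-70)^2 +
#'          alpha_value * m(t) + alpha_velocity * m'(t))`,
#' where `m(t)` is the error-free log-scale PSA level and `m'(t)` its velocity.
#'
#' @param gamma length-2 coefficients on `(age - 70)` and `(age - 70)^2`.
#' @param alpha_value association with the PSA level `m(t)`.
#' @param alpha_velocity association with the PSA velocity `m'(t)`.
#' @param baseline a [weibullHazard()] or [piecewiseHazard()].
#' @param form functional form of the association: `"value"` or
#'   `"value+velocity"`.
#' @return an object of class `"riskSpec"`.
#' @export
riskSpec <- function(gamma = c(0, 0), alpha_value = 0, alpha_velocity = 0,
                     baseline = weibullHazard(3, 5),
                     form = c("value+velocity", "value")) {
  form <- match.arg(form)
  gamma <- as.numeric(gamma)
  if (length(gamma) != 2L) stop("gamma must have length 2", call. = FALSE)
  vals <- c(gamma, alpha_value, alpha_velocity)
  if (!all(is.finite(vals))) stop("coefficients must be finite", call. = FALSE)
  if (form == "value" && alpha_velocity != 0)
    stop("form 'value' requires alpha_velocity == 0", call. = FALSE)
  if (!inherits(baseline, "baselineHazard"))
    stop("baseline must be a baselineHazard", call. = FALSE)
  structure(list(gamma = gamma, alpha_value = alpha_value,
                 alpha_velocity = alpha_velocity, baseline = baseline,
                 form = form),
            class = "riskSpec")
}

#' @export
print.riskSpec <- function(x, ...) {
  cat("Relative-risk sub-model for Gleason reclassification\n")
  cat(sprintf("  gamma (age, age^2): %.4g, %.4g\n", x$gamma[1], x$gamma[2]))
  cat(sprintf("  alpha (value, velocity): %.4g, %.4g [%s]\n",
              x$alpha_value, x$alpha_velocity, x$form))
  print(x$baseline)
  invisible(x)
}

## -- parameter bundle ---------------------------------------------------------

#' Bundle of joint-model population parameters
#'
#' @param long a [longitudinalSpec()].
#' @param risk a [riskSpec()].
#' @return an object of class `"modelParameters"`.
#' @export
modelParameters <- function(long, risk) {
  stopifnot(inherits(long, "longSpec"), inherits(risk, "riskSpec"))
  structure(list(long = long, risk = risk), class = "modelParameters")
}

#' @export
print.modelParameters <- function(x, ...) {
  cat("Joint-model population parameters\n\n")
  print(x$long); cat("\n"); print(x$risk)
  invisible(x)
}

#' Read / write a parameter bundle as YAML
#'
#' The serialized form has named blocks `beta`, `D`, `sigma`, `residual_df`,
#' `gamma`, `alpha`, `baseline` and `spline`, so fitted or hand-specified
#' parameters can be exchanged as plain text.
#'
#' @param params a `modelParameters` object.
#' @param path file path.
#' @return `readModelParameters` returns a `modelParameters`;
#'   `writeModelParameters` returns `path` invisibly.
#' @export
writeModelParameters <- function(params, path) {
  lg <- params$long; rk <- params$risk
  obj <- list(
    beta = as.numeric(lg$beta),
    D = unname(apply(lg$D, 1L, as.numeric, simplify = FALSE)),
    sigma = lg$sigma,
    residual_df = lg$residual_df,
    gamma = as.numeric(rk$gamma),
    alpha = list(value = rk$alpha_value, velocity = rk$alpha_velocity),
    baseline = if (rk$baseline$kind == "weibull")
      list(kind = "weibull", shape = rk$baseline$shape,
           scale = rk$baseline$scale)
    else list(kind = "piecewise_constant",
              breaks = as.numeric(rk$baseline$breaks),
              rates = as.numeric(rk$baseline$rates)),
    spline = list(internal_knots = lg$internal_knots,
                  boundary_knots = lg$boundary_knots,
                  re_internal_knots = lg$re_internal_knots,
                  fixed_time_basis = lg$fixed_time_basis,
                  random_time_basis = lg$random_time_basis),
    include_age = lg$include_age,
    psa_scale = lg$psa_scale)
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname writeModelParameters
#' @export
readModelParameters <- function(path) {
  obj <- yaml::read_yaml(path)
  D <- do.call(rbind, lapply(obj$D, as.numeric))
  long <- longitudinalSpec(
    beta = obj$beta, D = D, sigma = obj$sigma,
    residual_df = obj$residual_df,
    internal_knots = obj$spline$internal_knots,
    boundary_knots = obj$spline$boundary_knots,
    re_internal_knots = obj$spline$re_internal_knots,
    include_age = isTRUE(obj$include_age),
    fixed_time_basis = obj$spline$fixed_time_basis,
    random_time_basis = obj$spline$random_time_basis,
    psa_scale = obj$psa_scale)
  bl <- if (obj$baseline$kind == "weibull")
    weibullHazard(obj$baseline$shape, obj$baseline$scale)
  else piecewiseHazard(obj$baseline$breaks, obj$baseline$rates)
  alpha <- obj$alpha
  risk <- riskSpec(gamma = obj$gamma,
                   alpha_value = alpha$value %||% alpha[[1]],
                   alpha_velocity = alpha$velocity %||% alpha[[2]],
                   baseline = bl,
                   form = if ((alpha$velocity %||% alpha[[2]]) != 0)
                     "value+velocity" else "value")
  modelParameters(long, risk)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
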