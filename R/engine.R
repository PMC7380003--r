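# Fast evaluation engine for schedule experiments.
#
# The fixed-effects design splits into a scalar age offset plus a shared
# function of time, so all spline bases, baseline log-hazards and random
# designs at the quadrature nodes of the global grid [0, horizon] can be
# precomputed once per parameter set. Per patient-visit work then reduces to
# one matrix product over the posterior draws.

makeCurveEngine <- function(params, control) {
  lg <- params$long; rk <- params$risk
  H <- control$horizon
  bidx <- if (lg$include_age) 4L else 2L

  nodeSet <- function(edges, rule) {
    pn <- panelNodes(edges, rule)
    nT <- timeBasis(lg$fixed_time_basis, pn$nodes, lg$internal_knots,
                    lg$boundary_knots)
    nTd <- timeBasis(lg$fixed_time_basis, pn$nodes, lg$internal_knots,
                     lg$boundary_knots, deriv = 1L)
    bspl <- lg$beta[seq.int(bidx, length.out = ncol(nT))]
    list(nodes = pn$nodes, wts = pn$wts, seg = pn$seg,
         logh0 = logBaseHaz(rk$baseline, pn$nodes),
         fm = lg$beta[1] + if (ncol(nT)) drop(nT %*% bspl) else 0,
         fv = if (ncol(nTd)) drop(nTd %*% bspl)
              else rep(0, length(pn$nodes)),
         Z = randomDesign(lg, pn$nodes),
         Zd = randomDesign(lg, pn$nodes, deriv = 1L))
  }

  env <- new.env(parent = emptyenv())
  env$params <- params; env$control <- control
  ## node set (3-point rule per panel) shared by the survival curve and the
  ## posterior conditioning term; panel edges are aligned with any
  ## piecewise-constant baseline breakpoints
  env$edges <- refineEdges(panelEdges(0, H, control$step), rk$baseline)
  fine <- nodeSet(env$edges, .gl3)
  env$nodes <- fine$nodes; env$wts <- fine$wts; env$seg <- fine$seg
  env$nseg <- length(env$edges) - 1L
  env$logh0 <- fine$logh0; env$fm <- fine$fm; env$fv <- fine$fv
  env$Zg <- fine$Z; env$Zgd <- fine$Zd
  env$Ag <- rk$alpha_value * fine$Z + rk$alpha_velocity * fine$Zd
  env$a1 <- rk$alpha_value; env$a2 <- rk$alpha_velocity
  env$Dinv <- solve(lg$D)
  env
}

# scalar per-patient pieces
engineAgeTerms <- function(eng, age) {
  lg <- eng$params$long; rk <- eng$params$risk
  w <- c(age - 70, (age - 70)^2)
  ageOff <- if (lg$include_age) sum(lg$beta[2:3] * w) else 0
  list(ageOff = ageOff, eta0 = sum(rk$gamma * w))
}

# cumulative hazard at every grid edge for a matrix of draws:
# returns ndraw x (nseg + 1) matrix, first column 0
engineLamDraws <- function(eng, B, at) {
  base <- eng$logh0 + at$eta0 + eng$a1 * (eng$fm + at$ageOff) +
    eng$a2 * eng$fv
  .cpp_cum_lam(base, eng$Ag, B, eng$wts, as.integer(eng$seg), eng$nseg)
}

# interpolate the per-draw cumulative hazard at arbitrary times
engineLamAt <- function(eng, Lam, u) {
  k <- pmin(pmax(findInterval(u, eng$edges), 1L), eng$nseg)
  fr <- (u - eng$edges[k]) / (eng$edges[k + 1L] - eng$edges[k])
  Lam[, k, drop = FALSE] +
    rep(fr, each = nrow(Lam)) * (Lam[, k + 1L, drop = FALSE] -
                                   Lam[, k, drop = FALSE])
}

# curve object: conditional survival given latest biopsy at t
engineCurve <- function(eng, B, w, at, t) {
  Lam <- engineLamDraws(eng, B, at)
  Lam_t <- if (t > 0) drop(engineLamAt(eng, Lam, t)) else numeric(nrow(B))
  keep <- which(eng$edges > t)
  grid <- c(t, eng$edges[keep])
  Lg <- cbind(Lam_t, Lam[, keep, drop = FALSE])
  pi <- drop(w %*% exp(-pmax(Lg - Lam_t, 0)))
  list(eng = eng, Lam = Lam, Lam_t = Lam_t, w = w, t = t,
       grid = grid, pi = pi, H = eng$control$horizon)
}

enginePi <- function(crv, u) {
  drop(.cpp_pi_at(crv$Lam, crv$eng$edges, crv$w, crv$Lam_t, crv$t,
                  as.numeric(u)))
}

engineInvert <- function(crv, target, tol = 1e-4) {
  pi <- crv$pi
  if (pi[length(pi)] > target) {
    out <- crv$H; attr(out, "censored") <- TRUE
    return(out)
  }
  k <- which(pi <= target)[1]
  if (k == 1L) return(crv$t)
  .cpp_curve_invert(crv$Lam, crv$eng$edges, crv$w, crv$Lam_t,
                    crv$grid[k - 1L], crv$grid[k], target, tol)
}

engineMoments <- function(crv) {
  g <- crv$grid
  mids <- (g[-1] + g[-length(g)]) / 2
  pim <- enginePi(crv, mids)
  p0 <- crv$pi[-length(crv$pi)]; p1 <- crv$pi[-1]
  h <- diff(g)
  I1 <- sum(h / 6 * (p0 + 4 * pim + p1))
  f0 <- (g[-length(g)] - crv$t) * p0
  fm <- (mids - crv$t) * pim
  f1 <- (g[-1] - crv$t) * p1
  I2 <- sum(h / 6 * (f0 + 4 * fm + f1))
  list(E = crv$t + I1, V = max(0, 2 * I2 - I1^2))
}

engineProposal <- function(sch, crv, kappa = NULL) {
  kap <- kappa %||% sch$kappa
  u <- switch(sch$kind,
    expected = engineMoments(crv)$E,
    median = engineInvert(crv, 0.5),
    dyn_risk = engineInvert(crv, kap),
    hybrid = {
      central <- if (sch$hybrid_central == "median")
        engineInvert(crv, 0.5) else engineMoments(crv)$E
      q025 <- engineInvert(crv, 0.975)
      if ((as.numeric(central) - as.numeric(q025)) >
          sch$hybrid_spread_threshold)
        engineInvert(crv, kap)
      else central
    })
  max(as.numeric(u), crv$t)
}

# Quadrature block for the conditioning term Lambda(0 -> t): full coarse
# panels below t plus one fresh partial panel. Depends only on (age, t), so
# callers cache it across visits between biopsies.
engineSurvData <- function(eng, at, t) {
  lg <- eng$params$long
  if (t <= 0)
    return(list(qw = numeric(), logh0_eta = numeric(),
                m0_nod = numeric(), m0v_nod = numeric(),
                Z_nod = matrix(0, 0, lg$q), Zv_nod = matrix(0, 0, lg$q)))
  k <- findInterval(t, eng$edges)
  full <- which(eng$seg <= k - 1L)
  qw <- eng$wts[full]
  logh0_eta <- eng$logh0[full] + at$eta0
  m0 <- eng$fm[full] + at$ageOff
  m0v <- eng$fv[full]
  Zn <- eng$Zg[full, , drop = FALSE]
  Znv <- eng$Zgd[full, , drop = FALSE]
  lo <- eng$edges[k]
  if (t > lo + 1e-12) {
    pn <- panelNodes(c(lo, t))
    nT <- timeBasis(lg$fixed_time_basis, pn$nodes, lg$internal_knots,
                    lg$boundary_knots)
    nTd <- timeBasis(lg$fixed_time_basis, pn$nodes, lg$internal_knots,
                     lg$boundary_knots, deriv = 1L)
    bidx <- if (lg$include_age) 4L else 2L
    bspl <- lg$beta[seq.int(bidx, length.out = ncol(nT))]
    qw <- c(qw, pn$wts)
    logh0_eta <- c(logh0_eta,
                   logBaseHaz(eng$params$risk$baseline, pn$nodes) + at$eta0)
    m0 <- c(m0, lg$beta[1] + at$ageOff +
              if (ncol(nT)) drop(nT %*% bspl) else 0)
    m0v <- c(m0v, if (ncol(nTd)) drop(nTd %*% bspl)
             else rep(0, length(pn$nodes)))
    Zn <- rbind(Zn, randomDesign(lg, pn$nodes))
    Znv <- rbind(Znv, randomDesign(lg, pn$nodes, deriv = 1L))
  }
  list(qw = qw, logh0_eta = logh0_eta, m0_nod = m0, m0v_nod = m0v,
       Z_nod = Zn, Zv_nod = Znv)
}

# posterior data list for the compiled log-target
enginePostData <- function(eng, at, y, m0obs, Zobs, t, survCache = NULL) {
  lg <- eng$params$long
  c(list(y = y, m0_obs = m0obs, Z_obs = Zobs,
         sigma = lg$sigma, nu = lg$residual_df,
         a1 = eng$a1, a2 = eng$a2, Dinv = eng$Dinv),
    survCache %||% engineSurvData(eng, at, t))
}
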