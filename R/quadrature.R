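# Fixed-node quadrature helpers shared by the posterior machinery.
# Panels use 7-point Gauss-Legendre rules; panels near 0 are refined
# geometrically because Weibull hazards with shape < 2 have a square-root-type
# derivative singularity at the origin.

.gl7 <- list(
  x = c(-0.9491079123427585, -0.7415311855993945, -0.4058451513773972, 0,
        0.4058451513773972, 0.7415311855993945, 0.9491079123427585),
  w = c(0.1294849661688697, 0.2797053914892767, 0.3818300505051189,
        0.4179591836734694, 0.3818300505051189, 0.2797053914892767,
        0.1294849661688697))

.gl3 <- list(
  x = c(-0.7745966692414834, 0, 0.7745966692414834),
  w = c(5 / 9, 8 / 9, 5 / 9))

# 15-point Gauss-Kronrod rule (used for the predictive-moment integrals)
.gk15 <- list(
  x = c(-0.9914553711208126, -0.9491079123427585, -0.8648644233597691,
        -0.7415311855993945, -0.5860872354676911, -0.4058451513773972,
        -0.2077849550078985, 0, 0.2077849550078985, 0.4058451513773972,
        0.5860872354676911, 0.7415311855993945, 0.8648644233597691,
        0.9491079123427585, 0.9914553711208126),
  w = c(0.02293532201052922, 0.06309209262997855, 0.1047900103222502,
        0.1406532597155259, 0.1690047266392679, 0.1903505780647854,
        0.2044329400752989, 0.2094821410847278, 0.2044329400752989,
        0.1903505780647854, 0.1690047266392679, 0.1406532597155259,
        0.1047900103222502, 0.06309209262997855, 0.02293532201052922))

# Panel edges covering [t0, t1] with panel width <= step; a panel starting at
# exactly 0 is split geometrically.
panelEdges <- function(t0, t1, step = 0.25) {
  if (t1 <= t0) return(c(t0, t1))
  n <- max(1L, ceiling((t1 - t0) / step))
  e <- seq(t0, t1, length.out = n + 1L)
  if (t0 < 1e-12) {
    first <- e[2]
    e <- c(t0, first / c(256, 64, 16, 4), e[-1])
  }
  e
}

# Gauss-Legendre nodes/weights for consecutive panels defined by `edges`.
# Returns node times, node weights, and the panel index of each node.
panelNodes <- function(edges, rule = .gl7) {
  nseg <- length(edges) - 1L
  nr <- length(rule$x)
  half <- (edges[-1] - edges[-length(edges)]) / 2
  mid <- (edges[-1] + edges[-length(edges)]) / 2
  nodes <- rep(mid, each = nr) + rep(half, each = nr) * rep(rule$x, nseg)
  wts <- rep(half, each = nr) * rep(rule$w, nseg)
  list(nodes = nodes, wts = wts, seg = rep(seq_len(nseg), each = nr))
}

# Breakpoints of a piecewise-constant baseline strictly inside (lo, hi);
# quadrature panels must not straddle them.
baselineBreaks <- function(bh, lo, hi) {
  if (bh$kind != "piecewise_constant") return(numeric())
  bh$breaks[bh$breaks > lo + 1e-12 & bh$breaks < hi - 1e-12]
}

# Insert baseline breakpoints into a panel-edge vector (original edges are
# preserved, so cumulative values at them can be recovered by match()).
refineEdges <- function(edges, bh) {
  br <- baselineBreaks(bh, edges[1], edges[length(edges)])
  if (!length(br)) return(edges)
  sort(unique(c(edges, br)))
}

# Cumulative hazard Lambda(edges[1] -> edges[k]) for a matrix of random-effect
# draws B (ndraw x q). Returns an ndraw x (length(edges) - 1) matrix.
cumHazDraws <- function(risk, spec, age, B, edges) {
  fine <- refineEdges(edges, risk$baseline)
  pn <- panelNodes(fine)
  X <- fixedDesign(spec, pn$nodes, age)
  Z <- randomDesign(spec, pn$nodes)
  Xd <- fixedDesign(spec, pn$nodes, age, deriv = 1L)
  Zd <- randomDesign(spec, pn$nodes, deriv = 1L)
  m0 <- drop(X %*% spec$beta)
  m0v <- drop(Xd %*% spec$beta)
  w <- c(age - 70, (age - 70)^2)
  base <- logBaseHaz(risk$baseline, pn$nodes) + sum(risk$gamma * w) +
    risk$alpha_value * m0 + risk$alpha_velocity * m0v
  ## nnode x ndraw matrix of log hazards
  lh <- base + (risk$alpha_value * Z + risk$alpha_velocity * Zd) %*% t(B)
  hw <- exp(lh) * pn$wts
  seg <- rowsum(hw, pn$seg)              # nseg x ndraw panel integrals
  cs <- apply(seg, 2L, cumsum)
  if (is.null(dim(cs))) cs <- matrix(cs, nrow = 1L)
  out <- t(cs)
  if (length(fine) > length(edges))
    out <- out[, match(edges[-1L], fine[-1L]), drop = FALSE]
  out
}
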