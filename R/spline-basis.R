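#' Natural cubic spline basis with analytic derivatives
#'
#' Evaluates the natural cubic spline basis used for the PSA trajectory (the
#' same basis as [splines::ns()], without intercept), together with its exact
#' derivatives in time. Beyond the boundary knots the basis continues with its
#' linear tails (first-order Taylor extension at the boundary), so the fitted
#' trajectory and its velocity remain well defined over the whole follow-up.
#'
#' @param x numeric vector of evaluation times (years).
#' @param knots internal knots, strictly increasing, strictly inside the
#'   boundary knots.
#' @param boundary length-2 vector of boundary knots.
#' @param deriv derivative order: 0 (value), 1 (velocity) or 2.
#' @return a numeric matrix with `length(x)` rows and `length(knots) + 1`
#'   columns.
#' @examples
#' B <- nsBasis(seq(0, 7, 0.5), knots = c(0.1, 0.5, 4), boundary = c(0, 7))
#' @export
nsBasis <- function(x, knots, boundary, deriv = 0L) {
  stopifnot(length(boundary) == 2L, boundary[1] < boundary[2])
  if (length(knots)) {
    if (is.unsorted(knots, strictly = TRUE))
      stop("internal knots must be strictly increasing", call. = FALSE)
    if (min(knots) <= boundary[1] || max(knots) >= boundary[2])
      stop("internal knots must lie strictly inside the boundary knots",
           call. = FALSE)
  }
  deriv <- as.integer(deriv)
  stopifnot(deriv %in% 0:2)

  aknots <- sort(c(rep(boundary, 4L), knots))
  # natural constraint: zero second derivative at both boundary knots
  const <- splines::splineDesign(aknots, boundary, ord = 4L, derivs = c(2L, 2L))
  qr.const <- qr(t(const[, -1L, drop = FALSE]))
  project <- function(mat) {
    mat <- mat[, -1L, drop = FALSE]          # drop intercept column, as ns()
    t(qr.qty(qr.const, t(mat)))[, -(1:2), drop = FALSE]
  }

  inside <- x >= boundary[1] & x <= boundary[2]
  out <- matrix(0, length(x), length(knots) + 1L)
  if (any(inside)) {
    b <- splines::splineDesign(aknots, x[inside], ord = 4L,
                               derivs = rep(deriv, sum(inside)))
    out[inside, ] <- project(b)
  }
  if (any(!inside)) {
    idxOut <- which(!inside)
    xo <- x[idxOut]
    bk <- ifelse(xo < boundary[1], boundary[1], boundary[2])
    ub <- unique(bk)
    for (u in ub) {
      sel <- idxOut[bk == u]
      if (deriv == 0L) {
        v0 <- project(splines::splineDesign(aknots, u, ord = 4L, derivs = 0L))
        v1 <- project(splines::splineDesign(aknots, u, ord = 4L, derivs = 1L))
        out[sel, ] <- rep(1, length(sel)) %o% drop(v0) +
          (x[sel] - u) %o% drop(v1)
      } else if (deriv == 1L) {
        v1 <- project(splines::splineDesign(aknots, u, ord = 4L, derivs = 1L))
        out[sel, ] <- rep(1, length(sel)) %o% drop(v1)
      } # deriv == 2 -> 0 in the linear tails
    }
  }
  out
}
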