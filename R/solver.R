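#' @importFrom Matrix sparseMatrix Diagonal solve
NULL

# Assemble the symmetric positive-definite finite-volume operator M and the
# boundary source vector, in SI units (concentrations in mol/m3).
#
# The discrete balance for element i is sum_f eta_f S (C_f - C_i) = R_i V
# with eta = D/l across interior faces and eta = E across boundary faces.
# Written as M C = source - consumption with M = -(flux operator), M has
# positive diagonal sum(eta_f S) and off-diagonal -eta S.  Boundary faces
# with external concentration NA are insulated (zero flux) and drop out.
assembleOperator <- function(grid, params, external) {
  n <- nVoxels(grid)
  l <- grid@voxelEdge * 1e-6
  S <- l^2
  g_int <- params@D / l * S

  bf <- grid@boundaryFaces
  external <- rep_len(as.numeric(external), nrow(bf))
  open <- !is.na(external)
  if (!any(open))
    stop("solver error: no boundary face exchanges with the exterior")
  if (any(external[open] < 0))
    stop("external concentrations must be >= 0")

  ii <- grid@interiorFaces[, 1]
  jj <- grid@interiorFaces[, 2]
  g_b <- params@E * S

  di <- c(ii, jj, bf$elem[open])
  dv <- c(rep(g_int, 2 * length(ii)), rep(g_b, sum(open)))
  diag_vals <- as.numeric(tapply(dv, factor(di, levels = seq_len(n)), sum))
  diag_vals[is.na(diag_vals)] <- 0

  M <- Matrix::forceSymmetric(
    sparseMatrix(i = c(seq_len(n), ii, jj),
                 j = c(seq_len(n), jj, ii),
                 x = c(diag_vals, rep(-g_int, 2 * length(ii))),
                 dims = c(n, n)))

  cext <- external * params@kConv   # % O2 -> mol/m3
  src <- as.numeric(tapply(g_b * cext[open],
                           factor(bf$elem[open], levels = seq_len(n)), sum))
  src[is.na(src)] <- 0

  list(M = M, source = src, V = l^3, S = S, external = external,
       open = open)
}

#' Solve the steady-state oxygen balance of a voxelized embryo
#'
#' Solves the discrete mass balance in which, for every cubic element, the
#' oxygen flux across its six faces equals its zero-order consumption:
#' interior faces exchange with coefficient D/l, boundary faces with the
#' membrane permeability E against the external concentration at the face.
#' Zero-order consumption can drive the linear solution negative; elements
#' where that happens form the dead core: their consumption is switched off,
#' their concentration pinned to zero, and the reduced system re-solved until
#' the active set is consistent (concentration positive wherever consumption
#' is on, and oxygen inflow insufficient to sustain consumption wherever it
#' is off).
#'
#' @param grid a [VoxelGrid-class]
#' @param params a [TransportParams-class]
#' @param external external oxygen per boundary face (\% O2): a scalar
#'   (uniform) or a vector matching the grid's boundary face table; NA marks
#'   an insulated face (zero flux)
#' @param maxIter cap on dead-core active-set iterations
#' @return an [OxygenField-class] (concentrations in mol/m3)
#' @examples
#' grid <- voxelize(embryoGeometry(200, 100, 10))
#' fld <- solveSteadyState(grid, transportParams(E = 1e-4), external = 20)
#' @export
solveSteadyState <- function(grid, params, external, maxIter = 100L) {
  stopifnot(is(grid, "VoxelGrid"), is(params, "TransportParams"))
  op <- assembleOperator(grid, params, external)
  n <- nVoxels(grid)
  RV <- params@R * op$V
  tol <- 1e-12 * max(op$external, na.rm = TRUE) * params@kConv

  # inflow a pinned (C = 0) element would receive, to decide reactivation
  inflowAtZero <- function(C) {
    flux <- op$source - as.numeric(op$M %*% C)
    # for an element with C = 0 the diagonal term vanishes, so flux is the
    # inflow from neighbours and the exterior
    flux
  }

  alive <- rep(TRUE, n)
  C <- numeric(n)
  for (pass in seq_len(maxIter)) {
    C <- numeric(n)
    if (any(alive)) {
      rhs <- op$source - RV
      sol <- tryCatch(
        as.numeric(solve(op$M[alive, alive, drop = FALSE], rhs[alive])),
        error = function(e)
          stop("solver error: singular system (isolated region?): ",
               conditionMessage(e)))
      C[alive] <- sol
    }

    newlyDead <- alive & (C < -tol)
    revive <- logical(n)
    if (pass <= maxIter / 2) {  # fall back to monotone deactivation if slow
      inflow <- inflowAtZero(C)
      revive <- !alive & (inflow > RV * (1 + 1e-9))
    }
    if (!any(newlyDead) && !any(revive)) break
    alive <- (alive & !newlyDead) | revive
    if (pass == maxIter)
      stop("convergence error: dead-core iteration did not settle")
  }
  new("OxygenField", conc = pmax(C, 0), active = alive)
}

#' Evolve the transient oxygen balance
#'
#' Integrates \eqn{V\,dC_i/dt = \sum_f \eta_f S (C_f - C_i) - R_i V} from an
#' initial field, with consumption active only where the concentration is
#' positive.  The default implicit Euler scheme is unconditionally stable;
#' the explicit scheme requires \eqn{dt < l^2/(6D)}.
#'
#' @param grid a [VoxelGrid-class]
#' @param params a [TransportParams-class]
#' @param external external oxygen per boundary face (\% O2), as in
#'   [solveSteadyState()]
#' @param initialField an [OxygenField-class] (or NULL for a zero start)
#' @param dt time step (s)
#' @param tEnd horizon (s)
#' @param scheme \code{"implicit"} (default) or \code{"explicit"}
#' @param keepFields if TRUE, store the full concentration vector at every
#'   step (memory-heavy); otherwise only the final field
#' @return a list with \code{times} (s), \code{meanConc} (whole-embryo mean,
#'   mol/m3, one entry per time incl. t = 0), \code{finalField}
#'   (an [OxygenField-class]) and, if requested, \code{fields} (a matrix,
#'   one column per stored time)
#' @export
solveTransient <- function(grid, params, external, initialField = NULL,
                           dt, tEnd, scheme = c("implicit", "explicit"),
                           keepFields = FALSE) {
  stopifnot(is(grid, "VoxelGrid"), is(params, "TransportParams"))
  scheme <- match.arg(scheme)
  op <- assembleOperator(grid, params, external)
  n <- nVoxels(grid)
  l <- grid@voxelEdge * 1e-6
  if (scheme == "explicit" && dt >= l^2 / (6 * params@D))
    stop("configuration error: explicit scheme requires dt < l^2/(6D) = ",
         format(l^2 / (6 * params@D)), " s")

  C <- if (is.null(initialField)) numeric(n) else initialField@conc
  stopifnot(length(C) == n)
  RV <- params@R * op$V
  nsteps <- ceiling(tEnd / dt)
  times <- c(0, seq_len(nsteps) * dt)
  meanConc <- numeric(nsteps + 1L)
  meanConc[1L] <- mean(C)
  fields <- if (keepFields) matrix(NA_real_, n, nsteps + 1L) else NULL
  if (keepFields) fields[, 1L] <- C

  if (scheme == "implicit") {
    A <- Diagonal(n, op$V / dt) + op$M
    fac <- Matrix::Cholesky(methods::as(Matrix::forceSymmetric(A),
                                        "CsparseMatrix"))
    for (k in seq_len(nsteps)) {
      act <- C > 0
      rhs <- op$V / dt * C + op$source - RV * act
      C <- pmax(as.numeric(solve(fac, rhs)), 0)
      meanConc[k + 1L] <- mean(C)
      if (keepFields) fields[, k + 1L] <- C
    }
  } else {
    for (k in seq_len(nsteps)) {
      act <- C > 0
      C <- pmax(C + dt / op$V *
                  (op$source - as.numeric(op$M %*% C) - RV * act), 0)
      meanConc[k + 1L] <- mean(C)
      if (keepFields) fields[, k + 1L] <- C
    }
  }
  out <- list(times = times, meanConc = meanConc,
              finalField = new("OxygenField", conc = C, active = C > 0))
  if (keepFields) out$fields <- fields
  out
}

#' Volume-weighted regional mean oxygen concentration
#'
#' Averages the solved concentration over the elements whose AP coordinate
#' lies within a fraction of the body length measured from the chosen end,
#' and converts the result to \% O2.  The default region (posterior 75\%) is
#' the portion of the embryo where the engrailed stripes locate.
#'
#' @param field an [OxygenField-class]
#' @param grid the matching [VoxelGrid-class]
#' @param params a [TransportParams-class] (conversion factor)
#' @param apFraction fraction of the body length in (0, 1]
#' @param fromEnd \code{"posterior"} (x = 0 end) or \code{"anterior"}
#' @return mean concentration (\% O2)
#' @export
regionAverage <- function(field, grid, params, apFraction = 0.75,
                          fromEnd = c("posterior", "anterior")) {
  stopifnot(is(field, "OxygenField"), is(grid, "VoxelGrid"),
            is(params, "TransportParams"))
  fromEnd <- match.arg(fromEnd)
  if (apFraction <= 0 || apFraction > 1)
    stop("apFraction must lie in (0, 1]")
  L <- max(grid@centers[, 1]) + grid@voxelEdge / 2
  x <- grid@centers[, 1]
  sel <- if (fromEnd == "posterior") x <= apFraction * L
         else x >= (1 - apFraction) * L
  if (!any(sel)) stop("empty region")
  mean(field@conc[sel]) / params@kConv
}

#' Discrete mass-balance diagnostic
#'
#' At steady state the total oxygen influx across the membrane must equal
#' the consumption of the active elements plus the flux absorbed by the dead
#' core.  Returns both sides and their relative mismatch.
#'
#' @param field an [OxygenField-class] from [solveSteadyState()]
#' @param grid,params,external as passed to the solver
#' @return list with \code{influx} (mol/s), \code{consumption} (mol/s, over
#'   active elements), \code{deadCoreFlux} (mol/s absorbed at the dead-core
#'   interface) and \code{relError} of influx vs consumption + deadCoreFlux
#' @export
massBalance <- function(field, grid, params, external) {
  op <- assembleOperator(grid, params, external)
  bf <- grid@boundaryFaces
  cext <- op$external * params@kConv
  open <- op$open
  influx <- sum(params@E * (cext[open] - field@conc[bf$elem[open]]) * op$S)
  consumption <- params@R * op$V * sum(field@active)
  # flux entering pinned dead-core elements through interior faces
  dead <- !field@active
  dcf <- 0
  if (any(dead)) {
    ifc <- grid@interiorFaces
    g_int <- params@D / (grid@voxelEdge * 1e-6) * op$S
    d1 <- dead[ifc[, 1]] & !dead[ifc[, 2]]
    d2 <- dead[ifc[, 2]] & !dead[ifc[, 1]]
    dcf <- g_int * (sum(field@conc[ifc[d2, 1]]) +
                      sum(field@conc[ifc[d1, 2]]))
    dcf <- dcf + sum(params@E * cext[open][dead[bf$elem[open]]] * op$S)
  }
  list(influx = influx, consumption = consumption, deadCoreFlux = dcf,
       relError = abs(influx - consumption - dcf) /
         max(abs(influx), .Machine$double.eps))
}
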