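## Confined creeping flow by the method of regularized Stokeslets with
## no-slip boundary collocation. The regularized kernel used throughout is
## the planar Stokeslet of the blob phi_eps(r) = 3 eps^3 /
## (2 pi (r^2 + eps^2)^(5/2)); writing R = sqrt(r^2 + eps^2),
##   4 pi mu u_i = -f_i [ln(R + eps) - eps (R + 2 eps) / ((R + eps) R)]
##                 + (f . x) x_i (R + 2 eps) / ((R + eps)^2 R).
## The field is exactly divergence-free and reduces to the free-space
## Stokeslet (-f ln r + (f.x) x / r^2) / (4 pi mu) as eps -> 0.

## kernel blocks: velocities at m targets from n sources, u = Axx fx + ...
## eps may be a scalar or one value per source.
stokesletBlocks <- function(targets, sources, eps, viscosity) {
  dx <- outer(targets[, 1], sources[, 1], "-")
  dy <- outer(targets[, 2], sources[, 2], "-")
  e <- matrix(eps, nrow(targets), nrow(sources), byrow = TRUE)
  R <- sqrt(dx * dx + dy * dy + e * e)
  A <- log(R + e) - e * (R + 2 * e) / ((R + e) * R)
  B <- (R + 2 * e) / ((R + e)^2 * R)
  s <- 1 / (4 * pi * viscosity)
  list(xx = s * (-A + dx * dx * B), xy = s * (dx * dy * B),
       yy = s * (-A + dy * dy * B))
}

#' Free-space regularized-Stokeslet velocity
#'
#' Velocity at \code{targets} induced in an unbounded fluid by point forces
#' regularized with blob size \code{eps}. Serves as the analytic reference
#' for the confined solver far from boundaries, and as the building block of
#' the boundary-collocation method.
#'
#' @param targets m x 2 matrix of evaluation points (um).
#' @param sources n x 2 matrix of force positions (um).
#' @param forces n x 2 matrix of forces (pN).
#' @param eps Regularization length (um), scalar or per source.
#' @param viscosity Viscosity (Pa s).
#' @return m x 2 matrix of velocities (um/s).
#' @export
stokesletVelocity <- function(targets, sources, forces, eps,
                              viscosity = defaultViscosity()) {
  targets <- rbind(targets); sources <- rbind(sources); forces <- rbind(forces)
  if (nrow(sources) == 0L) return(matrix(0, nrow(targets), 2))
  K <- stokesletBlocks(targets, sources, eps, viscosity)
  cbind(K$xx %*% forces[, 1] + K$xy %*% forces[, 2],
        K$xy %*% forces[, 1] + K$yy %*% forces[, 2])
}

## ratio of boundary blob size to collocation spacing; chosen so the no-slip
## residual between collocation nodes stays below 1e-3 of the interior flow
BOUNDARY_EPS_FACTOR <- 2.0

## Precompute the boundary collocation system for a domain. Returns an
## opaque solver object reused across force systems and time steps.
newStokesSolver <- function(domain, cfg) {
  bp <- boundaryPoints(domain, cfg@nCollocation)
  epsB <- BOUNDARY_EPS_FACTOR * bp$spacing
  K <- stokesletBlocks(bp$points, bp$points, epsB, domain@viscosity)
  n <- nrow(bp$points)
  M <- rbind(cbind(K$xx, K$xy), cbind(K$xy, K$yy))
  if (anyNA(M) || any(!is.finite(M)))
    stop("solver-conditioning error: non-finite collocation matrix")
  sv <- svd(M)
  keep <- sv$d > 1e-12 * sv$d[1]
  if (sum(keep) < 2L)
    stop(sprintf(
      "solver-conditioning error: collocation system numerically singular (rank %d, cond %.3g)",
      sum(keep), sv$d[1] / sv$d[length(sv$d)]))
  structure(list(domain = domain, cfg = cfg, points = bp$points,
                 spacing = bp$spacing, epsB = epsB,
                 U = sv$u[, keep, drop = FALSE], dinv = 1 / sv$d[keep],
                 V = sv$v[, keep, drop = FALSE]),
            class = "StokesSolver")
}

## boundary Stokeslet weights cancelling the interior-force slip velocity
solverWeights <- function(solver, fs) {
  if (nrow(fs@positions) == 0L)
    return(matrix(0, nrow(solver$points), 2))
  if (!all(insideDomain(solver$domain, fs@positions)))
    stop("invalid input: force position outside the domain")
  ub <- stokesletVelocity(solver$points, fs@positions, fs@forces,
                          solver$cfg@epsilon, solver$domain@viscosity)
  rhs <- -c(ub[, 1], ub[, 2])
  w <- solver$V %*% (solver$dinv * crossprod(solver$U, rhs))
  n <- nrow(solver$points)
  cbind(w[seq_len(n)], w[n + seq_len(n)])
}

## total velocity (interior forces + boundary correction) at targets
solverVelocity <- function(solver, fs, weights, targets) {
  u <- stokesletVelocity(targets, fs@positions, fs@forces,
                         solver$cfg@epsilon, solver$domain@viscosity)
  u + stokesletVelocity(targets, solver$points, weights, solver$epsB,
                        solver$domain@viscosity)
}

#' Default solver configuration for a domain
#'
#' Grid spacing defaults to length/64, the regularization to 1.5 x grid
#' spacing, and the collocation count to at least 192 points (and at least
#' 64 per the resolution requirement).
#'
#' @param domain A \code{CellDomain}.
#' @param gridSpacing Grid spacing (um).
#' @param epsilon Interior blob size (um).
#' @param nCollocation Boundary collocation points.
#' @return A \code{SolverConfig}.
#' @export
solverConfig <- function(domain, gridSpacing = domain@length / 64,
                         epsilon = 1.5 * gridSpacing,
                         nCollocation = 192L) {
  new("SolverConfig", epsilon = epsilon,
      nCollocation = as.integer(nCollocation), gridSpacing = gridSpacing)
}

#' Construct a force system
#'
#' @param positions n x 2 matrix of positions (um).
#' @param forces n x 2 matrix of forces (pN).
#' @param pair Integer dipole labels (equal label = one dipole); defaults to
#'   no pairing metadata.
#' @return A \code{ForceSystem}.
#' @export
forceSystem <- function(positions, forces, pair = rep(0L, nrow(rbind(positions)))) {
  positions <- rbind(positions); forces <- rbind(forces)
  new("ForceSystem", positions = positions, forces = forces,
      pair = as.integer(pair))
}

#' Solve confined Stokes flow on a grid
#'
#' Solves incompressible creeping flow driven by \code{forces} inside
#' \code{domain} with a no-slip boundary, by superposing regularized
#' Stokeslets at the forces and at boundary collocation nodes whose weights
#' cancel the boundary slip (dense least squares via truncated SVD). Grid
#' nodes outside the domain are NA and masked.
#'
#' @param domain A \code{CellDomain}.
#' @param forces A \code{ForceSystem}; every position strictly inside.
#' @param cfg A \code{SolverConfig}; defaults to \code{solverConfig(domain)}.
#' @return A \code{FlowField}.
#' @examples
#' dom <- cellDomain(100)
#' fs <- forceSystem(rbind(c(-5, 0), c(5, 0)),
#'                   rbind(c(-10, 0), c(10, 0)), c(1L, 1L))
#' ff <- solveConfinedStokes(dom, fs, solverConfig(dom, gridSpacing = 5))
#' @export
solveConfinedStokes <- function(domain, forces, cfg = solverConfig(domain)) {
  if (cfg@gridSpacing > domain@length / 16)
    warning("coarse grid: spacing > length/16")
  solver <- newStokesSolver(domain, cfg)
  g <- domainGrid(domain, cfg@gridSpacing)
  nx <- length(g$x); ny <- length(g$y)
  u <- matrix(NA_real_, nx, ny); v <- matrix(NA_real_, nx, ny)
  idx <- which(g$inside)
  if (nrow(forces@positions) == 0L) {
    u[idx] <- 0; v[idx] <- 0
  } else {
    pts <- cbind(rep(g$x, times = ny), rep(g$y, each = nx))[idx, , drop = FALSE]
    w <- solverWeights(solver, forces)
    vel <- solverVelocity(solver, forces, w, pts)
    u[idx] <- vel[, 1]; v[idx] <- vel[, 2]
  }
  new("FlowField", x = g$x, y = g$y, u = u, v = v, mask = !g$inside)
}

#' Maximum residual boundary speed of a solve
#'
#' Evaluates the no-slip residual at boundary points midway between the
#' collocation nodes (where the residual is largest).
#'
#' @param domain,forces,cfg As in \code{\link{solveConfinedStokes}}.
#' @return List with \code{boundary} (max residual speed, um/s) and
#'   \code{interior} (max interior speed on the evaluation grid, um/s).
#' @export
noSlipResidual <- function(domain, forces, cfg = solverConfig(domain)) {
  solver <- newStokesSolver(domain, cfg)
  w <- solverWeights(solver, forces)
  ## midpoints: shift the collocation parameterization by half a spacing
  mid <- boundaryPoints(domain, 2L * nrow(solver$points))$points
  ub <- solverVelocity(solver, forces, w, mid)
  g <- domainGrid(domain, cfg@gridSpacing)
  pts <- cbind(rep(g$x, times = length(g$y)),
               rep(g$y, each = length(g$x)))[g$inside, , drop = FALSE]
  ui <- solverVelocity(solver, forces, w, pts)
  list(boundary = max(sqrt(rowSums(ub^2))),
       interior = max(sqrt(rowSums(ui^2))))
}

#' Vorticity of a gridded flow field
#'
#' Central-difference curl (dv/dx - du/dy) in the interior, one-sided
#' differences at the grid edges; NA wherever a stencil touches a masked or
#' NA node.
#'
#' @param flow A \code{FlowField} on a regular grid.
#' @return A \code{VorticityField} (1/s).
#' @export
vorticityField <- function(flow) {
  nx <- length(flow@x); ny <- length(flow@y)
  if (nx < 3L || ny < 3L) stop("invalid input: grid must be at least 3 x 3")
  hx <- diff(flow@x[1:2]); hy <- diff(flow@y[1:2])
  dvdx <- matrix(NA_real_, nx, ny); dudy <- matrix(NA_real_, nx, ny)
  v <- flow@v; u <- flow@u
  dvdx[2:(nx - 1), ] <- (v[3:nx, ] - v[1:(nx - 2), ]) / (2 * hx)
  dvdx[1, ] <- (v[2, ] - v[1, ]) / hx
  dvdx[nx, ] <- (v[nx, ] - v[nx - 1, ]) / hx
  dudy[, 2:(ny - 1)] <- (u[, 3:ny] - u[, 1:(ny - 2)]) / (2 * hy)
  dudy[, 1] <- (u[, 2] - u[, 1]) / hy
  dudy[, ny] <- (u[, ny] - u[, ny - 1]) / hy
  new("VorticityField", x = flow@x, y = flow@y, omega = dvdx - dudy)
}

#' Probe mobility as a function of distance from the boundary
#'
#' Places a cargo/anchor force dipole (force \code{probeForce} along +x at
#' the probe point, the opposite force \code{arm} um further along x) at
#' increasing offsets from the bottom boundary along the y axis, and reports
#' the flow speed at the probe point. Speeds increase with wall clearance
#' and saturate towards the unbounded-domain dipole value, the no-slip
#' confinement effect that underlies flow scaling.
#'
#' @param domain A \code{CellDomain}.
#' @param probeForce Force magnitude (pN).
#' @param offsets Distances from the boundary (um), each inside the domain.
#' @param cfg A \code{SolverConfig}.
#' @param arm Dipole arm (um).
#' @return data.frame with columns \code{offset} and \code{speed} (um/s).
#' @export
probeMobilityVsWall <- function(domain, probeForce, offsets,
                                cfg = solverConfig(domain), arm = 10) {
  solver <- newStokesSolver(domain, cfg)
  speeds <- vapply(offsets, function(off) {
    p <- c(0, -domain@width / 2 + off)
    p2 <- p + c(arm, 0)
    if (!all(insideDomain(domain, rbind(p, p2))))
      stop("invalid input: probe position outside the domain")
    fs <- forceSystem(rbind(p, p2),
                      rbind(c(probeForce, 0), c(-probeForce, 0)), c(1L, 1L))
    w <- solverWeights(solver, fs)
    sqrt(sum(solverVelocity(solver, fs, w, rbind(p))^2))
  }, numeric(1))
  data.frame(offset = offsets, speed = speeds)
}

#' Write a flow (and optional vorticity) field as CSV
#'
#' Long-format CSV with columns x_um, y_um, u_um_s, v_um_s and optionally
#' omega_per_s; masked nodes are omitted.
#'
#' @param flow A \code{FlowField}.
#' @param file Output path.
#' @param vorticity Optional matching \code{VorticityField}.
#' @return The file path, invisibly.
#' @export
writeFlowFieldCSV <- function(flow, file, vorticity = NULL) {
  nx <- length(flow@x); ny <- length(flow@y)
  df <- data.frame(x_um = rep(flow@x, times = ny),
                   y_um = rep(flow@y, each = nx),
                   u_um_s = as.vector(flow@u), v_um_s = as.vector(flow@v))
  if (!is.null(vorticity)) df$omega_per_s <- as.vector(vorticity@omega)
  df <- df[is.finite(df$u_um_s), , drop = FALSE]
  utils::write.csv(df, file, row.names = FALSE)
  invisible(file)
}
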