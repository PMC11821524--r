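## Anaphase simulation: kinematic, spindle-driven anaphase A followed by
## flow-driven anaphase B. Each half-spindle is an asymmetric aster carrying
## its chromosome set, treated as a rigid, porous object: the sparse
## microtubule network is represented by stokeslet nodes along the rays that
## are constrained to move with a single rigid velocity, and that velocity
## is set by force balance - the net dynein reaction (poleward, because the
## midzone-clipped rays carry fewer cargos) against the hydrodynamic drag of
## the confined network. Confinement reduces the mobility of an extended
## object far more in small cells, which is what scales the separation speed
## and the NER position with cell length.

## cargo pool calibrated once so the 4-cell-stage (L = 300 um) per-set
## anaphase-B speed is ~0.11 um/s; all other cell lengths are predictions.
## The force knob is engagedCount x dutyRatio x cargoFriction x dyneinSpeed;
## it is spread over a large pool of transiently engaged cargos (duty ratio
## 0.1) so the discrete near-fields stay small compared with the mean flow.
DEFAULT_ENGAGED_COUNT <- 2150

## hydrodynamic blob size of a network node (um): a third of the node
## spacing, so the dense astral network entrains the fluid between nodes
## (speckle and organelle flows track each other in these asters) while the
## discretization stays well conditioned
NETWORK_EPS <- 4

#' Anaphase simulation configuration
#'
#' Defaults are the calibrated parameter set used throughout: anaphase A at
#' a constant separation rate of 0.35 um/s for 100 s (placing the WGA event
#' at about 37.9 um of separation at 113 s), asters of radius 70 um at
#' anaphase-B onset growing at 0.2 um/s (embryonic asters nearly span the
#' blastomere), and a cargo force magnitude (engagedCount x dutyRatio x
#' cargoFriction x dyneinSpeed) calibrated once at the 4-cell stage.
#'
#' @param length Cell length (um).
#' @param width Cell width (um); default length / 2.
#' @param vA Anaphase-A separation rate (um/s).
#' @param anaphaseADuration Anaphase-A duration (s).
#' @param asterRadius Aster radius r_a at anaphase-B onset (um).
#' @param asterGrowthRate Growth rate of the aster radius during anaphase B
#'   (um/s); astral microtubule growth sustains the aster's midzone
#'   asymmetry as it moves poleward.
#' @param engagedCount Engaged cargos per aster; 0 disables flows.
#' @param dutyRatio Cargo force duty ratio.
#' @param dt Time step (s).
#' @param tEnd Simulation end (s), >= 271 s.
#' @param seed Seed for ray direction sampling.
#' @param nRays Rays per aster.
#' @param nodeSpacing Network node spacing along rays (um).
#' @param viscosity Cytoplasmic viscosity (Pa s).
#' @param gridSpacing,nCollocation Solver resolution; defaults length/64 and
#'   192.
#' @param flowsEnabled Set FALSE to switch off anaphase-B flows (the dynein
#'   inhibition control); implied by engagedCount = 0.
#' @return A \code{SimConfig}.
#' @examples
#' cfg <- simConfig(300)
#' @export
simConfig <- function(length, width = length / 2, vA = 0.35,
                      anaphaseADuration = 100, asterRadius = 70,
                      asterGrowthRate = 0.2,
                      engagedCount = DEFAULT_ENGAGED_COUNT, dutyRatio = 0.1,
                      dt = 5, tEnd = 300, seed = 1234L, nRays = 64L,
                      nodeSpacing = 12, viscosity = defaultViscosity(),
                      gridSpacing = length / 64,
                      nCollocation = 192L, flowsEnabled = TRUE) {
  if (engagedCount == 0) {
    flowsEnabled <- FALSE
    engagedCount <- 1
  }
  new("SimConfig", length = length, width = width, vA = vA,
      anaphaseADuration = anaphaseADuration, asterRadius = asterRadius,
      asterGrowthRate = asterGrowthRate,
      dt = dt, tEnd = tEnd, seed = as.integer(seed),
      solver = new("SolverConfig", epsilon = 1.5 * gridSpacing,
                   nCollocation = as.integer(nCollocation),
                   gridSpacing = gridSpacing),
      cargo = cargoParams(engagedCount = engagedCount,
                          dutyRatio = dutyRatio),
      viscosity = viscosity, nRays = as.integer(nRays),
      nodeSpacing = nodeSpacing, flowsEnabled = flowsEnabled)
}

## re-clip the (fixed) ray directions for the current aster position and
## (optionally grown) radius
updateAsterGeometry <- function(domain, aster, margin = 2,
                                radius = aster@radius) {
  lengths <- vapply(aster@rayAngles, function(th)
    clipRay(domain, aster@center, c(cos(th), sin(th)), radius,
            aster@midzoneX, aster@side, margin), numeric(1))
  initialize(aster, radius = radius, rayLengths = lengths)
}

## Coupled solve for two rigid asters in a confined domain.
##
## Unknowns: stokeslet weights at the boundary nodes (no-slip), at the left
## and right network nodes (rigid motion), and the two rigid velocities.
## Constraints: u = 0 at boundary nodes; u = V_side at network nodes; the
## network weights of each aster sum to its net motor reaction. Cargo drag
## forces are fixed stokeslets.
solveRigidAsters <- function(domain, bnd, epsB, left, right, cargo,
                             nodeSpacing = 12, epsCargo = 1,
                             cargoDensity = NULL) {
  cfL <- asterCargoForces(left, cargo, domain, cargoDensity)
  cfR <- asterCargoForces(right, cargo, domain, cargoDensity)
  nodesL <- asterNetworkNodes(left, nodeSpacing, domain)
  nodesR <- asterNetworkNodes(right, nodeSpacing, domain)
  nb <- nrow(bnd); nl <- nrow(nodesL); nr <- nrow(nodesR)
  X <- rbind(bnd, nodesL, nodesR)
  n <- nb + nl + nr
  eps <- c(rep(epsB, nb), rep(NETWORK_EPS, nl + nr))
  mu <- domain@viscosity
  K <- stokesletBlocks(X, X, eps, mu)
  ## unknown ordering: wx (n), wy (n), VLx, VLy, VRx, VRy
  M <- matrix(0, 2 * n + 4, 2 * n + 4)
  M[1:n, 1:n] <- K$xx;              M[1:n, n + 1:n] <- K$xy
  M[n + 1:n, 1:n] <- K$xy;          M[n + 1:n, n + 1:n] <- K$yy
  iL <- nb + seq_len(nl); iR <- nb + nl + seq_len(nr)
  M[iL, 2 * n + 1] <- -1;           M[n + iL, 2 * n + 2] <- -1
  M[iR, 2 * n + 3] <- -1;           M[n + iR, 2 * n + 4] <- -1
  M[2 * n + 1, iL] <- 1;            M[2 * n + 2, n + iL] <- 1
  M[2 * n + 3, iR] <- 1;            M[2 * n + 4, n + iR] <- 1
  cargoPos <- rbind(cfL$positions, cfR$positions)
  cargoF <- rbind(cfL$forces, cfR$forces)
  uc <- stokesletVelocity(X, cargoPos, cargoF, epsCargo, mu)
  rhs <- c(-uc[, 1], -uc[, 2],
           cfL$netReaction[1], cfL$netReaction[2],
           cfR$netReaction[1], cfR$netReaction[2])
  sol <- tryCatch(solve(M, rhs), error = function(e)
    stop("solver-conditioning error: rigid-aster system singular (",
         conditionMessage(e), ")"))
  list(VL = sol[2 * n + 1:2], VR = sol[2 * n + 3:4],
       sources = rbind(X, cargoPos),
       weights = rbind(cbind(sol[1:n], sol[n + 1:n]), cargoF),
       eps = c(eps, rep(epsCargo, nrow(cargoPos))), viscosity = mu)
}

## total flow velocity of a rigid-aster solution at arbitrary targets
rigidFlowVelocity <- function(sol, targets) {
  stokesletVelocity(targets, sol$sources, sol$weights, sol$eps,
                    sol$viscosity)
}

#' One explicit time step of the flow-driven dynamics
#'
#' Solves the rigid-aster force balance and advances both asters (each with
#' its chromosome set, which moves with it) by their rigid velocities; ray
#' geometry is then re-clipped against midzone and boundary. An aster that
#' would leave the domain is clamped in place and flagged.
#'
#' @param state List with elements \code{left} and \code{right}
#'   (\code{AsterState}) and logical \code{clamped}.
#' @param domain A \code{CellDomain}.
#' @param cargo A \code{CargoParams}.
#' @param bnd Boundary collocation points (matrix).
#' @param epsB Boundary blob size (um).
#' @param dt Time step (s).
#' @param nodeSpacing Network node spacing (um).
#' @return The updated state list.
#' @keywords internal
stepDynamics <- function(state, domain, cargo, bnd, epsB, dt,
                         nodeSpacing = 12, growthRate = 0,
                         cargoDensity = NULL) {
  sol <- solveRigidAsters(domain, bnd, epsB, state$left, state$right,
                          cargo, nodeSpacing, cargoDensity = cargoDensity)
  centers <- rbind(state$left@center, state$right@center)
  newCenters <- centers + rbind(sol$VL, sol$VR) * dt
  margin <- 2
  for (i in 1:2) {
    if (!insideDomain(domain, rbind(newCenters[i, ]), margin)) {
      newCenters[i, ] <- centers[i, ]
      state$clamped <- TRUE
    }
  }
  newRadius <- state$left@radius + growthRate * dt
  state$left <- updateAsterGeometry(
    domain, initialize(state$left, center = newCenters[1, ]),
    radius = newRadius)
  state$right <- updateAsterGeometry(
    domain, initialize(state$right, center = newCenters[2, ]),
    radius = newRadius)
  state$lastSolution <- sol
  state
}

#' Simulate anaphase chromosome separation
#'
#' Phase 1 (0 to \code{anaphaseADuration}): kinematic separation at rate
#' \code{vA} (anaphase A is spindle-driven and not flow-modelled). Phase 2:
#' flow-driven via \code{stepDynamics}, with both chromosome sets carried by
#' their asters.
#'
#' @param cfg A \code{SimConfig}.
#' @return A \code{Trajectory}.
#' @examples
#' \donttest{
#' traj <- simulateAnaphase(simConfig(300))
#' separationRate(traj, 100, 200) / 2   # per-set anaphase-B speed
#' }
#' @export
simulateAnaphase <- function(cfg) {
  domain <- cellDomain(cfg@length, cfg@width, viscosity = cfg@viscosity)
  nodeSpacing <- cfg@nodeSpacing
  ta <- cfg@anaphaseADuration
  times <- seq(0, cfg@tEnd, by = cfg@dt)
  if (max(times) < cfg@tEnd) times <- c(times, cfg@tEnd)
  sep <- numeric(length(times))
  leftX <- numeric(length(times)); rightX <- numeric(length(times))
  phase1 <- times <= ta
  sep[phase1] <- cfg@vA * times[phase1]
  leftX[phase1] <- -sep[phase1] / 2; rightX[phase1] <- sep[phase1] / 2
  d0 <- cfg@vA * ta
  left <- buildAsymmetricAster(domain, c(-d0 / 2, 0), cfg@asterRadius,
                               midzoneX = 0, nRays = cfg@nRays,
                               seed = cfg@seed)
  state <- list(left = left, right = mirrorAster(left), clamped = FALSE)
  ## fixed linear cargo density: the engaged count of the nominal
  ## (unclipped, onset-radius) aster spread over its total ray length
  cargoDensity <- cfg@cargo@engagedCount / (cfg@nRays * cfg@asterRadius)
  if (cfg@flowsEnabled) {
    bp <- boundaryPoints(domain, cfg@solver@nCollocation)
    epsB <- BOUNDARY_EPS_FACTOR * bp$spacing
    lastT <- ta
    for (i in which(!phase1)) {
      nsub <- max(1L, ceiling((times[i] - lastT) / cfg@dt - 1e-9))
      for (s in seq_len(nsub))
          state <- stepDynamics(state, domain, cfg@cargo, bp$points, epsB,
                                (times[i] - lastT) / nsub, nodeSpacing,
                                cfg@asterGrowthRate, cargoDensity)
      lastT <- times[i]
      leftX[i] <- state$left@center[1]; rightX[i] <- state$right@center[1]
      sep[i] <- rightX[i] - leftX[i]
    }
  } else {
    sep[!phase1] <- d0
    leftX[!phase1] <- -d0 / 2; rightX[!phase1] <- d0 / 2
  }
  new("Trajectory", times = times, separation = sep, leftX = leftX,
      rightX = rightX, clamped = state$clamped)
}

#' Mean separation rate over a time window
#'
#' @param traj A \code{Trajectory}.
#' @param from,to Window bounds (s); the anaphase-A and -B windows are
#'   [0, 100] and [100, 200] s. Per-set chromosome speed is half the
#'   separation rate.
#' @return Separation rate (um/s).
#' @export
separationRate <- function(traj, from = 100, to = 200) {
  d <- approx(traj@times, traj@separation, xout = c(from, to))$y
  (d[2] - d[1]) / (to - from)
}

#' NER scaling curve over a range of cell lengths
#'
#' Runs \code{\link{simulateAnaphase}} for each length (all other
#' parameters shared) and evaluates the separation at the NER threshold
#' time of the timing model. Failed runs are kept as NA and the curve
#' continues. The plateau estimate is the value at the largest length.
#'
#' @param lengths Cell lengths (um), spanning at least a 2x range.
#' @param model A \code{DecayModel}; default the calibrated model.
#' @param thetaNER NER threshold fraction.
#' @param ... Overrides passed to \code{\link{simConfig}} for every length.
#' @return A \code{ScalingCurve}.
#' @export
nerScalingCurve <- function(lengths, model = calibrateTwoPoint(),
                            thetaNER = 0.37, ...) {
  if (max(lengths) < 2 * min(lengths))
    warning("lengths span less than a 2x range")
  dNER <- vapply(lengths, function(L) {
    tryCatch(positionAtThreshold(simulateAnaphase(simConfig(L, ...)),
                                 model, thetaNER),
             error = function(e) NA_real_)
  }, numeric(1))
  ok <- is.finite(dNER)
  plateau <- if (any(ok)) dNER[ok][which.max(lengths[ok])] else NA_real_
  new("ScalingCurve", lengths = as.numeric(lengths), dNER = dNER,
      plateau = plateau)
}

#' Snapshot of the simulated flow field
#'
#' Solves the rigid-aster flow for the configuration the simulation has at
#' a given separation, on the solver grid, for plotting velocity and
#' vorticity maps.
#'
#' @param cfg A \code{SimConfig}.
#' @param sep Separation distance at which to place the asters (um).
#' @return A \code{FlowField}.
#' @export
simFlowSnapshot <- function(cfg, sep = cfg@vA * cfg@anaphaseADuration) {
  domain <- cellDomain(cfg@length, cfg@width, viscosity = cfg@viscosity)
  left <- buildAsymmetricAster(domain, c(-sep / 2, 0), cfg@asterRadius,
                               midzoneX = 0, nRays = cfg@nRays,
                               seed = cfg@seed)
  right <- mirrorAster(left)
  bp <- boundaryPoints(domain, cfg@solver@nCollocation)
  epsB <- BOUNDARY_EPS_FACTOR * bp$spacing
  sol <- solveRigidAsters(domain, bp$points, epsB, left, right, cfg@cargo,
                          cfg@nodeSpacing,
                          cargoDensity = cfg@cargo@engagedCount /
                            (cfg@nRays * cfg@asterRadius))
  g <- domainGrid(domain, cfg@solver@gridSpacing)
  nx <- length(g$x); ny <- length(g$y)
  u <- matrix(NA_real_, nx, ny); v <- matrix(NA_real_, nx, ny)
  idx <- which(g$inside)
  pts <- cbind(rep(g$x, times = ny), rep(g$y, each = nx))[idx, , drop = FALSE]
  vel <- rigidFlowVelocity(sol, pts)
  u[idx] <- vel[, 1]; v[idx] <- vel[, 2]
  new("FlowField", x = g$x, y = g$y, u = u, v = v, mask = !g$inside)
}
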