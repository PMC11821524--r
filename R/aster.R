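## Asymmetric asters and the cargo-drag force dipoles they carry.

#' Build an asymmetric microtubule aster
#'
#' Ray directions are sampled uniformly on the circle (seeded), then each ray
#' is clipped where it would cross the spindle midzone plane (astral
#' microtubules do not extend beyond the midzone) and where it would leave
#' the cell (2 um clearance from the cortex). The resulting anisotropy is
#' d_a / r_a, the centre-to-midzone distance over the aster radius.
#'
#' @param domain A \code{CellDomain}.
#' @param center Aster centre (um, 2-vector), strictly inside the domain.
#' @param radius Aster radius r_a (um).
#' @param midzoneX x position of the midzone plane (um); use \code{Inf} /
#'   \code{-Inf} for an unclipped (isotropic) aster.
#' @param side \code{"left"} or \code{"right"}; inferred from the centre
#'   position when NULL.
#' @param nRays Number of rays.
#' @param seed RNG seed for ray directions.
#' @param margin Clearance kept from the boundary (um).
#' @return An \code{AsterState}.
#' @examples
#' dom <- cellDomain(300)
#' buildAsymmetricAster(dom, c(-20, 0), radius = 50, midzoneX = 0)
#' @export
buildAsymmetricAster <- function(domain, center, radius, midzoneX = 0,
                                 side = NULL, nRays = 64L, seed = 1234L,
                                 margin = 2) {
  if (!(radius > 0)) stop("invalid geometry: radius must be > 0")
  if (!insideDomain(domain, rbind(center)))
    stop("invalid geometry: aster centre outside the domain")
  if (is.null(side))
    side <- if (is.finite(midzoneX) && center[1] > midzoneX) "right" else "left"
  ## stratified jittered sampling: uniform on the circle but with far less
  ## directional sampling noise than i.i.d. draws, so the clipping-induced
  ## force asymmetry is stable across seeds and ray counts
  angles <- withSeed(seed,
    (seq_len(nRays) - 1 + runif(nRays)) * 2 * pi / nRays)
  lengths <- vapply(angles, function(th) {
    clipRay(domain, center, c(cos(th), sin(th)), radius, midzoneX, side,
            margin)
  }, numeric(1))
  new("AsterState", center = as.numeric(center), radius = radius,
      midzoneX = midzoneX, side = side, rayAngles = angles,
      rayLengths = lengths)
}

## maximum ray length before hitting the midzone plane or the boundary
clipRay <- function(domain, center, dir, radius, midzoneX, side, margin) {
  lmax <- radius
  if (is.finite(midzoneX)) {
    gap <- midzoneX - center[1]
    towards <- if (side == "left") dir[1] > 0 else dir[1] < 0
    if (towards && abs(dir[1]) > 1e-12)
      lmax <- min(lmax, abs(gap / dir[1]))
  }
  ## boundary clip by bisection on the signed distance
  tip <- center + lmax * dir
  if (!insideDomain(domain, rbind(tip), margin)) {
    lo <- 0; hi <- lmax
    for (i in 1:40) {
      mid <- (lo + hi) / 2
      if (insideDomain(domain, rbind(center + mid * dir), margin)) lo <- mid
      else hi <- mid
    }
    lmax <- lo
  }
  max(lmax, 0)
}

#' Mirror an aster about the midzone plane
#'
#' Produces the exactly mirror-symmetric partner aster (angles reflected,
#' lengths preserved), used for the two half-spindles of a symmetric cell.
#'
#' @param aster An \code{AsterState}.
#' @return The mirrored \code{AsterState}.
#' @export
mirrorAster <- function(aster) {
  mx <- aster@midzoneX
  cx <- if (is.finite(mx)) 2 * mx - aster@center[1] else -aster@center[1]
  new("AsterState", center = c(cx, aster@center[2]), radius = aster@radius,
      midzoneX = mx,
      side = if (aster@side == "left") "right" else "left",
      rayAngles = pi - aster@rayAngles, rayLengths = aster@rayLengths)
}

#' Construct cargo parameters
#'
#' @param engagedCount Engaged cargos per aster.
#' @param dyneinSpeed Dynein transport speed (um/s); default the fast-episode
#'   cargo speed 0.95 um/s.
#' @param cargoFriction Cargo friction coefficient (pN s/um); default the
#'   1-um mitochondrion value 400 pN s/um.
#' @param dutyRatio Dimensionless engagement duty ratio scaling the force;
#'   together with \code{engagedCount} this is the calibrated force knob.
#' @return A \code{CargoParams}.
#' @export
cargoParams <- function(engagedCount = 60, dyneinSpeed = 0.95,
                        cargoFriction = 400, dutyRatio = 1) {
  new("CargoParams", engagedCount = engagedCount, dyneinSpeed = dyneinSpeed,
      cargoFriction = cargoFriction, dutyRatio = dutyRatio)
}

#' Force dipoles generated by dynein cargo on an aster
#'
#' Cargos are placed along the rays with uniform density per unit
#' microtubule length (stratified over total ray length, so placement is
#' deterministic given the aster). Each cargo exerts a drag force of
#' magnitude dutyRatio * cargoFriction * dyneinSpeed on the fluid directed
#' toward the aster centre (the transport direction), paired with the equal
#' and opposite anchor reaction at the aster centre; every pair sums to
#' zero. On a clipped aster the short (midzone-facing) rays carry fewer
#' cargos, so the net anchor reaction points away from the midzone -
#' poleward - which is what propels the aster.
#'
#' @param aster An \code{AsterState}.
#' @param cargo A \code{CargoParams}.
#' @param domain Optional \code{CellDomain}; when given, cargo positions are
#'   checked to lie inside it.
#' @return A \code{ForceSystem}.
#' @export
cargoForceSystem <- function(aster, cargo, domain = NULL) {
  cf <- asterCargoForces(aster, cargo, domain)
  n <- nrow(cf$positions)
  anchorPos <- matrix(aster@center, n, 2, byrow = TRUE)
  forceSystem(rbind(cf$positions, anchorPos), rbind(cf$forces, -cf$forces),
              pair = c(seq_len(n), seq_len(n)))
}

## cargo drag forces on the fluid (positions, forces) and the net motor
## reaction transmitted to the microtubule network; when a linear cargo
## density (cargos per um of microtubule) is given, the engaged count
## follows the clipped/grown total ray length at that fixed density
asterCargoForces <- function(aster, cargo, domain = NULL, density = NULL) {
  nr <- length(aster@rayAngles)
  Lcum <- cumsum(aster@rayLengths)
  Ltot <- Lcum[nr]
  if (Ltot <= 0) stop("invalid geometry: aster has zero total ray length")
  n <- if (is.null(density)) round(cargo@engagedCount)
       else max(1L, round(density * Ltot))
  s <- (seq_len(n) - 0.5) / n * Ltot          # stratified along total length
  ray <- findInterval(s, Lcum) + 1L
  along <- s - c(0, Lcum)[ray]                # distance from centre on ray
  along <- pmax(along, 1e-6)
  dirs <- cbind(cos(aster@rayAngles[ray]), sin(aster@rayAngles[ray]))
  cargoPos <- sweep(dirs * along, 2, aster@center, "+")
  if (!is.null(domain) && !all(insideDomain(domain, cargoPos)))
    stop("invalid geometry: cargo position outside the domain")
  fmag <- cargo@dutyRatio * cargo@cargoFriction * cargo@dyneinSpeed
  cargoF <- -fmag * dirs                      # drag on fluid, toward centre
  list(positions = cargoPos, forces = cargoF,
       netReaction = -colSums(cargoF))
}

#' Network node positions of an aster
#'
#' Points along each ray at roughly \code{spacing} intervals (plus the
#' centre), used as the rigid-body representation of the sparse microtubule
#' network in the hydrodynamic force balance.
#'
#' Nodes are laid out on concentric rings at radial steps of \code{spacing}
#' (ring midpoints, so nodes sit strictly off the midzone plane and the
#' boundary margin) with an even number of equally spaced angular bins of
#' about \code{spacing} arc length per ring; a ring node is kept only where
#' a ray of sufficient length passes through its angular bin. The layout is
#' exactly mirror-symmetric for mirror-symmetric ray sets and guarantees a
#' minimum node separation (conditioning of the rigid-body system).
#'
#' @param aster An \code{AsterState}.
#' @param spacing Node spacing (um).
#' @param domain Optional \code{CellDomain}; nodes outside it (1 um margin)
#'   are dropped.
#' @return n x 2 matrix of node positions (um).
#' @export
asterNetworkNodes <- function(aster, spacing = 12, domain = NULL) {
  pts <- rbind(aster@center)
  rmax <- max(aster@rayLengths)
  nRings <- floor(rmax / spacing + 0.5)
  ang <- aster@rayAngles %% (2 * pi)
  for (j in seq_len(nRings)) {
    r <- (j - 0.5) * spacing
    nAng <- max(4L, 2L * ceiling(pi * r / spacing))    # even bin count
    phi <- (seq_len(nAng) - 0.5) * 2 * pi / nAng
    halfBin <- pi / nAng
    keep <- vapply(phi, function(p) {
      d <- abs(((ang - p + pi) %% (2 * pi)) - pi)
      any(d <= halfBin & aster@rayLengths >= r)
    }, logical(1))
    if (any(keep))
      pts <- rbind(pts, cbind(aster@center[1] + r * cos(phi[keep]),
                              aster@center[2] + r * sin(phi[keep])))
  }
  ## bin centres can overshoot their ray by up to half a bin: keep nodes
  ## strictly on this aster's side of the midzone (mirrored partners would
  ## otherwise nearly coincide there) and inside the domain
  if (is.finite(aster@midzoneX)) {
    gap <- if (aster@side == "left") aster@midzoneX - pts[, 1]
           else pts[, 1] - aster@midzoneX
    pts <- pts[gap > 0.5, , drop = FALSE]
  }
  if (!is.null(domain)) pts <- pts[insideDomain(domain, pts, 1), , drop = FALSE]
  pts
}

#' Merge force systems with distinct dipole labels
#'
#' @param ... \code{ForceSystem} objects.
#' @return A single \code{ForceSystem}.
#' @export
combineForceSystems <- function(...) {
  fss <- list(...)
  off <- 0L
  pos <- NULL; fo <- NULL; pr <- integer(0)
  for (fs in fss) {
    pos <- rbind(pos, fs@positions); fo <- rbind(fo, fs@forces)
    p <- fs@pair
    p[p > 0L] <- p[p > 0L] + off
    pr <- c(pr, p)
    if (length(fs@pair)) off <- off + max(fs@pair)
  }
  if (is.null(pos)) pos <- matrix(0, 0, 2)
  if (is.null(fo)) fo <- matrix(0, 0, 2)
  forceSystem(pos, fo, pr)
}
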