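## Cell geometry: rounded-rectangle (default, approximating a blastomere
## cross-section) or elliptical planar domains. The x axis is the axis of
## chromosome separation; the origin is the cell centre / spindle midzone.

#' Construct a confined cell domain
#'
#' @param length Cell length along the chromosome-separation axis (um).
#' @param width Cell width (um), defaults to length / 2 (the stage-matched
#'   aspect used throughout the simulations).
#' @param shape \code{"roundrect"} (default) or \code{"ellipse"}.
#' @param cornerRadius Corner radius for the rounded rectangle (um), default
#'   width / 4.
#' @param viscosity Cytoplasmic viscosity (Pa s).
#' @return A \code{CellDomain}.
#' @examples
#' cellDomain(300)
#' @export
cellDomain <- function(length, width = length / 2, shape = "roundrect",
                       cornerRadius = width / 4,
                       viscosity = defaultViscosity()) {
  new("CellDomain", shape = shape, length = length, width = width,
      cornerRadius = if (shape == "roundrect") cornerRadius else 0,
      viscosity = viscosity)
}

#' Signed distance to the domain boundary
#'
#' Negative inside, zero on the boundary, positive outside.
#'
#' @param domain A \code{CellDomain}.
#' @param xy n x 2 matrix of points (um).
#' @return Numeric vector of signed distances (um; exact for the rounded
#'   rectangle, the standard quasi-distance for the ellipse).
#' @export
domainSignedDistance <- function(domain, xy) {
  xy <- rbind(xy)
  if (domain@shape == "roundrect") {
    a <- domain@length / 2; b <- domain@width / 2; rc <- domain@cornerRadius
    qx <- abs(xy[, 1]) - (a - rc)
    qy <- abs(xy[, 2]) - (b - rc)
    d2 <- pmax(qx, 0)^2 + pmax(qy, 0)^2
    sqrt(d2) + pmin(pmax(qx, qy), 0) - rc
  } else {
    a <- domain@length / 2; b <- domain@width / 2
    k <- sqrt((xy[, 1] / a)^2 + (xy[, 2] / b)^2)
    ## approximate distance: scaled radial gap times local semi-axis scale
    (k - 1) * min(a, b)
  }
}

#' Test whether points lie inside the domain
#'
#' @param domain A \code{CellDomain}.
#' @param xy n x 2 matrix of points (um).
#' @param margin Required clearance from the boundary (um).
#' @return Logical vector.
#' @export
insideDomain <- function(domain, xy, margin = 0) {
  domainSignedDistance(domain, xy) < -margin
}

#' Evenly spaced points on the domain boundary
#'
#' Points are spaced uniformly in arc length, used as no-slip collocation
#' nodes by the confined-Stokes solver.
#'
#' @param domain A \code{CellDomain}.
#' @param n Number of boundary points.
#' @return List with \code{points} (n x 2 matrix, um), \code{spacing}
#'   (arc-length spacing, um) and \code{perimeter} (um).
#' @export
boundaryPoints <- function(domain, n) {
  n <- as.integer(n)
  a <- domain@length / 2; b <- domain@width / 2
  if (domain@shape == "roundrect") {
    rc <- domain@cornerRadius
    lx <- 2 * (a - rc); ly <- 2 * (b - rc)
    per <- 2 * lx + 2 * ly + 2 * pi * rc
    ## per-segment midpoint allocation keeps the node set exactly symmetric
    ## under x -> -x and y -> -y, which the simulation's mirror-symmetry
    ## properties rely on
    seg <- c(lx, pi * rc / 2, ly, pi * rc / 2, lx, pi * rc / 2, ly,
             pi * rc / 2)
    nseg <- pmax(1L, round(n * seg / per))
    segPts <- function(k, m) {
      t <- (seq_len(m) - 0.5) / m * seg[k]
      switch(k,
        cbind(-a + rc + t, -b),                               # bottom
        { th <- -pi / 2 + t / rc
          cbind(a - rc + rc * cos(th), -b + rc + rc * sin(th)) },
        cbind(a, -b + rc + t),                                # right
        { th <- t / rc
          cbind(a - rc + rc * cos(th), b - rc + rc * sin(th)) },
        cbind(a - rc - t, b),                                 # top
        { th <- pi / 2 + t / rc
          cbind(-a + rc + rc * cos(th), b - rc + rc * sin(th)) },
        cbind(-a, b - rc - t),                                # left
        { th <- pi + t / rc
          cbind(-a + rc + rc * cos(th), -b + rc + rc * sin(th)) })
    }
    pts <- do.call(rbind, lapply(seq_along(seg), function(k)
      segPts(k, nseg[k])))
    list(points = pts, spacing = per / nrow(pts), perimeter = per)
  } else {
    ## ellipse: equal arc length via a fine cumulative-arc-length table
    th <- seq(0, 2 * pi, length.out = 4096L)
    px <- a * cos(th); py <- b * sin(th)
    ds <- c(0, cumsum(sqrt(diff(px)^2 + diff(py)^2)))
    per <- ds[length(ds)]
    s <- (seq_len(n) - 0.5) / n * per
    ti <- approx(ds, th, xout = s)$y
    list(points = cbind(a * cos(ti), b * sin(ti)), spacing = per / n,
         perimeter = per)
  }
}

#' Regular evaluation grid covering the domain
#'
#' @param domain A \code{CellDomain}.
#' @param spacing Grid spacing (um).
#' @return List with coordinate vectors \code{x}, \code{y} and logical matrix
#'   \code{inside}.
#' @export
domainGrid <- function(domain, spacing) {
  a <- domain@length / 2; b <- domain@width / 2
  x <- seq(-a, a, by = spacing)
  y <- seq(-b, b, by = spacing)
  pts <- cbind(rep(x, times = length(y)), rep(y, each = length(x)))
  inside <- matrix(insideDomain(domain, pts), length(x), length(y))
  list(x = x, y = y, inside = inside)
}
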