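## Friction coefficients of spherical cargo and slender microtubules in a
## viscous cytoplasm, and the velocity-ratio law by which cargo drag moves
## the microtubule network. Units: 1 Pa s = 1 pN s / um^2, so all
## coefficients come out in pN s / um (equivalently pN per um/s).

#' Default cytoplasmic viscosity (Pa s)
#'
#' Calibrated so that a 1-um-diameter sphere (a mitochondrion) has a Stokes
#' friction coefficient of 400 pN s/um, the value reported for embryonic
#' cytoplasm. Override wherever an independent viscosity estimate exists.
#'
#' @return Viscosity in Pa s.
#' @examples
#' sphereFriction(0.5, defaultViscosity()) # 400 pN s/um
#' @export
defaultViscosity <- function() 400 / (6 * pi * 0.5)

#' Stokes friction coefficient of a sphere
#'
#' xi = 6 pi eta r for a sphere of radius r in unbounded fluid of viscosity
#' eta. Models a bulky cargo such as a mitochondrion.
#'
#' @param radius Sphere radius (um), > 0.
#' @param viscosity Dynamic viscosity (Pa s), > 0.
#' @return Friction coefficient (pN s/um).
#' @examples
#' sphereFriction(0.5, defaultViscosity())
#' @export
sphereFriction <- function(radius, viscosity = defaultViscosity()) {
  if (!is.numeric(radius) || length(radius) != 1L || !is.finite(radius) ||
      radius <= 0)
    stop("invalid parameter: radius must be a positive number")
  if (!is.numeric(viscosity) || length(viscosity) != 1L ||
      !is.finite(viscosity) || viscosity <= 0)
    stop("invalid parameter: viscosity must be a positive number")
  6 * pi * viscosity * radius
}

#' Longitudinal friction coefficient of a slender rod
#'
#' Resistive-force (slender-body) coefficient for motion of a rod of length
#' L and diameter d along its axis: xi = 2 pi eta L / (ln(2 L / d) - 1/2).
#' Models a microtubule dragged lengthwise through the cytoplasm.
#'
#' @param length Rod length L (um).
#' @param diameter Rod diameter d (um), default 0.025 um (a microtubule).
#' @param viscosity Dynamic viscosity (Pa s).
#' @return Friction coefficient (pN s/um).
#' @examples
#' rodLongitudinalFriction(10, 0.025, defaultViscosity())
#' @export
rodLongitudinalFriction <- function(length, diameter = 0.025,
                                    viscosity = defaultViscosity()) {
  if (!is.numeric(length) || length(length) != 1L || !is.finite(length) ||
      !is.numeric(diameter) || length(diameter) != 1L || !is.finite(diameter))
    stop("invalid parameter: length and diameter must be numbers")
  if (diameter <= 0 || length <= diameter)
    stop("invalid parameter: need length > diameter > 0")
  if (!is.numeric(viscosity) || length(viscosity) != 1L ||
      !is.finite(viscosity) || viscosity <= 0)
    stop("invalid parameter: viscosity must be a positive number")
  if (length / diameter < 10)
    warning("aspect ratio < 10: outside the slender-body regime")
  2 * pi * viscosity * length / (log(2 * length / diameter) - 0.5)
}

#' Velocity ratio of cargo and filament under an internal motor force
#'
#' A motor walking between a cargo and a filament exerts equal and opposite
#' forces on the two; in the overdamped limit their steady speeds satisfy
#' v_cargo / v_filament = xi_filament / xi_cargo. Returns that ratio.
#'
#' @param cargoFriction Cargo friction coefficient (pN s/um).
#' @param filamentFriction Filament friction coefficient (pN s/um).
#' @return Dimensionless speed ratio v_cargo / v_filament.
#' @examples
#' velocityRatio(400, 400) # comparable speeds
#' @export
velocityRatio <- function(cargoFriction, filamentFriction) {
  for (v in c(cargoFriction, filamentFriction))
    if (!is.numeric(v) || !is.finite(v) || v <= 0)
      stop("invalid parameter: friction coefficients must be positive")
  filamentFriction / cargoFriction
}
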