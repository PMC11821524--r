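#' @import methods
#' @importFrom stats fft lm median nlminb optimize rnorm rpois runif sd coef
#'   nls approx setNames var quantile
NULL

## Central S4 containers. Geometry is planar (the imaging plane); lengths in
## micrometres, times in seconds, forces in piconewtons, viscosity in Pa s
## (1 Pa s = 1 pN s / um^2).

#' Confined planar cell domain
#'
#' A closed planar boundary (rounded rectangle or ellipse) representing the
#' cell outline in the plane of chromosome separation, together with the
#' cytoplasmic viscosity. The x axis is the axis of chromosome separation and
#' the origin is the cell (and spindle midzone) centre.
#'
#' @slot shape \code{"roundrect"} or \code{"ellipse"}.
#' @slot length Cell length along the separation axis (um).
#' @slot width Cell width perpendicular to it (um).
#' @slot cornerRadius Corner radius for the rounded rectangle (um).
#' @slot viscosity Cytoplasmic viscosity (Pa s).
#' @exportClass CellDomain
setClass("CellDomain",
  representation(shape = "character", length = "numeric", width = "numeric",
                 cornerRadius = "numeric", viscosity = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (!object@shape %in% c("roundrect", "ellipse"))
      msg <- c(msg, "shape must be 'roundrect' or 'ellipse'")
    if (!(object@width > 0) || object@length < object@width)
      msg <- c(msg, "need length >= width > 0")
    if (!(object@viscosity > 0)) msg <- c(msg, "viscosity must be > 0")
    if (object@shape == "roundrect" &&
        (object@cornerRadius <= 0 || object@cornerRadius > object@width / 2))
      msg <- c(msg, "cornerRadius must lie in (0, width/2]")
    if (is.null(msg)) TRUE else msg
  })

#' System of point forces acting on the cytoplasm
#'
#' Point forces applied to the fluid, organised as force dipoles: every cargo
#' drag force is paired (via \code{pair}) with an equal and opposite anchor
#' reaction so each dipole sums to zero and the system exerts no net force.
#'
#' @slot positions n x 2 matrix of force positions (um), strictly inside the
#'   domain they are used with.
#' @slot forces n x 2 matrix of forces (pN).
#' @slot pair Integer dipole index per row (0 for unpaired forces).
#' @exportClass ForceSystem
setClass("ForceSystem",
  representation(positions = "matrix", forces = "matrix", pair = "integer"),
  validity = function(object) {
    msg <- NULL
    if (ncol(object@positions) != 2L || ncol(object@forces) != 2L)
      msg <- c(msg, "positions and forces must have two columns")
    if (nrow(object@positions) != nrow(object@forces))
      msg <- c(msg, "positions and forces must have matching rows")
    if (length(object@pair) != nrow(object@forces))
      msg <- c(msg, "pair must have one entry per force")
    if (anyNA(object@positions) || anyNA(object@forces))
      msg <- c(msg, "positions/forces must be finite")
    ids <- setdiff(unique(object@pair), 0L)
    for (id in ids) {
      s <- colSums(object@forces[object@pair == id, , drop = FALSE])
      if (max(abs(s)) > 1e-9 * max(1, max(abs(object@forces))))
        msg <- c(msg, sprintf("dipole %d does not sum to zero", id))
    }
    if (is.null(msg)) TRUE else msg
  })

#' Solver configuration for the confined-Stokes solver
#'
#' @slot epsilon Regularization length of interior force blobs (um).
#' @slot nCollocation Number of no-slip collocation points on the boundary.
#' @slot gridSpacing Spacing of the evaluation grid (um).
#' @exportClass SolverConfig
setClass("SolverConfig",
  representation(epsilon = "numeric", nCollocation = "integer",
                 gridSpacing = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (!(object@epsilon > 0)) msg <- c(msg, "epsilon must be > 0")
    if (object@nCollocation < 64L) msg <- c(msg, "need >= 64 collocation points")
    if (!(object@gridSpacing > 0)) msg <- c(msg, "gridSpacing must be > 0")
    if (is.null(msg)) TRUE else msg
  })

#' Gridded planar velocity field
#'
#' @slot x,y Grid coordinates (um); \code{u}, \code{v} are length(x) x
#'   length(y) matrices of velocity components (um/s).
#' @slot mask Optional logical matrix marking excluded grid cells.
#' @exportClass FlowField
setClass("FlowField",
  representation(x = "numeric", y = "numeric", u = "matrix", v = "matrix",
                 mask = "ANY"),
  prototype(mask = NULL),
  validity = function(object) {
    msg <- NULL
    if (!all(dim(object@u) == c(length(object@x), length(object@y))) ||
        !all(dim(object@v) == dim(object@u)))
      msg <- c(msg, "u and v must be length(x) x length(y)")
    if (!all(is.finite(object@u) | is.na(object@u)) ||
        !all(is.finite(object@v) | is.na(object@v)))
      msg <- c(msg, "velocities must be finite or NA")
    if (is.null(msg)) TRUE else msg
  })

#' Gridded vorticity field (1/s)
#' @slot x,y Grid coordinates (um); \code{omega} scalar vorticity matrix.
#' @exportClass VorticityField
setClass("VorticityField",
  representation(x = "numeric", y = "numeric", omega = "matrix"),
  validity = function(object) {
    if (!all(dim(object@omega) == c(length(object@x), length(object@y))))
      "omega must be length(x) x length(y)" else TRUE
  })

#' Asymmetric microtubule aster
#'
#' Rays (astral microtubules) emanate from the aster centre in directions
#' sampled uniformly on the circle; rays are clipped where they would cross
#' the spindle midzone plane, producing the asymmetric aster, and where they
#' would leave the cell. Anisotropy is d_a / r_a, the ratio of the
#' centre-to-midzone distance to the aster radius (capped at 1).
#'
#' @slot center Aster centre (um, 2-vector).
#' @slot radius Aster (unclipped ray) radius r_a (um).
#' @slot midzoneX x coordinate of the midzone plane (um); may be infinite.
#' @slot side \code{"left"} or \code{"right"} of the midzone.
#' @slot rayAngles Ray direction angles (rad).
#' @slot rayLengths Clipped ray lengths (um).
#' @exportClass AsterState
setClass("AsterState",
  representation(center = "numeric", radius = "numeric", midzoneX = "numeric",
                 side = "character", rayAngles = "numeric",
                 rayLengths = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (!(object@radius > 0)) msg <- c(msg, "radius must be > 0")
    if (!object@side %in% c("left", "right")) msg <- c(msg, "bad side")
    if (length(object@rayAngles) != length(object@rayLengths))
      msg <- c(msg, "rayAngles and rayLengths must match")
    if (any(object@rayLengths < 0) ||
        any(object@rayLengths > object@radius + 1e-9))
      msg <- c(msg, "ray lengths must lie in [0, radius]")
    if (is.null(msg)) TRUE else msg
  })

#' Dynein cargo parameters
#'
#' \code{engagedCount} cargos are placed along the rays with uniform density
#' per unit microtubule length. Each exerts a drag force of magnitude
#' dutyRatio * cargoFriction * dyneinSpeed on the fluid, directed toward the
#' aster centre (the direction of cargo transport), with the equal and
#' opposite reaction applied at the aster centre where the microtubules are
#' anchored. dutyRatio is the fraction of time a cargo is actively hauled and
#' scales the whole force system; engagedCount * dutyRatio * cargoFriction *
#' dyneinSpeed is the single calibrated force knob of the model.
#'
#' @slot engagedCount Number of engaged cargos per aster.
#' @slot dyneinSpeed Dynein transport speed v_d (um/s).
#' @slot cargoFriction Cargo friction coefficient (pN s/um).
#' @slot dutyRatio Dimensionless force duty ratio in (0, 1].
#' @exportClass CargoParams
setClass("CargoParams",
  representation(engagedCount = "numeric", dyneinSpeed = "numeric",
                 cargoFriction = "numeric", dutyRatio = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (object@engagedCount < 1) msg <- c(msg, "engagedCount must be >= 1")
    if (!(object@dyneinSpeed > 0)) msg <- c(msg, "dyneinSpeed must be > 0")
    if (!(object@cargoFriction > 0)) msg <- c(msg, "cargoFriction must be > 0")
    if (!(object@dutyRatio > 0 && object@dutyRatio <= 1))
      msg <- c(msg, "dutyRatio must lie in (0, 1]")
    if (is.null(msg)) TRUE else msg
  })

#' Anaphase simulation configuration
#'
#' @slot length,width Cell dimensions (um).
#' @slot vA Anaphase-A separation rate (um/s, distance between the two sets).
#' @slot anaphaseADuration Duration of kinematic anaphase A (s).
#' @slot asterRadius Aster radius r_a at anaphase-B onset (um).
#' @slot asterGrowthRate Astral growth rate of r_a during anaphase B (um/s).
#' @slot dt Time step (s).
#' @slot tEnd End of simulation (s); must cover NER (>= 271 s).
#' @slot seed RNG seed for ray/cargo placement.
#' @slot solver \code{SolverConfig}.
#' @slot cargo \code{CargoParams}.
#' @slot viscosity Cytoplasmic viscosity (Pa s).
#' @slot nRays Number of aster rays.
#' @slot nodeSpacing Spacing of the rigid network nodes along rays (um).
#' @slot flowsEnabled If FALSE, anaphase B flows are switched off (dynein
#'   inhibition control).
#' @exportClass SimConfig
setClass("SimConfig",
  representation(length = "numeric", width = "numeric", vA = "numeric",
                 anaphaseADuration = "numeric", asterRadius = "numeric",
                 asterGrowthRate = "numeric",
                 dt = "numeric", tEnd = "numeric", seed = "integer",
                 solver = "SolverConfig", cargo = "CargoParams",
                 viscosity = "numeric", nRays = "integer",
                 nodeSpacing = "numeric", flowsEnabled = "logical"),
  validity = function(object) {
    msg <- NULL
    if (!(object@dt > 0)) msg <- c(msg, "dt must be > 0")
    if (object@tEnd < 271) msg <- c(msg, "tEnd must cover NER (>= 271 s)")
    if (!(object@length > 0)) msg <- c(msg, "length must be > 0")
    if (object@vA < 0) msg <- c(msg, "vA must be >= 0")
    if (is.null(msg)) TRUE else msg
  })

#' Chromosome separation trajectory
#'
#' @slot times Sample times (s), t = 0 at anaphase onset.
#' @slot separation Distance between the two chromosome-set centroids (um).
#' @slot leftX,rightX Per-set x positions (um).
#' @slot clamped TRUE if an aster reached the boundary and was clamped.
#' @exportClass Trajectory
setClass("Trajectory",
  representation(times = "numeric", separation = "numeric",
                 leftX = "numeric", rightX = "numeric", clamped = "logical"),
  validity = function(object) {
    msg <- NULL
    n <- length(object@times)
    if (length(object@separation) != n || length(object@leftX) != n ||
        length(object@rightX) != n)
      msg <- c(msg, "times/separation/positions must have equal length")
    if (any(diff(object@times) <= 0)) msg <- c(msg, "times must increase")
    if (any(object@separation < -1e-9)) msg <- c(msg, "separation must be >= 0")
    if (is.null(msg)) TRUE else msg
  })

#' NER scaling curve
#'
#' Separation distance at NER as a function of cell length, with the plateau
#' estimate (the value at the largest simulated length).
#'
#' @slot lengths Cell lengths (um).
#' @slot dNER NER separation distances (um); NA where a run failed.
#' @slot plateau Plateau estimate (um).
#' @exportClass ScalingCurve
setClass("ScalingCurve",
  representation(lengths = "numeric", dNER = "numeric", plateau = "numeric"),
  validity = function(object) {
    if (length(object@lengths) != length(object@dNER))
      "lengths and dNER must match" else TRUE
  })

#' Chromosomal phospho-intensity trace
#'
#' @slot times Sample times (s), t = 0 at anaphase onset.
#' @slot intensity Background-subtracted intensities (a.u.).
#' @slot normalized TRUE after division by the maximum within the first 80 s.
#' @exportClass PhosphoTrace
setClass("PhosphoTrace",
  representation(times = "numeric", intensity = "numeric",
                 normalized = "logical"),
  validity = function(object) {
    msg <- NULL
    if (length(object@times) != length(object@intensity))
      msg <- c(msg, "times and intensity must match")
    if (any(diff(object@times) <= 0))
      msg <- c(msg, "times must be strictly increasing")
    if (is.null(msg)) TRUE else msg
  })

#' Exponential dephosphorylation model
#'
#' C(t) = C0 for t <= t0 and C0 exp(-(t - t0)/tau) afterwards. The
#' dephosphorylation rate is 1/tau.
#'
#' @slot t0 Onset of decay (s).
#' @slot tau Decay time (s).
#' @slot C0 Plateau amplitude (normalized units).
#' @slot se Named numeric of standard errors (possibly empty).
#' @exportClass DecayModel
setClass("DecayModel",
  representation(t0 = "numeric", tau = "numeric", C0 = "numeric",
                 se = "numeric"),
  prototype(se = numeric(0)),
  validity = function(object) {
    msg <- NULL
    if (!(object@tau > 0)) msg <- c(msg, "tau must be > 0")
    if (object@t0 < 0) msg <- c(msg, "t0 must be >= 0")
    if (!(object@C0 > 0)) msg <- c(msg, "C0 must be > 0")
    if (is.null(msg)) TRUE else msg
  })

#' Particle trajectory
#'
#' @slot t,x,y Sample times (s) and planar positions (um).
#' @slot interval Nominal frame interval (s).
#' @slot switchTime Ground-truth fast-to-slow switch time (s) when generated
#'   synthetically, NA otherwise.
#' @exportClass Track
setClass("Track",
  representation(t = "numeric", x = "numeric", y = "numeric",
                 interval = "numeric", switchTime = "numeric"),
  prototype(switchTime = NA_real_),
  validity = function(object) {
    msg <- NULL
    n <- length(object@t)
    if (length(object@x) != n || length(object@y) != n)
      msg <- c(msg, "t, x, y must have equal length")
    if (n < 5L) msg <- c(msg, "a track needs >= 5 samples")
    if (any(diff(object@t) <= 0)) msg <- c(msg, "t must strictly increase")
    if (is.null(msg)) TRUE else msg
  })

#' Parabolic MSD fit (MSD(t) = 4 D t + v^2 t^2)
#'
#' @slot D Diffusion coefficient (um^2/s), constrained >= 0.
#' @slot v Directed speed (um/s), constrained >= 0.
#' @slot se Named standard errors for D and v.
#' @slot maxDelay Largest delay used in the fit (s).
#' @exportClass MSDFit
setClass("MSDFit",
  representation(D = "numeric", v = "numeric", se = "numeric",
                 maxDelay = "numeric"),
  validity = function(object) {
    if (object@D < 0 || object@v < 0) "D and v must be >= 0" else TRUE
  })

#' Grayscale time-lapse image stack
#'
#' @slot frames nx x ny x nframes array of grayscale intensities.
#' @slot pixelSize Pixel size (um/px).
#' @slot interval Frame interval (s).
#' @slot mask Optional logical matrix (TRUE = excluded, e.g. chromosomes).
#' @slot roi Optional logical matrix (TRUE = inside the cell ROI).
#' @exportClass ImageStack
setClass("ImageStack",
  representation(frames = "array", pixelSize = "numeric",
                 interval = "numeric", mask = "ANY", roi = "ANY"),
  prototype(mask = NULL, roi = NULL),
  validity = function(object) {
    msg <- NULL
    if (length(dim(object@frames)) != 3L)
      msg <- c(msg, "frames must be a 3D array")
    if (!(object@pixelSize > 0)) msg <- c(msg, "pixelSize must be > 0")
    if (!(object@interval > 0)) msg <- c(msg, "interval must be > 0")
    if (!is.null(object@mask) &&
        !all(dim(object@mask) == dim(object@frames)[1:2]))
      msg <- c(msg, "mask must match frame shape")
    if (is.null(msg)) TRUE else msg
  })

#' PIV configuration
#'
#' @slot claheWindow CLAHE tile size (px).
#' @slot windows Multipass interrogation window sizes (px), strictly
#'   decreasing powers of two >= 16.
#' @slot overlap Window overlap fraction in [0, 0.75].
#' @slot outlierFactor Vectors faster than outlierFactor x median speed are
#'   flagged invalid.
#' @slot smooth Apply the single-pass 3 x 3 mean smoother.
#' @exportClass PIVConfig
setClass("PIVConfig",
  representation(claheWindow = "numeric", windows = "numeric",
                 overlap = "numeric", outlierFactor = "numeric",
                 smooth = "logical"),
  validity = function(object) {
    msg <- NULL
    w <- object@windows
    if (any(diff(w) >= 0)) msg <- c(msg, "windows must be strictly decreasing")
    if (any(w < 16) || any(bitwAnd(as.integer(w), as.integer(w) - 1L) != 0L))
      msg <- c(msg, "windows must be powers of two >= 16")
    if (object@overlap < 0 || object@overlap > 0.75)
      msg <- c(msg, "overlap must lie in [0, 0.75]")
    if (!(object@outlierFactor > 0)) msg <- c(msg, "outlierFactor must be > 0")
    if (is.null(msg)) TRUE else msg
  })

#' Series of per-frame-pair PIV vector fields
#'
#' @slot x,y Grid node coordinates (um).
#' @slot u,v 3D arrays (nx x ny x npairs) of velocities (um/s); NA where no
#'   vector was computed (masked).
#' @slot valid Logical 3D array flagging usable vectors.
#' @slot times Mid-pair times (s).
#' @exportClass VectorFieldSeries
setClass("VectorFieldSeries",
  representation(x = "numeric", y = "numeric", u = "array", v = "array",
                 valid = "array", times = "numeric"),
  validity = function(object) {
    msg <- NULL
    d <- dim(object@u)
    if (length(d) != 3L || !all(dim(object@v) == d) ||
        !all(dim(object@valid) == d))
      msg <- c(msg, "u, v, valid must be matching 3D arrays")
    if (d[1] != length(object@x) || d[2] != length(object@y))
      msg <- c(msg, "grid coordinates must match array shape")
    if (d[3] != length(object@times)) msg <- c(msg, "times must match pairs")
    if (is.null(msg)) TRUE else msg
  })
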