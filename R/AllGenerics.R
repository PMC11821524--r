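## Accessor generics and show methods.

#' Separation distance of a trajectory
#' @param object A \code{Trajectory}.
#' @return Numeric vector of separations (um).
#' @export
setGeneric("separation", function(object) standardGeneric("separation"))

#' @rdname separation
#' @export
setMethod("separation", "Trajectory", function(object) object@separation)

#' Sample times
#' @param object A \code{Trajectory}, \code{PhosphoTrace} or \code{Track}.
#' @return Numeric vector of times (s).
#' @export
setGeneric("sampleTimes", function(object) standardGeneric("sampleTimes"))

#' @rdname sampleTimes
#' @export
setMethod("sampleTimes", "Trajectory", function(object) object@times)

#' @rdname sampleTimes
#' @export
setMethod("sampleTimes", "PhosphoTrace", function(object) object@times)

#' @rdname sampleTimes
#' @export
setMethod("sampleTimes", "Track", function(object) object@t)

#' Intensity values of a phospho trace
#' @param object A \code{PhosphoTrace}.
#' @return Numeric vector of intensities.
#' @export
setGeneric("intensity", function(object) standardGeneric("intensity"))

#' @rdname intensity
#' @export
setMethod("intensity", "PhosphoTrace", function(object) object@intensity)

#' Decay time of a dephosphorylation model
#' @param object A \code{DecayModel}.
#' @return The decay time tau (s).
#' @export
setGeneric("decayTau", function(object) standardGeneric("decayTau"))

#' @rdname decayTau
#' @export
setMethod("decayTau", "DecayModel", function(object) object@tau)

#' Onset time of a dephosphorylation model
#' @param object A \code{DecayModel}.
#' @return The onset time t0 (s).
#' @export
setGeneric("decayOnset", function(object) standardGeneric("decayOnset"))

#' @rdname decayOnset
#' @export
setMethod("decayOnset", "DecayModel", function(object) object@t0)

#' Aster anisotropy d_a / r_a
#'
#' Ratio of the aster-centre-to-midzone distance to the aster radius, the
#' standard measure of aster asymmetry; 1 for an unclipped (isotropic) aster.
#'
#' @param object An \code{AsterState}.
#' @return Anisotropy in (0, 1].
#' @export
setGeneric("anisotropy", function(object) standardGeneric("anisotropy"))

#' @rdname anisotropy
#' @export
setMethod("anisotropy", "AsterState", function(object) {
  da <- abs(object@midzoneX - object@center[1])
  min(da / object@radius, 1)
})

#' Speed magnitude matrix of a flow field
#' @param object A \code{FlowField}.
#' @return Matrix of speeds (um/s).
#' @export
setGeneric("speed", function(object) standardGeneric("speed"))

#' @rdname speed
#' @export
setMethod("speed", "FlowField", function(object) sqrt(object@u^2 + object@v^2))

setMethod("show", "CellDomain", function(object) {
  cat(sprintf("CellDomain (%s): %.1f x %.1f um, viscosity %.3g Pa s\n",
              object@shape, object@length, object@width, object@viscosity))
})

setMethod("show", "ForceSystem", function(object) {
  cat(sprintf("ForceSystem: %d point forces (%d dipoles), |F|max %.3g pN\n",
              nrow(object@forces), length(setdiff(unique(object@pair), 0L)),
              if (nrow(object@forces)) max(abs(object@forces)) else 0))
})

setMethod("show", "FlowField", function(object) {
  sp <- speed(object)
  cat(sprintf("FlowField: %d x %d grid, max speed %.4g um/s\n",
              length(object@x), length(object@y), max(sp, na.rm = TRUE)))
})

setMethod("show", "AsterState", function(object) {
  cat(sprintf(
    "AsterState (%s): centre (%.1f, %.1f) um, r_a %.1f um, %d rays, d_a/r_a %.2f\n",
    object@side, object@center[1], object@center[2], object@radius,
    length(object@rayAngles), anisotropy(object)))
})

setMethod("show", "Trajectory", function(object) {
  cat(sprintf(
    "Trajectory: %d samples over [%.0f, %.0f] s, final separation %.1f um%s\n",
    length(object@times), min(object@times), max(object@times),
    object@separation[length(object@separation)],
    if (object@clamped) " (clamped at boundary)" else ""))
})

setMethod("show", "ScalingCurve", function(object) {
  cat(sprintf(
    "ScalingCurve: %d cell lengths in [%.0f, %.0f] um, plateau %.1f um\n",
    length(object@lengths), min(object@lengths), max(object@lengths),
    object@plateau))
})

setMethod("show", "DecayModel", function(object) {
  cat(sprintf(
    "DecayModel: t0 = %.1f s, tau = %.1f s (rate %.3g 1/s), C0 = %.3g\n",
    object@t0, object@tau, 1 / object@tau, object@C0))
})

setMethod("show", "PhosphoTrace", function(object) {
  cat(sprintf("PhosphoTrace: %d samples over [%.0f, %.0f] s%s\n",
              length(object@times), min(object@times), max(object@times),
              if (object@normalized) " (normalized)" else ""))
})

setMethod("show", "Track", function(object) {
  cat(sprintf("Track: %d samples, %.1f s at %.2g s interval\n",
              length(object@t), max(object@t) - min(object@t),
              object@interval))
})

setMethod("show", "MSDFit", function(object) {
  cat(sprintf("MSDFit: D = %.4g um^2/s, v = %.4g um/s (delays <= %.1f s)\n",
              object@D, object@v, object@maxDelay))
})

setMethod("show", "ImageStack", function(object) {
  d <- dim(object@frames)
  cat(sprintf("ImageStack: %d frames of %d x %d px, %.2f um/px, dt %.1f s\n",
              d[3], d[1], d[2], object@pixelSize, object@interval))
})

setMethod("show", "VectorFieldSeries", function(object) {
  d <- dim(object@u)
  cat(sprintf("VectorFieldSeries: %d pairs on a %d x %d grid, %.0f%% valid\n",
              d[3], d[1], d[2], 100 * mean(object@valid, na.rm = TRUE)))
})

## internal: evaluate RNG-dependent code under a local, restored seed
withSeed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}
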