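## The temporal-to-spatial NER model: chromosomal substrates are
## phosphorylated at the midzone level at anaphase onset and dephosphorylated
## exponentially; envelope reassembly milestones fire when the normalized
## level crosses fixed thresholds (WGA recruitment at 75% of the midzone
## level, NER at 37%), and chromosome motion converts those times into
## positions.

#' Construct a phospho-intensity trace
#'
#' @param times Sample times (s), strictly increasing, t = 0 at anaphase
#'   onset.
#' @param intensity Background-subtracted intensities (a.u.).
#' @param normalized Whether the trace is already normalized.
#' @return A \code{PhosphoTrace}.
#' @export
phosphoTrace <- function(times, intensity, normalized = FALSE) {
  new("PhosphoTrace", times = as.numeric(times),
      intensity = as.numeric(intensity), normalized = normalized)
}

#' Normalize a trace to its early maximum
#'
#' Divides the intensity by its maximum over the first 80 s after anaphase
#' onset (background is assumed already subtracted).
#'
#' @param trace A \code{PhosphoTrace} covering [0, 80] s.
#' @return The normalized \code{PhosphoTrace}.
#' @export
normalizeTrace <- function(trace) {
  if (min(trace@times) > 0 || max(trace@times) < 80)
    stop("coverage error: trace must cover [0, 80] s")
  m <- max(trace@intensity[trace@times <= 80])
  if (!is.finite(m) || m <= 0)
    stop("degenerate trace: non-positive maximum in the first 80 s")
  phosphoTrace(trace@times, trace@intensity / m, normalized = TRUE)
}

#' Evaluate a decay model
#'
#' @param model A \code{DecayModel}.
#' @param times Times (s).
#' @return C(t) = C0 for t <= t0, C0 exp(-(t - t0)/tau) after.
#' @export
decayValue <- function(model, times) {
  ifelse(times <= model@t0, model@C0,
         model@C0 * exp(-(times - model@t0) / model@tau))
}

#' Calibrate the decay model from two threshold/time pairs
#'
#' Solves C(t1) = theta1 and C(t2) = theta2 with C0 = 1 for the onset t0 and
#' decay time tau: tau = (t2 - t1)/ln(theta1/theta2), t0 = t1 - tau
#' ln(1/theta1). The defaults are the printed WGA (113 s, 75%) and NER
#' (271 s, 37%) anchors, giving tau of about 224 s and onset about 49 s.
#'
#' @param pWGA Numeric (time s, threshold fraction) for the earlier event.
#' @param pNER Numeric (time s, threshold fraction) for the later event.
#' @return A \code{DecayModel} with C0 = 1.
#' @examples
#' calibrateTwoPoint()
#' @export
calibrateTwoPoint <- function(pWGA = c(113, 0.75), pNER = c(271, 0.37)) {
  t1 <- pWGA[1]; th1 <- pWGA[2]; t2 <- pNER[1]; th2 <- pNER[2]
  if (!(t1 < t2)) stop("invalid input: need t1 < t2")
  if (!(th1 > th2)) stop("invalid input: need theta1 > theta2")
  if (th1 > 1 || th2 <= 0) stop("invalid input: thresholds must lie in (0, 1]")
  tau <- (t2 - t1) / log(th1 / th2)
  t0 <- t1 - tau * log(1 / th1)
  new("DecayModel", t0 = t0, tau = tau, C0 = 1)
}

#' Time at which the decay crosses a threshold
#'
#' t(theta) = t0 + tau ln(C0/theta); strictly decreasing in theta.
#'
#' @param model A \code{DecayModel}.
#' @param theta Threshold as a fraction of the midzone level, in (0, C0].
#' @return Crossing time (s).
#' @examples
#' timeAtThreshold(calibrateTwoPoint(), 0.75) # 113 s
#' timeAtThreshold(calibrateTwoPoint(), 0.37) # 271 s
#' @export
timeAtThreshold <- function(model, theta) {
  if (any(theta <= 0)) stop("invalid input: theta must be > 0")
  if (any(theta > model@C0))
    stop("no crossing: theta exceeds the plateau level C0")
  model@t0 + model@tau * log(model@C0 / theta)
}

#' Separation distance at a phosphorylation threshold
#'
#' Linearly interpolates the trajectory's separation d(t) at the threshold
#' crossing time of the decay model.
#'
#' @param traj A \code{Trajectory}.
#' @param model A \code{DecayModel}.
#' @param theta Threshold fraction.
#' @return Separation distance (um).
#' @export
positionAtThreshold <- function(traj, model, theta) {
  tc <- timeAtThreshold(model, theta)
  if (tc > max(traj@times) || tc < min(traj@times))
    stop(sprintf("coverage error: trajectory does not cover t = %.1f s", tc))
  approx(traj@times, traj@separation, xout = tc)$y
}

#' WGA and NER threshold events along a trajectory
#'
#' @param traj A \code{Trajectory}.
#' @param model A \code{DecayModel}; default the calibrated model.
#' @param thetaWGA,thetaNER Threshold fractions (defaults 0.75 and 0.37).
#' @return data.frame with columns name, theta, time_s, separation_um.
#' @export
thresholdEvents <- function(traj, model = calibrateTwoPoint(),
                            thetaWGA = 0.75, thetaNER = 0.37) {
  data.frame(
    name = c("WGA", "NER"),
    theta = c(thetaWGA, thetaNER),
    time_s = c(timeAtThreshold(model, thetaWGA),
               timeAtThreshold(model, thetaNER)),
    separation_um = c(positionAtThreshold(traj, model, thetaWGA),
                      positionAtThreshold(traj, model, thetaNER)))
}

#' Fit the exponential dephosphorylation model to a trace
#'
#' Nonlinear least squares of C(t) = C0 (t <= t0), C0 exp(-(t - t0)/tau)
#' (t > t0) over (t0, tau, C0), via Levenberg-Marquardt. The trace should be
#' normalized; the dephosphorylation rate is 1/tau of the result.
#'
#' @param trace A normalized \code{PhosphoTrace} with at least 8 samples
#'   after the decay onset.
#' @return A \code{DecayModel} with standard errors in \code{@se}.
#' @export
fitDecay <- function(trace) {
  t <- trace@times; y <- trace@intensity
  n <- length(t)
  if (n < 10L) stop("fit failure: too few samples")
  third <- max(2L, floor(n / 3))
  if (mean(y[(n - third + 1L):n]) >= mean(y[seq_len(third)]))
    stop("fit failure: trace does not decay")
  C0s <- max(y[t <= 80], na.rm = TRUE)
  below <- t[y < 0.9 * C0s]
  t0s <- if (length(below)) max(min(below) - diff(t[1:2]), 0) else 40
  tail <- y > 0.05 * C0s & t > t0s
  taus <- tryCatch({
    cf <- coef(lm(log(y[tail]) ~ t[tail]))
    if (is.finite(cf[2]) && cf[2] < 0) unname(-1 / cf[2]) else 200
  }, error = function(e) 200)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ C0 * ifelse(t <= t0, 1, exp(-(t - t0) / tau)),
      start = list(C0 = C0s, t0 = t0s, tau = taus),
      lower = c(C0 = 1e-6, t0 = 0, tau = 1e-3),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("fit failure: ", conditionMessage(e)))
  cf <- coef(fit)
  if (sum(t > cf["t0"]) < 8L)
    stop("fit failure: fewer than 8 samples after the fitted onset")
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) setNames(rep(NA_real_, 3), names(cf)))
  new("DecayModel", t0 = unname(cf["t0"]), tau = unname(cf["tau"]),
      C0 = unname(cf["C0"]), se = se)
}
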