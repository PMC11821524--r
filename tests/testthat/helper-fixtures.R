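## shared fixtures: modest solver resolutions keep unit tests fast while
## respecting the collocation-resolution requirement (spacing <= length/64)

quickDomain <- function(L = 100, W = L / 2) cellDomain(L, W)

quickSolverCfg <- function(domain, gridSpacing = domain@length / 16)
  solverConfig(domain, gridSpacing = gridSpacing)

centredDipole <- function(arm = 10, F = 100)
  forceSystem(rbind(c(-arm / 2, 0), c(arm / 2, 0)),
              rbind(c(-F, 0), c(F, 0)), c(1L, 1L))

## numerical two-equation solve for the decay calibration, independent of
## the closed form used by calibrateTwoPoint
calibrationOracle <- function(t1 = 113, th1 = 0.75, t2 = 271, th2 = 0.37) {
  tau <- uniroot(function(tau) exp((t2 - t1) / tau) - th1 / th2,
                 c(10, 2000), tol = 1e-10)$root
  t0 <- uniroot(function(t0) exp(-(t1 - t0) / tau) - th1,
                c(-500, t1), tol = 1e-10)$root
  c(t0 = t0, tau = tau)
}
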