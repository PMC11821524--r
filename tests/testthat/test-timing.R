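test_that("two-point calibration matches an independent numerical solve", {
  ## oracle: uniroot on the two threshold equations (helper-fixtures.R)
  orc <- calibrationOracle()
  m <- calibrateTwoPoint()
  expect_equal(decayTau(m), orc[["tau"]], tolerance = 1e-8)
  expect_equal(decayOnset(m), orc[["t0"]], tolerance = 1e-8)
  ## frozen values from the oracle
  expect_equal(decayTau(m), 223.6154, tolerance = 1e-6)
  expect_equal(decayOnset(m), 48.66985, tolerance = 1e-6)
})

test_that("calibration round-trips exact half-life pairs", {
  for (pars in list(c(20, 100), c(0, 300), c(60, 150))) {
    t0 <- pars[1]; tau <- pars[2]
    m <- calibrateTwoPoint(c(t0 + tau * log(2), 0.5),
                           c(t0 + 2 * tau * log(2), 0.25))
    expect_equal(decayTau(m), tau, tolerance = 1e-9)
    expect_equal(decayOnset(m), t0, tolerance = 1e-9)
  }
  expect_error(calibrateTwoPoint(c(100, 0.5), c(200, 0.5)), "invalid input")
  expect_error(calibrateTwoPoint(c(200, 0.75), c(100, 0.37)), "invalid input")
})

test_that("threshold times are monotone and match the printed anchors", {
  m <- calibrateTwoPoint()
  expect_equal(timeAtThreshold(m, 0.75), 113, tolerance = 1e-9)
  expect_equal(timeAtThreshold(m, 0.37), 271, tolerance = 1e-9)
  expect_equal(timeAtThreshold(m, 1), decayOnset(m))
  thetas <- seq(0.95, 0.1, by = -0.05)
  expect_true(all(diff(timeAtThreshold(m, thetas)) > 0))
  expect_error(timeAtThreshold(m, 1.2), "no crossing")
})

test_that("trace normalization uses the first-80-s maximum", {
  tr <- phosphoTrace(seq(0, 200, 20), rep(5, 11))
  expect_equal(intensity(normalizeTrace(tr)), rep(1, 11))
  y <- c(50, 100, 200, 150, 120, 100, 90, 80, 70, 60, 50)
  n <- normalizeTrace(phosphoTrace(seq(0, 200, 20), y))
  expect_equal(max(intensity(n)[sampleTimes(n) <= 80]), 1)
  expect_equal(intensity(n)[3], 1)
  expect_error(normalizeTrace(phosphoTrace(seq(100, 300, 20), 1:11)),
               "coverage")
  expect_error(normalizeTrace(phosphoTrace(seq(0, 200, 20), rep(-1, 11))),
               "degenerate")
})

test_that("decay fit recovers noiseless parameters to 4 significant digits", {
  m <- new("DecayModel", t0 = 48.7, tau = 223.6, C0 = 1)
  tr <- genPhosphoTraces(m, noiseSd = 0, n = 1, seed = 1)[[1]]
  fit <- fitDecay(tr)
  expect_equal(decayTau(fit), 223.6, tolerance = 1e-4)
  expect_equal(decayOnset(fit), 48.7, tolerance = 1e-4)
  expect_equal(fit@C0, 1, tolerance = 1e-4)
  increasing <- phosphoTrace(seq(0, 400, 20), seq(1, 2, length.out = 21))
  expect_error(fitDecay(increasing), "fit failure")
})

test_that("decay fit is unbiased within 5% on noisy ensembles", {
  m <- calibrateTwoPoint()
  traces <- genPhosphoTraces(m, noiseSd = 0.05, n = 100, seed = 1234)
  taus <- vapply(traces, function(tr) decayTau(fitDecay(normalizeTrace(tr))),
                 numeric(1))
  expect_lt(abs(mean(taus) - decayTau(m)) / decayTau(m), 0.05)
})

test_that("position at threshold interpolates the trajectory", {
  ## constant separation rate: d = v * t, so d(NER) = v * 271
  v <- 0.2
  traj <- new("Trajectory", times = seq(0, 300, 10),
              separation = v * seq(0, 300, 10),
              leftX = -v * seq(0, 300, 10) / 2,
              rightX = v * seq(0, 300, 10) / 2, clamped = FALSE)
  m <- calibrateTwoPoint()
  expect_equal(positionAtThreshold(traj, m, 0.37), v * 271)
  ## consistency with the crossing time by construction
  expect_equal(positionAtThreshold(traj, m, 0.75),
               approx(traj@times, traj@separation,
                      timeAtThreshold(m, 0.75))$y)
  short <- new("Trajectory", times = seq(0, 100, 10),
               separation = seq(0, 100, 10), leftX = numeric(11),
               rightX = numeric(11), clamped = FALSE)
  expect_error(positionAtThreshold(short, m, 0.37), "coverage")
  ev <- thresholdEvents(traj)
  expect_equal(ev$time_s, c(113, 271), tolerance = 1e-9)
})
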