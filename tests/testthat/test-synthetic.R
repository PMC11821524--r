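test_that("generators are bit-reproducible for identical seeds", {
  m <- calibrateTwoPoint()
  a <- genPhosphoTraces(m, 0.05, 3, seed = 7)
  b <- genPhosphoTraces(m, 0.05, 3, seed = 7)
  expect_identical(lapply(a, intensity), lapply(b, intensity))
  ta <- genTwoPhaseTracks(n = 3, seed = 7)
  tb <- genTwoPhaseTracks(n = 3, seed = 7)
  expect_identical(lapply(ta, function(x) x@x), lapply(tb, function(x) x@x))
  ma <- genParticleMovie(c(0.08, 0), nParticles = 50, nFrames = 2,
                         frameSize = c(64L, 64L), seed = 7)
  mb <- genParticleMovie(c(0.08, 0), nParticles = 50, nFrames = 2,
                         frameSize = c(64L, 64L), seed = 7)
  expect_identical(ma@frames, mb@frames)
  ## and the global RNG state is untouched
  set.seed(1); before <- runif(1)
  genPhosphoTraces(m, 0.05, 1, seed = 3)
  set.seed(1); expect_identical(runif(1), before)
})

test_that("noiseless traces equal the decay model exactly", {
  m <- calibrateTwoPoint()
  tr <- genPhosphoTraces(m, noiseSd = 0, n = 1, seed = 1)[[1]]
  expect_equal(intensity(tr), decayValue(m, sampleTimes(tr)))
  expect_equal(sampleTimes(tr), seq(0, 400, 20))
  expect_error(genPhosphoTraces(m, noiseSd = -1, n = 1), "config error")
})

test_that("two-phase tracks honour their motion parameters", {
  ## D = 0, slowV = 0: purely ballistic then static
  trks <- genTwoPhaseTracks(fastV = 1, fastDuration = 6, slowV = 0, D = 0,
                            n = 2, slowDuration = 6, seed = 3)
  tr <- trks[[1]]
  i <- which(tr@t <= tr@switchTime)
  step <- sqrt(diff(tr@x)^2 + diff(tr@y)^2) / diff(tr@t)
  expect_equal(unname(step[i[-length(i)]]), rep(1, length(i) - 1),
               tolerance = 1e-9)
  expect_equal(max(step[tr@t[-1] > tr@switchTime]), 0, tolerance = 1e-12)
  ## slow-phase displacement statistics follow 4 D t + v^2 t^2
  trks2 <- genTwoPhaseTracks(n = 200, fastDuration = 0.6, slowDuration = 48,
                             seed = 17)
  slowSegs <- lapply(trks2, function(tr) {
    i <- which(tr@t >= tr@switchTime)
    track(tr@t[i], tr@x[i], tr@y[i], interval = tr@interval)
  })
  msd <- weightedMSD(slowSegs)
  pred <- 4 * 0.017 * msd$delay + 0.089^2 * msd$delay^2
  expect_lt(max(abs(msd$msd - pred) / pred), 0.15)
})

test_that("particle movies carry their ground truth and density warning", {
  mov <- genParticleMovie(c(0.08, 0), nParticles = 300, nFrames = 3,
                          frameSize = c(128L, 128L), seed = 1)
  expect_identical(attr(mov, "flow"), c(0.08, 0))
  expect_s4_class(mov, "ImageStack")
  expect_warning(
    genParticleMovie(c(0, 0), nParticles = 5, nFrames = 2,
                     frameSize = c(256L, 256L), seed = 1),
    "density")
  ## zero flow: PIV displacement is (near) zero
  mz <- genParticleMovie(c(0, 0), nParticles = 400, nFrames = 3,
                         frameSize = c(128L, 128L), seed = 6)
  res <- pivPair(preprocessClahe(mz@frames[, , 1]),
                 preprocessClahe(mz@frames[, , 2]),
                 pivConfig(windows = c(64, 32)),
                 pixelSize = mz@pixelSize, interval = mz@interval)
  expect_lt(max(abs(res$u), na.rm = TRUE), 0.01)
})

test_that("particles avoid the chromosome mask", {
  ps <- 0.65
  mask <- chromosomeMask(c(128, 128), ps, c(41.6, 41.6), c(30, 15))
  mov <- genParticleMovie(c(0.08, 0), nParticles = 500, nFrames = 4,
                          frameSize = c(128L, 128L), mask = mask, seed = 9)
  maskInt <- vapply(1:4, function(f) mean(mov@frames[, , f][mask]),
                    numeric(1))
  outInt <- vapply(1:4, function(f) mean(mov@frames[, , f][!mask]),
                   numeric(1))
  expect_lt(mean(maskInt), 0.3 * mean(outInt))
})
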