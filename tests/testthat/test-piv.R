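makeSpeckleFrame <- function(n = 192L, seed = 3) {
  set.seed(seed)
  img <- matrix(0, n, n)
  px <- cbind(runif(400, 5, n - 5), runif(400, 5, n - 5))
  for (k in seq_len(nrow(px))) {
    i <- round(px[k, 1]); j <- round(px[k, 2])
    ii <- (i - 1):(i + 1); jj <- (j - 1):(j + 1)
    img[ii, jj] <- img[ii, jj] + outer(c(.5, 1, .5), c(.5, 1, .5))
  }
  img
}

test_that("CLAHE is deterministic, gain-invariant and flags flat frames", {
  fr <- makeSpeckleFrame()
  a <- preprocessClahe(fr)
  b <- preprocessClahe(fr)
  expect_identical(a, b)
  expect_true(all(a >= 0 & a <= 1))
  ## global gain and offset leave the output unchanged
  expect_equal(preprocessClahe(3 * fr + 10), a, tolerance = 1e-12)
  flat <- matrix(1, 64, 64)
  out <- preprocessClahe(flat)
  expect_true(isTRUE(attr(out, "flat")))
  expect_equal(as.numeric(out), as.numeric(flat))
  ## particle-to-background contrast is essentially preserved or enhanced
  bg <- median(a); pk <- max(a)
  expect_gte((pk - bg) / (max(fr) - median(fr)) * diff(range(fr)), 0.9)
})

test_that("an integer shift is recovered exactly at all valid nodes", {
  fr <- makeSpeckleFrame(192L)
  dx <- 3L; dy <- -2L
  shifted <- matrix(0, 192, 192)
  shifted[(1 + dx):192, 1:(192 + dy)] <- fr[1:(192 - dx), (1 - dy):192]
  cfg <- pivConfig(windows = c(64, 32))
  res <- pivPair(fr, shifted, cfg, pixelSize = 1, interval = 1)
  inner <- res$x > 40 & res$x < 150
  expect_lt(max(abs(res$u[inner, ] - dx), na.rm = TRUE), 0.2)
  expect_lt(max(abs(res$v[inner, ] - dy), na.rm = TRUE), 0.2)
  ## no shift -> zero field
  res0 <- pivPair(fr, fr, cfg, pixelSize = 1, interval = 1)
  expect_lt(max(abs(res0$u), na.rm = TRUE), 1e-6)
  ## translation equivariance: shifting both frames leaves the field the same
  res2 <- pivPair(shifted, shifted, cfg, pixelSize = 1, interval = 1)
  expect_lt(max(abs(res2$u), na.rm = TRUE), 1e-6)
  expect_error(pivPair(fr, shifted[1:100, 1:100], cfg), "same shape")
  expect_error(pivPair(fr[1:40, 1:40], fr[1:40, 1:40],
                       pivConfig(windows = c(128, 64, 32))), "config error")
})

test_that("outlier filtering flags spikes and smoothing preserves constants", {
  u <- array(0.1, c(8, 8, 2)); v <- array(0, c(8, 8, 2))
  u[4, 4, 1] <- 10                     # 100x spike
  s <- new("VectorFieldSeries", x = 1:8, y = 1:8, u = u, v = v,
           valid = array(TRUE, c(8, 8, 2)), times = c(5, 15))
  f <- filterVectorSeries(s, pivConfig(outlierFactor = 3, smooth = FALSE))
  expect_false(f@valid[4, 4, 1])
  expect_true(all(f@valid[, , 2]))
  ## uniform field is unchanged by the 3x3 mean smoother
  fSm <- filterVectorSeries(s, pivConfig(outlierFactor = 3, smooth = TRUE))
  expect_equal(fSm@u[, , 2], matrix(0.1, 8, 8), tolerance = 1e-12)
})

test_that("flagged fraction tracks the injected outlier rate", {
  set.seed(11)
  nx <- 20; ny <- 20; rate <- 0.10
  u <- array(rnorm(nx * ny, 0.1, 0.005), c(nx, ny, 1))
  spikes <- sample(nx * ny, round(rate * nx * ny))
  u[spikes] <- 5
  s <- new("VectorFieldSeries", x = 1:nx, y = 1:ny, u = u,
           v = array(0, dim(u)), valid = array(TRUE, dim(u)), times = 5)
  f <- filterVectorSeries(s, pivConfig(outlierFactor = 3, smooth = FALSE))
  flagged <- mean(!f@valid)
  expect_lt(abs(flagged - rate) / rate, 0.5)
})

test_that("time averaging uses only valid vectors in the window", {
  u <- array(NA_real_, c(4, 4, 4))
  u[, , 1] <- 1; u[, , 2] <- 2; u[, , 3] <- 4; u[, , 4] <- 100
  valid <- array(TRUE, c(4, 4, 4))
  valid[, , 4] <- FALSE                 # outside window anyway
  valid[1, 1, 3] <- FALSE; u[1, 1, 3] <- NA
  s <- new("VectorFieldSeries", x = 1:4, y = 1:4, u = u,
           v = array(0, dim(u)), valid = valid,
           times = c(50, 110, 190, 250))
  avg <- averageFields(s, 100, 200)
  expect_equal(avg@u[2, 2], 3)          # mean of 2 and 4
  expect_equal(avg@u[1, 1], 2)          # only pair 2 valid there
  ## a field and its negation average to zero
  u2 <- array(c(1, -1), c(2, 2, 2)); u2[, , 1] <- 1; u2[, , 2] <- -1
  s2 <- new("VectorFieldSeries", x = 1:2, y = 1:2, u = u2,
            v = array(0, dim(u2)), valid = array(TRUE, dim(u2)),
            times = c(110, 130))
  expect_equal(max(abs(averageFields(s2, 100, 200)@u)), 0)
  expect_error(averageFields(s, 300, 400), "coverage")
})

test_that("near-chromosome band speed matches a uniform field", {
  mask <- chromosomeMask(c(64, 64), 1, c(32, 32), c(20, 10))
  x <- seq(2, 62, 4); y <- seq(2, 62, 4)
  ff <- new("FlowField", x = x, y = y,
            u = matrix(0.3, length(x), length(y)),
            v = matrix(0.4, length(x), length(y)))
  expect_equal(nearChromosomeSpeed(ff, mask, band = 9, pixelSize = 1), 0.5)
  expect_error(nearChromosomeSpeed(ff, mask, band = 0), "coverage")
  expect_error(nearChromosomeSpeed(ff, mask & FALSE, band = 9), "empty mask")
})

test_that("kymographs turn motion into streaks of the right slope", {
  nx <- 64; nf <- 10
  frames <- array(0, c(nx, 16, nf))
  v <- 2                                 # px per frame along x
  for (f in seq_len(nf)) {
    pos <- 5 + v * (f - 1)
    frames[pos + (-1:1), 7:9, f] <- 1
  }
  stack <- new("ImageStack", frames = frames, pixelSize = 1, interval = 1)
  ## static scene: identical columns
  st <- new("ImageStack", frames = array(frames[, , 1], c(nx, 16, 3)),
            pixelSize = 1, interval = 1)
  k0 <- kymograph(st, c(0, 8), c(63, 8))
  expect_equal(k0[, 1], k0[, 3])
  ## moving object: peak advances v px per frame
  k <- kymograph(stack, c(0, 8), c(63, 8))
  peaks <- apply(k, 2, which.max)
  slope <- coef(lm(peaks ~ seq_len(nf)))[[2]]
  expect_equal(slope, v, tolerance = 0.1 * v)
  expect_error(kymograph(stack, c(0, 8), c(1000, 8)), "invalid input")
})

test_that("PIV recovers a rigid rotation's vorticity within 10%", {
  ## ground truth from the generator: omega = 2e-3 rad/s about the centre
  om <- 2e-3
  ctr <- c(83.2, 83.2)
  rot <- function(xy) {
    d <- sweep(xy, 2, ctr)
    cbind(-om * d[, 2], om * d[, 1])
  }
  mov <- genParticleMovie(rot, nParticles = 1200, pixelSize = 0.65,
                          interval = 10, nFrames = 6,
                          frameSize = c(256L, 256L), seed = 21)
  ser <- filterVectorSeries(pivSeries(mov, pivConfig(windows = c(64, 32))),
                            pivConfig(windows = c(64, 32)))
  avg <- averageFields(ser, 0, 60)
  vort <- vorticityField(avg)@omega
  inner <- abs(outer(avg@x - ctr[1], rep(1, length(avg@y)))) < 40 &
    abs(outer(rep(1, length(avg@x)), avg@y - ctr[2])) < 40
  expect_lt(abs(mean(vort[inner], na.rm = TRUE) - 2 * om) / (2 * om), 0.10)
})

test_that("image stacks round-trip through TIFF", {
  mov <- genParticleMovie(c(0.05, 0), nParticles = 100, nFrames = 2,
                          frameSize = c(64L, 64L), seed = 2)
  f <- tempfile(fileext = ".tif")
  writeImageStack(mov, f)
  back <- readImageStack(f, pixelSize = mov@pixelSize,
                         interval = mov@interval)
  expect_equal(dim(back@frames), dim(mov@frames))
  ## relative structure preserved (writing normalizes intensities)
  a <- mov@frames[, , 1]; b <- back@frames[, , 1]
  expect_gt(cor(as.vector(a), as.vector(b)), 0.999)
})
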