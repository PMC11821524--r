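test_that("a constant-velocity track is one fast episode", {
  t <- seq(0, 30, 0.6)
  tr <- track(t, 1.0 * t, 0 * t)
  ep <- segmentEpisodes(tr, speedThreshold = 0.4)
  expect_equal(nrow(ep), 1L)
  expect_equal(ep$kind, "fast")
  expect_equal(ep$start, 1L)
  expect_equal(ep$end, length(t))
  expect_equal(ep$meanSpeed, 1.0, tolerance = 1e-9)
})

test_that("pure diffusion is classified slow in >= 95% of replicates", {
  nSlow <- 0L
  reps <- withr::with_seed(42, lapply(1:200, function(i) {
    dt <- 0.6
    steps <- matrix(rnorm(100, sd = sqrt(2 * 0.017 * dt)), 50, 2)
    xy <- apply(steps, 2, cumsum)
    track(seq_len(50) * dt, xy[, 1], xy[, 2])
  }))
  for (tr in reps) {
    ep <- segmentEpisodes(tr, speedThreshold = 0.4)
    if (nrow(ep) == 1L && ep$kind == "slow") nSlow <- nSlow + 1L
  }
  expect_gte(nSlow / 200, 0.95)
})

test_that("the fast-to-slow switch is localized within 3 samples", {
  trks <- genTwoPhaseTracks(n = 200, seed = 99)
  err <- vapply(trks, function(tr) {
    ep <- segmentEpisodes(tr)
    i <- which(ep$kind == "slow")[1]
    if (is.na(i)) return(NA_real_)
    abs(tr@t[ep$start[i]] - tr@switchTime) / tr@interval
  }, numeric(1))
  expect_lte(median(err, na.rm = TRUE), 3)
})

test_that("MSD of a single ballistic episode is exactly v^2 t^2", {
  v <- 0.8
  t <- seq(0, 60, 0.6)
  seg <- track(t, v * t / sqrt(2), v * t / sqrt(2))
  msd <- weightedMSD(list(seg))
  expect_equal(msd$msd, v^2 * msd$delay^2, tolerance = 1e-10)
  expect_equal(msd$msd[1], v^2 * 0.6^2)   # first delay; MSD(0) = 0 trivially
  ## weights decrease with delay for finite tracks
  expect_true(all(diff(msd$weight) <= 0))
  expect_error(weightedMSD(list()), "empty input")
})

test_that("random-walk ensembles recover the 4D slope within 10%", {
  D <- 0.017
  eps <- withr::with_seed(7, lapply(1:200, function(i) {
    dt <- 0.6
    xy <- apply(matrix(rnorm(80, sd = sqrt(2 * D * dt)), 40, 2), 2, cumsum)
    track(seq_len(40) * dt, xy[, 1], xy[, 2])
  }))
  msd <- weightedMSD(eps)
  slope <- sum(msd$weight * msd$msd * msd$delay) /
    sum(msd$weight * msd$delay^2)
  expect_lt(abs(slope - 4 * D) / (4 * D), 0.10)
})

test_that("parabolic fit round-trips exact curves to 6 digits", {
  D <- 0.017; v <- 0.95
  delay <- seq(0.6, 6, 0.6)
  msd <- data.frame(delay = delay, msd = 4 * D * delay + v^2 * delay^2,
                    weight = rev(seq_along(delay)))
  fit <- fitMSDParabola(msd)
  expect_equal(fit@D, D, tolerance = 1e-6)
  expect_equal(fit@v, v, tolerance = 1e-6)
  ## scale consistency: coordinates x k -> v x k, D x k^2
  k <- 3.7
  fit2 <- fitMSDParabola(transform(msd, msd = msd * k^2))
  expect_equal(fit2@v, k * v, tolerance = 1e-6)
  expect_equal(fit2@D, k^2 * D, tolerance = 1e-6)
  decreasing <- data.frame(delay = delay, msd = rev(delay), weight = 1)
  expect_error(fitMSDParabola(decreasing), "fit failure")
  expect_error(fitMSDParabola(msd[1:3, ]), "invalid input")
})

test_that("parameter recovery holds across seeded replicate ensembles", {
  ## median recovered (v, D) within (10%, 50%) over replicate ensembles
  fastV <- numeric(10); slowV <- numeric(10); slowD <- numeric(10)
  for (r in 1:10) {
    trks <- genTwoPhaseTracks(n = 40, seed = 1000 + r)
    ff <- fitMSDParabola(weightedMSD(episodeSegments(trks, "fast")))
    fs <- fitMSDParabola(weightedMSD(episodeSegments(trks, "slow")))
    fastV[r] <- ff@v; slowV[r] <- fs@v; slowD[r] <- fs@D
  }
  expect_lt(abs(median(fastV) - 0.95) / 0.95, 0.10)
  expect_lt(abs(median(slowV) - 0.089) / 0.089, 0.10)
  expect_lt(abs(median(slowD) - 0.017) / 0.017, 0.50)
})

test_that("tracks survive a delimited-text round trip", {
  trks <- genTwoPhaseTracks(n = 3, seed = 5)
  f <- tempfile(fileext = ".tsv")
  writeTracks(trks, f)
  back <- readTracks(f)
  expect_length(back, 3)
  expect_equal(back[[1]]@x, trks[[1]]@x, tolerance = 1e-9)
  expect_equal(back[[1]]@t, trks[[1]]@t, tolerance = 1e-9)
})
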