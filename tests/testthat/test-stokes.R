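test_that("empty force system gives an identically zero field", {
  dom <- quickDomain()
  ff <- solveConfinedStokes(dom, forceSystem(matrix(0, 0, 2), matrix(0, 0, 2)),
                            quickSolverCfg(dom))
  expect_equal(max(abs(ff@u), na.rm = TRUE), 0)
  expect_equal(max(abs(ff@v), na.rm = TRUE), 0)
})

test_that("no-slip residual is below 1e-3 of the interior flow", {
  dom <- quickDomain(100, 50)
  res <- noSlipResidual(dom, centredDipole(), quickSolverCfg(dom))
  expect_lt(res$boundary, 1e-3 * res$interior)
  ## default-resolution config on a larger cell too
  dom2 <- cellDomain(300)
  res2 <- noSlipResidual(dom2, centredDipole(20, 300), solverConfig(dom2))
  expect_lt(res2$boundary, 1e-3 * res2$interior)
})

test_that("confined solve matches the free-space kernel far from boundaries", {
  ## dipole of 20 um extent in a 1000 um domain (50x); compare in the
  ## central quarter against the analytic free-space regularized Stokeslet
  dom <- cellDomain(1000, 1000, shape = "ellipse")
  cfg <- solverConfig(dom, gridSpacing = 10, nCollocation = 256L)
  fs <- forceSystem(rbind(c(-10, 0), c(10, 0)), rbind(c(-50, 0), c(50, 0)),
                    c(1L, 1L))
  solver <- anaflow:::newStokesSolver(dom, cfg)
  w <- anaflow:::solverWeights(solver, fs)
  pts <- as.matrix(expand.grid(x = seq(-120, 120, 24),
                               y = seq(-120, 120, 24)))
  r <- sqrt(rowSums(pts^2))
  pts <- pts[r > 30 & r < 96, ]     # central quarter of the domain
  uc <- anaflow:::solverVelocity(solver, fs, w, pts)
  uf <- stokesletVelocity(pts, fs@positions, fs@forces, cfg@epsilon,
                          dom@viscosity)
  relErr <- max(sqrt(rowSums((uc - uf)^2))) / max(sqrt(rowSums(uf^2)))
  expect_lt(relErr, 0.05)
})

test_that("solution is linear in the force system", {
  dom <- quickDomain()
  cfg <- quickSolverCfg(dom)
  f1 <- centredDipole(10, 100)
  f2 <- forceSystem(rbind(c(0, -10), c(0, 5)), rbind(c(30, 40), c(-30, -40)),
                    c(1L, 1L))
  both <- combineForceSystems(f1, f2)
  u1 <- solveConfinedStokes(dom, f1, cfg)
  u2 <- solveConfinedStokes(dom, f2, cfg)
  u12 <- solveConfinedStokes(dom, both, cfg)
  scale <- max(abs(u12@u), na.rm = TRUE)
  expect_lt(max(abs(u12@u - u1@u - u2@u), na.rm = TRUE), 1e-8 * scale)
  expect_lt(max(abs(u12@v - u1@v - u2@v), na.rm = TRUE), 1e-8 * scale)
})

test_that("mirror-symmetric forces give a mirror-antisymmetric field", {
  dom <- quickDomain(100, 50)
  cfg <- quickSolverCfg(dom)
  ## dipole mirrored about the y axis
  fs <- forceSystem(rbind(c(-20, 0), c(-5, 0), c(20, 0), c(5, 0)),
                    rbind(c(-50, 0), c(50, 0), c(50, 0), c(-50, 0)),
                    c(1L, 1L, 2L, 2L))
  ff <- solveConfinedStokes(dom, fs, cfg)
  nx <- length(ff@x)
  ## u(x, y) = -u(-x, y), v(x, y) = v(-x, y)
  uR <- ff@u[nx:1, ]; vR <- ff@v[nx:1, ]
  scale <- max(abs(ff@u), na.rm = TRUE)
  expect_lt(max(abs(ff@u + uR), na.rm = TRUE), 1e-6 * scale)
  expect_lt(max(abs(ff@v - vR), na.rm = TRUE), 1e-6 * scale)
})

test_that("discrete divergence is small relative to velocity gradients", {
  ## grid fine relative to the blob sizes, and evaluated away from the
  ## boundary layer, so the finite-difference truncation does not mask the
  ## solver's (analytically exact) incompressibility
  dom <- quickDomain(100, 50)
  cfg <- solverConfig(dom, gridSpacing = 1.25, epsilon = 10)
  ff <- solveConfinedStokes(dom, centredDipole(), cfg)
  h <- diff(ff@x[1:2])
  nx <- length(ff@x); ny <- length(ff@y)
  dudx <- (ff@u[3:nx, 2:(ny - 1)] - ff@u[1:(nx - 2), 2:(ny - 1)]) / (2 * h)
  dvdy <- (ff@v[2:(nx - 1), 3:ny] - ff@v[2:(nx - 1), 1:(ny - 2)]) / (2 * h)
  div <- abs(dudx + dvdy)
  ## interior nodes only (> 10 um from the boundary)
  ctr <- as.matrix(expand.grid(x = ff@x[2:(nx - 1)], y = ff@y[2:(ny - 1)]))
  interior <- matrix(domainSignedDistance(dom, ctr) < -10,
                     nx - 2, ny - 2)
  gradScale <- max(abs(dudx[interior]), abs(dvdy[interior]), na.rm = TRUE)
  expect_lt(max(div[interior], na.rm = TRUE), 1e-2 * gradScale)
})

test_that("vorticity of canonical fields is exact", {
  x <- seq(-10, 10, 1); y <- seq(-5, 5, 1)
  ## uniform translation
  ff <- new("FlowField", x = x, y = y,
            u = matrix(3, length(x), length(y)),
            v = matrix(-2, length(x), length(y)))
  expect_equal(max(abs(vorticityField(ff)@omega)), 0)
  ## rigid rotation omega: u = -w y, v = w x -> curl = 2w
  w <- 0.7
  U <- outer(x, y, function(x, y) -w * y)
  V <- outer(x, y, function(x, y) w * x)
  vf <- vorticityField(new("FlowField", x = x, y = y, u = U, v = V))
  expect_equal(max(abs(vf@omega - 2 * w)), 0, tolerance = 1e-12)
  expect_error(vorticityField(new("FlowField", x = 1:2, y = 1:2,
                                  u = matrix(0, 2, 2),
                                  v = matrix(0, 2, 2))), "3 x 3")
})

test_that("a force dipole produces an antisymmetric vortex pair", {
  ## sign pattern from the free-space kernel: a contractile dipole on the x
  ## axis has vorticity of opposite signs above and below the axis
  dom <- quickDomain(100, 60)
  ff <- solveConfinedStokes(dom, centredDipole(20, 200), quickSolverCfg(dom))
  om <- vorticityField(ff)@omega
  iy_up <- which(ff@y > 5 & ff@y < 20)
  iy_dn <- which(ff@y < -5 & ff@y > -20)
  ix <- which(abs(ff@x) < 20)
  up <- mean(om[ix, iy_up], na.rm = TRUE)
  dn <- mean(om[ix, iy_dn], na.rm = TRUE)
  expect_true(up * dn < 0)
})

test_that("probe mobility increases away from the wall and saturates", {
  dom <- cellDomain(200, 100)
  cfg <- solverConfig(dom, gridSpacing = 10)
  pm <- probeMobilityVsWall(dom, 100, c(10, 25, 50), cfg)
  expect_lt(pm$speed[1], pm$speed[3])          # w/10 vs w/2
  ## centre speed approaches the unbounded-domain dipole value within 10%
  domBig <- cellDomain(2000, 2000, shape = "ellipse")
  cfgBig <- solverConfig(domBig, gridSpacing = 40, nCollocation = 256L)
  pmBig <- probeMobilityVsWall(domBig, 100, 1000, cfgBig, arm = 10)
  free <- stokesletVelocity(rbind(c(0, 0)), rbind(c(0, 0), c(10, 0)),
                            rbind(c(100, 0), c(-100, 0)), cfgBig@epsilon,
                            domBig@viscosity)
  expect_lt(abs(pmBig$speed - sqrt(sum(free^2))) / sqrt(sum(free^2)), 0.10)
  ## a 2x larger domain is at least as mobile away from the near-wall layer
  ## (same blob size so the probes are identical objects)
  dom2 <- cellDomain(400, 200)
  pm2 <- probeMobilityVsWall(dom2, 100, c(25, 50),
                             solverConfig(dom2, gridSpacing = 20,
                                          epsilon = cfg@epsilon))
  expect_true(all(pm2$speed >= pm$speed[2:3] - 1e-9))
  expect_error(probeMobilityVsWall(dom, 100, 300, cfg), "outside")
})
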