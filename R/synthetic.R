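## Seeded generators for every input the pipeline consumes: noisy
## dephosphorylation traces, two-phase organelle tracks, particle movies
## advected by a known flow, and stage-matched simulation configs. Each
## generator carries its ground truth so downstream recovery is testable.

#' Synthetic noisy dephosphorylation traces
#'
#' Traces C(t) + Gaussian noise sampled every 20 s over [0, 400] s,
#' reproducing the acquisition cadence of the live phospho imaging.
#'
#' @param model A \code{DecayModel}.
#' @param noiseSd Gaussian noise s.d. (normalized units).
#' @param n Number of traces.
#' @param seed RNG seed.
#' @param times Sample times (s).
#' @return List of \code{PhosphoTrace} objects (unnormalized).
#' @examples
#' traces <- genPhosphoTraces(calibrateTwoPoint(), 0.05, 5, seed = 1)
#' @export
genPhosphoTraces <- function(model, noiseSd = 0.05, n = 100, seed = 1234L,
                             times = seq(0, 400, by = 20)) {
  if (noiseSd < 0) stop("config error: noiseSd must be >= 0")
  if (n < 1) stop("config error: n must be >= 1")
  base <- decayValue(model, times)
  withSeed(seed, lapply(seq_len(n), function(i)
    phosphoTrace(times, base + rnorm(length(times), sd = noiseSd))))
}

#' Synthetic two-phase organelle tracks
#'
#' Each track starts with a fast, dynein-engaged episode: ballistic motion
#' at \code{fastV} toward a virtual aster centre, plus diffusion. After
#' \code{fastDuration} it switches once to the slow episode: drift at
#' \code{slowV} in a common flow direction plus diffusion with coefficient
#' \code{D}. Defaults are the measured mitochondria motion parameters (fast
#' 0.95 um/s; slow 0.089 um/s; D 0.017 um^2/s) at 0.6 s sampling.
#'
#' @param fastV Fast-episode speed (um/s).
#' @param fastDuration Fast-episode duration (s).
#' @param slowV Slow-episode drift speed (um/s).
#' @param D Diffusion coefficient (um^2/s).
#' @param n Number of tracks.
#' @param slowDuration Slow-episode duration (s).
#' @param interval Frame interval (s).
#' @param seed RNG seed.
#' @return List of \code{Track} objects with the switch time recorded in
#'   \code{@switchTime}.
#' @examples
#' trks <- genTwoPhaseTracks(n = 3, seed = 1)
#' @export
genTwoPhaseTracks <- function(fastV = 0.95, fastDuration = 30,
                              slowV = 0.089, D = 0.017, n = 200,
                              slowDuration = 30, interval = 0.6,
                              seed = 1234L) {
  for (v in c(fastV, fastDuration, slowV, D, slowDuration))
    if (v < 0) stop("config error: rates and durations must be >= 0")
  withSeed(seed, lapply(seq_len(n), function(i) {
    ## virtual aster centre at the origin; track starts out on a radial ray
    ang <- runif(1, 0, 2 * pi)
    r0 <- runif(1, 30, 60)
    pos <- r0 * c(cos(ang), sin(ang))
    flowDir <- c(1, 0)                      # common flow direction
    nf <- round(fastDuration / interval)
    ns <- round(slowDuration / interval)
    sdStep <- sqrt(2 * D * interval)
    xs <- matrix(0, nf + ns + 1L, 2)
    xs[1L, ] <- pos
    for (k in seq_len(nf + ns)) {
      drift <- if (k <= nf) {
        toC <- -xs[k, ]; fastV * toC / max(sqrt(sum(toC^2)), 1e-9)
      } else slowV * flowDir
      xs[k + 1L, ] <- xs[k, ] + drift * interval + rnorm(2, sd = sdStep)
    }
    t <- (0:(nf + ns)) * interval
    track(t, xs[, 1], xs[, 2], interval = interval,
          switchTime = nf * interval)
  }))
}

#' Render a rectangular chromosome mask
#'
#' @param frameSize Frame size in px (nx, ny).
#' @param pixelSize Pixel size (um/px).
#' @param center Mask centre (um, image coordinates: origin top-left, x
#'   rightward, y downward).
#' @param size Mask width and height (um).
#' @return Logical matrix (TRUE inside the mask).
#' @export
chromosomeMask <- function(frameSize, pixelSize, center, size) {
  px <- (seq_len(frameSize[1]) - 0.5) * pixelSize
  py <- (seq_len(frameSize[2]) - 0.5) * pixelSize
  outer(abs(px - center[1]) <= size[1] / 2,
        abs(py - center[2]) <= size[2] / 2, "&")
}

## evaluate a flow specification (constant 2-vector, function, or FlowField)
## at n x 2 positions (um)
evalFlow <- function(flow, xy) {
  xy <- rbind(xy)
  if (is.numeric(flow) && length(flow) == 2L)
    return(matrix(flow, nrow(xy), 2, byrow = TRUE))
  if (is.function(flow)) return(rbind(flow(xy)))
  if (is(flow, "FlowField")) {
    u <- flow@u; v <- flow@v
    u[!is.finite(u)] <- 0; v[!is.finite(v)] <- 0
    ix <- pmin(pmax(findInterval(xy[, 1], flow@x), 1L), length(flow@x))
    iy <- pmin(pmax(findInterval(xy[, 2], flow@y), 1L), length(flow@y))
    return(cbind(u[cbind(ix, iy)], v[cbind(ix, iy)]))
  }
  stop("config error: unsupported flow specification")
}

#' Synthetic particle movie advected by a known flow
#'
#' Point particles (mitochondria-like spots) are seeded uniformly outside
#' the chromosome mask, advected each frame by the supplied flow
#' (semi-Lagrangian step of one frame interval), rendered as Gaussian spots
#' and degraded with Poisson shot noise plus Gaussian read noise. Particles
#' leaving the frame or entering the mask respawn uniformly, keeping the
#' seeding density. The supplied flow is the ground truth for PIV
#' validation.
#'
#' @param flow Constant velocity 2-vector (um/s), a function of n x 2
#'   positions, or a \code{FlowField}.
#' @param nParticles Particles per frame.
#' @param psfSigma Gaussian spot s.d. (um).
#' @param noiseSd Read-noise s.d. (counts).
#' @param pixelSize Pixel size (um/px).
#' @param interval Frame interval (s).
#' @param nFrames Number of frames.
#' @param frameSize Frame size (px).
#' @param mask Optional logical chromosome mask (px grid).
#' @param amplitude Spot amplitude (counts).
#' @param seed RNG seed.
#' @return An \code{ImageStack} with the mask attached; the ground-truth
#'   flow is stored in \code{attr(, "flow")}.
#' @examples
#' mov <- genParticleMovie(c(0.08, 0), nParticles = 200,
#'                         frameSize = c(128, 128), nFrames = 3, seed = 1)
#' @export
genParticleMovie <- function(flow, nParticles = 3000, psfSigma = 0.8,
                             noiseSd = 2, pixelSize = 0.65, interval = 10,
                             nFrames = 20, frameSize = c(512L, 512L),
                             mask = NULL, amplitude = 100, seed = 1234L) {
  nx <- frameSize[1]; ny <- frameSize[2]
  wUm <- nx * pixelSize; hUm <- ny * pixelSize
  winDensity <- nParticles * (32 * pixelSize)^2 / (wUm * hUm)
  if (winDensity < 5)
    warning("particle density low for 32-px PIV windows")
  inMask <- function(p) {
    if (is.null(mask)) return(rep(FALSE, nrow(p)))
    ix <- pmin(pmax(ceiling(p[, 1] / pixelSize), 1L), nx)
    iy <- pmin(pmax(ceiling(p[, 2] / pixelSize), 1L), ny)
    mask[cbind(ix, iy)]
  }
  spawn <- function(n) {
    p <- cbind(runif(n, 0, wUm), runif(n, 0, hUm))
    bad <- inMask(p)
    while (any(bad)) {
      p[bad, ] <- cbind(runif(sum(bad), 0, wUm), runif(sum(bad), 0, hUm))
      bad <- inMask(p)
    }
    p
  }
  half <- max(3L, ceiling(3 * psfSigma / pixelSize))
  kidx <- -half:half
  renderFrame <- function(p, amp) {
    img <- matrix(0, nx, ny)
    cx <- p[, 1] / pixelSize + 0.5; cy <- p[, 2] / pixelSize + 0.5
    s <- psfSigma / pixelSize
    for (k in seq_len(nrow(p))) {
      i0 <- round(cx[k]); j0 <- round(cy[k])
      ii <- i0 + kidx; jj <- j0 + kidx
      ok_i <- ii >= 1L & ii <= nx; ok_j <- jj >= 1L & jj <= ny
      if (!any(ok_i) || !any(ok_j)) next
      gx <- exp(-(ii[ok_i] - cx[k])^2 / (2 * s^2))
      gy <- exp(-(jj[ok_j] - cy[k])^2 / (2 * s^2))
      img[ii[ok_i], jj[ok_j]] <- img[ii[ok_i], jj[ok_j]] +
        amp[k] * outer(gx, gy)
    }
    img
  }
  withSeed(seed, {
    pos <- spawn(nParticles)
    amp <- runif(nParticles, 0.5, 1.5) * amplitude
    frames <- array(0, c(nx, ny, nFrames))
    for (f in seq_len(nFrames)) {
      clean <- renderFrame(pos, amp)
      noisy <- matrix(rpois(length(clean), lambda = clean), nx, ny) +
        matrix(rnorm(length(clean), sd = noiseSd), nx, ny)
      frames[, , f] <- noisy
      if (f < nFrames) {
        pos <- pos + evalFlow(flow, pos) * interval
        out <- pos[, 1] < 0 | pos[, 1] > wUm | pos[, 2] < 0 |
          pos[, 2] > hUm | inMask(pos)
        if (any(out)) {
          pos[out, ] <- spawn(sum(out))
          amp[out] <- runif(sum(out), 0.5, 1.5) * amplitude
        }
      }
    }
    stack <- new("ImageStack", frames = frames, pixelSize = pixelSize,
                 interval = interval, mask = mask, roi = NULL)
    attr(stack, "flow") <- flow
    stack
  })
}

## developmental stage -> cell length anchors (um): 1-cell 580, 4-cell 300,
## 512-cell 70, geometric in between (cleavage halves volume per cycle)
stageLengthTable <- function() {
  stages <- 2^(2:9)                          # 4 ... 512
  L <- 300 * (70 / 300)^(log2(stages / 4) / 7)
  c("1" = 580, "2" = sqrt(580 * 300), setNames(L, stages))
}

#' Stage-matched simulation config
#'
#' Maps a cleavage stage (cells per embryo) to the corresponding cell
#' length: 580 um at the 1-cell stage, 300 um at 4 cells, 70 um at 512
#' cells, geometric interpolation in between.
#'
#' @param stage 1, 2 or a power of two from 4 to 512.
#' @param ... Overrides passed to \code{\link{simConfig}}.
#' @return A \code{SimConfig}.
#' @examples
#' genStageFixture(4)@length    # 300
#' genStageFixture(512)@length  # 70
#' @export
genStageFixture <- function(stage, ...) {
  tab <- stageLengthTable()
  key <- as.character(stage)
  if (!key %in% names(tab))
    stop("config error: unsupported stage (use 1, 2, 4, 8, ..., 512)")
  simConfig(length = unname(tab[key]), ...)
}
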