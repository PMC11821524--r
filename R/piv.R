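## Particle image velocimetry: CLAHE preprocessing, coarse-to-fine multipass
## FFT cross-correlation with window shifting and 3-point Gaussian subpixel
## peaks, mask/ROI handling, outlier filtering, minimal smoothing, time
## averaging and the near-chromosome band speed.
##
## Image convention: frames are nx x ny matrices indexed [x, y] with the
## origin at the top-left pixel centre, x rightward, y downward; world
## coordinates in um are pixel centre positions times the pixel size.

#' Read / write a grayscale multi-page TIFF as an ImageStack
#'
#' @param file TIFF path.
#' @param pixelSize Pixel size (um/px).
#' @param interval Frame interval (s).
#' @return \code{readImageStack}: an \code{ImageStack}.
#' @export
readImageStack <- function(file, pixelSize, interval) {
  pages <- tiff::readTIFF(file, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  frames <- vapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1]
    t(p)                                # TIFF rows are y; store as [x, y]
  }, t(if (length(dim(pages[[1]])) == 3L) pages[[1]][, , 1] else pages[[1]]))
  new("ImageStack", frames = frames, pixelSize = pixelSize,
      interval = interval)
}

#' @rdname readImageStack
#' @param stack An \code{ImageStack}.
#' @return \code{writeImageStack}: the file path, invisibly.
#' @export
writeImageStack <- function(stack, file) {
  fr <- stack@frames
  rng <- range(fr)
  if (diff(rng) > 0) fr <- (fr - rng[1]) / diff(rng)
  pages <- lapply(seq_len(dim(fr)[3]), function(f) t(fr[, , f]))
  tiff::writeTIFF(pages, file, bits.per.sample = 16L)
  invisible(file)
}

#' Maximum-intensity projection over a substack
#'
#' @param frames 3D array (x, y, z or time).
#' @param which Indices of the slices to project; default all.
#' @return Matrix of per-pixel maxima.
#' @export
maxProject <- function(frames, which = seq_len(dim(frames)[3])) {
  apply(frames[, , which, drop = FALSE], c(1, 2), max)
}

#' PIV configuration
#'
#' @param claheWindow CLAHE tile size (px).
#' @param windows Multipass interrogation windows (px), coarse to fine.
#' @param overlap Window overlap fraction.
#' @param outlierFactor Outlier threshold as a multiple of the per-field
#'   median speed.
#' @param smooth Apply the single-pass 3 x 3 mean smoother.
#' @return A \code{PIVConfig}.
#' @export
pivConfig <- function(claheWindow = 64, windows = c(128, 64, 32),
                      overlap = 0.5, outlierFactor = 3, smooth = TRUE) {
  new("PIVConfig", claheWindow = claheWindow, windows = windows,
      overlap = overlap, outlierFactor = outlierFactor, smooth = smooth)
}

#' Contrast-limited adaptive histogram equalization
#'
#' Normalizes the frame to [0, 1] (making the result invariant to global
#' gain and offset) and applies CLAHE with tiles of \code{window} pixels. A
#' constant frame is returned unchanged with attribute \code{flat = TRUE}.
#'
#' @param frame Grayscale matrix.
#' @param window Tile size (px).
#' @return Equalized matrix in [0, 1].
#' @export
preprocessClahe <- function(frame, window = 64) {
  if (length(frame) == 0L) stop("invalid input: empty frame")
  rng <- range(frame)
  if (diff(rng) == 0) {
    attr(frame, "flat") <- TRUE
    return(frame)
  }
  img <- (frame - rng[1]) / diff(rng)
  ntx <- max(2L, round(nrow(img) / window))
  nty <- max(2L, round(ncol(img) / window))
  out <- EBImage::clahe(EBImage::Image(img), nx = ntx, ny = nty)
  as.matrix(EBImage::imageData(out))
}

## bilinear interpolation of matrix M sampled at (xs, ys) onto query points
bilinearInterp <- function(xs, ys, M, xq, yq) {
  M[!is.finite(M)] <- 0
  ix <- pmin(pmax(findInterval(xq, xs), 1L), length(xs) - 1L)
  iy <- pmin(pmax(findInterval(yq, ys), 1L), length(ys) - 1L)
  tx <- pmin(pmax((xq - xs[ix]) / (xs[ix + 1L] - xs[ix]), 0), 1)
  ty <- pmin(pmax((yq - ys[iy]) / (ys[iy + 1L] - ys[iy]), 0), 1)
  (1 - tx) * (1 - ty) * M[cbind(ix, iy)] +
    tx * (1 - ty) * M[cbind(ix + 1L, iy)] +
    (1 - tx) * ty * M[cbind(ix, iy + 1L)] +
    tx * ty * M[cbind(ix + 1L, iy + 1L)]
}

## FFT cross-correlation peak of two equal windows; returns displacement of
## the pattern from a to b in px, with 3-point Gaussian subpixel refinement
corrPeak <- function(a, b) {
  a <- a - mean(a); b <- b - mean(b)
  if (sd(a) == 0 || sd(b) == 0) return(c(NA_real_, NA_real_))
  cc <- Re(fft(Conj(fft(a)) * fft(b), inverse = TRUE))
  w <- nrow(a)
  pk <- which(cc == max(cc), arr.ind = TRUE)
  if (nrow(pk) > 1L) {                  # plateau: smallest displacement
    sh <- ((pk - 1L + w / 2) %% w) - w / 2
    pk <- pk[which.min(rowSums(sh^2)), , drop = FALSE]
  }
  i <- pk[1, 1]; j <- pk[1, 2]
  wrap <- function(k) ((k - 1L) %% w) + 1L
  sub <- function(cm, cz, cp) {
    cm <- max(cm, 1e-12); cz <- max(cz, 1e-12); cp <- max(cp, 1e-12)
    den <- 2 * log(cm) - 4 * log(cz) + 2 * log(cp)
    if (abs(den) < 1e-14) 0 else (log(cm) - log(cp)) / den
  }
  mx <- max(cc)
  dx0 <- ((i - 1L + w / 2) %% w) - w / 2
  dy0 <- ((j - 1L + w / 2) %% w) - w / 2
  ddx <- sub(cc[wrap(i - 1L), j] / mx, 1, cc[wrap(i + 1L), j] / mx)
  ddy <- sub(cc[i, wrap(j - 1L)] / mx, 1, cc[i, wrap(j + 1L)] / mx)
  c(dx0 + ddx, dy0 + ddy)
}

#' PIV displacement field for one frame pair
#'
#' Multipass coarse-to-fine FFT cross-correlation: each pass interrogates
#' windows on a regular grid, shifting the second frame's window by the
#' (rounded) displacement predicted by the previous pass, with a 3-point
#' Gaussian subpixel peak fit. Vectors whose window centre falls in the
#' chromosome mask (or whose window is mostly masked, or outside the ROI)
#' are invalidated. Displacements are converted to um/s.
#'
#' @param frameA,frameB Preprocessed grayscale matrices of equal shape.
#' @param cfg A \code{PIVConfig}.
#' @param mask Optional logical matrix (TRUE = excluded region).
#' @param roi Optional logical matrix (TRUE = inside the cell).
#' @param pixelSize Pixel size (um/px).
#' @param interval Time between the frames (s).
#' @return List with node coordinates \code{x}, \code{y} (um), velocity
#'   matrices \code{u}, \code{v} (um/s) and logical \code{valid}.
#' @export
pivPair <- function(frameA, frameB, cfg = pivConfig(), mask = NULL,
                    roi = NULL, pixelSize = 1, interval = 1) {
  if (!all(dim(frameA) == dim(frameB)))
    stop("invalid input: frames must have the same shape")
  nx <- nrow(frameA); ny <- ncol(frameA)
  if (max(cfg@windows) > min(nx, ny))
    stop("config error: interrogation window larger than the image/ROI")
  prev <- NULL
  for (w in cfg@windows) {
    step <- max(4L, round(w * (1 - cfg@overlap)))
    cx <- seq(1L, nx - w + 1L, by = step) + w / 2 - 0.5   # node centres, px
    cy <- seq(1L, ny - w + 1L, by = step) + w / 2 - 0.5
    U <- matrix(NA_real_, length(cx), length(cy))
    V <- matrix(NA_real_, length(cx), length(cy))
    ok <- matrix(TRUE, length(cx), length(cy))
    for (ii in seq_along(cx)) {
      for (jj in seq_along(cy)) {
        x0 <- round(cx[ii] - w / 2 + 0.5); y0 <- round(cy[jj] - w / 2 + 0.5)
        shift <- c(0, 0)
        if (!is.null(prev))
          shift <- round(c(
            bilinearInterp(prev$cx, prev$cy, prev$U, cx[ii], cy[jj]),
            bilinearInterp(prev$cx, prev$cy, prev$V, cx[ii], cy[jj])))
        xs <- min(max(x0 + shift[1], 1L), nx - w + 1L)
        ys <- min(max(y0 + shift[2], 1L), ny - w + 1L)
        shift <- c(xs - x0, ys - y0)
        pk <- corrPeak(frameA[x0:(x0 + w - 1L), y0:(y0 + w - 1L)],
                       frameB[xs:(xs + w - 1L), ys:(ys + w - 1L)])
        if (anyNA(pk)) { ok[ii, jj] <- FALSE; pk <- c(0, 0) }
        U[ii, jj] <- shift[1] + pk[1]
        V[ii, jj] <- shift[2] + pk[2]
      }
    }
    U[!ok] <- 0; V[!ok] <- 0
    prev <- list(cx = cx, cy = cy, U = U, V = V, ok = ok)
  }
  ## validity from mask / roi at the final grid
  valid <- prev$ok
  w <- cfg@windows[length(cfg@windows)]
  for (ii in seq_along(prev$cx)) {
    for (jj in seq_along(prev$cy)) {
      pxi <- round(prev$cx[ii] + 0.5); pyj <- round(prev$cy[jj] + 0.5)
      x0 <- round(prev$cx[ii] - w / 2 + 0.5)
      y0 <- round(prev$cy[jj] - w / 2 + 0.5)
      win <- function(m) m[x0:(x0 + w - 1L), y0:(y0 + w - 1L)]
      if (!is.null(mask) &&
          (mask[pxi, pyj] || mean(win(mask)) > 0.5))
        valid[ii, jj] <- FALSE
      if (!is.null(roi) && !roi[pxi, pyj]) valid[ii, jj] <- FALSE
    }
  }
  U <- prev$U; V <- prev$V
  U[!valid] <- NA_real_; V[!valid] <- NA_real_
  list(x = prev$cx * pixelSize, y = prev$cy * pixelSize,
       u = U * pixelSize / interval, v = V * pixelSize / interval,
       valid = valid)
}

#' Run PIV over all frame pairs of a stack
#'
#' Applies CLAHE to every frame and \code{\link{pivPair}} to consecutive
#' pairs.
#'
#' @param stack An \code{ImageStack}.
#' @param cfg A \code{PIVConfig}.
#' @return A \code{VectorFieldSeries}; pair times are midway between frames.
#' @export
pivSeries <- function(stack, cfg = pivConfig()) {
  nfr <- dim(stack@frames)[3]
  if (nfr < 2L) stop("invalid input: need at least two frames")
  pre <- lapply(seq_len(nfr), function(f)
    preprocessClahe(stack@frames[, , f], cfg@claheWindow))
  fields <- lapply(seq_len(nfr - 1L), function(f)
    pivPair(pre[[f]], pre[[f + 1L]], cfg, mask = stack@mask,
            roi = stack@roi, pixelSize = stack@pixelSize,
            interval = stack@interval))
  np <- length(fields)
  d <- dim(fields[[1L]]$u)
  u <- array(NA_real_, c(d, np)); v <- array(NA_real_, c(d, np))
  valid <- array(FALSE, c(d, np))
  for (k in seq_len(np)) {
    u[, , k] <- fields[[k]]$u; v[, , k] <- fields[[k]]$v
    valid[, , k] <- fields[[k]]$valid
  }
  new("VectorFieldSeries", x = fields[[1L]]$x, y = fields[[1L]]$y,
      u = u, v = v, valid = valid,
      times = (seq_len(np) - 0.5) * stack@interval)
}

#' Outlier filtering and minimal smoothing of a vector series
#'
#' Per field, vectors faster than \code{outlierFactor} times the field's
#' median valid speed are flagged invalid; a single-pass 3 x 3 unweighted
#' mean over valid vectors is then applied when \code{smooth} is set.
#'
#' @param series A \code{VectorFieldSeries}.
#' @param cfg A \code{PIVConfig}.
#' @return The filtered \code{VectorFieldSeries}.
#' @export
filterVectorSeries <- function(series, cfg = pivConfig()) {
  if (dim(series@u)[3] == 0L) stop("invalid input: empty series")
  if (cfg@outlierFactor <= 0) stop("config error: outlierFactor must be > 0")
  u <- series@u; v <- series@v; valid <- series@valid
  for (k in seq_len(dim(u)[3])) {
    sp <- sqrt(u[, , k]^2 + v[, , k]^2)
    med <- median(sp[valid[, , k]], na.rm = TRUE)
    if (is.finite(med) && med > 0) {
      bad <- valid[, , k] & sp > cfg@outlierFactor * med
      valid[, , k][bad] <- FALSE
      u[, , k][bad] <- NA_real_; v[, , k][bad] <- NA_real_
    }
    if (cfg@smooth) {
      u[, , k] <- meanSmooth(u[, , k], valid[, , k])
      v[, , k] <- meanSmooth(v[, , k], valid[, , k])
    }
  }
  initialize(series, u = u, v = v, valid = valid)
}

## 3x3 unweighted mean over valid entries only
meanSmooth <- function(M, valid) {
  nx <- nrow(M); ny <- ncol(M)
  out <- M
  for (i in seq_len(nx)) {
    for (j in seq_len(ny)) {
      if (!valid[i, j]) next
      ii <- max(1L, i - 1L):min(nx, i + 1L)
      jj <- max(1L, j - 1L):min(ny, j + 1L)
      vals <- M[ii, jj][valid[ii, jj]]
      out[i, j] <- mean(vals)
    }
  }
  out
}

#' Time-average a vector series into a single flow field
#'
#' Per-node mean over valid vectors of all fields whose pair time falls in
#' [tStart, tEnd] - by default the 100-200 s window after anaphase onset,
#' when the flows are most prominent.
#'
#' @param series A \code{VectorFieldSeries}.
#' @param tStart,tEnd Averaging window (s).
#' @return A \code{FlowField}; nodes with no valid vector are NA and masked.
#' @export
averageFields <- function(series, tStart = 100, tEnd = 200) {
  sel <- which(series@times >= tStart & series@times <= tEnd)
  if (length(sel) == 0L)
    stop("coverage error: no fields in the averaging window")
  nx <- length(series@x); ny <- length(series@y)
  usum <- matrix(0, nx, ny); vsum <- matrix(0, nx, ny)
  nsum <- matrix(0, nx, ny)
  for (k in sel) {
    ok <- series@valid[, , k]
    usum[ok] <- usum[ok] + series@u[, , k][ok]
    vsum[ok] <- vsum[ok] + series@v[, , k][ok]
    nsum[ok] <- nsum[ok] + 1
  }
  u <- ifelse(nsum > 0, usum / nsum, NA_real_)
  v <- ifelse(nsum > 0, vsum / nsum, NA_real_)
  new("FlowField", x = series@x, y = series@y, u = u, v = v,
      mask = nsum == 0)
}

#' Mean flow speed in the near-chromosome band
#'
#' Mean vector magnitude over grid nodes lying within \code{band} um above
#' or below the chromosome mask (along the axis perpendicular to chromosome
#' separation), excluding nodes inside the mask itself.
#'
#' @param field A \code{FlowField} (node coordinates in um).
#' @param mask Logical pixel matrix marking the chromosomes.
#' @param band Band width (um), default 9.
#' @param pixelSize Pixel size of the mask grid (um/px).
#' @return Mean speed (um/s).
#' @export
nearChromosomeSpeed <- function(field, mask, band = 9, pixelSize = 1) {
  if (is.null(mask) || !any(mask)) stop("invalid input: empty mask")
  if (band <= 0) stop("coverage error: band width must be > 0")
  ## per-column vertical extent of the mask, in um
  colHasMask <- which(apply(mask, 1, any))
  xRange <- range((colHasMask - 0.5) * pixelSize)
  yExt <- t(vapply(colHasMask, function(i) {
    r <- range(which(mask[i, ]))
    (r - 0.5) * pixelSize
  }, numeric(2)))
  yMin <- approx((colHasMask - 0.5) * pixelSize, yExt[, 1], xout = field@x,
                 rule = 2)$y
  yMax <- approx((colHasMask - 0.5) * pixelSize, yExt[, 2], xout = field@x,
                 rule = 2)$y
  speeds <- c()
  for (i in seq_along(field@x)) {
    if (field@x[i] < xRange[1] || field@x[i] > xRange[2]) next
    for (j in seq_along(field@y)) {
      yj <- field@y[j]
      inBand <- (yj < yMin[i] & yj >= yMin[i] - band) |
                (yj > yMax[i] & yj <= yMax[i] + band)
      if (inBand && is.finite(field@u[i, j]))
        speeds <- c(speeds, sqrt(field@u[i, j]^2 + field@v[i, j]^2))
    }
  }
  if (length(speeds) == 0L) stop("coverage error: no grid nodes in the band")
  mean(speeds)
}

#' Kymograph along a line segment
#'
#' Samples intensity along the segment in every frame (bilinear
#' interpolation at one-pixel spacing) and stacks the profiles by time.
#'
#' @param stack An \code{ImageStack}.
#' @param p1,p2 Segment endpoints (um, image coordinates).
#' @return Matrix (position along the line x time).
#' @export
kymograph <- function(stack, p1, p2) {
  ps <- stack@pixelSize
  d <- dim(stack@frames)
  lim <- c(d[1], d[2]) * ps
  if (any(c(p1, p2) < 0) || p1[1] > lim[1] || p2[1] > lim[1] ||
      p1[2] > lim[2] || p2[2] > lim[2])
    stop("invalid input: line outside the image")
  len <- sqrt(sum((p2 - p1)^2))
  n <- max(2L, ceiling(len / ps))
  tseq <- seq(0, 1, length.out = n)
  xq <- (p1[1] + tseq * (p2[1] - p1[1])) / ps + 0.5
  yq <- (p1[2] + tseq * (p2[2] - p1[2])) / ps + 0.5
  xs <- seq_len(d[1]); ys <- seq_len(d[2])
  out <- matrix(0, n, d[3])
  for (f in seq_len(d[3]))
    out[, f] <- bilinearInterp(xs, ys, stack@frames[, , f], xq, yq)
  out
}
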