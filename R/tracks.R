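## Two-regime analysis of organelle trajectories: a fast, dynein-engaged
## episode of directed transport toward the aster centre followed by a slow
## episode of diffusion plus drift with the cytoplasmic flow. Episodes are
## pooled into a pair-count-weighted ensemble MSD and fitted with
## MSD(t) = 4 D t + v^2 t^2.

#' Construct a particle track
#'
#' @param t Sample times (s), strictly increasing.
#' @param x,y Positions (um).
#' @param interval Nominal frame interval (s), default 0.6 s.
#' @param switchTime Ground-truth fast-to-slow switch time (synthetic
#'   tracks), NA otherwise.
#' @return A \code{Track}.
#' @export
track <- function(t, x, y, interval = 0.6, switchTime = NA_real_) {
  new("Track", t = as.numeric(t), x = as.numeric(x), y = as.numeric(y),
      interval = interval, switchTime = switchTime)
}

#' Read / write tracks as delimited text
#'
#' Tab-separated columns track_id, t_s, x_um, y_um.
#'
#' @param file Path to a delimited text file.
#' @param interval Frame interval passed to each \code{Track}.
#' @return \code{readTracks}: a named list of \code{Track} objects.
#' @export
readTracks <- function(file, interval = 0.6) {
  df <- utils::read.delim(file)
  lapply(split(df, df$track_id), function(d)
    track(d$t_s, d$x_um, d$y_um, interval = interval))
}

#' @rdname readTracks
#' @param tracks Named list of \code{Track} objects.
#' @return \code{writeTracks}: the file path, invisibly.
#' @export
writeTracks <- function(tracks, file) {
  ids <- if (is.null(names(tracks))) seq_along(tracks) else names(tracks)
  df <- do.call(rbind, Map(function(tr, id)
    data.frame(track_id = id, t_s = tr@t, x_um = tr@x, y_um = tr@y),
    tracks, ids))
  utils::write.table(df, file, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(file)
}

## instantaneous speed from a 3-sample rolling window (2-sample at the ends)
rollingSpeed <- function(tr) {
  n <- length(tr@t)
  i0 <- pmax(seq_len(n) - 1L, 1L)
  i1 <- pmin(seq_len(n) + 1L, n)
  sqrt((tr@x[i1] - tr@x[i0])^2 + (tr@y[i1] - tr@y[i0])^2) /
    (tr@t[i1] - tr@t[i0])
}

#' Segment a track into fast and slow episodes
#'
#' Computes a 3-sample rolling speed; contiguous runs above
#' \code{speedThreshold} lasting at least \code{minRun} samples are labelled
#' fast, the rest slow; adjacent same-kind runs are merged and episodes
#' shorter than 4 samples are absorbed into their longer neighbour. The
#' default threshold, 0.4 um/s, is the geometric midpoint between the fast
#' (0.95 um/s) and slow (0.089 um/s) regimes.
#'
#' @param tr A \code{Track}.
#' @param speedThreshold Fast/slow speed boundary (um/s).
#' @param minRun Minimum run length (samples) for a fast episode.
#' @return data.frame with columns kind, start, end (sample indices),
#'   nSamples, meanSpeed; zero rows for tracks shorter than \code{minRun}.
#' @export
segmentEpisodes <- function(tr, speedThreshold = 0.4, minRun = 4L) {
  n <- length(tr@t)
  empty <- data.frame(kind = character(0), start = integer(0),
                      end = integer(0), nSamples = integer(0),
                      meanSpeed = numeric(0))
  if (n < minRun) return(empty)
  sp <- rollingSpeed(tr)
  fast <- sp > speedThreshold
  r <- rle(fast)
  ## demote short fast runs
  r$values[r$values & r$lengths < minRun] <- FALSE
  lab <- inverse.rle(r)
  r2 <- rle(lab)
  ends <- cumsum(r2$lengths)
  starts <- ends - r2$lengths + 1L
  ## absorb sub-minimal fragments into the previous episode
  keep <- r2$lengths >= 4L
  if (!any(keep)) return(empty)
  ep <- data.frame(kind = ifelse(r2$values, "fast", "slow"),
                   start = starts, end = ends)[keep, , drop = FALSE]
  ep$end[seq_len(nrow(ep) - 1L)] <-
    pmax(ep$end[seq_len(nrow(ep) - 1L)],
         ep$start[seq_len(nrow(ep) - 1L) + 1L] - 1L)
  ep$end[nrow(ep)] <- n
  ep$start[1L] <- 1L
  ep$nSamples <- ep$end - ep$start + 1L
  ep$meanSpeed <- vapply(seq_len(nrow(ep)), function(i)
    mean(sp[ep$start[i]:ep$end[i]]), numeric(1))
  rownames(ep) <- NULL
  ep
}

#' Extract episode sub-tracks of one kind
#'
#' @param tracks List of \code{Track} objects.
#' @param kind \code{"fast"} or \code{"slow"}.
#' @param ... Passed to \code{\link{segmentEpisodes}}.
#' @return List of \code{Track} objects, one per episode.
#' @export
episodeSegments <- function(tracks, kind = c("fast", "slow"), ...) {
  kind <- match.arg(kind)
  segs <- list()
  for (tr in tracks) {
    ep <- segmentEpisodes(tr, ...)
    ep <- ep[ep$kind == kind, , drop = FALSE]
    for (i in seq_len(nrow(ep))) {
      idx <- ep$start[i]:ep$end[i]
      if (length(idx) >= 5L)
        segs[[length(segs) + 1L]] <-
          track(tr@t[idx], tr@x[idx], tr@y[idx], interval = tr@interval)
    }
  }
  segs
}

#' Pair-count-weighted ensemble MSD
#'
#' Ensemble mean square displacement over a set of episodes at multiples of
#' the frame interval. Each episode contributes all displacement pairs at
#' each delay up to \code{maxDelayFraction} of its duration; the weight at a
#' delay is the total number of contributing pairs.
#'
#' @param episodes List of \code{Track} objects (episodes of one kind).
#' @param maxDelayFraction Largest delay as a fraction of episode duration.
#' @return data.frame with columns delay (s), msd (um^2), weight (pairs).
#' @export
weightedMSD <- function(episodes, maxDelayFraction = 0.25) {
  if (length(episodes) == 0L) stop("empty input: no episodes")
  dt <- episodes[[1L]]@interval
  acc <- new.env()
  for (tr in episodes) {
    n <- length(tr@t)
    kmax <- max(1L, floor(maxDelayFraction * (n - 1L)))
    for (k in seq_len(kmax)) {
      d2 <- (tr@x[(k + 1L):n] - tr@x[1L:(n - k)])^2 +
            (tr@y[(k + 1L):n] - tr@y[1L:(n - k)])^2
      key <- as.character(k)
      prev <- if (is.null(acc[[key]])) c(0, 0) else acc[[key]]
      acc[[key]] <- prev + c(sum(d2), length(d2))
    }
  }
  ks <- sort(as.integer(ls(acc)))
  data.frame(delay = ks * dt,
             msd = vapply(ks, function(k) {
               a <- acc[[as.character(k)]]; a[1] / a[2]
             }, numeric(1)),
             weight = vapply(ks, function(k)
               acc[[as.character(k)]][2], numeric(1)))
}

#' Fit the parabolic MSD model
#'
#' Weighted least squares of MSD(t) = 4 D t + v^2 t^2 with D, v >= 0
#' (weights = pair counts). When the unconstrained solution would make one
#' coefficient negative, the fit is refitted with that coefficient pinned at
#' zero.
#'
#' @param msd data.frame from \code{\link{weightedMSD}} (columns delay, msd,
#'   weight), at least 4 delay points.
#' @return An \code{MSDFit}.
#' @export
fitMSDParabola <- function(msd) {
  if (nrow(msd) < 4L) stop("invalid input: need >= 4 delay points")
  t <- msd$delay; y <- msd$msd; w <- msd$weight
  f <- lm(y ~ 0 + t + I(t^2), weights = w)
  a <- coef(f)[["t"]]; b <- coef(f)[["I(t^2)"]]
  tr <- range(t)
  if ((a <= 0 && b <= 0) ||
      a * tr[2] + b * tr[2]^2 <= a * tr[1] + b * tr[1]^2)
    stop("fit failure: MSD curve is non-increasing")
  seD <- seV <- NA_real_
  if (a < 0) {                      # pure ballistic
    f <- lm(y ~ 0 + I(t^2), weights = w)
    a <- 0; b <- max(coef(f)[[1]], 0)
    seB <- suppressWarnings(summary(f))$coefficients[1, 2]
    seV <- if (b > 0) seB / (2 * sqrt(b)) else NA_real_
    seD <- 0
  } else if (b < 0) {               # pure diffusive
    f <- lm(y ~ 0 + t, weights = w)
    a <- max(coef(f)[[1]], 0); b <- 0
    seD <- suppressWarnings(summary(f))$coefficients[1, 2] / 4
    seV <- 0
  } else {
    sc <- suppressWarnings(summary(f))$coefficients
    seD <- sc["t", 2] / 4
    seV <- if (b > 0) sc["I(t^2)", 2] / (2 * sqrt(b)) else NA_real_
  }
  new("MSDFit", D = a / 4, v = sqrt(b),
      se = c(D = seD, v = seV), maxDelay = max(t))
}
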