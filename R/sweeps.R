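# Sweep extraction from decoded tracks and the alternation statistics
# computed on head-centred sweep / internal-direction sequences.

#' Transform points to head-centred coordinates
#'
#' Subtracts the reference position and rotates by minus the heading, so the
#' heading maps onto the +x axis and positive angles lie to the animal's
#' left. `fromHeadCentred()` is the exact inverse.
#'
#' @param points Matrix with columns x, y (or a length-2 vector).
#' @param ref Reference position `c(x, y)`.
#' @param heading Heading, rad.
#' @return Transformed matrix of the same shape.
#' @export
toHeadCentred <- function(points, ref, heading) {
  p <- if (is.null(dim(points))) matrix(points, ncol = 2) else points
  co <- cos(-heading); si <- sin(-heading)
  dx <- p[, 1] - ref[1]; dy <- p[, 2] - ref[2]
  cbind(x = co * dx - si * dy, y = si * dx + co * dy)
}

#' @rdname toHeadCentred
#' @export
fromHeadCentred <- function(points, ref, heading) {
  p <- if (is.null(dim(points))) matrix(points, ncol = 2) else points
  co <- cos(heading); si <- sin(heading)
  cbind(x = co * p[, 1] - si * p[, 2] + ref[1],
        y = si * p[, 1] + co * p[, 2] + ref[2])
}

# r^2 of a point cloud against the axis through `origin` along `vec`:
# 1 - var(perpendicular residuals) / (var(x) + var(y)).
sweepR2 <- function(px, py, origin, vec) {
  L <- sqrt(sum(vec^2))
  if (L == 0) return(0)
  u <- vec / L
  e <- -(px - origin[1]) * u[2] + (py - origin[2]) * u[1]
  tot <- var(px) + var(py)
  if (tot == 0) return(1)
  1 - var(e) / tot
}

#' Extract per-theta-cycle sweep trajectories
#'
#' In each theta cycle the longest run of consecutive valid decoded bins
#' with jumps below `maxJump` cm and bearing changes below `maxTurn` is
#' taken as the candidate sweep, truncated to the contiguous subsequence
#' maximizing the net Euclidean distance (exact search). The sweep vector
#' runs from the lowpass-filtered decoded position at the cycle start to
#' the most distal candidate point; candidates with at least `minPts`
#' samples and axis r-squared above `minR2` are kept. Analysis is
#' restricted to bins where running speed exceeds `speedMin`.
#'
#' @param decoded A [DecodedTrack] from a position decoder.
#' @param theta Theta signal (list with `cycle`, `windows`).
#' @param lowpass `DataFrame` with per-bin lowpass reference `x`, `y`.
#' @param session The [SweepSession] (heading and speed).
#' @param speedMin cm/s.
#' @param maxJump cm between consecutive bins.
#' @param maxTurn Maximum bearing change between consecutive displacements,
#'   rad.
#' @param minPts,minR2 Acceptance thresholds.
#' @param minMove Displacements below this (cm) carry no bearing
#'   information and do not trigger the turn criterion.
#' @return A [SweepSet].
#' @export
extractSweeps <- function(decoded, theta, lowpass, session, speedMin = 15,
                          maxJump = 20, maxTurn = pi / 2, minPts = 4,
                          minR2 = 0.5, minMove = 1) {
  d <- decoded@data
  cd <- colData(session)
  ok <- d$valid & cd$speed > speedMin
  tabs <- list(); pts <- list()
  for (w in seq_len(nrow(theta$windows))) {
    idx <- theta$windows$start[w]:theta$windows$end[w]
    vi <- idx[ok[idx]]
    if (length(vi) < minPts) next
    # split at non-consecutive bins, jumps and sharp turns
    runs <- split(vi, cumsum(c(1, diff(vi) != 1)))
    best <- NULL
    for (r in runs) {
      if (length(r) < 2) next
      dx <- diff(d$x[r]); dy <- diff(d$y[r])
      step <- sqrt(dx^2 + dy^2)
      jumpOk <- step < maxJump
      # bearings are meaningless below the decoder's bin resolution: carry
      # the last informative bearing across sub-threshold displacements
      bear <- atan2(dy, dx)
      inf <- step >= minMove
      lastInf <- cummax(ifelse(inf, seq_along(bear), 0L))
      bearAdj <- ifelse(lastInf > 0, bear[pmax(lastInf, 1L)], NA_real_)
      turn <- abs(wrapAngle(diff(bearAdj)))
      turnOk <- c(TRUE, is.na(turn) | turn < maxTurn)
      good <- jumpOk & turnOk # transition i -> i+1 admissible
      rl <- rle(good)
      ends <- cumsum(rl$lengths)
      starts <- ends - rl$lengths + 1
      for (q in which(rl$values)) {
        seg <- r[starts[q]:(ends[q] + 1)] # k good transitions = k+1 points
        if (is.null(best) || length(seg) > length(best)) best <- seg
      }
    }
    if (is.null(best) || length(best) < minPts) next
    # truncate to the subsequence with maximal net displacement
    k <- length(best)
    net <- -1; bi <- 1; bj <- k
    for (i in 1:(k - 1)) for (j in (i + 1):k) {
      nd <- (d$x[best[j]] - d$x[best[i]])^2 + (d$y[best[j]] - d$y[best[i]])^2
      if (nd > net) { net <- nd; bi <- i; bj <- j }
    }
    seg <- best[bi:bj]
    if (length(seg) < minPts) next
    orig <- c(lowpass$x[idx[1]], lowpass$y[idx[1]])
    dists <- (d$x[seg] - orig[1])^2 + (d$y[seg] - orig[2])^2
    tip <- seg[which.max(dists)]
    vec <- c(d$x[tip] - orig[1], d$y[tip] - orig[2])
    r2 <- sweepR2(d$x[seg], d$y[seg], orig, vec)
    if (!is.finite(r2) || r2 <= minR2) next
    hd0 <- cd$hd[idx[1]]
    dir <- atan2(vec[2], vec[1])
    hc <- wrapAngle(dir - hd0)
    tabs[[length(tabs) + 1]] <- DataFrame(
      cycle = theta$windows$cycle[w], tStart = cd$t[idx[1]], dir = dir,
      hcDir = hc, length = sqrt(sum(vec^2)), r2 = r2,
      side = ifelse(hc > 0, 1L, -1L), n = length(seg),
      hd = hd0, ox = orig[1], oy = orig[2])
    pts[[length(pts) + 1]] <- cbind(x = d$x[seg], y = d$y[seg])
  }
  if (!length(tabs))
    return(new("SweepSet", table = DataFrame(cycle = integer(0)),
               points = list()))
  new("SweepSet", table = do.call(rbind, tabs), points = pts)
}

#' Session-averaged sweep curves conditioned on the previous side
#'
#' Each sweep's points are head-centred (relative to its origin and
#' heading), linearly interpolated at 50 time points, grouped by the side of
#' the most recent preceding sweep, and summarized by the per-time-point
#' median.
#'
#' @param sweeps A [SweepSet].
#' @param minPerGroup Minimum sweeps per conditional group.
#' @return List with `postLeft` and `postRight` (50 x 2 matrices; one may be
#'   `NULL` with a warning for one-sided sessions).
#' @export
sessionAverageSweeps <- function(sweeps, minPerGroup = 10) {
  tab <- sweeps@table
  n <- nrow(tab)
  if (n < 2) stop("need at least 2 sweeps")
  prev <- c(NA, tab$side[-n])
  curves <- lapply(seq_len(n), function(i) {
    hc <- toHeadCentred(sweeps@points[[i]], c(tab$ox[i], tab$oy[i]),
                        tab$hd[i])
    resamplePath(hc[, 1], hc[, 2], 50)
  })
  med <- function(sel) {
    if (sum(sel, na.rm = TRUE) < minPerGroup) return(NULL)
    arr <- simplify2array(curves[which(sel)])
    apply(arr, c(1, 2), median)
  }
  out <- list(postLeft = med(prev == 1), postRight = med(prev == -1))
  if (is.null(out$postLeft) || is.null(out$postRight))
    warning("one-sided session: a conditional group is underpopulated")
  out
}

#' Sliding-window alternation score
#'
#' For each window of three successive directions with wrapped successive
#' differences `a` and `b`, the score is
#' \deqn{s = |a - b| / (2 \max(|a|, |b|))}
#' with `a - b` also circularly wrapped; 1 means perfect alternation
#' (equal-magnitude, opposite-sign changes), 0 no alternation. Windows with
#' `max(|a|,|b|) = 0` are undefined (`NA`).
#'
#' @param dirs Directions, rad.
#' @return Scores aligned to the window centres: a vector of
#'   `length(dirs)` with `NA` in the first and last position.
#' @export
alternationScore <- function(dirs) {
  n <- length(dirs)
  out <- rep(NA_real_, n)
  if (n < 3) return(out)
  d <- wrapAngle(diff(dirs))
  a <- d[-(n - 1)]; b <- d[-1]
  mx <- pmax(abs(a), abs(b))
  s <- abs(wrapAngle(a - b)) / (2 * mx)
  s[mx == 0] <- NA
  out[2:(n - 1)] <- s
  out
}

#' Triplet alternation fraction with a shuffle null
#'
#' The fraction of consecutive direction triplets whose two successive
#' (circularly wrapped) direction changes have opposite signs, compared
#' against the distribution obtained by randomly shuffling the direction
#' sequence.
#'
#' @param dirs Head-centred directions, rad (sequence of detected cycles).
#' @param shuffleN Shuffle iterations.
#' @param seed Seed.
#' @return List: `fraction`, `nTriplets`, `shuffleMean`, `shuffleSd`,
#'   `percentile` (of the observed value in the null), `shuffle99`.
#' @export
alternationFraction <- function(dirs, shuffleN = 1000, seed = 1) {
  frac <- function(v) {
    d <- wrapAngle(diff(v))
    a <- head(d, -1); b <- tail(d, -1)
    keep <- a != 0 & b != 0
    if (!sum(keep)) return(NA_real_)
    mean(sign(a[keep]) != sign(b[keep]))
  }
  n <- length(dirs)
  if (n < 5) stop("need at least 5 directions")
  obs <- frac(dirs)
  if (is.na(obs)) stop("constant direction sequence; alternation undefined")
  set.seed(seed)
  null <- vapply(seq_len(shuffleN), function(i) frac(sample(dirs)), 0)
  null <- null[is.finite(null)]
  if (!length(null)) null <- NA_real_
  list(fraction = obs, nTriplets = n - 2, shuffleMean = mean(null),
       shuffleSd = sd(null), percentile = mean(null < obs) * 100,
       shuffle99 = quantile(null, 0.99, names = FALSE))
}

#' Lagged circular autocorrelogram of a direction sequence
#'
#' Circular (Fisher-Lee) correlation between the sequence and its lagged
#' copies, for lags -maxLag..maxLag theta cycles.
#'
#' @param dirs Directions, rad.
#' @param maxLag Maximum lag.
#' @return `data.frame` with `lag` and `r` (lag 0 is 1 by construction).
#' @export
directionAutocorrelogram <- function(dirs, maxLag = 7) {
  n <- length(dirs)
  if (n < 50) warning("short sequence; lagged correlations are noisy")
  r <- vapply(-maxLag:maxLag, function(l) {
    if (l == 0) return(1)
    al <- abs(l)
    circCorr(dirs[1:(n - al)], dirs[(1 + al):n])
  }, 0)
  data.frame(lag = -maxLag:maxLag, r = r)
}

#' Conditional directional modes
#'
#' Each direction (from the second on) is classified left- or
#' right-directed by the sign of its wrapped offset from the previous
#' direction; head-centred directions following each class are histogrammed
#' (60 bins, circular smoothing) and the peak of each conditional histogram
#' is returned.
#'
#' @param dirs Head-centred directions, rad.
#' @param nbins Histogram bins.
#' @param smoothBins Circular Gaussian smoothing, bins.
#' @return List `modeAfterLeft`, `modeAfterRight` (rad), plus the two
#'   histograms.
#' @export
conditionalModes <- function(dirs, nbins = 60, smoothBins = 2) {
  n <- length(dirs)
  if (n < 5) stop("need at least 5 directions")
  delta <- wrapAngle(diff(dirs))
  cls <- sign(delta) # class of direction i+1, i = 1..n-1
  binw <- 2 * pi / nbins
  centers <- seq(-pi + binw / 2, pi - binw / 2, by = binw)
  histOf <- function(sel) {
    if (!sum(sel)) return(NULL)
    v <- dirs[sel]
    ib <- pmin(floor((wrapAngle(v) + pi) / binw) + 1L, nbins)
    gaussSmooth(tabulate(ib, nbins), smoothBins, circular = TRUE)
  }
  # directions that FOLLOW a left-directed (cls == 1) angle
  followsLeft <- c(FALSE, cls == 1)[seq_len(n)]
  followsRight <- c(FALSE, cls == -1)[seq_len(n)]
  hl <- histOf(followsLeft)
  hr <- histOf(followsRight)
  if (is.null(hl) || is.null(hr)) stop("both conditions must be populated")
  list(modeAfterLeft = centers[which.max(hl)],
       modeAfterRight = centers[which.max(hr)],
       histAfterLeft = hl, histAfterRight = hr, binCenters = centers)
}

#' Temporal delay between two regions' decoded sweeps
#'
#' For each region, the offset of the decoded position from the animal's
#' position is projected onto the head axis; the signed lag of the
#' cross-correlogram peak nearest zero gives the delay (positive = second
#' region delayed).
#'
#' @param decA,decB [DecodedTrack]s on the same clock.
#' @param session The [SweepSession].
#' @param maxLagMs Search range, ms.
#' @return Lag in ms.
#' @export
regionDelay <- function(decA, decB, session, maxLagMs = 100) {
  cd <- colData(session)
  dt <- binWidth(session)
  proj <- function(dec) {
    p <- (dec@data$x - cd$x) * cos(cd$hd) + (dec@data$y - cd$y) * sin(cd$hd)
    v <- dec@data$valid
    p[!v] <- NA
    # fill gaps for the correlogram
    filled <- approx(which(!is.na(p)), p[!is.na(p)], xout = seq_along(p),
                     rule = 2)$y
    filled
  }
  a <- proj(decA); b <- proj(decB)
  ok <- is.finite(a) & is.finite(b)
  if (sum(ok) < 1000) stop("need >= 1000 overlapping valid bins")
  maxLag <- round(maxLagMs / (dt * 1000))
  cc <- stats::ccf(a, b, lag.max = maxLag, plot = FALSE,
                   na.action = stats::na.pass)
  r <- as.numeric(cc$acf); lags <- as.numeric(cc$lag)
  locmax <- which(diff(sign(diff(r))) == -2) + 1
  if (!length(locmax)) locmax <- which.max(r)
  best <- locmax[which.min(abs(lags[locmax]))]
  # ccf(a, b) peaks at negative lag when b trails a; report positive as
  # "B delayed relative to A"
  -lags[best] * dt * 1000
}

#' Theta phase precession against in-field position
#'
#' In-field position is the projection of (position - nearest grid vertex)
#' onto the internal-direction axis (negative approaching the field centre,
#' positive leaving). Cells with a negative circular-linear correlation
#' between spike theta phase and in-field position at P < 0.01 are
#' classified as precessing.
#'
#' @param session A [SweepSession].
#' @param cell Cell index.
#' @param vertices Matrix of field-centre coordinates (columns x, y), e.g.
#'   local maxima of the cell's rate map.
#' @param internalDir Per-bin internal direction, rad.
#' @param phase Per-bin theta phase, rad.
#' @param maxDist Only spikes within this distance (cm) of a vertex count as
#'   in-field.
#' @return List: `rho`, `p.value`, `slope`, `precessing`, `nSpikes`.
#' @export
phasePrecession <- function(session, cell, vertices, internalDir, phase,
                            maxDist = 25) {
  cd <- colData(session)
  cnt <- spikeCounts(session)[cell, ]
  # nearest vertex per time bin
  nv <- nrow(vertices)
  dmin <- rep(Inf, ncol(session)); vi <- integer(ncol(session))
  for (v in seq_len(nv)) {
    dd <- (cd$x - vertices[v, 1])^2 + (cd$y - vertices[v, 2])^2
    upd <- dd < dmin
    dmin[upd] <- dd[upd]; vi[upd] <- v
  }
  infield <- sqrt(dmin) <= maxDist & cd$valid
  pos <- (cd$x - vertices[vi, 1]) * cos(internalDir) +
    (cd$y - vertices[vi, 2]) * sin(internalDir)
  sel <- infield & cnt > 0
  ph <- rep(phase[sel], cnt[sel])
  px <- rep(pos[sel], cnt[sel])
  if (length(ph) < 100)
    return(list(rho = NA_real_, p.value = NA_real_, slope = NA_real_,
                precessing = FALSE, nSpikes = length(ph)))
  cl <- circLinCorr(ph, px, slopeRange = c(-0.05, 0.05))
  list(rho = cl$rho, p.value = cl$p.value, slope = cl$slope,
       precessing = isTRUE(cl$rho < 0 && cl$p.value < 0.01),
       nSpikes = length(ph))
}

#' Sweep and direction alternation at population-activity peaks (sleep)
#'
#' Sleep has no behavioural heading and (in SWS) no theta, so analysis is
#' anchored to local maxima of the smoothed direction-cell population rate
#' (sigma = 20 ms). Decoded directions at the peaks are referenced to a
#' virtual heading (the sigma = 1 cycle circularly smoothed decoded
#' direction); decoded positions are referenced to a sigma = 100 ms lowpass
#' decoded trajectory. Alternation is quantified over pairs of successive
#' peaks 2-250 ms apart as the fraction with opposite head-centred sides,
#' against a side-shuffled null.
#'
#' @param posXY `DataFrame`/`data.frame` with per-bin decoded `x`, `y`.
#' @param dirPerBin Per-bin decoded direction, rad.
#' @param popRate Per-bin summed direction-cell counts.
#' @param dt Bin width, s.
#' @param spacing Grid spacing (cm) for the jump criterion.
#' @param shuffleN,seed Null distribution controls.
#' @return List: `peaks` (bin indices), `fraction`, `shuffleMean`,
#'   `shuffle99`, `sweeps` (per-peak run lengths of smooth decoded
#'   sequences).
#' @export
sleepSweeps <- function(posXY, dirPerBin, popRate, dt = 0.01, spacing = 75,
                        shuffleN = 1000, seed = 1) {
  sm <- gaussSmooth(popRate, 0.02 / dt)
  n <- length(sm)
  pk <- which(diff(sign(diff(sm))) == -2) + 1
  pk <- pk[sm[pk] > median(sm)]
  if (length(pk) < 5) stop("too few population-activity peaks")
  vhd <- circSmooth(dirPerBin, 0.125 / dt)
  lx <- gaussSmooth(posXY$x, 0.1 / dt)
  ly <- gaussSmooth(posXY$y, 0.1 / dt)
  half <- round(0.05 / dt)
  maxJump <- 0.15 * spacing
  runLen <- vapply(seq_along(pk), function(i) {
    lo <- max(1, pk[i] - half, if (i > 1) floor((pk[i - 1] + pk[i]) / 2) + 1)
    hi <- min(n, pk[i] + half,
              if (i < length(pk)) floor((pk[i] + pk[i + 1]) / 2))
    idx <- lo:hi
    if (length(idx) < 3) return(0L)
    dx <- diff(posXY$x[idx]); dy <- diff(posXY$y[idx])
    jump <- sqrt(dx^2 + dy^2)
    bear <- atan2(dy, dx)
    good <- jump < maxJump & c(TRUE, abs(wrapAngle(diff(bear))) < 2)
    r <- rle(good)
    max(c(0L, r$lengths[r$values])) + 1L
  }, 0L)
  side <- sign(wrapAngle(dirPerBin[pk] - vhd[pk]))
  dtpk <- diff(pk) * dt
  use <- dtpk >= 0.002 & dtpk <= 0.25
  if (!sum(use)) stop("no peak pairs in the 2-250 ms range")
  obs <- mean(side[-length(side)][use] != side[-1][use])
  set.seed(seed)
  null <- vapply(seq_len(shuffleN), function(i) {
    s <- sample(side)
    mean(s[-length(s)][use] != s[-1][use])
  }, 0)
  list(peaks = pk, fraction = obs, shuffleMean = mean(null),
       shuffle99 = quantile(null, 0.99, names = FALSE), sweeps = runLen)
}

# Circular smoothing of an angle series: smooth unit vectors, take Arg.
circSmooth <- function(a, sigma) {
  cx <- gaussSmooth(cos(a), sigma)
  sy <- gaussSmooth(sin(a), sigma)
  atan2(sy, cx)
}

#' Chance level of the alternation score
#'
#' Monte-Carlo expectation of the three-sweep alternation score for iid
#' uniform directions on the circle (the reference line for agent runs).
#'
#' @param nTriplets Number of random triplets.
#' @param seed Integer seed.
#' @return Mean score (about 0.40).
#' @export
chanceAlternationScore <- function(nTriplets = 1e6, seed = 1) {
  set.seed(seed)
  a <- wrapAngle(runif(nTriplets, 0, 2 * pi) - runif(nTriplets, 0, 2 * pi))
  b <- wrapAngle(runif(nTriplets, 0, 2 * pi) - runif(nTriplets, 0, 2 * pi))
  mx <- pmax(abs(a), abs(b))
  s <- abs(wrapAngle(a - b)) / (2 * mx)
  mean(s[mx > 0])
}
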