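# Preprocessing: binning, rate maps with cross-validated smoothing, theta
# phase from population activity, single-cell indices, grid-module
# identification and sleep staging.

#' Bin a spike table against a trajectory
#'
#' Spike times are counted in `dt` bins aligned to the trajectory samples;
#' bins where running speed is at or below `speedMin` are flagged invalid
#' (they are retained in the count matrix, so total spikes are conserved).
#'
#' @param spikes `data.frame` with columns `neuron` (1-based id) and `t` (s).
#' @param traj Trajectory `data.frame` (`t`, `x`, `y`, `hd`, `speed`).
#' @param dt Bin width, s.
#' @param speedMin Speed threshold, cm/s (5 for generic spatial analyses;
#'   sweep analyses typically re-filter at 15).
#' @param nCells Number of cells (defaults to `max(spikes$neuron)`).
#' @return A [SweepSession].
#' @export
binSession <- function(spikes, traj, dt = 0.01, speedMin = 5,
                       nCells = NULL) {
  if (nrow(spikes) == 0) warning("empty spike table; counts are all zero")
  if (is.null(nCells))
    nCells <- if (nrow(spikes)) max(spikes$neuron) else 0L
  n <- nrow(traj)
  edges <- c(traj$t, traj$t[n] + dt)
  keep <- spikes$t >= edges[1] & spikes$t < edges[n + 1]
  sp <- spikes[keep, , drop = FALSE]
  bin <- findInterval(sp$t, edges)
  counts <- matrix(0L, nCells, n)
  if (nrow(sp)) {
    tab <- table(factor(sp$neuron, levels = seq_len(nCells)),
                 factor(bin, levels = seq_len(n)))
    counts <- matrix(as.integer(tab), nCells, n)
  }
  cd <- DataFrame(t = traj$t, x = traj$x, y = traj$y, hd = traj$hd,
                  speed = traj$speed, valid = traj$speed > speedMin)
  se <- SummarizedExperiment(assays = list(counts = counts), colData = cd,
                             metadata = list(dt = dt, speedMin = speedMin))
  new("SweepSession", se)
}

# Sum of x grouped by integer bin index, over a fixed number of bins
# (rowsum() drops empty groups, so it cannot be used directly).
binSum <- function(x, idx, nBins) {
  s <- rowsum(as.numeric(x), idx)
  out <- numeric(nBins)
  out[as.integer(rownames(s))] <- s
  out
}

# Occupancy (s) and spike counts of one cell on a square spatial grid.
spatialBinStats <- function(session, cell, binSize, useValid = TRUE) {
  cd <- colData(session)
  sel <- if (useValid) cd$valid else rep(TRUE, ncol(session))
  x <- cd$x[sel]; y <- cd$y[sel]
  cnt <- spikeCounts(session)[cell, sel]
  dt <- binWidth(session)
  xr <- range(cd$x); yr <- range(cd$y)
  xb <- seq(floor(xr[1] / binSize) * binSize,
            ceiling(xr[2] / binSize) * binSize + binSize, by = binSize)
  yb <- seq(floor(yr[1] / binSize) * binSize,
            ceiling(yr[2] / binSize) * binSize + binSize, by = binSize)
  ix <- findInterval(x, xb, rightmost.closed = TRUE)
  iy <- findInterval(y, yb, rightmost.closed = TRUE)
  nx <- length(xb) - 1L; ny <- length(yb) - 1L
  idx <- (iy - 1L) * nx + ix
  occ <- matrix(tabulate(idx, nx * ny) * dt, nx, ny)
  spk <- matrix(binSum(cnt, idx, nx * ny), nx, ny)
  list(occ = occ, spk = spk,
       xBins = xb[-length(xb)] + binSize / 2,
       yBins = yb[-length(yb)] + binSize / 2,
       ix = ix, iy = iy, nx = nx, ny = ny)
}

#' Firing-rate map or angular tuning curve
#'
#' Spatial maps use square bins of `binSize` cm; angular curves use
#' `nAngleBins` evenly spaced bins of the supplied angle signal. With
#' `sigma = "auto"` the smoothing width is chosen by 10-fold cross-validation
#' (contiguous equal-duration folds): the width minimizing the mean squared
#' error between each fold's observed per-bin firing rate and the prediction
#' from the remaining folds, searched over (1, 50) cm or (0.01, 1) rad. A
#' numeric `sigma` is honoured exactly. Unvisited bins are `NA`.
#'
#' @param session A [SweepSession].
#' @param cell Cell index (row).
#' @param kind `"spatial"` or `"angular"`.
#' @param sigma `"auto"` or a fixed width (cm / rad).
#' @param binSize Spatial bin side, cm.
#' @param angle Angular signal per time bin (defaults to head direction).
#' @param nAngleBins Number of angular bins.
#' @param foldSeed Unused placeholder kept for reproducibility bookkeeping
#'   (folds are contiguous and deterministic).
#' @return A [TuningMap].
#' @export
rateMap <- function(session, cell, kind = c("spatial", "angular"),
                    sigma = "auto", binSize = 2.5, angle = NULL,
                    nAngleBins = 60, foldSeed = 1) {
  kind <- match.arg(kind)
  cd <- colData(session)
  dt <- binWidth(session)
  sel <- which(cd$valid)
  cnt <- spikeCounts(session)[cell, ]
  if (identical(sigma, "auto") && sum(cnt[sel]) < 100)
    stop("auto-smoothing needs >= 100 spikes")
  if (kind == "spatial") {
    st <- spatialBinStats(session, cell, binSize)
    buildRate <- function(useBins) {
      ii <- (st$iy[useBins] - 1L) * st$nx + st$ix[useBins]
      occ <- matrix(tabulate(ii, st$nx * st$ny) * dt, st$nx, st$ny)
      spk <- matrix(binSum(cnt[sel][useBins], ii, st$nx * st$ny),
                    st$nx, st$ny)
      r <- spk / occ
      r[occ == 0] <- NA
      r
    }
    if (identical(sigma, "auto")) {
      nsel <- length(sel)
      fold <- ceiling(seq_len(nsel) / (nsel / 10))
      cvErr <- function(sg) {
        sgBins <- sg / binSize
        err <- 0
        for (f in 1:10) {
          tr <- fold != f
          rtr <- gaussSmooth2(buildRate(tr), sgBins)
          te <- which(fold == f)
          pred <- rtr[cbind(st$ix[te], st$iy[te])]
          obs <- cnt[sel][te] / dt
          ok <- is.finite(pred)
          err <- err + sum((obs[ok] - pred[ok])^2)
        }
        err
      }
      sigma <- optimize(cvErr, interval = c(1, 50))$minimum
    }
    rate <- gaussSmooth2(buildRate(rep(TRUE, length(sel))), sigma / binSize)
    occAll <- st$occ
    rate[occAll == 0] <- NA
    new("TuningMap", kind = "spatial", rate = rate, occupancy = occAll,
        sigma = sigma, binSize = binSize, xBins = st$xBins, yBins = st$yBins)
  } else {
    if (is.null(angle)) angle <- cd$hd
    a <- wrapAngle(angle[sel])
    binw <- 2 * pi / nAngleBins
    ib <- pmin(floor((a + pi) / binw) + 1L, nAngleBins)
    buildCurve <- function(useBins) {
      occ <- tabulate(ib[useBins], nAngleBins) * dt
      spk <- binSum(cnt[sel][useBins], ib[useBins], nAngleBins)
      r <- spk / occ
      r[occ == 0] <- NA
      r
    }
    if (identical(sigma, "auto")) {
      nsel <- length(sel)
      fold <- ceiling(seq_len(nsel) / (nsel / 10))
      cvErr <- function(sg) {
        err <- 0
        for (f in 1:10) {
          rtr <- gaussSmooth(buildCurve(fold != f), sg / binw,
                             circular = TRUE)
          te <- which(fold == f)
          pred <- rtr[ib[te]]
          obs <- cnt[sel][te] / dt
          ok <- is.finite(pred)
          err <- err + sum((obs[ok] - pred[ok])^2)
        }
        err
      }
      sigma <- optimize(cvErr, interval = c(0.01, 1))$minimum
    }
    occ <- tabulate(ib, nAngleBins) * dt
    rate <- gaussSmooth(buildCurve(rep(TRUE, length(sel))), sigma / binw,
                        circular = TRUE)
    rate[occ == 0] <- NA
    new("TuningMap", kind = "angular", rate = rate, occupancy = occ,
        sigma = sigma, binSize = binw,
        xBins = seq(-pi + binw / 2, pi - binw / 2, by = binw), yBins = 0)
  }
}

#' Estimate theta phase from population activity
#'
#' Spike counts are bandpass-filtered in the theta band (2nd-order
#' Butterworth, zero phase), PCA is applied across neurons and the phase is
#' the angle of the population vector projected onto the PC1-PC2 plane,
#' calibrated so that the phase of minimal population firing is zero and
#' phase advances in time.
#'
#' @param session A [SweepSession].
#' @param band Theta band, Hz.
#' @return List with `phase` (in `[0, 2pi)`), `cycle`, `windows`, `dt`, and
#'   `reliable` (FALSE when the population spectrum has no peak in the
#'   band).
#' @export
extractThetaPhase <- function(session, band = c(5, 10)) {
  cnt <- spikeCounts(session)
  dt <- binWidth(session)
  fs <- 1 / dt
  filt <- t(apply(cnt, 1, bandpassFilter, low = band[1], high = band[2],
                  fs = fs, order = 2))
  pc <- prcomp(t(filt), center = TRUE, scale. = FALSE, rank. = 2)
  proj <- pc$x
  phase <- atan2(proj[, 2], proj[, 1])
  # orientation: make phase advance in time
  if (mean(wrapAngle(diff(phase))) < 0) phase <- -phase
  # calibration: phase of minimal population activity defined as zero
  pop <- colSums(cnt)
  nb <- 60
  ib <- pmin(floor((phase + pi) / (2 * pi / nb)) + 1L, nb)
  mr <- binSum(pop, ib, nb) / pmax(tabulate(ib, nb), 1)
  mrS <- gaussSmooth(mr, 2, circular = TRUE)
  phi0 <- (-pi + (which.min(mrS) - 0.5) * 2 * pi / nb)
  phase <- (phase - phi0) %% (2 * pi)
  # reliability: spectral peak of the population rate inside the band
  spec <- Mod(fft(pop - mean(pop)))^2
  freqs <- (seq_along(spec) - 1) * fs / length(spec)
  half <- freqs <= fs / 2
  inBand <- half & freqs >= band[1] & freqs <= band[2]
  outBand <- half & freqs > 0.5 & !inBand & freqs <= 25
  reliable <- mean(sort(spec[inBand], decreasing = TRUE)[1:5]) >
    3 * median(spec[outBand])
  if (!reliable) warning("no clear theta-band power; phase unreliable")
  cyc <- cumsum(c(1, diff(phase) < -pi))
  win <- data.frame(cycle = sort(unique(cyc)),
                    start = match(sort(unique(cyc)), cyc),
                    end = length(cyc) - match(sort(unique(cyc)), rev(cyc)) + 1)
  list(phase = phase, cycle = cyc, windows = win, dt = dt,
       reliable = reliable)
}

# Spike-time autocorrelogram (self-pairs removed implicitly by zeroing lag 0
# where stated by the index definition).
spikeACG <- function(spikeTimes, binMs = 1, windowMs = 50) {
  counts <- .ccgCounts(spikeTimes, spikeTimes, binMs / 1000, windowMs / 1000)
  lags <- seq(-windowMs, windowMs, by = binMs)
  counts[lags == 0] <- counts[lags == 0] - length(spikeTimes) # self pairs
  list(lags = lags, counts = as.numeric(counts))
}

#' Burst score
#'
#' From the +-50 ms, 1 ms-bin autocorrelogram (centre bin zeroed, counts
#' mean-normalized): mean over 2-10 ms lags minus mean over 13-50 ms lags.
#' Cells score > 0 are bursty, < -0.4 non-bursty, in between unclassified.
#'
#' @param spikeTimes Sorted spike times, s.
#' @return List with `score` and `class`; score is `NA` (flagged) when the
#'   autocorrelogram has fewer than 100 counts.
#' @export
burstScore <- function(spikeTimes) {
  acg <- spikeACG(spikeTimes, 1, 50)
  y <- acg$counts
  y[acg$lags == 0] <- 0
  if (sum(y) < 100) return(list(score = NA_real_, class = "undefined"))
  y <- y / mean(y)
  early <- abs(acg$lags) >= 2 & abs(acg$lags) <= 10
  late <- abs(acg$lags) >= 13 & abs(acg$lags) <= 50
  bs <- mean(y[early]) - mean(y[late])
  cls <- if (bs > 0) "bursty" else if (bs < -0.4) "non-bursty" else
    "unclassified"
  list(score = bs, class = cls)
}

#' Theta-cycle skipping index
#'
#' From the +-500 ms autocorrelogram (5 ms bins, Gaussian sigma = 10 ms
#' smoothing): `(p2 - p1) / max(p1, p2)` with `p1` the maximum over lags
#' 90-170 ms and `p2` over 180-300 ms. Positive TSI (second theta peak
#' higher than the first) indicates cycle skipping. Only meaningful for
#' theta-modulated cells; callers should gate on that classification.
#'
#' @param spikeTimes Sorted spike times, s.
#' @return TSI in `[-1, 1]`, or `NA` if the autocorrelogram is empty.
#' @export
thetaSkippingIndex <- function(spikeTimes) {
  acg <- spikeACG(spikeTimes, 5, 500)
  y <- acg$counts
  y[acg$lags == 0] <- 0
  if (sum(y) < 100) return(NA_real_)
  y <- gaussSmooth(y, 2) # 10 ms / 5 ms bins
  p1 <- max(y[acg$lags >= 90 & acg$lags <= 170])
  p2 <- max(y[acg$lags >= 180 & acg$lags <= 300])
  if (max(p1, p2) == 0) return(NA_real_)
  (p2 - p1) / max(p1, p2)
}

#' Classify direction-tuned cells
#'
#' A cell is direction-tuned when its 60-bin tuning curve with respect to
#' `angle` deviates from uniformity (Rayleigh P < 0.001) and is stable
#' across session halves (P < 0.01 for the Pearson correlation of the two
#' half-session curves). With `mvlMin > 0` (used for internal-direction
#' cells) the mean vector length must also exceed that threshold. Tuning
#' width is twice the circular SD of the tuning curve.
#'
#' @param session A [SweepSession].
#' @param angle Angular signal per time bin (default: head direction).
#' @param mvlMin Minimum mean vector length (0 disables).
#' @param sigma Fixed smoothing (rad) for the tuning curves.
#' @return `DataFrame` per cell: `isTuned`, `mvl`, `prefDir`, `widthDeg`,
#'   `rayleighP`, `stabilityP`.
#' @export
classifyDirectionCells <- function(session, angle = NULL, mvlMin = 0,
                                   sigma = 12 * pi / 180) {
  cd <- colData(session)
  if (is.null(angle)) angle <- cd$hd
  sel <- which(cd$valid)
  nb <- 60
  binw <- 2 * pi / nb
  a <- wrapAngle(angle[sel])
  ib <- pmin(floor((a + pi) / binw) + 1L, nb)
  if (length(unique(ib)) < nb)
    warning("not all angular bins sampled; unsampled cells skipped")
  occ <- tabulate(ib, nb) * binWidth(session)
  centers <- seq(-pi + binw / 2, pi - binw / 2, by = binw)
  half <- sel <= sel[ceiling(length(sel) / 2)]
  cnt <- spikeCounts(session)
  res <- lapply(seq_len(nrow(session)), function(i) {
    y <- cnt[i, sel]
    spk <- binSum(y, ib, nb)
    rate <- spk / occ
    rate[occ == 0] <- NA
    if (anyNA(rate) || sum(spk) < 50)
      return(DataFrame(isTuned = FALSE, mvl = NA_real_, prefDir = NA_real_,
                       widthDeg = NA_real_, rayleighP = NA_real_,
                       stabilityP = NA_real_))
    mvl <- circR(centers, rate)
    pref <- circMean(centers, rate)
    ray <- rayleighTest(centers, w = rate / sum(rate) * sum(spk))
    c1 <- vapply(1:nb, function(b)
      sum(y[half & ib == b]) / max(sum(half & ib == b), 1), 0)
    c2 <- vapply(1:nb, function(b)
      sum(y[!half & ib == b]) / max(sum(!half & ib == b), 1), 0)
    stab <- tryCatch(stats::cor.test(c1, c2)$p.value, error = function(e) 1)
    width <- 2 * sqrt(-2 * log(max(mvl, 1e-12))) * 180 / pi
    tuned <- ray$p.value < 0.001 && stab < 0.01 && mvl > mvlMin
    DataFrame(isTuned = tuned, mvl = mvl, prefDir = pref, widthDeg = width,
              rayleighP = ray$p.value, stabilityP = stab)
  })
  do.call(rbind, res)
}

#' Pearson cross-correlogram of two rate maps
#'
#' Correlation of map `a` (shifted by each lag) against map `b`, over
#' overlapping visited bins; the lag of the peak nearest the origin gives
#' the spatial offset of `b` relative to `a`.
#'
#' @param a,b Rate matrices of equal size (NA = unvisited).
#' @param maxLag Maximum lag per axis, bins.
#' @param minOverlap Minimum overlapping bins.
#' @return Square matrix of correlations, centre = zero lag.
#' @export
spatialCrosscorr <- function(a, b, maxLag = NULL, minOverlap = 20) {
  nx <- nrow(a); ny <- ncol(a)
  if (is.null(maxLag)) maxLag <- floor(min(nx, ny) / 2)
  lx <- -maxLag:maxLag
  out <- matrix(NA_real_, length(lx), length(lx))
  for (p in seq_along(lx)) for (q in seq_along(lx)) {
    dx <- lx[p]; dy <- lx[q]
    if (max(1, 1 + dx) > min(nx, nx + dx) ||
        max(1, 1 + dy) > min(ny, ny + dy)) next
    x1 <- max(1, 1 + dx):min(nx, nx + dx)
    y1 <- max(1, 1 + dy):min(ny, ny + dy)
    m1 <- a[x1 - dx, y1 - dy, drop = FALSE]
    m2 <- b[x1, y1, drop = FALSE]
    ok <- is.finite(m1) & is.finite(m2)
    if (sum(ok) < minOverlap) next
    v1 <- m1[ok]; v2 <- m2[ok]
    if (sd(v1) == 0 || sd(v2) == 0) next
    out[p, q] <- cor(v1, v2)
  }
  out
}

#' Spatial autocorrelogram of a rate map
#'
#' Pearson correlation of the map with itself at every 2D lag, computed over
#' the overlapping visited bins (NA-aware), as used for grid scoring and
#' module templates.
#'
#' @param m Rate matrix (NA = unvisited).
#' @param maxLag Maximum lag in bins per axis (default: full).
#' @param minOverlap Minimum overlapping bins to report a value.
#' @return Matrix of size (2*maxLag+1)^2 with the correlation at each lag.
#' @export
spatialAutocorr <- function(m, maxLag = NULL, minOverlap = 20) {
  nx <- nrow(m); ny <- ncol(m)
  if (is.null(maxLag)) maxLag <- max(nx, ny) - 1
  lx <- -maxLag:maxLag
  out <- matrix(NA_real_, length(lx), length(lx))
  for (a in seq_along(lx)) for (b in seq_along(lx)) {
    dx <- lx[a]; dy <- lx[b]
    if (max(1, 1 + dx) > min(nx, nx + dx) ||
        max(1, 1 + dy) > min(ny, ny + dy)) next
    x1 <- max(1, 1 + dx):min(nx, nx + dx)
    y1 <- max(1, 1 + dy):min(ny, ny + dy)
    m1 <- m[x1, y1, drop = FALSE]
    m2 <- m[x1 - dx, y1 - dy, drop = FALSE]
    ok <- is.finite(m1) & is.finite(m2)
    if (sum(ok) < minOverlap) next
    v1 <- m1[ok]; v2 <- m2[ok]
    if (sd(v1) == 0 || sd(v2) == 0) next
    out[a, b] <- cor(v1, v2)
  }
  out
}

# Bilinear rotation of a square autocorrelogram about its centre.
rotateMap <- function(m, angleRad) {
  n <- nrow(m)
  c0 <- (n + 1) / 2
  co <- cos(-angleRad); si <- sin(-angleRad)
  ix <- rep(seq_len(n), times = n) - c0
  iy <- rep(seq_len(n), each = n) - c0
  sx <- co * ix - si * iy + c0
  sy <- si * ix + co * iy + c0
  x0 <- floor(sx); y0 <- floor(sy)
  fx <- sx - x0; fy <- sy - y0
  val <- function(xx, yy) {
    out <- rep(NA_real_, length(xx))
    ok <- xx >= 1 & xx <= n & yy >= 1 & yy <= n
    out[ok] <- m[cbind(xx[ok], yy[ok])]
    out
  }
  v <- (1 - fx) * (1 - fy) * val(x0, y0) + fx * (1 - fy) * val(x0 + 1, y0) +
    (1 - fx) * fy * val(x0, y0 + 1) + fx * fy * val(x0 + 1, y0 + 1)
  matrix(v, n, n)
}

#' Grid score of a spatial autocorrelogram
#'
#' Standard rotational-symmetry score: the autocorrelogram is rotated by 30,
#' 60, 90, 120 and 150 degrees and correlated with itself on an annulus that
#' excludes the central peak; the score is the minimum correlation at 60/120
#' degrees minus the maximum at 30/90/150. The annulus outer radius is
#' scanned and the best score returned.
#'
#' @param acg Square autocorrelogram matrix (bins).
#' @return Score in `[-2, 2]`, `NA` for degenerate input.
#' @export
gridScore <- function(acg) {
  n <- nrow(acg)
  if (all(!is.finite(acg)) || sd(acg[is.finite(acg)]) == 0) return(NA_real_)
  c0 <- (n + 1) / 2
  d <- sqrt(outer((seq_len(n) - c0)^2, (seq_len(n) - c0)^2, `+`))
  # inner radius: first radius where the angular-mean profile drops below 0.2
  maxR <- floor(n / 2)
  prof <- vapply(seq_len(maxR), function(r)
    mean(acg[d >= r - 0.5 & d < r + 0.5], na.rm = TRUE), 0)
  rIn <- which(prof < 0.2)[1]
  if (is.na(rIn)) rIn <- max(2, round(maxR / 4))
  rots <- lapply(c(30, 60, 90, 120, 150) * pi / 180, rotateMap, m = acg)
  best <- NA_real_
  for (rOut in seq(min(rIn + 3, maxR), maxR, by = 2)) {
    ann <- d >= rIn & d <= rOut
    v0 <- acg[ann]
    cors <- vapply(rots, function(rm) {
      vr <- rm[ann]
      ok <- is.finite(v0) & is.finite(vr)
      if (sum(ok) < 20 || sd(v0[ok]) == 0 || sd(vr[ok]) == 0) return(NA_real_)
      cor(v0[ok], vr[ok])
    }, 0)
    if (anyNA(cors)) next
    sc <- min(cors[c(2, 4)]) - max(cors[c(1, 3, 5)])
    if (is.na(best) || sc > best) best <- sc
  }
  best
}

#' Identify grid modules by clustering spatial autocorrelograms
#'
#' Coarse (10 cm, unsmoothed) rate maps are autocorrelated, the
#' autocorrelograms (central two bins and corners beyond the map radius
#' masked) are vectorized, and a 30-nearest-neighbour graph on Manhattan
#' distances is clustered with the Leiden algorithm. Clusters qualify as grid
#' modules when the grid score of their median autocorrelogram exceeds 0.3,
#' the median member-to-mean correlation (consistency) exceeds 0.5 and they
#' hold at least `minCells` cells; clusters whose mean autocorrelograms
#' correlate above 0.7 are merged first.
#'
#' @param session A [SweepSession].
#' @param binSize Coarse bin size, cm.
#' @param k Neighbours in the graph.
#' @param resolution Leiden resolution parameter.
#' @param minCells Minimum module size.
#' @param seed Seed for the clustering.
#' @return `DataFrame` per cell with `module` (integer or NA) plus a
#'   `"modules"` attribute in `metadata`: per-module spacing (cm) and size.
#' @export
identifyGridModules <- function(session, binSize = 10, k = 30,
                                resolution = 1.0, minCells = 10, seed = 1) {
  nCell <- nrow(session)
  if (nCell < 30) stop("need >= 30 cells with spatial maps")
  acgs <- vector("list", nCell)
  for (i in seq_len(nCell)) {
    st <- spatialBinStats(session, i, binSize)
    r <- st$spk / st$occ
    r[st$occ == 0] <- NA
    acgs[[i]] <- spatialAutocorr(r)
  }
  n <- nrow(acgs[[1]])
  c0 <- (n + 1) / 2
  d <- sqrt(outer((seq_len(n) - c0)^2, (seq_len(n) - c0)^2, `+`))
  mask <- d > 2 & d <= floor(n / 2)
  vecs <- t(vapply(acgs, function(a) {
    v <- a[mask]
    v[!is.finite(v)] <- 0
    v
  }, numeric(sum(mask))))
  dm <- as.matrix(stats::dist(vecs, method = "manhattan"))
  kk <- min(k, nCell - 1)
  edges <- do.call(rbind, lapply(seq_len(nCell), function(i) {
    nb <- order(dm[i, ])[2:(kk + 1)]
    cbind(i, nb)
  }))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::simplify(g)
  set.seed(seed)
  cl <- igraph::cluster_leiden(g, objective_function = "modularity",
                               resolution = resolution)
  mem <- igraph::membership(cl)
  # cluster means, then merge highly correlated clusters
  ids <- sort(unique(mem))
  means <- lapply(ids, function(cid) colMeans(vecs[mem == cid, , drop = FALSE]))
  merged <- seq_along(ids)
  for (a in seq_along(ids)) for (b in seq_along(ids)) {
    if (a < b && cor(means[[a]], means[[b]]) > 0.7)
      merged[merged == merged[b]] <- merged[a]
  }
  mem <- merged[match(mem, ids)]
  ids <- sort(unique(mem))
  modules <- list()
  label <- rep(NA_integer_, nCell)
  modId <- 0L
  for (cid in ids) {
    members <- which(mem == cid)
    if (length(members) < minCells) next
    medAcg <- apply(simplify2array(lapply(members, function(i) {
      a <- acgs[[i]]; a[!is.finite(a)] <- 0; a
    })), c(1, 2), median)
    gs <- gridScore(medAcg)
    mAvg <- colMeans(vecs[members, , drop = FALSE])
    consistency <- median(vapply(members, function(i)
      suppressWarnings(cor(vecs[i, ], mAvg)), 0), na.rm = TRUE)
    if (is.na(gs) || gs <= 0.3 || consistency <= 0.5) next
    modId <- modId + 1L
    label[members] <- modId
    # spacing: median radial distance of the inner peak ring
    spacing <- acgRingRadius(medAcg) * binSize
    modules[[modId]] <- data.frame(module = modId, n = length(members),
                                   gridScore = gs,
                                   consistency = consistency,
                                   spacing = spacing)
  }
  out <- DataFrame(module = label)
  metadata(out)$modules <- if (length(modules)) do.call(rbind, modules)
    else data.frame()
  out
}

# Radius (bins) of the six-peak ring of an autocorrelogram: median distance
# of local maxima nearest the centre.
acgRingRadius <- function(acg) {
  n <- nrow(acg)
  c0 <- (n + 1) / 2
  pk <- which(vapply(seq_len(n * n), function(idx) {
    i <- (idx - 1) %% n + 1; j <- (idx - 1) %/% n + 1
    if (i < 2 || i > n - 1 || j < 2 || j > n - 1) return(FALSE)
    v <- acg[i, j]
    if (!is.finite(v)) return(FALSE)
    nb <- acg[(i - 1):(i + 1), (j - 1):(j + 1)]
    v >= max(nb, na.rm = TRUE) && v > 0.1
  }, TRUE))
  if (!length(pk)) return(NA_real_)
  pi_ <- (pk - 1) %% n + 1; pj <- (pk - 1) %/% n + 1
  dd <- sqrt((pi_ - c0)^2 + (pj - c0)^2)
  dd <- dd[dd > 1.5]
  if (!length(dd)) return(NA_real_)
  ring <- dd[dd <= min(dd) * 1.5]
  median(ring)
}

#' Classify sleep states from population activity
#'
#' Immobility periods (> 120 s below the speed threshold) are subclassified
#' by the theta/delta amplitude ratio of the summed population rate: delta
#' (1-4 Hz) and theta (5-10 Hz) envelopes via zero-phase 4th-order
#' Butterworth filters and the Hilbert transform, smoothed with a Gaussian
#' (sigma = 5 s). Ratios above `remMin` sustained for at least 20 s give
#' REM; below `swsMax`, SWS.
#'
#' @param session A [SweepSession].
#' @param speedMax Immobility threshold, cm/s.
#' @param remMin,swsMax Ratio thresholds.
#' @return `data.frame` of epochs: `state`, `tStart`, `tEnd` (s).
#' @export
classifySleepStates <- function(session, speedMax = 1, remMin = 5,
                                swsMax = 2) {
  cd <- colData(session)
  dt <- binWidth(session)
  n <- ncol(session)
  if (n * dt <= 120) return(data.frame(state = character(0),
                                       tStart = numeric(0),
                                       tEnd = numeric(0)))
  pop <- colSums(pmin(spikeCounts(session), 1L)) # binarized counts
  fs <- 1 / dt
  ampl <- function(lo, hi)
    gaussSmooth(hilbertAmplitude(bandpassFilter(pop, lo, hi, fs, order = 4)),
                5 / dt)
  thA <- ampl(5, 10)
  deA <- ampl(1, 4)
  ratio <- thA / pmax(deA, 1e-12)
  still <- cd$speed < speedMax
  runs <- rle(still)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  out <- list()
  for (ri in which(runs$values & runs$lengths * dt > 120)) {
    idx <- starts[ri]:ends[ri]
    for (st in c("REM", "SWS")) {
      flag <- if (st == "REM") ratio[idx] > remMin else ratio[idx] < swsMax
      rr <- rle(flag)
      ee <- cumsum(rr$lengths); ss <- ee - rr$lengths + 1
      for (q in which(rr$values & rr$lengths * dt >= 20)) {
        out[[length(out) + 1]] <- data.frame(
          state = st, tStart = cd$t[idx[ss[q]]], tEnd = cd$t[idx[ee[q]]])
      }
    }
  }
  if (!length(out)) return(data.frame(state = character(0),
                                      tStart = numeric(0),
                                      tEnd = numeric(0)))
  do.call(rbind, out)
}
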