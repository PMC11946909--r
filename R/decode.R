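# Population decoders: PV-correlation position/direction decoding, the
# lowpass reference trajectory, Bayesian inversion, single-module toroidal
# decoding and the unsupervised PCA direction readout.

# Stack spatial TuningMaps into an N x M rate matrix over bins visited in
# the session (non-NA in every map); returns the matrix plus bin centres.
stackMaps <- function(maps) {
  rates <- lapply(maps, function(m) as.numeric(m@rate))
  R <- do.call(rbind, rates)
  ok <- colSums(!is.finite(R)) == 0
  m1 <- maps[[1]]
  grid <- expand.grid(x = m1@xBins, y = m1@yBins)
  list(R = R[, ok, drop = FALSE], x = grid$x[ok], y = grid$y[ok],
       keep = ok, dims = dim(m1@rate))
}

# Column-standardize (z-score across cells); constant columns become 0.
zCols <- function(M) {
  mu <- colMeans(M)
  sdv <- sqrt(colMeans(M^2) - mu^2)
  sdv[sdv == 0] <- Inf
  sweep(sweep(M, 2, mu), 2, sdv, "/")
}

#' Decode position by population-vector correlation
#'
#' Instantaneous firing-rate population vectors (counts smoothed with a
#' sigma = 10 ms Gaussian) are Pearson-correlated with the mean-normalized
#' session-averaged population vector of every position bin; the decoded
#' position is the bin with the highest correlation, and the decoded
#' trajectory is smoothed with a sigma = 8 ms Gaussian. Bins are invalid when
#' fewer than `minActive` cells fired or when the peak correlation does not
#' exceed the 99th percentile of a cell-identity-shuffled correlation
#' distribution.
#'
#' @param session A [SweepSession].
#' @param maps List of spatial [TuningMap]s, one per cell (same grid).
#' @param cells Cell indices corresponding to `maps` (default: all).
#' @param shuffleN Shuffle draws for the validity criterion.
#' @param minActive Minimum active cells per bin.
#' @param seed Seed for the shuffle.
#' @return A [DecodedTrack] (confidence = peak correlation).
#' @export
pvDecodePosition <- function(session, maps, cells = seq_len(nrow(session)),
                             shuffleN = 100, minActive = 5, seed = 1) {
  if (length(maps) < 2) stop("need at least 2 cells to correlate")
  st <- stackMaps(maps)
  Rm <- st$R / pmax(rowMeans(st$R), 1e-9) # mean-normalize each tuning curve
  cnt <- spikeCounts(session)[cells, , drop = FALSE]
  dt <- binWidth(session)
  rates <- t(apply(cnt, 1, gaussSmooth, sigma = 1)) / dt # sigma = 10 ms
  Tn <- ncol(rates)
  Mz <- zCols(Rm) # each reference PV standardized across cells
  N <- nrow(Rm)
  dec <- integer(Tn); conf <- numeric(Tn)
  chunk <- 4000L
  for (s0 in seq(1L, Tn, by = chunk)) {
    s1 <- min(Tn, s0 + chunk - 1L)
    Rz <- zCols(rates[, s0:s1, drop = FALSE])
    cc <- crossprod(Rz, Mz) / N
    dec[s0:s1] <- max.col(cc, ties.method = "first")
    conf[s0:s1] <- cc[cbind(seq_len(nrow(cc)), dec[s0:s1])]
  }
  # shuffle criterion: permute cell identities of the map stack
  set.seed(seed)
  sub <- sort(sample(Tn, min(200L, Tn)))
  Rz <- zCols(rates[, sub, drop = FALSE])
  shufPeaks <- numeric(0)
  for (k in seq_len(shuffleN)) {
    Msh <- Mz[sample(N), , drop = FALSE]
    cc <- crossprod(Rz, Msh) / N
    shufPeaks <- c(shufPeaks, apply(cc, 1, max))
  }
  thr <- quantile(shufPeaks, 0.99, names = FALSE)
  active <- colSums(cnt > 0)
  valid <- conf > thr & active >= minActive
  xs <- gaussSmooth(st$x[dec], 0.8) # sigma = 8 ms on the 10 ms clock
  ys <- gaussSmooth(st$y[dec], 0.8)
  dat <- DataFrame(t = colData(session)$t, x = xs, y = ys,
                   rawX = st$x[dec], rawY = st$y[dec],
                   confidence = conf, valid = valid)
  new("DecodedTrack", data = dat, lowpass = DataFrame(), kind = "pv-position")
}

#' Lowpass-filtered decoded reference trajectory
#'
#' Spike counts from the first half of each theta cycle, smoothed with a
#' wide Gaussian (sigma = `sigmaCycles` theta cycles), are PV-decoded to give
#' the slowly evolving trajectory from which each sweep originates; the
#' result is smoothed with a sigma = 10 ms kernel.
#'
#' @param session A [SweepSession].
#' @param maps Spatial maps as in [pvDecodePosition()].
#' @param theta Theta signal (list with `phase`, `cycle`).
#' @param cells Cell indices corresponding to `maps`.
#' @param sigmaCycles Kernel width in theta cycles.
#' @return `DataFrame` with per-bin `x`, `y`.
#' @export
lowpassReference <- function(session, maps, theta,
                             cells = seq_len(nrow(session)),
                             sigmaCycles = 1.7) {
  st <- stackMaps(maps)
  Rm <- st$R / pmax(rowMeans(st$R), 1e-9)
  cnt <- spikeCounts(session)[cells, , drop = FALSE]
  dt <- binWidth(session)
  firstHalf <- theta$phase < pi
  cycLen <- mean(tabulate(factor(theta$cycle)))
  sg <- sigmaCycles * cycLen
  masked <- sweep(cnt, 2, as.numeric(firstHalf), "*")
  sm <- t(apply(masked, 1, gaussSmooth, sigma = sg))
  wgt <- gaussSmooth(as.numeric(firstHalf), sg)
  rates <- sweep(sm, 2, pmax(wgt, 1e-9), "/") / dt
  Mz <- zCols(Rm)
  N <- nrow(Rm)
  Tn <- ncol(rates)
  dec <- integer(Tn)
  chunk <- 4000L
  for (s0 in seq(1L, Tn, by = chunk)) {
    s1 <- min(Tn, s0 + chunk - 1L)
    Rz <- zCols(rates[, s0:s1, drop = FALSE])
    cc <- crossprod(Rz, Mz) / N
    dec[s0:s1] <- max.col(cc, ties.method = "first")
  }
  DataFrame(x = gaussSmooth(st$x[dec], 1), y = gaussSmooth(st$y[dec], 1))
}

#' Decode internal direction by population-vector correlation
#'
#' Angular tuning curves take the place of spatial maps; for each theta
#' cycle the time bin of maximal population activity is read out, and the
#' decoded direction is the circular mean of all angular bins weighted by
#' their PV-correlation values at that time bin.
#'
#' @param session A [SweepSession].
#' @param dirMaps List of angular [TuningMap]s (one per direction cell).
#' @param theta Theta signal.
#' @param cells Row indices of the direction cells.
#' @return `DataFrame` per cycle: `cycle`, `t`, `bin`, `alpha` (allocentric,
#'   rad), `hcAlpha` (head-centred) and `conf` (peak correlation).
#' @export
pvDecodeDirection <- function(session, dirMaps, theta,
                              cells = seq_len(nrow(session))) {
  R <- do.call(rbind, lapply(dirMaps, function(m) as.numeric(m@rate)))
  R[!is.finite(R)] <- 0
  Rm <- R / pmax(rowMeans(R), 1e-9)
  angles <- dirMaps[[1]]@xBins
  cnt <- spikeCounts(session)[cells, , drop = FALSE]
  dt <- binWidth(session)
  rates <- t(apply(cnt, 1, gaussSmooth, sigma = 1)) / dt
  Mz <- zCols(Rm)
  N <- nrow(Rm)
  cc <- crossprod(zCols(rates), Mz) / N # T x 60
  pop <- gaussSmooth(colSums(cnt), 1)
  cd <- colData(session)
  out <- lapply(theta$windows$cycle, function(cy) {
    w <- theta$windows[theta$windows$cycle == cy, ]
    idx <- w$start:w$end
    if (sum(cnt[, idx]) == 0) return(NULL)
    peak <- idx[which.max(pop[idx])]
    r <- cc[peak, ]
    alpha <- circMean(angles, w = r)
    DataFrame(cycle = cy, t = cd$t[peak], bin = peak, alpha = alpha,
              hcAlpha = wrapAngle(alpha - cd$hd[peak]),
              conf = max(r))
  })
  do.call(rbind, out[!vapply(out, is.null, TRUE)])
}

#' Bayesian position decoding
#'
#' Poisson likelihood with a flat prior over position bins:
#' \deqn{P(x | y) \propto \exp\left(\sum_i y_i \log f_i(x) -
#'   \Delta t \sum_i f_i(x)\right)}
#' Tuning curves are floored at `floorRate` Hz to avoid log(0). The MAP
#' estimate is the argmax bin (earliest-index on ties, with a tie flag).
#'
#' @param session A [SweepSession].
#' @param maps Spatial maps (list of [TuningMap]).
#' @param cells Cell indices corresponding to `maps`.
#' @param floorRate Rate floor, Hz.
#' @param smoothSigmaMs Gaussian smoothing of the spike counts before
#'   decoding, ms (10 matches the PV decoder's firing-rate input; 0 decodes
#'   raw counts).
#' @param returnPosterior Keep the full normalized posterior? (memory-heavy;
#'   only honoured for sessions up to 5000 bins).
#' @return A [DecodedTrack]; if requested, `metadata`-style attribute
#'   `posterior` (bins x positions) attached to the `lowpass` slot is
#'   replaced by a list entry in the returned object's `data` metadata.
#' @export
bayesDecode <- function(session, maps, cells = seq_len(nrow(session)),
                        floorRate = 0.01, smoothSigmaMs = 10,
                        returnPosterior = FALSE) {
  st <- stackMaps(maps)
  zeroRow <- rowSums(st$R) == 0
  if (any(zeroRow)) {
    warning(sum(zeroRow), " all-zero tuning rows excluded")
    st$R <- st$R[!zeroRow, , drop = FALSE]
    cells <- cells[!zeroRow]
  }
  f <- pmax(st$R, floorRate)
  lf <- log(f)
  sf <- colSums(f)
  cnt <- spikeCounts(session)[cells, , drop = FALSE]
  dt <- binWidth(session)
  if (smoothSigmaMs > 0) {
    sg <- smoothSigmaMs / 1000 / dt
    cnt <- t(apply(cnt, 1, gaussSmooth, sigma = sg))
  }
  Tn <- ncol(cnt)
  dec <- integer(Tn); conf <- numeric(Tn); tied <- logical(Tn)
  post <- NULL
  keepPost <- returnPosterior && Tn <= 5000
  if (keepPost) post <- matrix(NA_real_, Tn, ncol(f))
  chunk <- 4000L
  for (s0 in seq(1L, Tn, by = chunk)) {
    s1 <- min(Tn, s0 + chunk - 1L)
    lp <- crossprod(cnt[, s0:s1, drop = FALSE], lf) -
      matrix(dt * sf, s1 - s0 + 1L, ncol(f), byrow = TRUE)
    mx <- apply(lp, 1, max)
    p <- exp(lp - mx)
    p <- p / rowSums(p)
    ii <- max.col(p, ties.method = "first")
    dec[s0:s1] <- ii
    conf[s0:s1] <- p[cbind(seq_len(nrow(p)), ii)]
    tied[s0:s1] <- abs(apply(p, 1, max) -
                         apply(p, 1, function(z) sort(z, decreasing = TRUE)[2])) < 1e-12
    if (keepPost) post[s0:s1, ] <- p
  }
  dat <- DataFrame(t = colData(session)$t, x = st$x[dec], y = st$y[dec],
                   confidence = conf, valid = rep(TRUE, Tn), tied = tied)
  out <- new("DecodedTrack", data = dat, lowpass = DataFrame(),
             kind = "bayes-position")
  if (keepPost) attr(out, "posterior") <- list(p = post, x = st$x, y = st$y)
  out
}

#' Single-module toroidal decoding
#'
#' The PV-correlation map of a single grid module is cross-correlated with
#' the module's template grid pattern (the mean spatial autocorrelogram of
#' its cells); the cross-correlogram peak nearest the origin is the decoded
#' position, expressed as a phase in the unit tile spanned by the two
#' shortest lattice vectors of the template (positions wrap around the grid
#' axes).
#'
#' @param session A [SweepSession].
#' @param maps Spatial maps of the module cells.
#' @param cells Module cell indices.
#' @param template Mean autocorrelogram matrix (same bin size as maps); if
#'   `NULL` it is computed from the maps.
#' @return `DataFrame` per bin: `u`, `v` (lattice phase in [0,1)), `dx`,
#'   `dy` (cm displacement of the nearest peak) and `conf`.
#' @export
decodeSingleModule <- function(session, maps, cells = seq_len(nrow(session)),
                               template = NULL) {
  if (length(maps) < 2) stop("need a module of maps")
  if (is.null(template)) {
    acgs <- lapply(maps, function(m) {
      a <- spatialAutocorr(m@rate)
      a[!is.finite(a)] <- 0
      a
    })
    template <- apply(simplify2array(acgs), c(1, 2), mean)
  }
  binSize <- maps[[1]]@binSize
  lat <- latticeVectors(template, binSize)
  if (is.null(lat)) stop("template has no hexagonal peak ring")
  # trim the template to the central peak plus the first ring: the far
  # lattice orders add no alignment information on an arena-sized map but
  # dominate the edge artefacts of the cross-correlation
  ntt <- nrow(template)
  ct <- (ntt + 1) / 2
  halfT <- min(ct - 1, ceiling(1.35 * lat$spacing / binSize))
  template <- template[(ct - halfT):(ct + halfT),
                       (ct - halfT):(ct + halfT)]
  st <- stackMaps(maps)
  Rm <- st$R / pmax(rowMeans(st$R), 1e-9)
  cnt <- spikeCounts(session)[cells, , drop = FALSE]
  dt <- binWidth(session)
  rates <- t(apply(cnt, 1, gaussSmooth, sigma = 1)) / dt
  Mz <- zCols(Rm)
  N <- nrow(Rm)
  cc <- crossprod(zCols(rates), Mz) / N
  nx <- st$dims[1]; ny <- st$dims[2]
  tc <- template - mean(template)
  nt <- nrow(tc)
  c0 <- (nt + 1) / 2
  Tn <- nrow(cc)
  out <- matrix(NA_real_, Tn, 5)
  full <- matrix(0, nx, ny)
  for (tt in seq_len(Tn)) {
    full[st$keep] <- cc[tt, ]
    xc <- xcorr2(full, tc)
    pk <- localMaxima2(xc)
    if (!nrow(pk)) next
    # displacement of each peak from the map centre, in bins
    dxs <- pk[, 1] - (nx + 1) / 2
    dys <- pk[, 2] - (ny + 1) / 2
    j <- which.min(dxs^2 + dys^2)
    d <- c(dxs[j], dys[j]) * binSize
    uv <- solve(lat$A, d)
    out[tt, ] <- c(uv[1] %% 1, uv[2] %% 1, d[1], d[2], xc[pk[j, 1], pk[j, 2]])
  }
  DataFrame(u = out[, 1], v = out[, 2], dx = out[, 3], dy = out[, 4],
            conf = out[, 5], t = colData(session)$t)
}

# Two shortest lattice vectors (cm-free, in bins) from a template
# autocorrelogram's inner peak ring; NULL when no ring is found.
latticeVectors <- function(template, binSize = 1) {
  n <- nrow(template)
  c0 <- (n + 1) / 2
  pks <- localMaxima2(template)
  if (!nrow(pks)) return(NULL)
  d <- cbind(pks[, 1] - c0, pks[, 2] - c0)
  r <- sqrt(rowSums(d^2))
  keep <- r > 1.5
  d <- d[keep, , drop = FALSE]; r <- r[keep]
  if (!nrow(d)) return(NULL)
  ring <- r <= min(r) * 1.4
  d <- d[ring, , drop = FALSE]
  if (nrow(d) < 2) return(NULL)
  ang <- atan2(d[, 2], d[, 1])
  i1 <- which.min(abs(wrapAngle(ang)))
  rest <- which(abs(wrapAngle(ang - ang[i1])) > pi / 6)
  if (!length(rest)) return(NULL)
  i2 <- rest[which.min(abs(wrapAngle(ang[rest] - ang[i1] - pi / 3)))]
  A <- cbind(d[i1, ], d[i2, ]) * binSize
  list(A = A, spacing = mean(sqrt(colSums(A^2))))
}

# Plain (unnormalized) 2D cross-correlation of a field with a centred,
# zero-mean template; 'same' size output.
xcorr2 <- function(field, tmpl) {
  nx <- nrow(field); ny <- ncol(field)
  nt <- nrow(tmpl)
  half <- (nt - 1) %/% 2
  px <- nx + nt - 1; py <- ny + nt - 1
  F1 <- matrix(0, px, py); F1[1:nx, 1:ny] <- field
  T1 <- matrix(0, px, py); T1[1:nt, 1:nt] <- tmpl[nt:1, nt:1]
  out <- Re(fft(fft(F1) * fft(T1), inverse = TRUE)) / (px * py)
  out[(half + 1):(half + nx), (half + 1):(half + ny)]
}

# Local maxima of a matrix (8-neighbourhood), returned as index pairs.
localMaxima2 <- function(m, thresh = -Inf) {
  nx <- nrow(m); ny <- ncol(m)
  res <- NULL
  for (i in 2:(nx - 1)) for (j in 2:(ny - 1)) {
    v <- m[i, j]
    if (!is.finite(v) || v <= thresh) next
    nb <- m[(i - 1):(i + 1), (j - 1):(j + 1)]
    if (v >= max(nb, na.rm = TRUE)) res <- rbind(res, c(i, j))
  }
  if (is.null(res)) matrix(numeric(0), 0, 2) else res
}

#' Unsupervised PCA decoding of internal direction
#'
#' Spike counts of rhythmic direction cells are binned per theta cycle (to
#' keep global within-cycle rate fluctuations from dominating), PCA is
#' applied across cells, and the internal direction is the angle in the
#' PC1-PC2 plane, aligned to the environment by removing the mean offset
#' from head direction (internal and head direction are assumed to share
#' their mean).
#'
#' @param session A [SweepSession].
#' @param cells Indices of rhythmic direction-tuned cells (>= 20 advised).
#' @param theta Theta signal.
#' @return `DataFrame` per cycle: `cycle`, `angle` (aligned, rad), `hd`
#'   (cycle head direction), plus `varFrac` (PC1+PC2 explained variance) in
#'   `metadata`.
#' @export
pcaDirectionDecode <- function(session, cells, theta) {
  cnt <- spikeCounts(session)[cells, , drop = FALSE]
  cyc <- theta$cycle
  X <- t(rowsum(t(cnt), cyc)) # cells x cycles (columns in sorted cycle order)
  cycIds <- sort(unique(cyc))
  lens <- tabulate(factor(cyc, levels = cycIds))
  X <- sweep(X, 2, pmax(lens, 1), "/")
  pc <- prcomp(t(X), center = TRUE, scale. = FALSE)
  varFrac <- sum(pc$sdev[1:2]^2) / sum(pc$sdev^2)
  raw <- atan2(pc$x[, 2], pc$x[, 1])
  cd <- colData(session)
  hd0 <- cd$hd[theta$windows$start]
  # the PCA plane has an arbitrary rotation and possibly mirrored chirality
  off1 <- circMean(wrapAngle(raw - hd0))
  r1 <- circR(wrapAngle(raw - hd0))
  off2 <- circMean(wrapAngle(-raw - hd0))
  r2 <- circR(wrapAngle(-raw - hd0))
  aligned <- if (r1 >= r2) wrapAngle(raw - off1) else wrapAngle(-raw - off2)
  out <- DataFrame(cycle = theta$windows$cycle, angle = aligned, hd = hd0)
  metadata(out)$varFrac <- varFrac
  out
}
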