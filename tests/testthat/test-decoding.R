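# Small hand-built maps for exact decoder identities.
tinyMaps <- function(nCells = 8, nx = 6, ny = 6, seed = 50) {
  set.seed(seed)
  lapply(seq_len(nCells), function(i) {
    r <- matrix(runif(nx * ny, 0.5, 10), nx, ny)
    new("TuningMap", kind = "spatial", rate = r,
        occupancy = matrix(1, nx, ny), sigma = 0, binSize = 2.5,
        xBins = (seq_len(nx) - 3.5) * 2.5, yBins = (seq_len(ny) - 3.5) * 2.5)
  })
}

tinySession <- function(counts, dt = 0.01) {
  n <- ncol(counts)
  cd <- DataFrame(t = (seq_len(n) - 1) * dt, x = 0, y = 0, hd = 0,
                  speed = 20, valid = TRUE)
  se <- SummarizedExperiment(assays = list(counts = counts), colData = cd,
                             metadata = list(dt = dt))
  new("SweepSession", se)
}

test_that("a population vector equal to a reference PV decodes that bin", {
  maps <- tinyMaps()
  st <- thetasweeps:::stackMaps(maps)
  target <- 13
  rpv <- st$R[, target] / pmax(rowMeans(st$R), 1e-9)
  counts <- matrix(rep(round(rpv * 40), 60), nrow = 8)
  dec <- pvDecodePosition(tinySession(counts), maps, seed = 1)
  mid <- 20:40 # away from smoothing edge effects
  expect_true(all(dec@data$rawX[mid] == st$x[target]))
  expect_true(all(dec@data$rawY[mid] == st$y[target]))
  expect_gt(min(dec@data$confidence[mid]), 0.95)
})

test_that("bins with fewer than five active cells are invalid", {
  maps <- tinyMaps()
  counts <- matrix(0L, 8, 60)
  counts[1:4, ] <- 3L # only four active cells everywhere
  dec <- pvDecodePosition(tinySession(counts), maps, seed = 1)
  expect_false(any(dec@data$valid))
})

test_that("position decoding recovers the trajectory without sweeps", {
  fx <- gridOnlySession(duration = 45, nCells = 200, seed = 102)
  maps <- spatialMapsFor(fx$session)
  dec <- pvDecodePosition(fx$session, maps, seed = 2)
  v <- dec@data$valid
  expect_gt(mean(v), 0.5)
  err <- sqrt((dec@data$x - fx$traj$x)^2 + (dec@data$y - fx$traj$y)^2)
  expect_lte(median(err[v]), 5)
  # lowpass reference also tracks the trajectory
  lp <- lowpassReference(fx$session, maps, fx$theta)
  errLp <- sqrt((lp$x - fx$traj$x)^2 + (lp$y - fx$traj$y)^2)
  expect_lte(median(errLp), 5)
  # Bayesian decoding agrees (cross-decoder checks live in the acceptance
  # suite at full scale)
  bd <- bayesDecode(fx$session, maps)
  errB <- sqrt((bd@data$x - fx$traj$x)^2 + (bd@data$y - fx$traj$y)^2)
  expect_lte(median(errB[v]), 6)
})

test_that("label-shuffled data rarely passes the validity criterion", {
  fx <- gridOnlySession(duration = 45, nCells = 200, seed = 102)
  maps <- spatialMapsFor(fx$session)
  shuf <- fx$session
  set.seed(3)
  SummarizedExperiment::assay(shuf, "counts") <-
    spikeCounts(fx$session)[sample(200), ]
  dec <- pvDecodePosition(shuf, maps, seed = 4)
  expect_lte(mean(dec@data$valid), 0.015)
})

test_that("Bayesian posteriors are normalized and localize one-hot input", {
  # uniform maps: flat posterior, earliest-bin MAP with tie flag
  uni <- lapply(1:6, function(i)
    new("TuningMap", kind = "spatial", rate = matrix(2, 4, 4),
        occupancy = matrix(1, 4, 4), sigma = 0, binSize = 2.5,
        xBins = 1:4, yBins = 1:4))
  counts <- matrix(1L, 6, 20)
  bd <- bayesDecode(tinySession(counts), uni, smoothSigmaMs = 0,
                    returnPosterior = TRUE)
  post <- attr(bd, "posterior")$p
  expect_equal(rowSums(post), rep(1, 20), tolerance = 1e-9)
  expect_true(all(bd@data$tied))
  expect_equal(bd@data$x[1], 1) # earliest-index bin on ties
  # single cell, one-hot map, one spike: mass concentrates on that bin
  hot <- matrix(0.01, 4, 4); hot[2, 3] <- 60
  oneHot <- list(new("TuningMap", kind = "spatial", rate = hot,
                     occupancy = matrix(1, 4, 4), sigma = 0, binSize = 2.5,
                     xBins = 1:4, yBins = 1:4),
                 uni[[1]])
  counts2 <- matrix(0L, 2, 10); counts2[1, ] <- 1L
  bd2 <- bayesDecode(tinySession(counts2), oneHot, smoothSigmaMs = 0,
                     returnPosterior = TRUE)
  post2 <- attr(bd2, "posterior")$p
  expect_gt(min(post2[, (3 - 1) * 4 + 2]), 0.9) # bin (2, 3), column-major
  expect_equal(bd2@data$x[1], 2)
  expect_equal(bd2@data$y[1], 3)
})

test_that("decoding is equivariant under a 90-degree rotation", {
  fx <- gridOnlySession(duration = 30, nCells = 120, arena = 100,
                        seed = 103)
  maps <- spatialMapsFor(fx$session)
  dec <- pvDecodePosition(fx$session, maps, seed = 5)
  # rotate the world: (x, y) -> (-y, x); rebuild maps from rotated data
  rot <- fx$session
  cd <- colData(rot)
  old <- list(x = cd$x, y = cd$y)
  cd$x <- -old$y
  cd$y <- old$x
  colData(rot) <- cd
  mapsR <- spatialMapsFor(rot)
  decR <- pvDecodePosition(rot, mapsR, seed = 5)
  # raw argmax positions rotate with the data (identical binning because the
  # trajectory ranges are not symmetric, so allow one bin of slack)
  expect_lt(median(abs(decR@data$rawX - (-dec@data$rawY))), 2.6)
  expect_lt(median(abs(decR@data$rawY - dec@data$rawX)), 2.6)
})

test_that("per-cycle internal direction is decoded from direction cells", {
  ses <- quietSession(duration = 60, nGrid = 0, nDir = 60, arenaSize = 150,
                      alternating = TRUE, seed = 104)
  theta <- metadata(ses)$theta
  lat <- metadata(ses)$latent
  dirMaps <- lapply(1:60, function(i)
    rateMap(ses, i, "angular", sigma = 12 * pi / 180,
            angle = lat$internalDir))
  dt <- pvDecodeDirection(ses, dirMaps, theta)
  trueDir <- wrapAngle(colData(ses)$hd[theta$windows$start] +
                         lat$side * pi / 6)
  err <- abs(wrapAngle(dt$alpha -
                         trueDir[match(dt$cycle, theta$windows$cycle)]))
  expect_lte(median(err) * 180 / pi, 10)
  # head-centred modes near +-30 degrees
  cm <- conditionalModes(dt$hcAlpha)
  expect_equal(sort(abs(c(cm$modeAfterLeft, cm$modeAfterRight))) * 180 / pi,
               c(30, 30), tolerance = 0.2)
})

test_that("single-module decoding lives on the torus and tracks position", {
  tr <- generateTrajectory(45, "rect", c(150, 150), seed = 105)
  th <- generateTheta(45, 8, seed = 106)
  set.seed(107)
  orient <- 0.2
  cells <- lapply(1:80, function(i)
    gridCellModel(50, orientation = orient, phaseOffset = runif(2, 0, 50),
                  amplitude = exp(rnorm(1, log(35), 0.3))))
  sim <- simulateSpikes(tr, th, NULL, cells, seed = 108)
  ses <- binSession(sim$spikes, tr, nCells = 80)
  maps <- spatialMapsFor(ses)
  dm <- decodeSingleModule(ses, maps)
  expect_true(all(dm$u >= 0 & dm$u < 1, na.rm = TRUE))
  expect_true(all(dm$v >= 0 & dm$v < 1, na.rm = TRUE))
  a1 <- 50 * c(cos(orient), sin(orient))
  a2 <- 50 * c(cos(orient + pi / 3), sin(orient + pi / 3))
  uvT <- solve(cbind(a1, a2), rbind(colData(ses)$x, colData(ses)$y)) %% 1
  expect_gt(circCorr(2 * pi * dm$u, 2 * pi * uvT[1, ]), 0.5)
  expect_gt(circCorr(2 * pi * dm$v, 2 * pi * uvT[2, ]), 0.5)
  # periodicity: displacing a decoded point by a full lattice vector leaves
  # its phase unchanged
  d0 <- c(dm$dx[100], dm$dy[100])
  A <- cbind(a1, a2)
  expect_equal(unname(solve(A, d0) %% 1),
               unname(as.numeric(solve(A, d0 + A %*% c(1, 0)))) %% 1,
               tolerance = 1e-9)
})

test_that("PCA direction readout recovers the internal-direction ring", {
  ses <- quietSession(duration = 90, nGrid = 0, nDir = 70, arenaSize = 150,
                      alternating = TRUE, seed = 109)
  theta <- metadata(ses)$theta
  lat <- metadata(ses)$latent
  pd <- pcaDirectionDecode(ses, 1:70, theta)
  idt <- wrapAngle(colData(ses)$hd[theta$windows$start] + lat$side * pi / 6)
  expect_gt(circCorr(pd$angle, idt), 0.8)
  # mean offset from head direction removed by the alignment step
  hd0 <- colData(ses)$hd[theta$windows$start]
  expect_lt(abs(circMean(wrapAngle(pd$angle - hd0))), 0.2)
})
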