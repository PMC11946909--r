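test_that("binning conserves spikes and applies the speed filter", {
  tr <- generateTrajectory(30, seed = 21)
  spikes <- data.frame(neuron = rep(1:3, each = 50),
                       t = runif(150, 0, 29.9))
  ses <- binSession(spikes, tr, speedMin = 5)
  expect_equal(sum(spikeCounts(ses)), 150)
  expect_equal(unname(rowSums(spikeCounts(ses))), rep(50, 3))
  # stationary animal: every bin fails the speed filter
  still <- data.frame(t = tr$t, x = 0, y = 0, hd = 0, speed = 0)
  ses2 <- binSession(spikes, still, speedMin = 5)
  expect_false(any(colData(ses2)$valid))
  expect_warning(binSession(spikes[0, ], tr, nCells = 2), "empty")
})

test_that("rate maps honour fixed smoothing and conserve spike mass", {
  fx <- gridOnlySession(duration = 30, nCells = 2, seed = 22)
  m <- rateMap(fx$session, 1, "spatial", sigma = 7.5)
  expect_s4_class(m, "TuningMap")
  expect_equal(m@sigma, 7.5)
  # unsmoothed map integral x occupancy returns the spike count exactly
  m0 <- rateMap(fx$session, 1, "spatial", sigma = 0)
  tot <- sum(m0@rate * m0@occupancy, na.rm = TRUE)
  expect_equal(tot,
               sum(spikeCounts(fx$session)[1, colData(fx$session)$valid]),
               tolerance = 1e-9)
  # unvisited bins stay NA, never zero
  expect_true(anyNA(m0@rate) || all(m0@occupancy > 0))
})

test_that("cross-validated smoothing adapts to sampling density", {
  # a sharp place field, densely vs sparsely sampled
  tr <- generateTrajectory(240, "rect", c(60, 60), seed = 23)
  th <- generateTheta(240, 8, seed = 24)
  cell <- placeCellModel(center = c(5, -5), sigma = 4, amplitude = 150,
                         phaseKappa = 0)
  sim <- simulateSpikes(tr, th, NULL, list(cell), seed = 25)
  dense <- binSession(sim$spikes, tr)
  sparse <- binSession(sim$spikes[seq(1, nrow(sim$spikes), by = 5), ], tr,
                       nCells = 1)
  sDense <- rateMap(dense, 1, "spatial", sigma = "auto")@sigma
  sSparse <- rateMap(sparse, 1, "spatial", sigma = "auto")@sigma
  expect_lt(sDense, sSparse)
  expect_error(rateMap(sparse, 1, "angular", sigma = "auto",
                       angle = rep(0.3, ncol(sparse))), NA)
})

test_that("population theta phase is recovered and calibrated", {
  tr <- generateTrajectory(40, "rect", c(100, 100), seed = 26)
  th <- generateTheta(40, 8, jitter = 0, seed = 27)
  set.seed(28)
  cells <- lapply(1:80, function(i)
    directionCellModel(mu = 0, kappa = 0, amplitude = 100, phaseKappa = 2,
                       phaseMu = pi + rnorm(1, 0, 0.8)))
  sim <- simulateSpikes(tr, th, NULL, cells, seed = 29)
  ses <- binSession(sim$spikes, tr)
  ph <- extractThetaPhase(ses)
  expect_true(ph$reliable)
  expect_gt(circCorr(ph$phase, th$phase), 0.95)
  # calibration: minimal population rate sits at phase ~ 0
  pop <- colSums(spikeCounts(ses))
  nb <- 60
  ib <- pmin(floor(ph$phase / (2 * pi / nb)) + 1L, nb)
  mr <- tapply(pop, ib, mean)
  minPhase <- (as.numeric(names(which.min(mr))) - 0.5) * 2 * pi / nb
  expect_lt(abs(wrapAngle(minPhase)), 0.35)
})

test_that("burst score separates doublet firing from Poisson trains", {
  pois <- poissonTrain(8, 600, seed = 30)
  bsP <- burstScore(pois)
  expect_lt(abs(bsP$score), 0.15)
  set.seed(31)
  doublet <- sort(c(pois, pois[runif(length(pois)) < 0.5] + 0.005))
  bsD <- burstScore(doublet)
  expect_gt(bsD$score, 0)
  expect_equal(bsD$class, "bursty")
  expect_true(is.na(burstScore(c(1, 2, 3))$score))
})

test_that("theta-skipping index detects alternate-cycle firing", {
  set.seed(32)
  skip <- sort(unlist(lapply(seq(0, 600, by = 0.25),
                             function(t0) t0 + rnorm(3, 0, 0.01))))
  nonskip <- sort(unlist(lapply(seq(0, 600, by = 0.125),
                                function(t0) t0 + rnorm(2, 0, 0.01))))
  tsiS <- thetaSkippingIndex(skip)
  tsiN <- thetaSkippingIndex(nonskip)
  expect_gt(tsiS, 0.2)
  expect_lt(abs(tsiN), 0.2)
  expect_true(tsiS >= -1 && tsiS <= 1)
})

test_that("direction-cell classification recovers von Mises tuning width", {
  tr <- generateTrajectory(120, seed = 33)
  th <- generateTheta(120, 8, seed = 34)
  cells <- list(directionCellModel(mu = 1, kappa = 6, amplitude = 40),
                directionCellModel(mu = 0, kappa = 0, amplitude = 10,
                                   phaseKappa = 0)) # untuned control
  sim <- simulateSpikes(tr, th, NULL, cells, seed = 35)
  ses <- binSession(sim$spikes, tr, nCells = 2)
  lab <- classifyDirectionCells(ses)
  expect_true(lab$isTuned[1])
  expect_false(lab$isTuned[2])
  expect_equal(lab$prefDir[1], 1, tolerance = 0.15)
  # analytic 2-SD width of a von Mises with kappa = 6
  R <- besselI(6, 1) / besselI(6, 0)
  width <- 2 * sqrt(-2 * log(R)) * 180 / pi
  expect_equal(lab$widthDeg[1], width, tolerance = 0.15)
})

test_that("grid score is high for hexagonal and ~0 for radial symmetry", {
  gm <- gridCellModel(spacing = 50, amplitude = 10, phaseKappa = 0)
  gx <- seq(-60, 60, by = 2.5)
  hex <- outer(gx, gx, function(a, b) modelRate(gm, a, b))
  expect_gt(gridScore(spatialAutocorr(hex, maxLag = 40)), 1)
  radial <- outer(gx, gx, function(a, b)
    exp(-((sqrt(a^2 + b^2) - 30)^2) / 50))
  expect_lt(abs(gridScore(spatialAutocorr(radial, maxLag = 40))), 0.3)
  expect_true(is.na(gridScore(matrix(1, 21, 21))))
})

test_that("grid modules are recovered and small clusters rejected", {
  tr <- generateTrajectory(180, "rect", c(150, 150), seed = 36)
  th <- generateTheta(180, 8, seed = 37)
  set.seed(38)
  cells <- c(
    lapply(1:40, function(i) gridCellModel(50, orientation = 0.2,
      phaseOffset = runif(2, 0, 50),
      amplitude = exp(rnorm(1, log(30), 0.3)))),
    lapply(1:40, function(i) gridCellModel(75, orientation = 0.9,
      phaseOffset = runif(2, 0, 75),
      amplitude = exp(rnorm(1, log(30), 0.3)))),
    lapply(1:40, function(i) directionCellModel(mu = runif(1, -pi, pi))))
  sim <- simulateSpikes(tr, th, NULL, cells, seed = 39)
  ses <- binSession(sim$spikes, tr, nCells = 120)
  mod <- identifyGridModules(ses, seed = 40)
  truth <- rep(c(1, 2, NA), each = 40)
  agree <- mapply(function(a, b) identical(is.na(a), is.na(b)),
                  mod$module, truth)
  # membership accuracy across the 120 cells
  tab <- table(mod$module[1:80], truth[1:80])
  acc <- sum(apply(tab, 2, max)) / 80
  expect_gte(acc, 0.95)
  expect_true(all(is.na(mod$module[81:120])))
  info <- metadata(mod)$modules
  expect_equal(nrow(info), 2)
  expect_equal(sort(info$spacing), c(50, 75), tolerance = 0.12)
  # a would-be module of 9 cells fails the minimum-size criterion
  sub <- c(1:9, 41:80, 81:120)
  mod9 <- identifyGridModules(ses[sub, ], minCells = 10, seed = 41)
  expect_true(all(is.na(mod9$module[1:9])))
})

test_that("sleep staging separates REM-like and SWS-like immobility", {
  dt <- 0.01; n <- 40000
  set.seed(42)
  tt <- (seq_len(n) - 1) * dt
  rate <- numeric(n)
  rate[tt < 150] <- 20 * (1 + 0.9 * sin(2 * pi * 8 * tt[tt < 150]))
  rate[tt >= 150] <- 20 * (1 + 0.9 * sin(2 * pi * 2 * tt[tt >= 150]))
  cnt <- rpois(n * 30, rep(rate, each = 30) / 30)
  cntM <- matrix(cnt, 30, n)
  spikes <- do.call(rbind, lapply(1:30, function(i) {
    b <- which(cntM[i, ] > 0)
    data.frame(neuron = i,
               t = rep(tt[b], cntM[i, b]) + runif(sum(cntM[i, b]), 0, dt))
  }))
  traj <- data.frame(t = tt, x = 0, y = 0, hd = 0, speed = 0.1)
  ses <- binSession(spikes[order(spikes$t), ], traj, nCells = 30)
  ep <- classifySleepStates(ses)
  rem <- ep[ep$state == "REM", ]
  sws <- ep[ep$state == "SWS", ]
  expect_gte(nrow(rem), 1)
  expect_gte(nrow(sws), 1)
  expect_lt(rem$tStart[1], 150)
  expect_gt(sum(sws$tEnd - sws$tStart), 100)
  expect_true(all(sws$tStart > 140))
  # sessions shorter than the immobility requirement yield no epochs
  shortSes <- ses[, 1:10000]
  metadata(shortSes)$dt <- dt
  expect_equal(nrow(classifySleepStates(shortSes)), 0)
})
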