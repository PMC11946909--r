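test_that("open-field trajectory covers the arena and respects its walls", {
  tr <- generateTrajectory(600, "rect", c(150, 150), seed = 1)
  expect_true(all(abs(tr$x) < 75 & abs(tr$y) < 75))
  expect_equal(diff(tr$t), rep(0.01, nrow(tr) - 1))
  ix <- floor((tr$x + 75) / 2.5)
  iy <- floor((tr$y + 75) / 2.5)
  coverage <- length(unique(ix * 1000 + iy)) / 3600
  expect_gte(coverage, 0.8)
})

test_that("linear-track trajectories shuttle in one dimension", {
  tr <- generateTrajectory(10, "linear", 200, seed = 2)
  expect_true(all(tr$y == 0))
  expect_true(all(tr$x >= 0 & tr$x <= 200))
})

test_that("degenerate trajectory inputs are rejected", {
  expect_error(generateTrajectory(5), "duration")
  expect_error(generateTrajectory(60, size = c(0, 100)), "degenerate")
})

test_that("theta generator produces the requested cycle structure", {
  th <- generateTheta(1, 8, jitter = 0)
  lens <- th$windows$end - th$windows$start + 1
  expect_equal(nrow(th$windows), 8)
  expect_true(all(lens %in% c(12, 13)))
  # phase advances 2 pi per 125 ms at 8 Hz
  expect_equal(th$phase[13] - th$phase[1], 2 * pi * 0.12 / 0.125,
               tolerance = 1e-6)
  expect_error(generateTheta(10, freq = 3), "theta band")
})

test_that("latent sweeps alternate sides by construction", {
  tr <- generateTrajectory(30, seed = 3)
  th <- generateTheta(30, 8, seed = 4)
  lat <- generateLatentSweeps(tr, th, alternating = TRUE, seed = 5)
  expect_true(all(abs(diff(lat$side)) == 2))
  # internal direction sits offsetDeg off the cycle-start heading
  hd0 <- tr$hd[th$windows$start]
  off <- wrapAngle(lat$internalDir[th$windows$start] - hd0)
  expect_equal(abs(off), rep(pi / 6, length(off)), tolerance = 1e-9)
  expect_error(generateLatentSweeps(tr[1:10, ], th), "time bases")
})

test_that("non-alternating sides follow the iid-coin triplet oracle", {
  tr <- generateTrajectory(240, seed = 6)
  th <- generateTheta(240, 8, seed = 7)
  lat <- generateLatentSweeps(tr, th, alternating = FALSE, seed = 8)
  s <- lat$side
  n <- length(s)
  trip <- sapply(1:(n - 2), function(i)
    s[i] != s[i + 1] && s[i + 1] != s[i + 2])
  # LRL / RLR each have probability 1/8 under a fair coin -> 1/4 total
  phat <- mean(trip)
  tol <- 4 * sqrt(0.25 * 0.75 / length(trip)) # ~4 binomial SEs (overlap)
  expect_equal(phat, 0.25, tolerance = tol / 0.25)
})

test_that("grid tuning is invariant under its lattice translations", {
  gm <- gridCellModel(spacing = 75, orientation = 0.4, phaseKappa = 0)
  a1 <- 75 * c(cos(0.4), sin(0.4))
  x <- runif(50, -50, 50); y <- runif(50, -50, 50)
  expect_equal(modelRate(gm, x + a1[1], y + a1[2]),
               modelRate(gm, x, y), tolerance = 1e-6)
  expect_true(all(modelRate(gm, x, y) >= 0))
})

test_that("Poisson spiking matches its analytic rate and variance", {
  tr <- generateTrajectory(1000, seed = 9)
  th <- generateTheta(1000, 8, seed = 10)
  # constant-rate cell: no direction or phase tuning
  const <- directionCellModel(mu = 0, kappa = 0, amplitude = 12,
                              phaseKappa = 0)
  zero <- directionCellModel(mu = 0, kappa = 6, amplitude = 0)
  sim <- simulateSpikes(tr, th, NULL, list(const, zero), seed = 11)
  counts <- sim$counts[1, ]
  expect_gte(length(counts), 1e5)
  expect_equal(var(counts) / mean(counts), 1, tolerance = 0.1)
  se <- sqrt(12 * 0.01 / length(counts)) / 0.01
  expect_lt(abs(mean(counts) / 0.01 - 12), 3 * se)
  expect_equal(sum(sim$counts[2, ]), 0)
})

test_that("session CSV export round-trips through binSession", {
  ses <- quietSession(duration = 20, nGrid = 20, nDir = 10, arenaSize = 80,
                      seed = 12)
  dir <- file.path(tempdir(), "ts-session")
  writeSessionCSV(ses, dir)
  sp <- read.csv(file.path(dir, "spikes.csv"))
  tr <- read.csv(file.path(dir, "trajectory.csv"))
  tr$speed <- c(0, sqrt(diff(tr$x)^2 + diff(tr$y)^2) / diff(tr$t))
  ses2 <- binSession(sp, tr, nCells = nrow(ses))
  expect_equal(unname(spikeCounts(ses2)), unname(spikeCounts(ses)))
})
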