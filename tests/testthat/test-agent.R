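test_that("footprint geometry follows 1/d^2 and the von Mises ratio", {
  kappa <- 5
  along1 <- footprintValue(1, 0, 0, kappa)
  along2 <- footprintValue(2, 0, 0, kappa)
  expect_equal(along2 / along1, 1 / 4)
  fwd <- footprintValue(3, 0, 0, kappa)
  bwd <- footprintValue(-3, 0, 0, kappa)
  expect_equal(fwd / bwd, exp(2 * kappa), tolerance = 1e-9)
  f <- sweepFootprint(41, c(21, 21), 0.7, kappa)
  expect_equal(f[21, 21], 0) # origin cell masked
  expect_true(all(f >= 0))
})

test_that("an empty trace ties all directions; one footprint repels", {
  tr <- coverageTrace(n = 41)
  set.seed(120)
  ch <- chooseDirection(tr, c(21, 21))
  expect_true(ch$tie)
  expect_lt(diff(range(ch$overlap)), 1e-12)
  # a single previous footprint from the same spot pushes the choice to
  # within 90 degrees of the opposite direction
  tr2 <- addSweep(tr, c(21, 21), 0.5)
  ch2 <- chooseDirection(tr2, c(21, 21))
  expect_lt(abs(wrapAngle(ch2$alpha - (0.5 + pi))), pi / 2)
  # two symmetric footprints at +-30 deg: the minimum lies on the symmetry
  # axis (0 or 180 deg)
  tr3 <- addSweep(addSweep(tr, c(21, 21), pi / 6), c(21, 21), -pi / 6)
  ch3 <- chooseDirection(tr3, c(21, 21))
  axial <- min(abs(wrapAngle(ch3$alpha)), abs(wrapAngle(ch3$alpha - pi)))
  expect_lt(axial, 3 * pi / 180)
})

test_that("direction choice matches a 0.1-degree brute-force oracle", {
  bruteArgmin <- function(trace, pos, kappa = 5, dmin = 1.5, rsub = 12,
                          k = 5) {
    h <- trace@h
    angles <- seq(0, 2 * pi - 1e-9, by = 0.1 * pi / 180)
    ov <- numeric(length(angles))
    for (j in seq_len(ncol(h))) for (i in seq_len(nrow(h))) {
      hx <- h[i, j]
      if (hx == 0) next
      dx <- i - pos[1]; dy <- j - pos[2]
      d2 <- dx^2 + dy^2
      if (d2 < dmin^2) next
      if (d2 <= rsub^2) {
        for (a in 1:k) for (b in 1:k) {
          sx <- dx + (a - 0.5) / k - 0.5
          sy <- dy + (b - 0.5) / k - 0.5
          sd2 <- sx^2 + sy^2
          if (sd2 < 1e-12) next
          ov <- ov + (hx / k^2) *
            exp(kappa * cos(atan2(sy, sx) - angles)) / sd2
        }
      } else {
        ov <- ov + hx * exp(kappa * cos(atan2(dy, dx) - angles)) / d2
      }
    }
    angles[which.min(ov)]
  }
  set.seed(121)
  for (rep in 1:5) {
    tr <- coverageTrace(n = 41)
    for (q in 1:3) tr <- addSweep(tr, runif(2, 12, 30), runif(1, 0, 2 * pi))
    pos <- runif(2, 15, 27)
    got <- chooseDirection(tr, pos)$alpha
    want <- bruteArgmin(tr, pos)
    expect_lt(abs(wrapAngle(got - want)), 1.2 * pi / 180)
  }
})

test_that("trace decay follows tau^dt with the documented half-life", {
  tr <- addSweep(coverageTrace(n = 31, tau = 0.04), c(16, 16), 1)
  h0 <- sum(tr@h)
  halfLife <- log(0.5) / log(0.04)
  expect_equal(halfLife, 0.215, tolerance = 0.002)
  expect_equal(sum(decayTrace(tr, halfLife)@h), h0 / 2, tolerance = 1e-9)
  # tau = 1: no decay
  tr1 <- addSweep(coverageTrace(n = 31, tau = 1), c(16, 16), 1)
  expect_equal(decayTrace(tr1, 10)@h, tr1@h)
})

test_that("with fast decay only the latest sweep matters", {
  old <- c(10, 16); new <- c(22, 16)
  trBoth <- addSweep(coverageTrace(n = 31, tau = 0.04), old, 0.3)
  trBoth <- decayTrace(trBoth, 20) # ~ 64 half-lives: old sweep vanishes
  trBoth <- addSweep(trBoth, new, 2.1)
  trOne <- addSweep(coverageTrace(n = 31, tau = 0.04), new, 2.1)
  set.seed(122)
  a1 <- chooseDirection(trBoth, c(16, 16))$alpha
  set.seed(122)
  a2 <- chooseDirection(trOne, c(16, 16))$alpha
  expect_equal(a1, a2)
})

test_that("linear runs are reproducible and alternation builds up early", {
  r1 <- runLinearAgent(12, seed = 5)
  r2 <- runLinearAgent(12, seed = 5)
  expect_identical(r1@directions, r2@directions)
  expect_equal(length(agentScores(r1)), 12)
  # mean score over seeds increases across the first windows
  sc <- sapply(1:120, function(s) runLinearAgent(7, seed = 300 + s)@scores)
  m <- rowMeans(sc, na.rm = TRUE)[2:6]
  expect_true(all(diff(m) > 0))
})

test_that("multimodule rules share or separate directions as specified", {
  runs <- runMultiModuleAgent(nSteps = 18, rule = "common", seed = 6)
  expect_equal(runs[[1]]@directions, runs[[2]]@directions)
  expect_equal(runs[[2]]@directions, runs[[3]]@directions)
  for (rule in c("common", "parallel", "serial")) {
    rr <- runMultiModuleAgent(nSteps = 22, rule = rule, seed = 7)
    sc <- vapply(rr, function(r) mean(agentScores(r), na.rm = TRUE), 0)
    expect_true(all(sc > 0.40)) # above the iid chance score
  }
})

test_that("self-driven trajectory agent alternates more at higher speed", {
  tr <- generateTrajectory(90, "rect", c(150, 150), seed = 123)
  th <- generateTheta(90, 8, seed = 124)
  cycT <- (th$windows$start - 1) * 0.01
  run <- runAgentOnTrajectory(tr, cycT, mode = "self", tau = 0.04,
                              seed = 125)
  expect_equal(length(agentDirections(run)), length(cycT))
  sc <- agentScores(run)
  spd <- approx(tr$t, tr$speed, cycT, rule = 2)$y
  lohi <- split(sc, spd > median(spd))
  expect_gt(mean(lohi$`TRUE`, na.rm = TRUE),
            mean(lohi$`FALSE`, na.rm = TRUE))
})
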