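test_that("head-centred transform maps heading onto +x and inverts", {
  expect_equal(unname(toHeadCentred(c(10, 0), c(0, 0), 0)),
               matrix(c(10, 0), 1))
  # heading 90 deg: allocentric (0, 10) is dead ahead -> (10, 0)
  expect_equal(unname(toHeadCentred(c(0, 10), c(0, 0), pi / 2)),
               matrix(c(10, 0), 1), tolerance = 1e-12)
  set.seed(60)
  for (i in 1:20) {
    p <- matrix(runif(10, -50, 50), ncol = 2)
    ref <- runif(2, -20, 20); hd <- runif(1, -pi, pi)
    back <- fromHeadCentred(toHeadCentred(p, ref, hd), ref, hd)
    expect_lt(max(abs(back - p)), 1e-9)
  }
})

test_that("alternation score matches its closed form", {
  # equal magnitude, opposite sign -> 1; equal changes -> 0
  expect_equal(alternationScore(c(30, -30, 30) * pi / 180)[2], 1)
  expect_equal(alternationScore(c(10, 20, 30) * pi / 180)[2], 0)
  # a = 10 deg, b = -30 deg -> 40/60
  s <- alternationScore(c(0, 10, -20) * pi / 180)[2]
  expect_equal(s, 40 / 60, tolerance = 1e-12)
  expect_true(is.na(alternationScore(c(1, 1, 1))[2]))
  expect_equal(sum(!is.finite(alternationScore(runif(10)))), 2)
})

test_that("triplet alternation fraction matches exhaustive enumeration", {
  bruteFrac <- function(v) {
    d <- wrapAngle(diff(v))
    n <- length(v)
    hits <- 0; tot <- 0
    for (i in 1:(n - 2)) {
      a <- d[i]; b <- d[i + 1]
      if (a == 0 || b == 0) next
      tot <- tot + 1
      if (sign(a) != sign(b)) hits <- hits + 1
    }
    hits / tot
  }
  set.seed(61)
  for (i in 1:25) {
    v <- runif(sample(5:8, 1), -pi, pi)
    expect_equal(alternationFraction(v, shuffleN = 10, seed = 1)$fraction,
                 bruteFrac(v))
  }
  # strict alternation scores 1
  alt <- rep(c(0.5, -0.5), 10)
  expect_equal(alternationFraction(alt, shuffleN = 50, seed = 1)$fraction, 1)
})

test_that("iid direction chance rates: 1/2 uniform, 2/3 concentrated", {
  # wrapped differences of iid UNIFORM angles are independent, so sign
  # inversions occur at rate exactly 1/2; for concentrated (bimodal)
  # directions wrapping is immaterial and the linear iid rate 2/3 applies
  set.seed(62)
  v <- runif(4000, -pi, pi)
  af <- alternationFraction(v, shuffleN = 200, seed = 2)
  expect_equal(af$fraction, 1 / 2, tolerance = 0.05)
  expect_equal(af$shuffleMean, 1 / 2, tolerance = 0.05)
  conc <- sample(c(-1, 1), 4000, replace = TRUE) * pi / 6 +
    rnorm(4000, 0, 0.05)
  af2 <- alternationFraction(conc, shuffleN = 200, seed = 3)
  expect_equal(af2$fraction, 2 / 3, tolerance = 0.05)
  expect_error(alternationFraction(rep(1, 20)), "constant")
})

test_that("direction autocorrelogram reflects alternation structure", {
  set.seed(63)
  alt <- rep(c(0.5, -0.5), 40) + rnorm(80, 0, 0.05)
  ac <- directionAutocorrelogram(alt)
  expect_equal(ac$r[ac$lag == 0], 1)
  odd <- ac$r[ac$lag %in% c(-3, -1, 1, 3)]
  even <- ac$r[ac$lag %in% c(-4, -2, 2, 4)]
  expect_true(all(odd < 0))
  expect_true(all(even > 0))
  iid <- runif(400, -pi, pi)
  aci <- directionAutocorrelogram(iid)
  expect_true(all(abs(aci$r[aci$lag != 0]) < 3 / sqrt(400)))
})

test_that("conditional modes recover injected offsets within 5 degrees", {
  set.seed(64)
  for (offset in c(10, 25, 45)) {
    side <- rep(c(1, -1), 150)
    dirs <- side * offset * pi / 180 + rnorm(300, 0, 6 * pi / 180)
    cm <- conditionalModes(dirs)
    got <- sort(c(cm$modeAfterLeft, cm$modeAfterRight) * 180 / pi)
    expect_lt(max(abs(got - c(-offset, offset))), 5)
  }
  # mirror symmetry under left-right reflection
  dirs <- rep(c(1, -1), 100) * 0.5 + rnorm(200, 0, 0.1)
  cm1 <- conditionalModes(dirs)
  cm2 <- conditionalModes(-dirs)
  expect_equal(cm1$modeAfterLeft, -cm2$modeAfterRight, tolerance = 1e-9)
})

test_that("sweeps are extracted from a constructed decoded track", {
  # two theta cycles; a clean 6-point outward sweep in the first, only 3
  # valid bins in the second
  n <- 26
  cd <- DataFrame(t = (seq_len(n) - 1) * 0.01, x = 0, y = 0, hd = 0,
                  speed = 25, valid = TRUE)
  counts <- matrix(1L, 2, n)
  se <- SummarizedExperiment(assays = list(counts = counts), colData = cd,
                             metadata = list(dt = 0.01))
  ses <- new("SweepSession", se)
  theta <- list(cycle = rep(1:2, each = 13),
                windows = data.frame(cycle = 1:2, start = c(1, 14),
                                     end = c(13, 26)))
  valid <- c(rep(TRUE, 6), rep(FALSE, 7), rep(TRUE, 3), rep(FALSE, 10))
  px <- numeric(n); py <- numeric(n)
  px[1:6] <- seq(2, 22, by = 4) # collinear along +x, 4 cm steps
  px[14:16] <- seq(2, 10, by = 4)
  dec <- new("DecodedTrack",
             data = DataFrame(t = cd$t, x = px, y = py, confidence = 1,
                              valid = valid),
             lowpass = DataFrame(), kind = "test")
  lowpass <- DataFrame(x = rep(0, n), y = rep(0, n))
  sw <- extractSweeps(dec, theta, lowpass, ses, speedMin = 15)
  expect_equal(length(sw), 1) # the 3-point candidate is rejected
  tab <- sweepTable(sw)
  expect_equal(tab$cycle, 1L)
  expect_equal(tab$r2, 1)
  expect_equal(tab$dir, 0)
  expect_equal(tab$length, 22)
  expect_equal(tab$n, 6L)
})

test_that("session-averaged sweeps are mirror symmetric", {
  set.seed(65)
  mkSweep <- function(side) {
    u <- seq(0, 1, length.out = 8)
    ang <- side * pi / 6
    cbind(x = 25 * u * cos(ang) + rnorm(8, 0, 0.5),
          y = 25 * u * sin(ang) + rnorm(8, 0, 0.5))
  }
  sides <- rep(c(1L, -1L), 30)
  pts <- lapply(sides, mkSweep)
  tab <- DataFrame(cycle = seq_along(sides), tStart = seq_along(sides) * 0.125,
                   dir = sides * pi / 6, hcDir = sides * pi / 6,
                   length = 25, r2 = 1, side = sides, n = 8L,
                   hd = 0, ox = 0, oy = 0)
  sw <- new("SweepSet", table = tab, points = pts)
  avg <- sessionAverageSweeps(sw)
  expect_equal(dim(avg$postLeft), c(50, 2))
  # post-left sweeps are the right-going ones and vice versa
  expect_lt(max(abs(avg$postLeft[, 2] + avg$postRight[, 2])), 2)
  expect_lt(abs(mean(avg$postLeft[, 2]) + 25 * 0.5 * sin(pi / 6)), 2)
  one <- new("SweepSet", table = tab[sides == 1, ],
             points = pts[sides == 1])
  expect_warning(sessionAverageSweeps(one), "one-sided")
})

test_that("region delay recovers a constructed temporal shift", {
  fx <- gridOnlySession(duration = 30, nCells = 5, seed = 66)
  n <- ncol(fx$session)
  set.seed(67)
  proj <- cumsum(rnorm(n, 0, 1))
  mk <- function(shift) {
    x <- fx$traj$x + c(rep(proj[1], shift), head(proj, n - shift)) *
      cos(fx$traj$hd)
    y <- fx$traj$y + c(rep(proj[1], shift), head(proj, n - shift)) *
      sin(fx$traj$hd)
    new("DecodedTrack",
        data = DataFrame(t = fx$traj$t, x = x, y = y, confidence = 1,
                         valid = TRUE),
        lowpass = DataFrame(), kind = "test")
  }
  expect_equal(regionDelay(mk(0), mk(0), fx$session), 0)
  expect_equal(regionDelay(mk(0), mk(2), fx$session), 20)
})

test_that("sweep-driven grid cells phase precess", {
  ses <- quietSession(duration = 150, nGrid = 1, nDir = 0, arenaSize = 120,
                      seed = 68)
  th <- metadata(ses)$theta
  lat <- metadata(ses)$latent
  m <- rateMap(ses, 1, "spatial", sigma = 7.5)
  pk <- thetasweeps:::localMaxima2(m@rate)
  keep <- is.finite(m@rate[pk]) &
    m@rate[pk] > 0.5 * max(m@rate[pk], na.rm = TRUE)
  verts <- cbind(m@xBins[pk[, 1]], m@yBins[pk[, 2]])[keep, , drop = FALSE]
  pp <- phasePrecession(ses, 1, verts, lat$internalDir, th$phase)
  expect_lt(pp$rho, 0)
  expect_lt(pp$p.value, 0.01)
  expect_true(pp$precessing)
})

test_that("sleep alternation is detected at activity peaks in REM only", {
  dt <- 0.01; n <- 20000
  set.seed(69)
  th <- generateTheta(200, 8, seed = 70)
  vhd <- cumsum(rnorm(n, 0, 0.01))
  pos <- data.frame(x = cumsum(rnorm(n, 0, 0.5)),
                    y = cumsum(rnorm(n, 0, 0.5)))
  mkDir <- function(sides) {
    sb <- sides[match(th$cycle, th$windows$cycle)]
    vhd + sb * pi / 6 + rnorm(n, 0, 0.1)
  }
  popREM <- 20 * (1 + 0.8 * cos(th$phase - pi))
  alt <- rep(c(1, -1), length.out = nrow(th$windows))
  rem <- sleepSweeps(pos, mkDir(alt), rpois(n, popREM * dt) + popREM * dt,
                     dt = dt, spacing = 75, seed = 71)
  expect_gt(rem$fraction, rem$shuffle99)
  iid <- sample(c(1, -1), nrow(th$windows), replace = TRUE)
  popSWS <- 20 * (1 + 0.8 * rep(rbinom(n / 50, 1, 0.3), each = 50))
  sws <- sleepSweeps(pos, mkDir(iid), rpois(n, popSWS * dt) + popSWS * dt,
                     dt = dt, spacing = 75, seed = 72)
  expect_lt(sws$fraction, sws$shuffle99)
  expect_equal(sws$fraction, sws$shuffleMean, tolerance = 0.1)
})

test_that("chance alternation score sits near 0.40", {
  expect_equal(chanceAlternationScore(2e5, seed = 4), 0.4, tolerance = 0.01)
})
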