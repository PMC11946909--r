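test_that("CCGs are lag-antisymmetric between pair orderings", {
  a <- poissonTrain(6, 500, seed = 80)
  b <- poissonTrain(6, 500, seed = 81)
  ab <- computeCCG(a, b)
  ba <- computeCCG(b, a)
  expect_equal(ab$counts, rev(ba$counts))
  # identical trains: dominant zero-lag peak
  aa <- computeCCG(a, a)
  expect_equal(aa$lags[which.max(aa$counts)], 0)
})

test_that("independent Poisson pairs give a flat corrected CCG", {
  a <- poissonTrain(8, 600, seed = 82)
  b <- poissonTrain(8, 600, seed = 83)
  cc <- computeCCG(a, b)
  expect_true(cc$eligible)
  se <- sd(cc$corrected) / sqrt(length(cc$corrected))
  expect_lt(abs(mean(cc$corrected)), 4 * se + 0.5)
  expect_null(detectConnection(cc))
  # baseline subtraction conserves counts up to kernel edge effects
  expect_lt(abs(sum(cc$corrected)) / sum(cc$counts), 0.01)
  # eligibility gates on spike and count totals
  expect_false(computeCCG(a[1:100], b)$eligible)
})

test_that("a planted 2 ms connection is detected at the right lag", {
  set.seed(84)
  pre <- poissonTrain(5, 600, seed = 85)
  relay <- pre[runif(length(pre)) < 0.1] + 0.002
  post <- sort(c(poissonTrain(5, 600, seed = 86), relay))
  conn <- detectConnection(computeCCG(pre, post))
  expect_false(is.null(conn))
  expect_equal(conn$lag, 2)
  expect_gt(conn$z, 5)
  # detection is invariant to a global time shift of both trains
  conn2 <- detectConnection(computeCCG(pre + 5, post + 5))
  expect_equal(conn2$lag, conn$lag)
  expect_equal(conn2$z, conn$z, tolerance = 1e-9)
  # a synchronous (zero-lag) peak is rejected as common input
  relay0 <- pre[runif(length(pre)) < 0.1] + 0.0001
  post0 <- sort(c(poissonTrain(5, 600, seed = 87), relay0))
  expect_null(detectConnection(computeCCG(pre, post0)))
})

test_that("rate-map cross-correlation reads out spatial offsets", {
  gm <- gridCellModel(spacing = 50, amplitude = 10, phaseKappa = 0)
  gx <- seq(-48.75, 48.75, by = 2.5)
  mk <- function(dx) {
    r <- outer(gx, gx, function(a, b) modelRate(gm, a - dx, b))
    new("TuningMap", kind = "spatial", rate = r,
        occupancy = matrix(1, length(gx), length(gx)), sigma = 0,
        binSize = 2.5, xBins = gx, yBins = gx)
  }
  same <- pairTuningAlignment(mk(0), mk(0), spacing = 50)
  expect_equal(same$offsetMag, 0)
  sh <- pairTuningAlignment(mk(0), mk(10), spacing = 50)
  expect_equal(unname(sh$offsetXY), c(10, 0), tolerance = 1e-9)
  expect_equal(sh$offsetFrac, 0.2, tolerance = 1e-9)
})

test_that("class-pair connection rates count planted connections", {
  labels <- rep(c("id", "conj"), each = 10)
  tested <- expand.grid(pre = 1:10, post = 11:20)
  none <- connectionRates(data.frame(pre = integer(0), post = integer(0)),
                          tested, labels)
  expect_true(all(none$rate == 0))
  conns <- data.frame(pre = c(1, 2), post = c(11, 12))
  cr <- connectionRates(conns, tested, labels)
  expect_equal(cr$rate[cr$pair == "id->conj"], 2 / 100)
  expect_equal(cr$nPairs[cr$pair == "id->conj"], 100)
})
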