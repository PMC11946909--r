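# Shared fixture builders. Sessions are deliberately small; statistical
# assertions use tolerances derived from their sampling noise.

suppressPackageStartupMessages({
  library(SummarizedExperiment)
  library(S4Vectors)
})

quietSession <- function(...) suppressWarnings(makeSyntheticSession(...))

# A direction-cell-free grid session without latent sweeps (spikes driven by
# the tracked position), for decoder ground-truth tests.
gridOnlySession <- function(duration = 45, nCells = 200, arena = 120,
                            seed = 101) {
  tr <- generateTrajectory(duration, "rect", c(arena, arena), seed = seed)
  th <- generateTheta(duration, 8, seed = seed + 1)
  set.seed(seed + 2)
  cells <- lapply(seq_len(nCells), function(i)
    gridCellModel(spacing = sample(c(75, 106), 1),
                  orientation = runif(1, 0, pi / 3),
                  phaseOffset = runif(2, 0, 106),
                  amplitude = exp(rnorm(1, log(35), 0.3)),
                  phaseMu = pi + rnorm(1, 0, 0.8)))
  sim <- simulateSpikes(tr, th, NULL, cells, seed = seed + 3)
  ses <- binSession(sim$spikes, tr, nCells = nCells)
  list(session = ses, theta = th, traj = tr, cells = cells)
}

spatialMapsFor <- function(session, cells = seq_len(nrow(session)),
                           sigma = 7.5) {
  lapply(cells, function(i) rateMap(session, i, "spatial", sigma = sigma))
}

# Poisson spike train helper (sorted times over [0, dur] at `rate` Hz).
poissonTrain <- function(rate, dur, seed) {
  set.seed(seed)
  sort(runif(rpois(1, rate * dur), 0, dur))
}
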