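# Synthetic sessions: trajectory, theta, latent sweeps, tuning models and
# Poisson spiking. These generators define the study conditions assumed by
# every downstream stage, so the whole pipeline is testable without data.

#' Generate a foraging trajectory
#'
#' Correlated random walk with an Ornstein-Uhlenbeck speed process and
#' Gaussian heading diffusion, reflected at the arena walls. Head direction
#' is taken as the movement direction. Defaults emulate open-field foraging
#' in a 150 x 150 cm box at typical rat running speeds.
#'
#' @param duration Session length, seconds (>= 10).
#' @param arena `"rect"`, `"circle"` or `"linear"`.
#' @param size Arena size in cm: `c(width, height)` for `"rect"`, diameter for
#'   `"circle"`, track length for `"linear"`.
#' @param speedMean,speedSd Mean and long-run SD of running speed, cm/s.
#' @param turnSd Heading diffusion, rad per sqrt(s).
#' @param dt Time step, seconds.
#' @param seed Integer seed.
#' @return `data.frame` with `t`, `x`, `y`, `hd` (rad, (-pi, pi]) and `speed`
#'   (cm/s).
#' @export
generateTrajectory <- function(duration, arena = c("rect", "circle", "linear"),
                               size = c(150, 150), speedMean = 24,
                               speedSd = 8, turnSd = 1.6, dt = 0.01,
                               seed = 1) {
  arena <- match.arg(arena)
  if (duration < 10) stop("duration must be >= 10 s")
  if (any(size <= 0)) stop("degenerate arena dimensions")
  set.seed(seed)
  n <- round(duration / dt)
  if (arena == "linear") {
    len <- size[1]
    # shuttling: speed follows the same OU process, direction flips at ends
    v <- abs(speedMean + speedSd * as.numeric(
      filter(rnorm(n, 0, sqrt(2 * dt)), 1 - dt, method = "recursive")))
    x <- numeric(n); dirn <- 1; x[1] <- len / 2
    for (i in 2:n) {
      x[i] <- x[i - 1] + dirn * v[i] * dt
      if (x[i] > len) { x[i] <- 2 * len - x[i]; dirn <- -1 }
      if (x[i] < 0) { x[i] <- -x[i]; dirn <- 1 }
    }
    hd <- ifelse(c(0, diff(x)) >= 0, 0, pi)
    sp <- c(0, abs(diff(x)) / dt)
    return(data.frame(t = (seq_len(n) - 1) * dt, x = x, y = rep(0, n),
                      hd = hd, speed = sp))
  }
  halfw <- if (arena == "circle") size[1] / 2 else size / 2
  x <- numeric(n); y <- numeric(n); hd <- numeric(n)
  x[1] <- 0; y[1] <- 0; hd[1] <- runif(1, -pi, pi)
  v <- pmax(0, speedMean + speedSd * as.numeric(
    filter(rnorm(n, 0, sqrt(2 * dt)), 1 - dt, method = "recursive")))
  dhd <- rnorm(n, 0, turnSd * sqrt(dt))
  inside <- function(px, py) {
    if (arena == "circle") px^2 + py^2 < halfw[1]^2
    else abs(px) < halfw[1] && abs(py) < halfw[2]
  }
  for (i in 2:n) {
    hd[i] <- hd[i - 1] + dhd[i]
    px <- x[i - 1] + v[i] * dt * cos(hd[i])
    py <- y[i - 1] + v[i] * dt * sin(hd[i])
    if (!inside(px, py)) {
      # reflect heading off the wall normal
      if (arena == "circle") {
        nrm <- atan2(y[i - 1], x[i - 1])
        hd[i] <- wrapAngle(2 * nrm + pi - hd[i])
      } else {
        if (abs(px) >= halfw[1]) hd[i] <- wrapAngle(pi - hd[i])
        if (abs(py) >= halfw[2]) hd[i] <- -hd[i]
      }
      px <- x[i - 1] + v[i] * dt * cos(hd[i])
      py <- y[i - 1] + v[i] * dt * sin(hd[i])
      px <- min(max(px, -halfw[1] + 1e-6), halfw[1] - 1e-6)
      py <- min(max(py, -halfw[length(halfw)] + 1e-6),
                halfw[length(halfw)] - 1e-6)
    }
    x[i] <- px; y[i] <- py
  }
  data.frame(t = (seq_len(n) - 1) * dt, x = x, y = y, hd = wrapAngle(hd),
             speed = v)
}

#' Generate a theta-phase signal
#'
#' Theta cycles with lognormal cycle-length jitter; phase advances linearly
#' from 0 to 2*pi within each cycle. Phase 0 marks the cycle start (the
#' population-activity minimum in sessions simulated with von Mises phase
#' tuning centred at 180 degrees).
#'
#' @param duration Seconds.
#' @param freq Theta frequency, Hz (5-10).
#' @param jitter Lognormal SD of cycle length as a fraction of the mean
#'   (0 = perfectly periodic).
#' @param dt Bin width, seconds.
#' @param seed Integer seed.
#' @return List with `phase` (rad, per bin, in `[0, 2pi)`), `cycle` (integer
#'   per bin), `windows` (`data.frame` of first/last bin per cycle) and `dt`.
#' @export
generateTheta <- function(duration, freq = 8, jitter = 0.05, dt = 0.01,
                          seed = 1) {
  if (freq < 5 || freq > 10) stop("freq outside the 5-10 Hz theta band")
  set.seed(seed)
  n <- round(duration / dt)
  mcl <- 1 / freq
  ncyc <- ceiling(duration / mcl) + 10
  lens <- if (jitter > 0) {
    sdlog <- sqrt(log(1 + jitter^2))
    exp(rnorm(ncyc, log(mcl) - sdlog^2 / 2, sdlog))
  } else rep(mcl, ncyc)
  bounds <- c(0, cumsum(lens))
  tt <- (seq_len(n) - 1) * dt
  cyc <- findInterval(tt, bounds)
  phase <- 2 * pi * (tt - bounds[cyc]) / lens[cyc]
  win <- data.frame(
    cycle = sort(unique(cyc)),
    start = match(sort(unique(cyc)), cyc),
    end = length(cyc) - match(sort(unique(cyc)), rev(cyc)) + 1)
  list(phase = phase, cycle = cyc, windows = win, dt = dt)
}

#' Generate latent sweep and internal-direction signals
#'
#' For each theta cycle an internal direction is drawn as head direction
#' plus/minus `offsetDeg` degrees; the sign alternates across cycles when
#' `alternating = TRUE` and is an iid fair coin otherwise. Within a cycle the
#' represented position starts `startBehind` cm behind the animal (along the
#' heading) and ramps linearly in phase to `maxLen` cm out along the internal
#' direction.
#'
#' @param traj Trajectory from [generateTrajectory()].
#' @param theta Theta signal from [generateTheta()] on the same time base.
#' @param offsetDeg Angular offset of internal direction from heading, deg.
#' @param maxLen Maximal sweep length, cm.
#' @param alternating Alternate sides across cycles?
#' @param startBehind Distance behind the animal at cycle start, cm.
#' @param seed Integer seed (first side / iid coin).
#' @return List with per-bin `trueX`, `trueY`, `internalDir` (rad) and
#'   per-cycle `side` (+1 left, -1 right).
#' @export
generateLatentSweeps <- function(traj, theta, offsetDeg = 30, maxLen = 35,
                                 alternating = TRUE, startBehind = 5,
                                 seed = 1) {
  n <- nrow(traj)
  if (length(theta$phase) != n) stop("trajectory and theta time bases differ")
  set.seed(seed)
  cycles <- theta$windows$cycle
  ncyc <- length(cycles)
  side <- if (alternating) {
    s0 <- sample(c(-1, 1), 1)
    s0 * (-1)^(seq_len(ncyc) - 1)
  } else sample(c(-1, 1), ncyc, replace = TRUE)
  sideBin <- side[match(theta$cycle, cycles)]
  hd0 <- traj$hd[theta$windows$start][match(theta$cycle, cycles)]
  internalDir <- wrapAngle(hd0 + sideBin * offsetDeg * pi / 180)
  u <- theta$phase / (2 * pi)
  trueX <- traj$x + (1 - u) * (-startBehind) * cos(traj$hd) +
    u * maxLen * cos(internalDir)
  trueY <- traj$y + (1 - u) * (-startBehind) * sin(traj$hd) +
    u * maxLen * sin(internalDir)
  list(trueX = trueX, trueY = trueY, internalDir = internalDir,
       side = side, cycles = cycles)
}

#' Tuning models
#'
#' Constructors for idealized single-cell tuning. `gridCellModel()` places
#' Gaussian bumps of width `sigma` on a hexagonal lattice (defined on the
#' unbounded plane, so tuning extends beyond the arena); `placeCellModel()`
#' is a single bump; `directionCellModel()` is a von Mises function of the
#' internal direction; `conjunctiveCellModel()` multiplies grid and
#' directional tuning. All models carry a multiplicative von Mises theta-phase
#' gain with concentration `phaseKappa` (0 disables it) centred on
#' `phaseMu` (180 degrees by default, so population activity is minimal at
#' phase 0).
#'
#' @param spacing Grid spacing, cm.
#' @param orientation Grid orientation, rad.
#' @param phaseOffset Lattice translation, cm (length-2).
#' @param sigma Field width, cm. Default `spacing/6`.
#' @param amplitude Peak rate, Hz.
#' @param mu Preferred direction, rad.
#' @param kappa Directional concentration.
#' @param center Place-field centre, cm (length-2).
#' @param phaseKappa,phaseMu Theta-phase gain parameters.
#' @return A list of class `"tuningModel"`.
#' @export
gridCellModel <- function(spacing = 75, orientation = 0,
                          phaseOffset = c(0, 0), sigma = spacing / 6,
                          amplitude = 30, phaseKappa = 0.5, phaseMu = pi) {
  structure(list(kind = "grid", spacing = spacing, orientation = orientation,
                 phaseOffset = phaseOffset, sigma = sigma,
                 amplitude = amplitude, phaseKappa = phaseKappa,
                 phaseMu = phaseMu), class = "tuningModel")
}

#' @rdname gridCellModel
#' @export
placeCellModel <- function(center = c(0, 0), sigma = 10, amplitude = 10,
                           phaseKappa = 0.5, phaseMu = pi) {
  structure(list(kind = "place", center = center, sigma = sigma,
                 amplitude = amplitude, phaseKappa = phaseKappa,
                 phaseMu = phaseMu), class = "tuningModel")
}

#' @rdname gridCellModel
#' @export
directionCellModel <- function(mu = 0, kappa = 6, amplitude = 30,
                               phaseKappa = 1.5, phaseMu = pi) {
  structure(list(kind = "direction", mu = mu, kappa = kappa,
                 amplitude = amplitude, phaseKappa = phaseKappa,
                 phaseMu = phaseMu), class = "tuningModel")
}

#' @rdname gridCellModel
#' @export
conjunctiveCellModel <- function(spacing = 75, orientation = 0,
                                 phaseOffset = c(0, 0), sigma = spacing / 6,
                                 mu = 0, kappa = 2, amplitude = 15,
                                 phaseKappa = 0.5, phaseMu = pi) {
  structure(list(kind = "conjunctive", spacing = spacing,
                 orientation = orientation, phaseOffset = phaseOffset,
                 sigma = sigma, mu = mu, kappa = kappa, amplitude = amplitude,
                 phaseKappa = phaseKappa, phaseMu = phaseMu),
            class = "tuningModel")
}

# Spatial rate of a grid model at points (x, y): sum of Gaussian bumps at the
# nearest lattice sites (a 5 x 5 neighbourhood in lattice coordinates, ample
# for sigma <= spacing/3).
gridRate <- function(model, x, y) {
  a1 <- model$spacing * c(cos(model$orientation), sin(model$orientation))
  a2 <- model$spacing * c(cos(model$orientation + pi / 3),
                          sin(model$orientation + pi / 3))
  A <- cbind(a1, a2)
  Ainv <- solve(A)
  px <- x - model$phaseOffset[1]
  py <- y - model$phaseOffset[2]
  uv <- Ainv %*% rbind(px, py)
  u0 <- floor(uv[1, ]); v0 <- floor(uv[2, ])
  r <- numeric(length(x))
  inv2s2 <- 1 / (2 * model$sigma^2)
  for (du in -2:2) for (dv in -2:2) {
    cx <- A[1, 1] * (u0 + du) + A[1, 2] * (v0 + dv)
    cy <- A[2, 1] * (u0 + du) + A[2, 2] * (v0 + dv)
    r <- r + exp(-((px - cx)^2 + (py - cy)^2) * inv2s2)
  }
  model$amplitude * pmin(r, 1)
}

#' Evaluate the firing rate of a tuning model
#'
#' @param model A `"tuningModel"`.
#' @param x,y Position, cm.
#' @param dir Internal direction, rad (direction/conjunctive models).
#' @param phase Theta phase, rad (optional gain).
#' @return Rate in Hz (same length as the inputs), always >= 0.
#' @export
modelRate <- function(model, x = NULL, y = NULL, dir = NULL, phase = NULL) {
  r <- switch(model$kind,
    grid = gridRate(model, x, y),
    place = model$amplitude *
      exp(-((x - model$center[1])^2 + (y - model$center[2])^2) /
            (2 * model$sigma^2)),
    direction = model$amplitude * vonMisesBump(dir, model$mu, model$kappa),
    conjunctive = gridRate(model, x, y) *
      vonMisesBump(dir, model$mu, model$kappa))
  if (!is.null(phase) && model$phaseKappa > 0)
    r <- r * vonMisesBump(phase, model$phaseMu, model$phaseKappa)
  r
}

#' Simulate Poisson spike trains from tuning models
#'
#' Per-bin rates are evaluated at the latent represented position (grid,
#' place, conjunctive) and latent internal direction (direction,
#' conjunctive), multiplied by the theta-phase gain; counts are Poisson with
#' mean rate * dt.
#'
#' @param traj Trajectory (`data.frame`).
#' @param theta Theta signal ([generateTheta()]).
#' @param latent Latent track ([generateLatentSweeps()]), or `NULL` to use
#'   the tracked position and heading directly (no sweeps).
#' @param cells List of `"tuningModel"` objects.
#' @param dt Bin width, s.
#' @param seed Integer seed.
#' @return List with `counts` (cells x bins integer matrix) and `spikes`
#'   (`data.frame` with `neuron` and `t`, spike times uniform within bins).
#' @export
simulateSpikes <- function(traj, theta, latent, cells, dt = 0.01, seed = 1) {
  set.seed(seed)
  n <- nrow(traj)
  if (is.null(latent))
    latent <- list(trueX = traj$x, trueY = traj$y, internalDir = traj$hd)
  counts <- matrix(0L, length(cells), n)
  for (i in seq_along(cells)) {
    r <- modelRate(cells[[i]], latent$trueX, latent$trueY,
                   latent$internalDir, theta$phase)
    if (any(r < 0) || any(!is.finite(r))) stop("malformed tuning model")
    counts[i, ] <- rpois(n, r * dt)
  }
  idx <- which(counts > 0, arr.ind = TRUE)
  reps <- counts[idx]
  neuron <- rep(idx[, 1], reps)
  bin <- rep(idx[, 2], reps)
  tt <- traj$t[bin] + runif(length(bin), 0, dt)
  o <- order(neuron, tt)
  list(counts = counts,
       spikes = data.frame(neuron = neuron[o], t = tt[o]))
}

#' Build a complete synthetic session
#'
#' Convenience wrapper tying together trajectory, theta, latent sweeps, a
#' standard cell population (grid modules, internal-direction cells,
#' optionally conjunctive cells) and Poisson spiking; returns a
#' [SweepSession] with the latent ground truth stored in `metadata()`.
#'
#' @param duration Seconds.
#' @param nGrid,nDir,nConj Population sizes.
#' @param gridSpacings Spacing of each grid module, cm; grid cells are split
#'   evenly across modules.
#' @param arenaSize Side of the square arena, cm.
#' @param freq Theta frequency, Hz.
#' @param alternating Alternate sweep sides?
#' @param offsetDeg,maxLen Latent sweep geometry (deg, cm).
#' @param speedMin Speed filter threshold, cm/s.
#' @param seed Integer seed; sub-seeds for each stage are derived from it.
#' @return A [SweepSession].
#' @export
makeSyntheticSession <- function(duration = 300, nGrid = 120, nDir = 60,
                                 nConj = 0, gridSpacings = c(75, 106),
                                 arenaSize = 150, freq = 8,
                                 alternating = TRUE, offsetDeg = 30,
                                 maxLen = 35, speedMin = 5, seed = 1) {
  traj <- generateTrajectory(duration, "rect", c(arenaSize, arenaSize),
                             seed = seed)
  theta <- generateTheta(duration, freq = freq, seed = seed + 1000L)
  latent <- generateLatentSweeps(traj, theta, offsetDeg = offsetDeg,
                                 maxLen = maxLen, alternating = alternating,
                                 seed = seed + 2000L)
  set.seed(seed + 3000L)
  cells <- list()
  kinds <- character(0)
  if (nGrid > 0) {
    perMod <- rep(ceiling(nGrid / length(gridSpacings)),
                  length(gridSpacings))[seq_along(gridSpacings)]
    for (m in seq_along(gridSpacings)) {
      sp <- gridSpacings[m]
      orient <- runif(1, 0, pi / 3)
      k <- if (m < length(gridSpacings)) perMod[m] else
        nGrid - sum(perMod[seq_len(m - 1)])
      for (j in seq_len(k)) {
        cells <- c(cells, list(gridCellModel(
          spacing = sp, orientation = orient,
          phaseOffset = runif(2, 0, sp),
          amplitude = exp(rnorm(1, log(30), 0.3)),
          phaseMu = pi + rnorm(1, 0, 0.8))))
        kinds <- c(kinds, sprintf("grid_m%d", m))
      }
    }
  }
  if (nDir > 0) for (j in seq_len(nDir)) {
    cells <- c(cells, list(directionCellModel(
      mu = runif(1, -pi, pi), amplitude = exp(rnorm(1, log(30), 0.3)),
      phaseMu = pi + rnorm(1, 0, 0.8))))
    kinds <- c(kinds, "direction")
  }
  if (nConj > 0) for (j in seq_len(nConj)) {
    cells <- c(cells, list(conjunctiveCellModel(
      spacing = gridSpacings[1], orientation = runif(1, 0, pi / 3),
      phaseOffset = runif(2, 0, gridSpacings[1]), mu = runif(1, -pi, pi))))
    kinds <- c(kinds, "conjunctive")
  }
  sim <- simulateSpikes(traj, theta, latent, cells, seed = seed + 4000L)
  cd <- DataFrame(t = traj$t, x = traj$x, y = traj$y, hd = traj$hd,
                  speed = traj$speed, valid = traj$speed > speedMin,
                  phase = theta$phase, cycle = theta$cycle)
  rd <- DataFrame(kind = kinds)
  se <- SummarizedExperiment(
    assays = list(counts = sim$counts), colData = cd, rowData = rd,
    metadata = list(dt = 0.01, arenaSize = arenaSize, speedMin = speedMin,
                    theta = theta, latent = latent, cells = cells,
                    spikes = sim$spikes, seed = seed))
  new("SweepSession", se)
}

#' Write a synthetic session to plain-text files
#'
#' Emits the CSV session format: `spikes.csv` (neuron, t), `trajectory.csv`
#' (t, x, y, hd) and a JSON `manifest.json` with the generator parameters
#' and seeds.
#'
#' @param session A [SweepSession] from [makeSyntheticSession()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
writeSessionCSV <- function(session, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sp <- metadata(session)$spikes
  tr <- trajectory(session)
  p1 <- file.path(dir, "spikes.csv")
  p2 <- file.path(dir, "trajectory.csv")
  utils::write.csv(sp, p1, row.names = FALSE)
  utils::write.csv(tr[, c("t", "x", "y", "hd")], p2, row.names = FALSE)
  p3 <- file.path(dir, "manifest.json")
  man <- list(dt = metadata(session)$dt,
              arenaSize = metadata(session)$arenaSize,
              seed = metadata(session)$seed,
              nCells = nrow(session))
  if (requireNamespace("jsonlite", quietly = TRUE))
    jsonlite::write_json(man, p3, auto_unbox = TRUE)
  invisible(c(p1, p2, p3))
}
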