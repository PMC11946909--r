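# The overlap-minimizing sweep-generating agent: beam-shaped footprint,
# decaying coverage trace, direction choice, and the linear-path,
# trajectory-driven and multimodule simulations.

besselCoefs <- function(kappa, M = 12) {
  v <- besselI(kappa, 0:M)
  v[-1] <- 2 * v[-1]
  v
}

defaultAngles <- function(stepDeg = 1) seq(0, 360 - stepDeg, by = stepDeg) *
  pi / 180

#' Sweep footprint value and grid
#'
#' The footprint intensity at displacement (dx, dy) from the agent for sweep
#' direction `alpha` is `1/d^2 * exp(kappa * cos(theta - alpha))` with `d`
#' the distance and `theta` the direction of the displacement.
#' `sweepFootprint()` evaluates it on an `n` x `n` grid of unit bins around
#' `pos` (1-based grid coordinates); cells within `dmin` bins of the origin
#' are masked to zero (the 1/d^2 cell integral diverges there), and cells
#' within `rsub` bins are evaluated by `ksub` x `ksub` sub-cell averaging to
#' suppress square-lattice anisotropy (see the package vignette).
#'
#' @param dx,dy Displacements, bins.
#' @param alpha Sweep direction, rad.
#' @param kappa Angular concentration.
#' @param n Grid side.
#' @param pos Agent position `c(x, y)` in grid coordinates.
#' @param dmin Origin mask radius, bins.
#' @param cellAverage Sub-sample cells near the origin?
#' @param rsub,ksub Sub-sampling radius (bins) and factor.
#' @return `footprintValue()`: numeric; `sweepFootprint()`: `n` x `n` matrix.
#' @export
footprintValue <- function(dx, dy, alpha, kappa = 5) {
  d2 <- dx^2 + dy^2
  th <- atan2(dy, dx)
  exp(kappa * cos(th - alpha)) / d2
}

#' @rdname footprintValue
#' @export
sweepFootprint <- function(n, pos, alpha, kappa = 5, dmin = 1.5,
                           cellAverage = TRUE, rsub = 12, ksub = 5) {
  h <- matrix(0, n, n)
  if (cellAverage)
    .addFootprintAvg(h, pos[1], pos[2], alpha, kappa, dmin, 1.0, rsub, ksub)
  else
    .addFootprint(h, pos[1], pos[2], alpha, kappa, dmin, 1.0)
  h
}

#' Create an empty coverage trace
#'
#' @param n Grid side, bins.
#' @param binSize Bin size (cm in trajectory mode; arbitrary units for the
#'   scale-free linear run).
#' @param tau Decay factor per second (1 = no decay).
#' @param kappa Footprint concentration used with this trace.
#' @return A [CoverageTrace].
#' @export
coverageTrace <- function(n = 401, binSize = 1, tau = 1, kappa = 5) {
  new("CoverageTrace", h = matrix(0, n, n), binSize = binSize,
      origin = c((n + 1) / 2, (n + 1) / 2), tau = tau, kappa = kappa)
}

#' Add a sweep footprint to a coverage trace
#'
#' @param trace A [CoverageTrace].
#' @param pos Agent position, grid coordinates (bins).
#' @param alpha Sweep direction, rad.
#' @param gain Footprint weight.
#' @param ... Passed to the footprint evaluation (`dmin`, `cellAverage`,
#'   `rsub`, `ksub`).
#' @return The updated [CoverageTrace].
#' @export
addSweep <- function(trace, pos, alpha, gain = 1, dmin = 1.5,
                     cellAverage = TRUE, rsub = 12, ksub = 5) {
  h <- trace@h + 0 # force a copy before the in-place C++ update
  if (cellAverage)
    .addFootprintAvg(h, pos[1], pos[2], alpha, trace@kappa, dmin, gain,
                     rsub, ksub)
  else
    .addFootprint(h, pos[1], pos[2], alpha, trace@kappa, dmin, gain)
  trace@h <- h
  trace
}

#' Decay a coverage trace
#'
#' Multiplies the trace by `tau^dt` (exponential discounting of past sweep
#' footprints; `tau = 1` leaves the trace untouched).
#'
#' @param trace A [CoverageTrace].
#' @param dt Elapsed time, s.
#' @return The decayed [CoverageTrace].
#' @export
decayTrace <- function(trace, dt) {
  trace@h <- trace@h * trace@tau^dt
  trace
}

#' Overlap of candidate sweep directions with the coverage trace
#'
#' `sum_x f(x, alpha) h(x)` for each candidate `alpha`, computed with a
#' Jacobi-Anger (Bessel) expansion of the von Mises factor (exact to series
#' truncation; 12 harmonics).
#'
#' @param trace A [CoverageTrace].
#' @param pos Agent position, grid coordinates.
#' @param angles Candidate directions, rad.
#' @param dmin,cellAverage,rsub,ksub Footprint regularization (must match
#'   the parameters used to build the trace).
#' @return Numeric vector of overlaps, one per angle.
#' @export
overlapCurve <- function(trace, pos, angles = defaultAngles(),
                         dmin = 1.5, cellAverage = TRUE, rsub = 12,
                         ksub = 5) {
  co <- besselCoefs(trace@kappa)
  if (cellAverage)
    .overlapCurveAvg(trace@h, pos[1], pos[2], angles, co, dmin, rsub, ksub)
  else
    .overlapCurve(trace@h, pos[1], pos[2], angles, co, dmin)
}

#' Choose the overlap-minimizing sweep direction
#'
#' The direction minimizing the overlap between the candidate footprint and
#' the cumulative trace; exact ties (within relative 1e-10) are broken by a
#' seeded uniform draw among the minimal angles.
#'
#' @inheritParams overlapCurve
#' @return List: `alpha` (chosen direction), `overlap` (the curve), `tie`
#'   (was the minimum tied?).
#' @export
chooseDirection <- function(trace, pos, angles = defaultAngles(),
                            dmin = 1.5, cellAverage = TRUE, rsub = 12,
                            ksub = 5) {
  o <- overlapCurve(trace, pos, angles, dmin, cellAverage, rsub, ksub)
  omin <- min(o)
  mins <- which(o - omin <= 1e-10 * abs(omin) + 1e-300)
  pick <- if (length(mins) > 1) sample(mins, 1) else mins
  list(alpha = angles[pick], overlap = o, tie = length(mins) > 1)
}

#' Linear-path agent runs
#'
#' The agent moves along a straight line at constant speed on a scale-free
#' 401 x 401 grid, places a footprint every step and, from the second step
#' on, chooses the overlap-minimizing direction (1 degree angle grid). The
#' first direction is drawn uniformly, and the start position is jittered
#' within a bin (the run's random initial conditions). No temporal decay is
#' applied on the linear path.
#'
#' @param nSteps Steps per run.
#' @param stepLen Step length, bins.
#' @param kappa Footprint concentration.
#' @param n Grid side.
#' @param seed Integer seed.
#' @param dmin,rsub,ksub Footprint regularization.
#' @param angleStepDeg Angle-grid resolution, degrees.
#' @return An [AgentRun]; directions in radians, movement along +x.
#' @export
runLinearAgent <- function(nSteps = 30, stepLen = 5, kappa = 5, n = 401,
                           seed = 1, dmin = 1.5, rsub = 12, ksub = 5,
                           angleStepDeg = 1) {
  set.seed(seed)
  firstDir <- runif(1, 0, 2 * pi)
  x0 <- (n - (nSteps - 1) * stepLen) / 2 + runif(1, -0.5, 0.5)
  y0 <- (n + 1) / 2 + runif(1, -0.5, 0.5)
  angles <- defaultAngles(angleStepDeg)
  co <- besselCoefs(kappa)
  dirs <- .runLinearAgentAvg(n, nSteps, stepLen, x0, y0, kappa, angles, co,
                             firstDir, dmin, rsub, ksub)
  pos <- cbind(x = x0 + (seq_len(nSteps) - 1) * stepLen, y = y0)
  new("AgentRun", positions = pos, directions = as.numeric(dirs),
      scores = alternationScore(as.numeric(dirs)), mode = "linear",
      params = list(kappa = kappa, stepLen = stepLen, n = n, seed = seed,
                    dmin = dmin))
}

#' Drive the agent along a trajectory
#'
#' The agent follows the animal's path on a 1 cm grid (arena centred), with
#' one time step per theta cycle and exponential decay `tau^dt` of the
#' coverage trace between cycles. In `"self"` mode the trace accumulates the
#' agent's own chosen sweeps; in `"empirical"` mode it accumulates the
#' observed (decoded) sweep directions and the chosen direction is the
#' agent's prediction of the next sweep.
#'
#' @param traj Trajectory `data.frame` (`t`, `x`, `y` in cm).
#' @param cycleTimes Times of theta cycles, s.
#' @param mode `"self"` or `"empirical"`.
#' @param kappa Footprint concentration.
#' @param tau Decay per second.
#' @param binSize Grid bin, cm.
#' @param n Grid side.
#' @param decodedDirs Observed directions per cycle (required in empirical
#'   mode), rad.
#' @param seed Integer seed (tie-breaks, first direction in self mode).
#' @param angleStepDeg Angle-grid resolution, degrees.
#' @return An [AgentRun] (positions in grid bins; `params$binSize` maps to
#'   cm).
#' @export
runAgentOnTrajectory <- function(traj, cycleTimes, mode = c("self",
                                 "empirical"), kappa = 5, tau = 0.04,
                                 binSize = 1, n = 401, decodedDirs = NULL,
                                 seed = 1, angleStepDeg = 2) {
  mode <- match.arg(mode)
  if (mode == "empirical" && is.null(decodedDirs))
    stop("empirical mode needs decoded directions per cycle")
  set.seed(seed)
  cx <- (n + 1) / 2 + (approx(traj$t, traj$x, cycleTimes, rule = 2)$y -
                         mean(range(traj$x))) / binSize
  cy <- (n + 1) / 2 + (approx(traj$t, traj$y, cycleTimes, rule = 2)$y -
                         mean(range(traj$y))) / binSize
  angles <- defaultAngles(angleStepDeg)
  co <- besselCoefs(kappa)
  nc <- length(cycleTimes)
  h <- matrix(0, n, n)
  chosen <- numeric(nc)
  for (i in seq_len(nc)) {
    if (i > 1) h <- h * tau^(cycleTimes[i] - cycleTimes[i - 1])
    if (i == 1) {
      chosen[i] <- runif(1, 0, 2 * pi)
    } else {
      o <- .overlapCurveAvg(h, cx[i], cy[i], angles, co, 1.5, 12, 5)
      omin <- min(o)
      mins <- which(o - omin <= 1e-10 * abs(omin) + 1e-300)
      chosen[i] <- angles[if (length(mins) > 1) sample(mins, 1) else mins]
    }
    placed <- if (mode == "empirical") decodedDirs[i] else chosen[i]
    .addFootprintAvg(h, cx[i], cy[i], placed, kappa, 1.5, 1.0, 12L, 5L)
  }
  new("AgentRun", positions = cbind(x = cx, y = cy), directions = chosen,
      scores = alternationScore(chosen), mode = mode,
      params = list(kappa = kappa, tau = tau, binSize = binSize, n = n,
                    seed = seed, cycleTimes = cycleTimes))
}

#' Multimodule agent on a linear path
#'
#' Sweep footprints of `nModules` grid modules are Gaussian blobs whose
#' width and sweep length grow with geometric `ratio`; modules share a
#' summed coverage trace and update under one of three rules: `"common"`
#' (one direction minimizing the summed-footprint overlap), `"parallel"`
#' (independent simultaneous argmins) or `"serial"` (sequential updates of
#' the shared trace).
#'
#' @param nSteps,stepLen,n,seed As in [runLinearAgent()].
#' @param rule Updating rule.
#' @param nModules Number of modules.
#' @param ratio Geometric scale ratio.
#' @param baseLen Sweep length of the smallest module, bins.
#' @param baseSigma Field width of the smallest module, bins.
#' @param angleStepDeg Angle-grid resolution, degrees.
#' @return List of per-module [AgentRun]s.
#' @export
runMultiModuleAgent <- function(nSteps = 30, stepLen = 5,
                                rule = c("common", "parallel", "serial"),
                                nModules = 3, ratio = 1.5, baseLen = 12,
                                baseSigma = 4, n = 401, seed = 1,
                                angleStepDeg = 2) {
  rule <- match.arg(rule)
  set.seed(seed)
  lens <- baseLen * ratio^(seq_len(nModules) - 1)
  sigs <- baseSigma * ratio^(seq_len(nModules) - 1)
  angles <- defaultAngles(angleStepDeg)
  h <- matrix(0, n, n)
  x0 <- (n - (nSteps - 1) * stepLen) / 2 + runif(1, -0.5, 0.5)
  y0 <- (n + 1) / 2 + runif(1, -0.5, 0.5)
  dirs <- matrix(0, nSteps, nModules)
  argminAngle <- function(o) {
    omin <- min(o)
    mins <- which(o - omin <= 1e-10 * abs(omin) + 1e-300)
    angles[if (length(mins) > 1) sample(mins, 1) else mins]
  }
  for (t in seq_len(nSteps)) {
    cx <- x0 + (t - 1) * stepLen
    if (t == 1) {
      dirs[t, ] <- runif(1, 0, 2 * pi)
      if (rule != "common") dirs[t, ] <- runif(nModules, 0, 2 * pi)
    } else if (rule == "common") {
      o <- Reduce(`+`, lapply(seq_len(nModules), function(m)
        .gaussOverlapCurve(h, cx, y0, angles, lens[m], sigs[m])))
      dirs[t, ] <- argminAngle(o)
    } else if (rule == "parallel") {
      for (m in seq_len(nModules))
        dirs[t, m] <- argminAngle(
          .gaussOverlapCurve(h, cx, y0, angles, lens[m], sigs[m]))
    } else { # serial: update the shared trace between module choices
      for (m in seq_len(nModules)) {
        dirs[t, m] <- argminAngle(
          .gaussOverlapCurve(h, cx, y0, angles, lens[m], sigs[m]))
        .addGaussFootprint(h, cx, y0, dirs[t, m], lens[m], sigs[m], 1.0)
      }
    }
    if (rule != "serial")
      for (m in seq_len(nModules))
        .addGaussFootprint(h, cx, y0, dirs[t, m], lens[m], sigs[m], 1.0)
  }
  lapply(seq_len(nModules), function(m)
    new("AgentRun",
        positions = cbind(x = x0 + (seq_len(nSteps) - 1) * stepLen, y = y0),
        directions = dirs[, m], scores = alternationScore(dirs[, m]),
        mode = paste0("multimodule-", rule),
        params = list(rule = rule, module = m, len = lens[m],
                      sigma = sigs[m], seed = seed)))
}

#' Summary statistics of 1,000-run linear agent simulations
#'
#' Replicates the straight-path simulation across seeds and reports the mean
#' alternation score at the third sweep (window centred on it), the mean
#' plateau score (last `plateauSteps` windows) and the mean absolute angle
#' of the chosen directions from the movement direction over the same
#' plateau.
#'
#' @param nRuns Number of replicate runs.
#' @param seed Base seed (run `i` uses `seed * 10000 + i`).
#' @param nSteps,stepLen,kappa,n Passed to [runLinearAgent()].
#' @param plateauSteps Steps in the plateau window.
#' @return List: `scoreThird`, `scorePlateau`, `angleDeg`, plus per-run
#'   vectors.
#' @export
linearAgentStats <- function(nRuns = 1000, seed = 1, nSteps = 30,
                             stepLen = 5, kappa = 5, n = 401,
                             plateauSteps = 10) {
  s3 <- numeric(nRuns); sp <- numeric(nRuns); ang <- numeric(nRuns)
  for (i in seq_len(nRuns)) {
    run <- runLinearAgent(nSteps, stepLen, kappa, n,
                          seed = (seed %% 1000L) * 10000L + i)
    sc <- run@scores
    s3[i] <- sc[3]
    late <- (nSteps - plateauSteps + 1):nSteps
    sp[i] <- mean(sc[intersect(late, which(is.finite(sc)))])
    ang[i] <- mean(abs(wrapAngle(run@directions[late]))) * 180 / pi
  }
  list(scoreThird = mean(s3, na.rm = TRUE),
       scorePlateau = mean(sp, na.rm = TRUE),
       angleDeg = mean(ang), s3 = s3, plateau = sp, angles = ang)
}
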