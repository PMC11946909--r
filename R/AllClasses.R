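# Central S4 classes.

#' SweepSession: binned population activity plus trajectory covariates
#'
#' A `SweepSession` extends [SummarizedExperiment::SummarizedExperiment]. The
#' single `"counts"` assay holds per-neuron spike counts in fixed time bins
#' (rows = neurons, columns = time bins). `colData` carries the time-aligned
#' trajectory covariates (`t`, `x`, `y`, `hd`, `speed`, logical `valid` from
#' the speed filter and, once theta phase has been attached, `phase` and
#' `cycle`). `rowData` describes the cells. `metadata(x)$dt` is the bin width
#' in seconds; synthetic sessions also store the latent ground truth
#' (`metadata(x)$latent`).
#'
#' @export
setClass("SweepSession", contains = "SummarizedExperiment")

setValidity("SweepSession", function(object) {
  msg <- NULL
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'counts' is required")
  else {
    cnt <- SummarizedExperiment::assay(object, "counts")
    if (any(cnt < 0)) msg <- c(msg, "counts must be non-negative")
  }
  need <- c("t", "x", "y", "hd", "speed", "valid")
  miss <- setdiff(need, colnames(colData(object)))
  if (length(miss))
    msg <- c(msg, paste("missing colData columns:", paste(miss, collapse = ", ")))
  if (is.null(metadata(object)$dt))
    msg <- c(msg, "metadata$dt (bin width, s) is required")
  if (is.null(msg)) TRUE else msg
})

#' TuningMap: a spatial rate map or angular tuning curve
#'
#' Spatial maps hold firing rate (Hz) on a square grid of `binSize` cm bins;
#' unvisited bins are `NA` (never zero-filled). Angular maps hold rate over
#' evenly spaced angular bins. `occupancy` is the time (s) spent per bin.
#'
#' @slot kind `"spatial"` or `"angular"`.
#' @slot rate Matrix (spatial, x along rows) or numeric vector (angular), Hz.
#' @slot occupancy Same shape as `rate`, seconds.
#' @slot sigma Smoothing width actually applied (cm or rad).
#' @slot binSize Spatial bin side (cm) or angular bin width (rad).
#' @slot xBins,yBins Bin centre coordinates (spatial maps; angular maps use
#'   `xBins` for bin centre angles).
#' @export
setClass("TuningMap", representation(
  kind = "character", rate = "ANY", occupancy = "ANY", sigma = "numeric",
  binSize = "numeric", xBins = "numeric", yBins = "numeric"))

setValidity("TuningMap", function(object) {
  if (!object@kind %in% c("spatial", "angular")) return("kind must be spatial|angular")
  if (any(object@rate < 0, na.rm = TRUE)) return("rates must be >= 0")
  TRUE
})

#' DecodedTrack: per-bin decoded position or direction
#'
#' @slot data `DataFrame` with one row per time bin: `t`, decoded `x`, `y`
#'   (position decoders) or `dir` (direction decoders), `confidence`
#'   (peak PV correlation or posterior maximum) and logical `valid`.
#' @slot lowpass `DataFrame` with the lowpass-filtered decoded reference
#'   trajectory (`x`, `y`), or 0-row if not attached.
#' @slot kind Decoder label.
#' @export
setClass("DecodedTrack", representation(
  data = "DataFrame", lowpass = "DataFrame", kind = "character"))

#' SweepSet: per-theta-cycle sweep trajectories
#'
#' @slot table `DataFrame` with one row per detected sweep: `cycle`, `tStart`,
#'   `dir` (rad, allocentric), `hcDir` (rad, head-centred), `length` (cm),
#'   `r2`, `side` (+1 left / -1 right), `n` points.
#' @slot points List of per-sweep point matrices (columns x, y; allocentric).
#' @export
setClass("SweepSet", representation(table = "DataFrame", points = "list"))

#' CoverageTrace: the agent's decaying memory of past sweep footprints
#'
#' @slot h Accumulated footprint intensity on a square grid (rows = x).
#' @slot binSize Spatial bin side in the agent's units (cm for trajectory
#'   mode, arbitrary for the scale-free linear run).
#' @slot origin Grid coordinate (bins, 1-based) of the world origin.
#' @slot tau Temporal decay factor per second (1 = no decay).
#' @slot kappa Angular concentration of the footprint.
#' @export
setClass("CoverageTrace", representation(
  h = "matrix", binSize = "numeric", origin = "numeric", tau = "numeric",
  kappa = "numeric"))

setValidity("CoverageTrace", function(object) {
  if (any(object@h < 0)) return("coverage trace must be non-negative")
  if (object@tau < 0 || object@tau > 1) return("tau must be in [0, 1]")
  TRUE
})

#' AgentRun: one run of the sweep-generating agent
#'
#' @slot positions Matrix (steps x 2) of agent positions (grid bins or cm).
#' @slot directions Chosen sweep directions per step, radians.
#' @slot scores Sliding-window alternation scores (NA at the ends).
#' @slot mode `"linear"`, `"self"` or `"empirical"`.
#' @slot params List of run parameters (kappa, tau, stepLen, seed, ...).
#' @export
setClass("AgentRun", representation(
  positions = "matrix", directions = "numeric", scores = "numeric",
  mode = "character", params = "list"))

#' ShiftGLMFit: Poisson GLM with theta-phase-dependent position shift
#'
#' @slot beta Fitted coefficients (intercept first) on the retained design.
#' @slot gamma Shift coefficients: constant plus weights over the retained
#'   theta-phase basis dimensions.
#' @slot loglik Poisson log-likelihood trace over outer iterations.
#' @slot converged Logical.
#' @slot design List describing the basis/PCA projection used.
#' @export
setClass("ShiftGLMFit", representation(
  beta = "numeric", gamma = "numeric", loglik = "numeric",
  converged = "logical", design = "list"))
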