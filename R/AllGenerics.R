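# Generics and simple accessors.

#' Trajectory covariates of a session
#'
#' @param x A [SweepSession].
#' @return A `data.frame` with columns `t`, `x`, `y`, `hd`, `speed`, `valid`
#'   (plus `phase` and `cycle` when theta phase has been attached).
#' @export
setGeneric("trajectory", function(x) standardGeneric("trajectory"))

#' @rdname trajectory
#' @export
setMethod("trajectory", "SweepSession", function(x)
  as.data.frame(colData(x)))

#' Spike-count matrix of a session
#'
#' @param x A [SweepSession].
#' @return Integer matrix, neurons by time bins.
#' @export
setGeneric("spikeCounts", function(x) standardGeneric("spikeCounts"))

#' @rdname spikeCounts
#' @export
setMethod("spikeCounts", "SweepSession", function(x)
  SummarizedExperiment::assay(x, "counts"))

#' Bin width of a session (seconds)
#' @param x A [SweepSession].
#' @return Numeric scalar.
#' @export
setGeneric("binWidth", function(x) standardGeneric("binWidth"))

#' @rdname binWidth
#' @export
setMethod("binWidth", "SweepSession", function(x) metadata(x)$dt)

#' Sweep table of a SweepSet
#' @param x A [SweepSet].
#' @return The per-sweep `DataFrame`.
#' @export
setGeneric("sweepTable", function(x) standardGeneric("sweepTable"))

#' @rdname sweepTable
#' @export
setMethod("sweepTable", "SweepSet", function(x) x@table)

#' @export
setMethod("length", "SweepSet", function(x) nrow(x@table))

#' Rate values of a TuningMap
#' @param x A [TuningMap].
#' @return Matrix (spatial) or vector (angular) of rates, Hz.
#' @export
setGeneric("tuningRate", function(x) standardGeneric("tuningRate"))

#' @rdname tuningRate
#' @export
setMethod("tuningRate", "TuningMap", function(x) x@rate)

#' Chosen directions of an agent run
#' @param x An [AgentRun].
#' @return Numeric vector of directions (radians).
#' @export
setGeneric("agentDirections", function(x) standardGeneric("agentDirections"))

#' @rdname agentDirections
#' @export
setMethod("agentDirections", "AgentRun", function(x) x@directions)

#' Sliding-window alternation scores of an agent run
#' @param x An [AgentRun].
#' @return Numeric vector (NA where the window is incomplete).
#' @export
setGeneric("agentScores", function(x) standardGeneric("agentScores"))

#' @rdname agentScores
#' @export
setMethod("agentScores", "AgentRun", function(x) x@scores)

setMethod("show", "SweepSession", function(object) {
  cat("SweepSession:", nrow(object), "cells x", ncol(object), "bins (",
      sprintf("%.1f s at dt = %g s", ncol(object) * metadata(object)$dt,
              metadata(object)$dt), ")\n")
  cat("  speed-valid bins:", sum(colData(object)$valid), "/", ncol(object), "\n")
  if (!is.null(colData(object)$cycle))
    cat("  theta cycles:", length(unique(colData(object)$cycle)), "\n")
})

setMethod("show", "TuningMap", function(object) {
  cat("TuningMap (", object@kind, "), sigma = ",
      signif(object@sigma, 3), "\n", sep = "")
  if (object@kind == "spatial")
    cat("  grid:", nrow(object@rate), "x", ncol(object@rate), "bins of",
        object@binSize, "cm; peak rate",
        signif(max(object@rate, na.rm = TRUE), 3), "Hz\n")
  else
    cat(" ", length(object@rate), "angular bins; peak rate",
        signif(max(object@rate, na.rm = TRUE), 3), "Hz\n")
})

setMethod("show", "DecodedTrack", function(object) {
  cat("DecodedTrack (", object@kind, "): ", nrow(object@data), " bins, ",
      sum(object@data$valid), " valid\n", sep = "")
})

setMethod("show", "SweepSet", function(object) {
  cat("SweepSet:", nrow(object@table), "sweeps\n")
  if (nrow(object@table) > 0)
    cat("  median length", signif(median(object@table$length), 3),
        "cm; median |head-centred dir|",
        signif(median(abs(object@table$hcDir)) * 180 / pi, 3), "deg\n")
})

setMethod("show", "CoverageTrace", function(object) {
  cat("CoverageTrace:", nrow(object@h), "x", ncol(object@h),
      "bins; tau =", object@tau, "\n")
})

setMethod("show", "AgentRun", function(object) {
  cat("AgentRun (", object@mode, "): ", length(object@directions),
      " steps\n", sep = "")
  s <- object@scores[is.finite(object@scores)]
  if (length(s))
    cat("  mean alternation score", signif(mean(s), 3), "\n")
})

setMethod("show", "ShiftGLMFit", function(object) {
  cat("ShiftGLMFit: loglik", signif(tail(object@loglik, 1), 6),
      if (object@converged) "(converged)" else "(not converged)", "\n")
})
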