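# Putative excitatory monosynaptic connections from spike-train
# cross-correlograms with a hollowed-Gaussian baseline.

#' Spike-train cross-correlogram with convolved baseline
#'
#' Counts of (post - pre) lags in 1 ms bins over a +-50 ms window, with a
#' baseline from convolving the raw CCG with a hollowed Gaussian kernel
#' (sigma = 5 ms, hollow fraction 60%: the centre weight is scaled by 0.4
#' and the kernel renormalized; edges handled by reflection). Pairs are
#' eligible when both trains have at least `minSpikes` spikes and the raw
#' CCG holds at least `minCounts` counts.
#'
#' @param pre,post Sorted spike times, s.
#' @param binMs,windowMs CCG resolution and span.
#' @param sigmaMs,hollow Baseline kernel parameters.
#' @param minSpikes,minCounts Eligibility thresholds.
#' @return List with `lags` (ms), `counts`, `baseline`, `corrected`,
#'   `eligible`; ineligible pairs carry `eligible = FALSE`.
#' @export
computeCCG <- function(pre, post, binMs = 1, windowMs = 50, sigmaMs = 5,
                       hollow = 0.6, minSpikes = 2000, minCounts = 1000) {
  counts <- as.numeric(.ccgCounts(sort(pre), sort(post), binMs / 1000,
                                  windowMs / 1000))
  lags <- seq(-windowMs, windowMs, by = binMs)
  eligible <- length(pre) >= minSpikes && length(post) >= minSpikes &&
    sum(counts) >= minCounts
  half <- ceiling(4 * sigmaMs / binMs)
  k <- exp(-0.5 * ((-half:half) * binMs / sigmaMs)^2)
  k[half + 1] <- k[half + 1] * (1 - hollow)
  k <- k / sum(k)
  n <- length(counts)
  padded <- c(rev(counts[1:half]), counts, rev(counts[(n - half + 1):n]))
  base <- as.numeric(filter(padded, k, sides = 2))[(half + 1):(half + n)]
  list(lags = lags, counts = counts, baseline = base,
       corrected = counts - base, eligible = eligible)
}

#' Detect a putative excitatory connection in a CCG
#'
#' The highest positive baseline-corrected peak must satisfy all five
#' criteria: (1) lag within the monosynaptic window (0.7-4.7 ms); (2) height
#' above five standard deviations of the corrected CCG (SD over all bins
#' excluding the candidate peak); (3) Poisson P < 0.001 against the baseline
#' with continuity correction; (4) peak width (contiguous bins above half
#' height or 2 SD with P < 0.01) under 3 ms; (5) the width not reaching the
#' zero-lag bin. Candidates are discarded when any non-peak bin exceeds
#' 2.5 SD or any bin in the mirrored (anticausal) monosynaptic window has
#' P < 0.01 (suggestive of common input).
#'
#' @param ccg Output of [computeCCG()].
#' @param window Monosynaptic lag window, ms.
#' @param peakSd,maxWidthMs,alphaPeak Thresholds.
#' @return A one-row `data.frame` (`lag`, `z`, `p`, `width`, plus
#'   per-criterion booleans) or `NULL` when no connection is detected.
#' @export
detectConnection <- function(ccg, window = c(0.7, 4.7), peakSd = 5,
                             maxWidthMs = 3, alphaPeak = 0.001) {
  if (!isTRUE(ccg$eligible)) return(NULL)
  lags <- ccg$lags
  corr <- ccg$corrected
  base <- pmax(ccg$baseline, 1e-12)
  # Poisson P with continuity correction (per bin, against the baseline)
  pPois <- 1 - ppois(ccg$counts - 1, base) - 0.5 * dpois(ccg$counts, base)
  pPois <- pmin(pmax(pPois, 0), 1)
  win <- lags >= window[1] & lags <= window[2]
  if (!any(win) || all(corr[win] <= 0)) return(NULL)
  peakIdx <- which(win)[which.max(corr[win])]
  # ties toward smaller lag
  cand <- which(win & corr == corr[peakIdx])
  peakIdx <- cand[which.min(abs(lags[cand]))]
  sdAll <- sd(corr[-peakIdx])
  z <- corr[peakIdx] / sdAll
  # peak width: contiguous bins above max(half height, 2 SD) with P < 0.01
  hthr <- max(corr[peakIdx] / 2, 2 * sdAll)
  above <- corr >= hthr & pPois < 0.01
  wlo <- peakIdx
  while (wlo > 1 && above[wlo - 1]) wlo <- wlo - 1
  whi <- peakIdx
  while (whi < length(lags) && above[whi + 1]) whi <- whi + 1
  widthMs <- (whi - wlo + 1) * (lags[2] - lags[1])
  inPeak <- seq(wlo, whi)
  passes <- c(
    lagInWindow = TRUE,
    height = z > peakSd,
    pval = pPois[peakIdx] < alphaPeak,
    width = widthMs < maxWidthMs,
    noZeroLag = !(0 %in% lags[inPeak]))
  # common-input guard: the mirror of the monosynaptic window (a blanket
  # test of every anticausal bin would trip on noise ~40% of the time)
  anticausal <- lags <= -window[1] & lags >= -window[2]
  excl <- any(corr[-inPeak] > 2.5 * sdAll) ||
    any(pPois[anticausal & !(seq_along(lags) %in% inPeak)] < 0.01)
  if (!all(passes) || excl) return(NULL)
  data.frame(lag = lags[peakIdx], z = z, p = pPois[peakIdx],
             width = widthMs,
             height = passes[["height"]], pval = passes[["pval"]],
             narrow = passes[["width"]], offZero = passes[["noZeroLag"]])
}

#' Tuning alignment of connected pairs
#'
#' For direction-tuned pairs the circular correlation between preferred
#' directions; for spatially tuned pairs the offset of the rate-map
#' cross-correlogram peak nearest the origin (direction and magnitude, the
#' latter also as a fraction of the grid spacing).
#'
#' @param mapA,mapB Spatial [TuningMap]s of the two cells.
#' @param spacing Module spacing, cm (for the relative offset).
#' @return List: `offsetXY` (cm), `offsetMag` (cm), `offsetDir` (rad),
#'   `offsetFrac` (of spacing, or NA).
#' @export
pairTuningAlignment <- function(mapA, mapB, spacing = NA) {
  cc <- spatialCrosscorr(mapA@rate, mapB@rate)
  pk <- localMaxima2(cc, thresh = 0)
  if (!nrow(pk)) return(list(offsetXY = c(NA, NA), offsetMag = NA,
                             offsetDir = NA, offsetFrac = NA))
  ctr <- (nrow(cc) + 1) / 2 # zero-lag bin (odd-sized by construction)
  dd <- sweep(pk, 2, c(ctr, ctr))
  j <- which.min(rowSums(dd^2))
  off <- dd[j, ] * mapA@binSize
  mag <- sqrt(sum(off^2))
  list(offsetXY = off, offsetMag = mag, offsetDir = atan2(off[2], off[1]),
       offsetFrac = if (is.na(spacing)) NA else mag / spacing)
}

#' Class-pair connection rates
#'
#' The number of detected connections from one functional class to another
#' divided by the number of tested pairs of that class combination.
#'
#' @param connections `data.frame` with `pre`, `post` (cell indices) of
#'   detected connections (0-row allowed).
#' @param tested `data.frame` with `pre`, `post` of all tested pairs.
#' @param labels Character vector of cell class labels.
#' @return `data.frame` per class pair: `from`, `to`, `nConn`, `nPairs`,
#'   `rate`.
#' @export
connectionRates <- function(connections, tested, labels) {
  key <- function(df) paste(labels[df$pre], labels[df$post], sep = "->")
  tk <- key(tested)
  ck <- if (nrow(connections)) key(connections) else character(0)
  allk <- sort(unique(tk))
  data.frame(
    pair = allk,
    from = sub("->.*", "", allk),
    to = sub(".*->", "", allk),
    nConn = as.integer(table(factor(ck, levels = allk))),
    nPairs = as.integer(table(factor(tk, levels = allk))),
    rate = as.numeric(table(factor(ck, levels = allk))) /
      as.numeric(table(factor(tk, levels = allk))),
    row.names = NULL)
}
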