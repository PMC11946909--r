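# Poisson GLM with basis-expanded covariates and a theta-phase-dependent
# shift of the position covariate along the internal-direction axis.

# Triangular grid of 2D Gaussian basis centres covering [xr, yr] plus a
# buffer zone (so fields may extend beyond the arena walls).
positionBasisDef <- function(xr, yr, spacing = 10, sigma = 2, buffer = 40) {
  dy <- spacing * sqrt(3) / 2
  ys <- seq(yr[1] - buffer, yr[2] + buffer, by = dy)
  centers <- do.call(rbind, lapply(seq_along(ys), function(j) {
    off <- if (j %% 2 == 0) spacing / 2 else 0
    xs <- seq(xr[1] - buffer + off, xr[2] + buffer, by = spacing)
    cbind(xs, ys[j])
  }))
  list(centers = centers, sigma = sigma)
}

evalPositionBasis <- function(def, x, y) {
  inv2s2 <- 1 / (2 * def$sigma^2)
  nc <- nrow(def$centers)
  out <- matrix(0, length(x), nc)
  for (j in seq_len(nc)) {
    out[, j] <- exp(-((x - def$centers[j, 1])^2 +
                        (y - def$centers[j, 2])^2) * inv2s2)
  }
  out
}

angularBasisDef <- function(n = 50, kappa = 10) {
  list(mu = seq(0, 2 * pi, length.out = n + 1)[-(n + 1)], kappa = kappa)
}

evalAngularBasis <- function(def, a) {
  out <- matrix(0, length(a), length(def$mu))
  for (j in seq_along(def$mu))
    out[, j] <- exp(def$kappa * (cos(a - def$mu[j]) - 1))
  out
}

# PCA reduction of a basis-expanded block, retaining components explaining
# `varFrac` of the variance; returns the projected block plus the projection
# (applied identically to re-evaluated bases during shifting).
pcaReduce <- function(B, varFrac) {
  pc <- prcomp(B, center = TRUE, scale. = FALSE)
  cum <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
  k <- max(1L, which(cum >= varFrac)[1])
  list(X = pc$x[, seq_len(k), drop = FALSE],
       rotation = pc$rotation[, seq_len(k), drop = FALSE],
       center = pc$center, k = k)
}

applyProjection <- function(B, proj)
  sweep(B, 2, proj$center) %*% proj$rotation

#' Build the GLM design matrix
#'
#' Basis-expands position (2D Gaussians, sigma = 2 cm, on a 10-cm triangular
#' grid covering the arena plus a 40 cm buffer), head direction, internal
#' direction and theta phase (50 von Mises functions each, kappa = 10), then
#' reduces each block by PCA: components explaining 99% of the variance are
#' retained for position and 80% for the angular blocks.
#'
#' @param session A [SweepSession].
#' @param internalDir Per-bin internal direction, rad.
#' @param theta Theta signal (uses `theta$phase`).
#' @param spacing,sigma,buffer Position-basis geometry, cm.
#' @param nAngular,kappaAngular Angular-basis size and concentration.
#' @return List with the concatenated design `X`, per-block column indices,
#'   basis definitions and projections (needed to re-evaluate the position
#'   block at shifted coordinates), and the bin selection used.
#' @export
buildDesign <- function(session, internalDir, theta, spacing = 10,
                        sigma = 2, buffer = 40, nAngular = 50,
                        kappaAngular = 10) {
  cd <- colData(session)
  sel <- which(cd$valid)
  posDef <- positionBasisDef(range(cd$x), range(cd$y), spacing, sigma,
                             buffer)
  angDef <- angularBasisDef(nAngular, kappaAngular)
  Bpos <- evalPositionBasis(posDef, cd$x[sel], cd$y[sel])
  pPos <- pcaReduce(Bpos, 0.99)
  blocks <- list(pos = pPos$X)
  projs <- list(pos = pPos)
  for (nm in c("id", "hd", "theta")) {
    a <- switch(nm, id = internalDir[sel], hd = cd$hd[sel],
                theta = theta$phase[sel])
    B <- evalAngularBasis(angDef, a)
    if (stats::sd(a) == 0) { # constant covariate -> no information
      blocks[[nm]] <- matrix(0, length(sel), 0)
      projs[[nm]] <- NULL
      next
    }
    p <- pcaReduce(B, 0.80)
    blocks[[nm]] <- p$X
    projs[[nm]] <- p
  }
  X <- do.call(cbind, blocks)
  idx <- split(seq_len(ncol(X)),
               rep(names(blocks), vapply(blocks, ncol, 0L)))
  list(X = X, blockIdx = idx, posDef = posDef, angDef = angDef,
       projs = projs, sel = sel,
       alpha = internalDir[sel], phase = theta$phase[sel],
       x = cd$x[sel], y = cd$y[sel])
}

poissonLoglik <- function(y, eta) sum(y * eta - exp(eta))

fitPoisson <- function(X, y) {
  fit <- suppressWarnings(glm.fit(cbind(1, X), y, family = poisson()))
  beta <- fit$coefficients
  beta[!is.finite(beta)] <- 0
  eta <- as.numeric(cbind(1, X) %*% beta)
  list(beta = beta, loglik = poissonLoglik(y, eta))
}

#' Fit the shift GLM for one cell
#'
#' Jointly fits the Poisson GLM coefficients and the theta-phase-dependent
#' shift of the position covariate: positions are displaced by
#' `delta(theta) = gamma0 + gamma . X_theta` along the per-bin internal
#' direction, the position basis is re-evaluated at the shifted coordinates
#' (same PCA projection), and the model is optimized by alternating convex
#' beta steps with BFGS steps on gamma (analytic chain-rule gradient through
#' the shifted basis) until the log-likelihood gain falls below `tol`.
#'
#' @param session A [SweepSession].
#' @param cell Cell index.
#' @param design Output of [buildDesign()].
#' @param maxOuter Maximum outer iterations.
#' @param tol Log-likelihood convergence tolerance.
#' @param fitShift Set `FALSE` for the nested gamma = 0 model.
#' @return A [ShiftGLMFit].
#' @export
fitShiftGLM <- function(session, cell, design, maxOuter = 12, tol = 1e-6,
                        fitShift = TRUE) {
  y <- spikeCounts(session)[cell, design$sel]
  thetaX <- design$X[, design$blockIdx$theta, drop = FALSE]
  ca <- cos(design$alpha); sa <- sin(design$alpha)
  rebuild <- function(gamma) {
    delta <- gamma[1] + as.numeric(thetaX %*% gamma[-1])
    Bp <- evalPositionBasis(design$posDef, design$x + delta * ca,
                            design$y + delta * sa)
    Xp <- applyProjection(Bp, design$projs$pos)
    X <- design$X
    X[, design$blockIdx$pos] <- Xp
    X
  }
  gamma <- rep(0, 1 + ncol(thetaX))
  fit0 <- fitPoisson(design$X, y)
  ll <- fit0$loglik
  beta <- fit0$beta
  trace <- ll
  converged <- FALSE
  centers <- design$posDef$centers
  sig2 <- design$posDef$sigma^2
  rot <- design$projs$pos$rotation
  posCols <- design$blockIdx$pos
  if (fitShift) {
    for (it in seq_len(maxOuter)) {
      # gamma step at fixed beta: BFGS on the profile likelihood with the
      # analytic chain-rule gradient through the shifted position basis
      nll <- function(g) {
        X <- rebuild(g)
        -poissonLoglik(y, as.numeric(cbind(1, X) %*% beta))
      }
      ngr <- function(g) {
        delta <- g[1] + as.numeric(thetaX %*% g[-1])
        xs <- design$x + delta * ca
        ys <- design$y + delta * sa
        Bp <- evalPositionBasis(design$posDef, xs, ys)
        Xp <- applyProjection(Bp, design$projs$pos)
        X <- design$X
        X[, posCols] <- Xp
        eta <- as.numeric(cbind(1, X) %*% beta)
        w <- y - exp(eta)
        # d eta / d delta_t = sum_j Bp_tj * (-(r_tj . u_t)/sigma^2) * v_j
        v <- as.numeric(rot %*% beta[1 + posCols]) # per-centre weight
        dd <- numeric(length(y))
        for (j in seq_len(nrow(centers))) {
          proj <- (xs - centers[j, 1]) * ca + (ys - centers[j, 2]) * sa
          dd <- dd - Bp[, j] * proj * v[j] / sig2
        }
        wd <- w * dd
        -c(sum(wd), as.numeric(crossprod(thetaX, wd)))
      }
      opt <- tryCatch(
        stats::optim(gamma, nll, gr = ngr, method = "BFGS",
                     control = list(maxit = 8, reltol = 1e-8)),
        error = function(e) NULL)
      if (!is.null(opt) && is.finite(opt$value)) gamma <- opt$par
      # beta step at fixed gamma (convex)
      X <- rebuild(gamma)
      fb <- fitPoisson(X, y)
      if (!is.finite(fb$loglik) || fb$loglik < ll - 1e-6) {
        # divergence: fall back to the gamma = 0 fit
        gamma <- rep(0, length(gamma))
        beta <- fit0$beta
        trace <- c(trace, fit0$loglik)
        break
      }
      beta <- fb$beta
      gain <- fb$loglik - ll
      ll <- fb$loglik
      trace <- c(trace, ll)
      if (gain < tol) { converged <- TRUE; break }
    }
  } else converged <- TRUE
  new("ShiftGLMFit", beta = beta, gamma = gamma, loglik = trace,
      converged = converged,
      design = list(blockIdx = design$blockIdx, posDef = design$posDef,
                    angDef = design$angDef, projs = design$projs))
}

#' Shift profile delta(theta) of a fitted model
#'
#' @param fit A [ShiftGLMFit].
#' @param phases Theta phases at which to evaluate, rad.
#' @return Shift in cm at each phase.
#' @export
shiftProfile <- function(fit, phases = seq(0, 2 * pi, length.out = 73)) {
  B <- evalAngularBasis(fit@design$angDef, phases)
  Xt <- applyProjection(B, fit@design$projs$theta)
  as.numeric(fit@gamma[1] + Xt %*% fit@gamma[-1])
}

#' Rate map against shifted coordinates
#'
#' Recomputes a cell's rate map after displacing each position sample by the
#' fitted delta(theta) along the internal direction, yielding the
#' sweep-corrected ("sharpened") tuning map.
#'
#' @param fit A [ShiftGLMFit].
#' @param session A [SweepSession].
#' @param internalDir,theta As passed to [buildDesign()].
#' @param cell Cell index.
#' @param sigma Smoothing, cm.
#' @param binSize Bin side, cm.
#' @return A [TuningMap].
#' @export
shiftedRateMap <- function(fit, session, cell, internalDir, theta,
                           sigma = 5, binSize = 2.5) {
  cd <- colData(session)
  B <- evalAngularBasis(fit@design$angDef, theta$phase)
  Xt <- applyProjection(B, fit@design$projs$theta)
  delta <- as.numeric(fit@gamma[1] + Xt %*% fit@gamma[-1])
  shifted <- session
  cd2 <- colData(shifted)
  cd2$x <- cd$x + delta * cos(internalDir)
  cd2$y <- cd$y + delta * sin(internalDir)
  colData(shifted) <- cd2
  rateMap(shifted, cell, "spatial", sigma = sigma, binSize = binSize)
}

#' Spatial information content of a rate map (bits/spike)
#'
#' Skaggs information, used to compare shifted and unshifted maps.
#'
#' @param map A spatial [TuningMap].
#' @return Bits per spike.
#' @export
spatialInformation <- function(map) {
  r <- as.numeric(map@rate); occ <- as.numeric(map@occupancy)
  ok <- is.finite(r) & occ > 0
  p <- occ[ok] / sum(occ[ok])
  rr <- r[ok]
  rbar <- sum(p * rr)
  if (rbar == 0) return(0)
  sum(p * rr / rbar * log2(pmax(rr / rbar, 1e-12)), na.rm = TRUE)
}
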