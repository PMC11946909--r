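#' Wrap angles to (-pi, pi]
#'
#' @param a Numeric vector of angles in radians.
#' @return Angles wrapped to the interval (-pi, pi].
#' @examples
#' wrapAngle(c(0, 3 * pi, -3 * pi / 2))
#' @export
wrapAngle <- function(a) {
  w <- (a + pi) %% (2 * pi) - pi
  w[w == -pi] <- pi
  w
}

#' Circular mean and resultant length
#'
#' `circMean()` returns the direction of the resultant vector of a sample of
#' angles; `circR()` its mean resultant length. Optional weights give the
#' weighted versions (weights may be negative, as for correlation-weighted
#' decoding averages).
#'
#' @param a Angles in radians.
#' @param w Optional weights.
#' @return `circMean()`: a single angle in (-pi, pi]; `circR()`: a value in
#'   `[0, 1]` (unweighted case).
#' @export
circMean <- function(a, w = NULL) {
  if (is.null(w)) w <- rep(1, length(a))
  Arg(sum(w * exp(1i * a)))
}

#' @rdname circMean
#' @export
circR <- function(a, w = NULL) {
  if (is.null(w)) w <- rep(1, length(a))
  Mod(sum(w * exp(1i * a))) / sum(abs(w))
}

#' Rayleigh test for circular non-uniformity
#'
#' Tests the null hypothesis that angles are uniformly distributed on the
#' circle, using the standard large-sample approximation of the Rayleigh
#' statistic with the small-sample correction of Zar.
#'
#' @param a Angles in radians.
#' @param w Optional non-negative weights (e.g. per-bin firing rates); the
#'   effective sample size is then `sum(w)`.
#' @return A list with elements `r` (mean resultant length), `z` (Rayleigh
#'   statistic) and `p.value`.
#' @export
rayleighTest <- function(a, w = NULL) {
  if (is.null(w)) w <- rep(1, length(a))
  n <- sum(w)
  r <- Mod(sum(w * exp(1i * a))) / n
  z <- n * r^2
  p <- exp(-z) * (1 + (2 * z - z^2) / (4 * n) -
                    (24 * z - 132 * z^2 + 76 * z^3 - 9 * z^4) / (288 * n^2))
  list(r = r, z = z, p.value = max(min(p, 1), 0))
}

#' Circular-circular correlation (Fisher-Lee)
#'
#' The pairwise T-linear circular correlation coefficient of Fisher and Lee:
#' \deqn{r = \frac{\sum_{i<j} \sin(a_i - a_j)\sin(b_i - b_j)}
#'   {\sqrt{\sum_{i<j}\sin^2(a_i - a_j)\sum_{i<j}\sin^2(b_i - b_j)}}}
#' evaluated in O(n) via resultant-vector identities; unlike the
#' mean-centred approximation it remains valid when the marginals are
#' (near-)uniform on the circle, as phase signals are.
#'
#' @param a,b Paired angles in radians.
#' @return Correlation in `[-1, 1]`, `NA` if degenerate.
#' @export
circCorr <- function(a, b) {
  ok <- is.finite(a) & is.finite(b)
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  if (n < 3) return(NA_real_)
  sMinus <- Mod(sum(exp(1i * (a - b))))^2
  sPlus <- Mod(sum(exp(1i * (a + b))))^2
  a2 <- Mod(sum(exp(2i * a)))^2
  b2 <- Mod(sum(exp(2i * b)))^2
  den <- sqrt((n^2 - a2) * (n^2 - b2))
  if (den == 0) return(NA_real_)
  (sMinus - sPlus) / den
}

#' Circular-linear correlation (Kempter et al.)
#'
#' Correlation between a circular variable (e.g. theta phase) and a linear
#' variable (e.g. in-field position), obtained by fitting the regression
#' phase ~ 2*pi*s*x + b and reporting the circular correlation between the
#' observed and fitted phases, with the sign of the fitted slope. The p-value
#' comes from the associated large-sample test.
#'
#' @param phase Circular variable, radians.
#' @param x Linear variable.
#' @param slopeRange Range of candidate slopes (cycles per unit of `x`) over
#'   which the resultant-length criterion is maximized.
#' @return List with `rho` (signed correlation), `slope` (cycles per unit
#'   `x`) and `p.value`.
#' @export
circLinCorr <- function(phase, x, slopeRange = c(-0.1, 0.1)) {
  ok <- is.finite(phase) & is.finite(x)
  phase <- phase[ok]; x <- x[ok]
  n <- length(phase)
  if (n < 5) return(list(rho = NA_real_, slope = NA_real_, p.value = NA_real_))
  # maximize resultant length of (phase - 2 pi s x) over s
  rl <- function(s) -Mod(mean(exp(1i * (phase - 2 * pi * s * x))))
  opt <- optimize(rl, interval = slopeRange)
  s <- opt$minimum
  fitted <- wrapAngle(2 * pi * s * x)
  ph <- wrapAngle(phase)
  sa <- sin(ph - circMean(ph))
  sb <- sin(fitted - circMean(fitted))
  den <- sqrt(sum(sa^2) * sum(sb^2))
  rho <- if (den == 0) 0 else sum(sa * sb) / den
  # report with the sign of the regression slope (field convention: phase
  # precession = negative circular-linear correlation)
  rho <- abs(rho) * sign(s)
  # large-sample test (Kempter et al. 2012, eq. 5)
  l20 <- mean(sa^2); l02 <- mean(sb^2); l22 <- mean(sa^2 * sb^2)
  zstat <- if (l22 > 0) rho * sqrt(n * l20 * l02 / l22) else 0
  p <- 2 * (1 - pnorm(abs(zstat)))
  list(rho = rho, slope = s, p.value = p)
}

#' Evaluate a von Mises tuning function
#'
#' Unnormalized von Mises bump `exp(kappa * (cos(a - mu) - 1))`, scaled so its
#' peak value is 1 at `a = mu`.
#'
#' @param a Angles, radians.
#' @param mu Preferred angle, radians.
#' @param kappa Concentration.
#' @return Values in `(0, 1]`.
#' @export
vonMisesBump <- function(a, mu, kappa) exp(kappa * (cos(a - mu) - 1))
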