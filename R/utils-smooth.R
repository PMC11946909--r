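# Smoothing and signal helpers shared across modules.

#' Gaussian smoothing of a regularly sampled signal
#'
#' Convolves a vector with a Gaussian kernel. `sigma` is expressed in samples.
#' NA values are handled by normalized convolution (missing samples get zero
#' weight), and `circular = TRUE` wraps the signal (for angular histograms).
#'
#' @param x Numeric vector (may contain NA).
#' @param sigma Kernel width in samples; 0 returns `x` unchanged.
#' @param circular Wrap around the ends?
#' @return Smoothed vector, same length.
#' @export
gaussSmooth <- function(x, sigma, circular = FALSE) {
  if (sigma <= 0) return(x)
  half <- max(1L, ceiling(4 * sigma))
  k <- exp(-0.5 * ((-half:half) / sigma)^2)
  k <- k / sum(k)
  n <- length(x)
  w <- as.numeric(is.finite(x))
  x0 <- ifelse(is.finite(x), x, 0)
  if (circular) {
    pad <- function(v) c(tail(v, half), v, head(v, half))
    num <- filter(pad(x0), k, sides = 2)[(half + 1):(half + n)]
    den <- filter(pad(w), k, sides = 2)[(half + 1):(half + n)]
  } else {
    num <- filter(c(rep(0, half), x0, rep(0, half)), k,
                  sides = 2)[(half + 1):(half + n)]
    den <- filter(c(rep(0, half), w, rep(0, half)), k,
                  sides = 2)[(half + 1):(half + n)]
  }
  out <- as.numeric(num) / as.numeric(den)
  out[den == 0] <- NA
  out
}

#' Gaussian smoothing of a 2D field
#'
#' Separable Gaussian smoothing with NA-aware normalized convolution:
#' unvisited bins (NA) contribute no weight and remain NA only if no mass
#' reaches them.
#'
#' @param m Numeric matrix.
#' @param sigma Kernel width in bins.
#' @return Smoothed matrix.
#' @export
gaussSmooth2 <- function(m, sigma) {
  if (sigma <= 0) return(m)
  sm <- function(mm) t(apply(mm, 1, gaussSmooth, sigma = sigma))
  w <- matrix(as.numeric(is.finite(m)), nrow(m))
  m0 <- ifelse(is.finite(m), m, 0)
  num <- sm(t(sm(m0))); num <- t(num)
  den <- sm(t(sm(w))); den <- t(den)
  out <- num / den
  out[den == 0] <- NA
  out
}

# Zero-phase Butterworth bandpass (uses signal::butter + filtfilt).
bandpassFilter <- function(x, low, high, fs, order = 2) {
  ny <- fs / 2
  bf <- signal::butter(order, c(low, high) / ny, type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

# Analytic-signal amplitude via FFT (Hilbert envelope).
hilbertAmplitude <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  Mod(fft(X * h, inverse = TRUE) / n)
}

# Linear interpolation of an (x, y) path at m equally spaced arc positions
# of its ordered samples (used for 50-point sweep resampling).
resamplePath <- function(x, y, m = 50) {
  n <- length(x)
  if (n == 1) return(cbind(x = rep(x, m), y = rep(y, m)))
  s <- seq(1, n, length.out = m)
  cbind(x = approx(seq_len(n), x, xout = s)$y,
        y = approx(seq_len(n), y, xout = s)$y)
}
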