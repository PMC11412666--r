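# Shared numerical helpers (internal).

# Analytic signal via the frequency-domain Hilbert transform.
analyticSignal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

# Fourier-domain resampling (band-limited interpolation): zero-phase and
# implicitly anti-aliasing. Returns round(n * rateOut/rateIn) samples.
fftResample <- function(x, rateIn, rateOut) {
  n <- length(x)
  m <- max(1L, round(n * rateOut / rateIn))
  if (m == n) return(x)
  X <- stats::fft(x)
  Y <- complex(m)
  keep <- min(n, m)
  half <- floor((keep - 1) / 2)
  Y[1] <- X[1]
  if (half > 0) {
    Y[2:(half + 1)] <- X[2:(half + 1)]
    Y[(m - half + 1):m] <- X[(n - half + 1):n]
  }
  if (keep %% 2 == 0) { # split the Nyquist bin symmetrically when shrinking
    ny <- X[keep / 2 + 1]
    if (m < n) {
      Y[keep / 2 + 1] <- ny / 2
      Y[m - keep / 2 + 1] <- Conj(ny) / 2
    } else Y[keep / 2 + 1] <- ny
  }
  Re(stats::fft(Y, inverse = TRUE)) * (m / n) / m
}

# Full linear convolution via FFT: length(x) + length(k) - 1 values,
# y[t] = sum_j k[j] x[t - j + 1].
fftConv <- function(x, k) {
  n <- length(x) + length(k) - 1L
  m <- stats::nextn(n, 2)
  y <- Re(stats::fft(stats::fft(c(x, numeric(m - length(x)))) *
                       stats::fft(c(k, numeric(m - length(k)))),
                     inverse = TRUE)) / m
  y[seq_len(n)]
}

# Causal filtering: y[t] = sum_j k[j] x[t - j + 1] (k[1] acts at lag 0).
causalFilter <- function(x, k) fftConv(x, k)[seq_along(x)]

# Apply an odd-length linear-phase FIR kernel with group-delay compensation,
# i.e. zero-phase single-pass filtering with zero padding at the edges.
firZeroPhase <- function(x, b) {
  stopifnot(length(b) %% 2 == 1)
  half <- (length(b) - 1L) / 2L
  fftConv(x, b)[(half + 1L):(half + length(x))]
}

# Hamming-rule FIR length for a given transition width (Hz): N ~ 3.3 / (df/fs),
# forced odd.
firLength <- function(rate, transitionHz) {
  n <- ceiling(3.3 * rate / transitionHz)
  if (n %% 2 == 0) n <- n + 1
  as.integer(n)
}

# Band-limited 1/f ("pink") Gaussian noise, power ~ 1/f inside [lo, hi] Hz,
# zero outside; unit variance.
pinkNoise <- function(n, rate, lo = 1, hi = 15) {
  freqs <- seq(0, rate / 2, length.out = floor(n / 2) + 1)
  amp <- numeric(length(freqs))
  inband <- freqs >= lo & freqs <= hi
  amp[inband] <- 1 / sqrt(freqs[inband])
  phase <- stats::runif(length(freqs), 0, 2 * pi)
  spec <- amp * exp(1i * phase)
  full <- complex(n)
  full[seq_along(freqs)] <- spec
  if (n %% 2 == 0) {
    full[(n / 2 + 2):n] <- Conj(spec[(n / 2):2])
  } else {
    full[(floor(n / 2) + 2):n] <- Conj(spec[(floor(n / 2) + 1):2])
  }
  x <- Re(stats::fft(full, inverse = TRUE))
  s <- stats::sd(x)
  if (s == 0) x else x / s
}

#' Log-spaced grid
#'
#' @param lo,hi endpoints (inclusive).
#' @param n number of points.
#' @return numeric vector.
#' @export
logspace <- function(lo, hi, n) exp(seq(log(lo), log(hi), length.out = n))

# Column z-scoring with externally supplied statistics; sd 0 columns are
# centered only.
zscoreFit <- function(m) {
  mu <- colMeans(m)
  sd <- apply(m, 2L, stats::sd)
  sd[sd == 0 | !is.finite(sd)] <- 1
  list(center = mu, scale = sd)
}

# Column-wise, modifying one column at a time to avoid whole-matrix
# temporaries on large embedded designs.
zscoreApply <- function(m, stats) {
  for (j in seq_len(ncol(m)))
    m[, j] <- (m[, j] - stats$center[j]) / stats$scale[j]
  m
}

# Per-column Pearson correlation of two equally shaped matrices; zero-variance
# columns give 0 with a warning.
colCorr <- function(a, b, warn = TRUE) {
  a <- as.matrix(a); b <- as.matrix(b)
  stopifnot(identical(dim(a), dim(b)))
  ac <- sweep(a, 2L, colMeans(a))
  bc <- sweep(b, 2L, colMeans(b))
  num <- colSums(ac * bc)
  den <- sqrt(colSums(ac^2) * colSums(bc^2))
  bad <- den == 0
  r <- numeric(ncol(a))
  r[!bad] <- num[!bad] / den[!bad]
  if (any(bad)) {
    if (warn) warning("zero-variance column(s); correlation reported as 0")
    r[bad] <- 0
  }
  pmin(1, pmax(-1, r))
}

# Derive a child seed from a base seed and a stream index (kept < 2^31).
childSeed <- function(seed, k) {
  as.integer((as.double(seed) * 7919 + as.double(k) * 104729) %% 2147483647)
}
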