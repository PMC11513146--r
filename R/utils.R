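`%||%` <- function(a, b) if (is.null(a)) b else a

#' Discrete Gaussian kernel
#'
#' @param sigma kernel standard deviation, in samples/bins.
#' @param radius half-width in samples; defaults to 4 sigma.
#' @return normalized kernel vector of odd length.
#' @keywords internal
gaussian_kernel <- function(sigma, radius = ceiling(4 * sigma)) {
  x <- seq.int(-radius, radius)
  k <- exp(-0.5 * (x / sigma)^2)
  k / sum(k)
}

#' Gaussian smoothing with edge renormalization
#'
#' Convolves `x` with a truncated Gaussian; near the edges the kernel mass
#' falling outside the signal is renormalized away so means are preserved.
#'
#' @param x numeric vector.
#' @param sigma kernel s.d. in samples; `sigma <= 0` returns `x` unchanged.
#' @return smoothed vector, same length as `x`.
#' @export
gauss_smooth <- function(x, sigma) {
  if (sigma <= 0) return(x)
  k <- gaussian_kernel(sigma)
  n <- length(x)
  r <- (length(k) - 1L) / 2L
  # direct convolution via stats::filter (predictable O(n * taps); FFT
  # convolution degrades badly at awkward lengths), edges renormalized
  xp <- c(rep(0, r), x, rep(0, r))
  wp <- c(rep(0, r), rep(1, n), rep(0, r))
  num <- stats::filter(xp, k, method = "convolution", sides = 2)
  den <- stats::filter(wp, k, method = "convolution", sides = 2)
  as.numeric((num / den)[(r + 1L):(r + n)])
}

# Derive a set of reproducible sub-seeds (< 2^31) from one master seed.
derive_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

# First index of each run of at least `min_len` consecutive TRUEs; 0 if none.
first_run_start <- function(flags, min_len) {
  flags[is.na(flags)] <- FALSE
  r <- rle(flags)
  ends <- cumsum(r$lengths)
  hit <- which(r$values & r$lengths >= min_len)
  if (!length(hit)) return(0L)
  ends[hit[1]] - r$lengths[hit[1]] + 1L
}

# Raised-cosine band-pass gain as a function of absolute frequency.
band_gain <- function(af, lo, hi, transition) {
  g <- numeric(length(af))
  g[af >= lo & af <= hi] <- 1
  rl <- af > (lo - transition) & af < lo
  g[rl] <- 0.5 * (1 - cos(pi * (af[rl] - (lo - transition)) / transition))
  rh <- af > hi & af < (hi + transition)
  g[rh] <- 0.5 * (1 + cos(pi * (af[rh] - hi) / transition))
  g
}

#' Zero-phase FFT band-pass filter (optionally returning the analytic signal)
#'
#' Filters in the frequency domain with raised-cosine band edges; zero phase
#' by construction.  With `analytic = TRUE` the negative frequencies are
#' zeroed and positive doubled, so the modulus of the returned complex
#' signal is the Hilbert envelope of the band-passed trace.
#'
#' @param x numeric vector (a continuous LFP segment).
#' @param fs sampling rate in Hz.
#' @param lo,hi pass-band edges in Hz.
#' @param transition transition-band width in Hz.
#' @param analytic return the complex analytic signal instead of the real
#'   filtered trace.
#' @return numeric (or complex) vector of `length(x)`.
#' @export
fft_bandpass <- function(x, fs, lo, hi, transition = 10, analytic = FALSE) {
  n <- length(x)
  if (n == 0L) return(x)
  bad <- which(!is.finite(x))
  if (length(bad)) {
    stop("non-finite sample in input at index ", bad[1])
  }
  nf <- stats::nextn(n, c(2L, 3L, 5L))
  xp <- c(x - mean(x), rep(0, nf - n))
  X <- stats::fft(xp)
  fr <- seq_len(nf) - 1L
  af <- pmin(fr, nf - fr) * fs / nf   # absolute frequency per FFT bin
  g <- band_gain(af, lo, hi, transition)
  if (analytic) {
    h <- numeric(nf)
    h[1] <- 1
    if (nf %% 2 == 0) {
      h[nf / 2 + 1] <- 1
      h[2:(nf / 2)] <- 2
    } else {
      h[2:((nf + 1) / 2)] <- 2
    }
    y <- stats::fft(X * g * h, inverse = TRUE) / nf
    return(y[seq_len(n)])
  }
  Re(stats::fft(X * g, inverse = TRUE) / nf)[seq_len(n)]
}

#' Causal windowed-sinc FIR band-pass coefficients
#'
#' Hamming-windowed sinc design; linear phase with group delay
#' `(n_taps - 1) / 2` samples.  Used for the closed-loop (streaming)
#' ripple trigger, where only past samples may be touched.
#'
#' @param n_taps odd number of taps.
#' @param fs sampling rate (Hz).
#' @param lo,hi band edges (Hz).
#' @return numeric coefficient vector.
#' @export
fir_bandpass <- function(n_taps, fs, lo, hi) {
  stopifnot(n_taps %% 2 == 1, hi > lo, hi < fs / 2)
  m <- (n_taps - 1L) / 2L
  t <- seq.int(-m, m)
  sinc_lp <- function(fc) {
    h <- sin(2 * pi * fc / fs * t) / (pi * t)
    h[m + 1L] <- 2 * fc / fs
    h
  }
  h <- sinc_lp(hi) - sinc_lp(lo)
  w <- 0.54 + 0.46 * cos(pi * t / m)
  h * w
}

# Causal FIR application; the first n_taps-1 outputs (filter warm-up) are 0.
causal_filter <- function(x, h) {
  y <- stats::filter(x, h, method = "convolution", sides = 1)
  y[is.na(y)] <- 0
  as.numeric(y)
}

# Pearson correlation that returns NA (without warnings) on zero variance.
safe_cor <- function(a, b, method = "pearson") {
  if (length(a) < 3L || stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
  stats::cor(a, b, method = method)
}

# Count, for each half-open window [lo[i], hi[i]), the number of sorted
# event times falling inside.  Vectorized over windows.
count_in_windows <- function(times, lo, hi) {
  findInterval(hi, times, left.open = TRUE) -
    findInterval(lo, times, left.open = TRUE)
}
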