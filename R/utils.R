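# Internal numerical helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's RNG
# state. All stochastic operations in the package funnel through this.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  withr::with_seed(as.integer(seed), code)
}

# Analytic signal by the FFT construction: double positive frequencies,
# zero negative ones, keep DC (and Nyquist for even n).
analytic_signal <- function(x) {
  n <- length(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1L, n / 2L + 1L)] <- 1
    h[2:(n / 2L)] <- 2
  } else {
    h[1L] <- 1
    h[2:((n + 1L) / 2L)] <- 2
  }
  fft(fft(x) * h, inverse = TRUE) / n
}

# Frequency axis (Hz) of an n-point DFT at sampling rate fs; two-sided,
# matching R's fft() bin order.
fft_freqs <- function(n, fs) {
  k <- seq_len(n) - 1L
  f <- k / n * fs
  f[f > fs / 2] <- f[f > fs / 2] - fs
  f
}

# Zero-phase ideal band extraction: returns the component of x whose DFT
# support lies in [f_lo, f_hi] (absolute frequency). Exact and zero-phase;
# used for the narrow 2.2-2.7 Hz notch where IIR band-stops are fragile.
fft_band_component <- function(x, fs, f_lo, f_hi) {
  n <- length(x)
  f <- abs(fft_freqs(n, fs))
  mask <- as.numeric(f >= f_lo & f <= f_hi)
  Re(fft(fft(x) * mask, inverse = TRUE) / n)
}

# Unit-variance 1/f^alpha ("pink" at alpha = 1) noise by spectral shaping of
# white Gaussian noise.
pink_noise <- function(n, alpha = 1) {
  if (n < 2) return(rnorm(n))
  w <- rnorm(n)
  sp <- fft(w)
  f <- abs(fft_freqs(n, 1))
  scale <- ifelse(f > 0, f^(-alpha / 2), 0)
  x <- Re(fft(sp * scale, inverse = TRUE) / n)
  x <- x - mean(x)
  s <- sd(x)
  if (s > 0) x / s else x
}

# Zero-phase Butterworth band-pass (4th order, forward-backward).
butter_filtfilt <- function(x, fs, band, type = "pass", order = 4L) {
  w <- band / (fs / 2)
  flt <- signal::butter(order, w, type = type)
  signal::filtfilt(flt, x)
}

stopf <- function(...) abort(sprintf(...))
warnf <- function(...) warn(sprintf(...))
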