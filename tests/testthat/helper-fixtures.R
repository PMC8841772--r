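# Shared fixtures, built in code at test time.

# Small speckle A-line segment from explicit scatterers (closed form), so
# fractional shifts can be imposed exactly by re-evaluating at shifted
# scatterer positions.
speckle_segment <- function(n = 128, n_scat = 25, shift = 0, seed = 42,
                            dz = 0.0385, lambda = 0.308, sigma = 0.077) {
  set.seed(seed)
  z <- (seq_len(n) - 1) * dz
  zi <- runif(n_scat, min(z) + 0.3, max(z) - 0.3) + shift * dz
  ai <- rnorm(n_scat)
  colSums(ai * exp(-0.5 * outer(zi, z, "-")^2 / sigma^2) *
            cos(4 * pi * outer(zi, z, "-") / lambda))
}

# Brute-force NCC oracle on an `up`-times upsampled lag grid: band-limited
# (FFT zero-padding) upsampling of both segments, integer-lag NCC on the
# fine grid, argmax returned in original-sample units.
brute_force_lag <- function(ref, cur, max_lag, up = 100) {
  fft_upsample <- function(x, up) {
    n <- length(x)
    X <- stats::fft(x)
    m <- n * up
    Y <- complex(m)
    half <- floor(n / 2)
    Y[1:(half + 1)] <- X[1:(half + 1)]
    if (half > 1) Y[(m - half + 2):m] <- X[(n - half + 2):n]
    Re(stats::fft(Y, inverse = TRUE)) * up / m * up
  }
  r <- fft_upsample(ref, up); cu <- fft_upsample(cur, up)
  n <- length(r); m <- length(cu)
  off <- (m - n) %/% 2
  lags <- seq(-max_lag * up, max_lag * up)
  vals <- vapply(lags, function(l) {
    s <- off + l
    i0 <- max(1, 1 - s); i1 <- min(n, m - s)
    if (i1 - i0 < 16) return(-Inf)
    a <- r[i0:i1]; b <- cu[(i0 + s):(i1 + s)]
    suppressWarnings(stats::cor(a, b))
  }, numeric(1))
  lags[which.max(vals)] / up
}

# Tiny wall field for fast tests.
small_field <- function(pwv = 5, duration = 1.0, n_cycles = 1,
                        frame_rate = 1000, n_positions = 16, ...) {
  generate_wall_displacement_field(
    pwv_true = pwv, duration = duration, n_cycles = n_cycles,
    frame_rate = frame_rate, n_positions = n_positions, ...)
}
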