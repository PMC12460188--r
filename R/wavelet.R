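#' Logarithmic scale grid for the analytic Morlet wavelet
#'
#' Builds the geometric scale/frequency grid used by the continuous wavelet
#' transform and all downstream coherence computations. Scales are spaced at
#' `2^(1/voices)` so that `voices` scales cover one frequency octave; the
#' number of scales is `floor(voices * log2(f_max / f_min)) + 1`. Frequencies
#' are ordered high to low (small to large scale) throughout the package.
#'
#' The scale/frequency correspondence uses the standard Fourier factor of the
#' analytic Morlet wavelet with centre frequency `omega0` (radians):
#' `lambda = 4 * pi / (omega0 + sqrt(2 + omega0^2))`, `f = 1 / (lambda * s)`.
#'
#' @param f_min,f_max Frequency limits in Hz; `f_max` must lie strictly below
#'   the Nyquist frequency `1 / (2 * dt)`.
#' @param voices Voices per octave (scales per frequency doubling).
#' @param dt Sampling interval in seconds (the fMRI TR for BOLD series).
#' @param omega0 Morlet centre frequency in radians; 6 is the conventional
#'   default for which the wavelet is numerically admissible.
#' @return An object of class `scale_grid`: a list with `frequencies` (Hz,
#'   descending), `scales` (seconds, ascending), `periods` (s), `voices`,
#'   `dt`, `omega0`, `fourier_factor` and `n_scales`.
#' @examples
#' g <- build_scale_grid(0.0039, 0.2894, voices = 12, dt = 1.5)
#' g$n_scales # 75
#' @export
build_scale_grid <- function(f_min, f_max, voices = 12, dt = 1.5, omega0 = 6) {
  if (!is.numeric(f_min) || f_min <= 0) {
    abort("`f_min` must be a positive frequency in Hz.", class = "dyadcoh_domain_error")
  }
  if (f_max < f_min) {
    abort("`f_max` must be >= `f_min`.", class = "dyadcoh_domain_error")
  }
  nyquist <- 1 / (2 * dt)
  if (f_max >= nyquist) {
    abort(
      sprintf("`f_max` (%.4g Hz) must lie below the Nyquist frequency %.4g Hz.", f_max, nyquist),
      class = "dyadcoh_grid_error"
    )
  }
  if (voices < 1) abort("`voices` must be >= 1.", class = "dyadcoh_domain_error")

  n_scales <- floor(voices * log2(f_max / f_min)) + 1
  freqs <- f_max * 2^(-(seq_len(n_scales) - 1) / voices)
  lambda <- 4 * pi / (omega0 + sqrt(2 + omega0^2))
  scales <- 1 / (lambda * freqs)
  structure(
    list(
      frequencies = freqs,
      scales = scales,
      periods = 1 / freqs,
      voices = voices,
      dt = dt,
      omega0 = omega0,
      fourier_factor = lambda,
      n_scales = as.integer(n_scales)
    ),
    class = "scale_grid"
  )
}

#' @export
print.scale_grid <- function(x, ...) {
  cat(sprintf(
    "<scale_grid> %d scales, %g voices/octave, %.4g-%.4g mHz, dt = %g s\n",
    x$n_scales, x$voices, 1000 * min(x$frequencies), 1000 * max(x$frequencies), x$dt
  ))
  invisible(x)
}

# padded FFT length: record plus twice the largest kernel half-width, so
# circular convolution never wraps signal into signal
.pad_length <- function(n, max_halfwidth) {
  2^ceiling(log2(n + 2 * max_halfwidth + 1))
}

# frequency response of the L2-normalised analytic Morlet daughters on the
# padded DFT grid; one column per scale. Matches the time-domain sampling
# (dt / sqrt(s)) * conj(psi((m - n) dt / s)) with psi(t) = pi^(-1/4)
# exp(i omega0 t - t^2 / 2).
.morlet_filters <- function(grid, npad) {
  w <- 2 * pi * seq(0, npad - 1) / (npad * grid$dt)
  w[w > pi / grid$dt] <- 0 # negative frequencies: analytic wavelet is zero there
  pos <- w > 0
  out <- matrix(0, npad, grid$n_scales)
  for (j in seq_len(grid$n_scales)) {
    s <- grid$scales[j]
    out[pos, j] <- sqrt(s) * sqrt(2 * pi) * pi^(-0.25) *
      exp(-0.5 * (s * w[pos] - grid$omega0)^2)
  }
  out
}

# internal CWT: returns time x scale complex matrix (transposed relative to the
# public surface, which is scale x time) so mvfft batches across scales
.cwt_engine <- function(x, grid, filters = NULL, npad = NULL) {
  n <- length(x)
  if (is.null(npad)) {
    halfw <- min(ceiling(5 * max(grid$scales) / grid$dt), n)
    npad <- .pad_length(n, halfw)
  }
  if (is.null(filters)) filters <- .morlet_filters(grid, npad)
  xp <- c(x - mean(x), rep(0, npad - n))
  xh <- fft(xp)
  W <- mvfft(filters * xh, inverse = TRUE) / npad
  W[seq_len(n), , drop = FALSE]
}

#' Continuous wavelet transform with the analytic Morlet wavelet
#'
#' Computes the CWT by frequency-domain convolution with L2-normalised
#' analytic Morlet daughter wavelets, zero-padding to the next power of two
#' past the wavelet support so no periodic wrap-around occurs. The signal mean
#' is removed before transforming; amplitudes are otherwise untouched.
#'
#' @param x Real numeric series (length >= 8), sampled at `grid$dt`.
#' @param grid A [build_scale_grid()] object.
#' @return A `wavelet_field`: list with `coefficients` (complex, scale x time,
#'   scales ordered high to low frequency), `grid` and `n_samples`.
#' @export
cwt_morlet <- function(x, grid) {
  if (!inherits(grid, "scale_grid")) abort("`grid` must be a scale_grid.")
  if (!is.numeric(x) || length(x) < 8) {
    abort("`x` must be a numeric series of length >= 8.", class = "dyadcoh_domain_error")
  }
  if (!all(is.finite(x))) {
    abort("`x` contains non-finite values.", class = "dyadcoh_domain_error")
  }
  W <- .cwt_engine(x, grid)
  structure(
    list(coefficients = t(W), grid = grid, n_samples = length(x)),
    class = "wavelet_field"
  )
}

#' Cone of influence mask
#'
#' A point (scale s, time t) lies inside the cone of influence when its
#' distance from the nearer record edge is at least `sqrt(2) * s`, the
#' e-folding time of the Morlet Gaussian envelope; outside it, edge effects
#' dominate and coefficients should not be interpreted.
#'
#' @param grid A [build_scale_grid()] object.
#' @param n_samples Number of time samples in the record.
#' @return Logical matrix (scale x time), `TRUE` inside the cone.
#' @export
cone_of_influence <- function(grid, n_samples) {
  if (n_samples < 2) abort("`n_samples` must be >= 2.", class = "dyadcoh_domain_error")
  idx <- seq_len(n_samples) - 1
  edge_dist <- pmin(idx, n_samples - 1 - idx) * grid$dt
  outer(sqrt(2) * grid$scales, edge_dist, FUN = "<=")
}

# Gaussian time-smoothing kernels (one per scale) in wrap-around layout on the
# padded grid, plus their FFTs; half-widths truncated at 5 standard deviations
.time_kernel_ffts <- function(grid, npad, n) {
  ks <- matrix(0, npad, grid$n_scales)
  max_half <- npad - n # no wrap of in-record mass
  for (j in seq_len(grid$n_scales)) {
    s_samp <- grid$scales[j] / grid$dt
    half <- min(max(1L, ceiling(5 * s_samp)), max_half)
    g <- exp(-0.5 * ((0:half) / s_samp)^2)
    ks[1, j] <- g[1]
    if (half >= 1) {
      ks[1 + seq_len(half), j] <- g[-1]
      ks[npad + 1 - seq_len(half), j] <- g[-1]
    }
  }
  mvfft(ks)
}

# smoothing operator context, reusable across many fields on one (grid, n);
# npad can be pinned so a sub-grid reproduces the full-grid computation exactly
.smoother <- function(grid, n, npad = NULL) {
  if (is.null(npad)) {
    halfw <- min(ceiling(5 * max(grid$scales) / grid$dt), n)
    npad <- .pad_length(n, halfw)
  }
  kf <- .time_kernel_ffts(grid, npad, n)
  ones <- matrix(0, npad, grid$n_scales)
  ones[seq_len(n), ] <- 1
  norm <- Re(mvfft(mvfft(ones) * kf, inverse = TRUE)) / npad
  norm <- norm[seq_len(n), , drop = FALSE]
  list(npad = npad, kernel_fft = kf, norm = norm, n = n, grid = grid)
}

# time smoothing of a (time x scale) field, edge-renormalised
.smooth_time <- function(F, sm) {
  npad <- sm$npad
  n <- sm$n
  P <- matrix(0, npad, ncol(F))
  P[seq_len(n), ] <- F
  S <- mvfft(mvfft(P) * sm$kernel_fft, inverse = TRUE) / npad
  S <- S[seq_len(n), , drop = FALSE] / sm$norm
  if (is.complex(F)) S else Re(S)
}

# boxcar smoothing across scales (columns), edge-renormalised; width w uses
# floor((w-1)/2) scales below and floor(w/2) above the centre
.smooth_scale <- function(F, w) {
  if (w <= 1) return(F)
  ns <- ncol(F)
  lo_off <- floor((w - 1) / 2)
  hi_off <- floor(w / 2)
  out <- F
  for (j in seq_len(ns)) {
    cols <- max(1, j - lo_off):min(ns, j + hi_off)
    out[, j] <- rowMeans(F[, cols, drop = FALSE])
  }
  out
}

#' Smooth a scale-time field
#'
#' The smoothing operator used inside the wavelet coherence estimator: each
#' scale's time series is convolved with a Gaussian kernel whose standard
#' deviation equals that scale (matching the Morlet envelope), then a centred
#' moving average of width `n_scales_smooth` runs across scales. Both kernels
#' are renormalised at record edges, so a constant field is preserved exactly.
#'
#' @param field Real or complex matrix, scale x time, rows matching `grid`.
#' @param grid A [build_scale_grid()] object.
#' @param n_scales_smooth Width of the scale-direction moving average.
#' @return Matrix of the same shape and mode as `field`.
#' @export
smooth_field <- function(field, grid, n_scales_smooth = 12) {
  if (n_scales_smooth < 1) abort("`n_scales_smooth` must be >= 1.", class = "dyadcoh_domain_error")
  if (nrow(field) != grid$n_scales) {
    abort("`field` must have one row per grid scale.", class = "dyadcoh_domain_error")
  }
  if (n_scales_smooth > grid$n_scales) {
    warn(sprintf(
      "`n_scales_smooth` (%d) exceeds the scale count (%d); clipping.",
      n_scales_smooth, grid$n_scales
    ))
    n_scales_smooth <- grid$n_scales
  }
  sm <- .smoother(grid, ncol(field))
  out <- .smooth_time(t(field), sm)
  out <- .smooth_scale(out, n_scales_smooth)
  t(out)
}
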