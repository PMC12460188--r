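# internal coherence from two time x scale transforms plus a smoother; returns
# list(r2, phase) as time x scale matrices. scale_inv = 1/s per column.
.wtc_engine <- function(Wx, Wy, grid, sm, n_scales_smooth = 12) {
  inv_s <- matrix(1 / grid$scales, nrow(Wx), grid$n_scales, byrow = TRUE)
  Sxx <- .smooth_scale(.smooth_time(Mod(Wx)^2 * inv_s, sm), n_scales_smooth)
  Syy <- .smooth_scale(.smooth_time(Mod(Wy)^2 * inv_s, sm), n_scales_smooth)
  Sxy <- .smooth_scale(.smooth_time(Wx * Conj(Wy) * inv_s, sm), n_scales_smooth)
  denom <- Sxx * Syy
  r2 <- ifelse(denom > 0, Mod(Sxy)^2 / denom, 0)
  list(r2 = r2, phase = Arg(Sxy))
}

#' Magnitude-squared wavelet transform coherence
#'
#' Computes the wavelet coherence of two equally sampled real series:
#' `r2 = |S(Wx conj(Wy) / s)|^2 / (S(|Wx|^2 / s) * S(|Wy|^2 / s))`, where `W`
#' are analytic-Morlet CWTs, `s` the scale and `S` the scale-dependent
#' smoothing operator of [smooth_field()]. Because the same positive-weight
#' operator smooths numerator and denominator, `r2` lies in `[0, 1]` by the
#' Cauchy-Schwarz inequality. The cross-phase is the argument of the smoothed
#' cross-spectrum; with this sign convention a pure delay `y(t) = x(t - tau)`
#' at frequency `f` gives `phase = +2 pi f tau` (mod `2 pi`).
#'
#' @param x,y Real numeric series of equal length (>= 8).
#' @param grid A [build_scale_grid()] object.
#' @param n_scales_smooth Scale-direction smoothing width (scales).
#' @return A `coherence_map`: list with `r2`, `phase` (scale x time matrices),
#'   `coi` (logical scale x time, `TRUE` inside the cone of influence),
#'   `grid`, and `n_samples`.
#' @examples
#' g <- build_scale_grid(0.02, 0.2, voices = 8, dt = 1)
#' t <- seq(0, 255)
#' m <- wtc(sin(2 * pi * 0.05 * t), sin(2 * pi * 0.05 * (t - 2)), g)
#' range(m$r2)
#' @export
wtc <- function(x, y, grid, n_scales_smooth = 12) {
  if (length(x) != length(y)) {
    abort("`x` and `y` must have the same length.", class = "dyadcoh_domain_error")
  }
  if (length(x) < 8) abort("series too short (need >= 8 samples).", class = "dyadcoh_domain_error")
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    abort("series contain non-finite values.", class = "dyadcoh_domain_error")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    abort("zero-variance input: coherence undefined.", class = "dyadcoh_degenerate_error")
  }
  n <- length(x)
  sm <- .smoother(grid, n)
  filters <- .morlet_filters(grid, sm$npad)
  Wx <- .cwt_engine(x, grid, filters, sm$npad)
  Wy <- .cwt_engine(y, grid, filters, sm$npad)
  res <- .wtc_engine(Wx, Wy, grid, sm, n_scales_smooth)
  structure(
    list(
      r2 = t(res$r2),
      phase = t(res$phase),
      coi = cone_of_influence(grid, n),
      grid = grid,
      n_samples = n
    ),
    class = "coherence_map"
  )
}

#' @export
print.coherence_map <- function(x, ...) {
  cat(sprintf(
    "<coherence_map> %d scales x %d samples, r2 in [%.3f, %.3f]\n",
    nrow(x$r2), ncol(x$r2), min(x$r2), max(x$r2)
  ))
  invisible(x)
}

#' Tidy a coherence map into a long tibble
#'
#' @param x A `coherence_map`.
#' @param ... Unused.
#' @return A tibble with columns `time` (s), `frequency` (Hz), `r2`, `phase`
#'   and `in_coi`.
#' @method tidy coherence_map
#' @export
tidy.coherence_map <- function(x, ...) {
  ns <- nrow(x$r2)
  nt <- ncol(x$r2)
  tibble(
    time = rep((seq_len(nt) - 1) * x$grid$dt, each = ns),
    frequency = rep(x$grid$frequencies, times = nt),
    r2 = as.vector(x$r2),
    phase = as.vector(x$phase),
    in_coi = as.vector(x$coi)
  )
}

#' Plot a coherence map as a time-frequency heat map
#'
#' @param object A `coherence_map`.
#' @param ... Unused.
#' @return A ggplot object; frequency on a log axis, the cone of influence
#'   marked by dimming out-of-cone cells.
#' @method autoplot coherence_map
#' @export
autoplot.coherence_map <- function(object, ...) {
  df <- tidy(object)
  df$r2_shown <- ifelse(df$in_coi, df$r2, NA_real_)
  ggplot(df, aes(x = .data$time, y = .data$frequency, fill = .data$r2_shown)) +
    geom_raster() +
    ggplot2::scale_y_log10() +
    scale_fill_viridis_c(na.value = "grey85", limits = c(0, 1)) +
    labs(x = "time (s)", y = "frequency (Hz)", fill = expression(r^2)) +
    theme_minimal()
}
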