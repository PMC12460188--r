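#' Dyad- and time-averaged coherence spectrum
#'
#' Averages magnitude-squared coherence per (ROI, scale) over all dyads and
#' all in-window time points, and appends the grand mean curve over ROIs -
#' the spectrum from which the frequency band of interest is selected.
#'
#' @param maps Tibble with columns `dyad_id`, `roi` and `map` (list column of
#'   `coherence_map` objects sharing one grid).
#' @param windows Either one [block_windows()] tibble applied to every map, or
#'   a tibble of windows with a `dyad_id` column (per-dyad windows).
#' @return A `coherence_spectrum`: list with `roi_by_scale` (ROI x scale
#'   matrix), `mean_curve`, `frequencies` (Hz, descending), `grid`,
#'   `n_dyads`.
#' @export
mean_coherence_spectrum <- function(maps, windows) {
  stopifnot(nrow(maps) >= 1)
  if (nrow(windows) == 0) abort("empty window set.", class = "dyadcoh_domain_error")
  grid <- maps$map[[1]]$grid
  rois <- sort(unique(maps$roi))
  acc <- matrix(0, length(rois), grid$n_scales)
  cnt <- matrix(0, length(rois), grid$n_scales)
  per_dyad <- "dyad_id" %in% names(windows)
  for (i in seq_len(nrow(maps))) {
    m <- maps$map[[i]]
    w <- if (per_dyad) {
      dplyr::filter(windows, .data$dyad_id == maps$dyad_id[i])
    } else {
      windows
    }
    cols <- unlist(lapply(seq_len(nrow(w)), function(k) {
      (w$start_index[k] + 1):w$end_index[k]
    }))
    cols <- cols[cols >= 1 & cols <= m$n_samples]
    ri <- match(maps$roi[i], rois)
    acc[ri, ] <- acc[ri, ] + rowSums(m$r2[, cols, drop = FALSE])
    cnt[ri, ] <- cnt[ri, ] + length(cols)
  }
  roi_by_scale <- acc / cnt
  structure(
    list(
      roi_by_scale = roi_by_scale,
      mean_curve = colMeans(roi_by_scale),
      frequencies = grid$frequencies,
      grid = grid,
      rois = rois,
      n_dyads = length(unique(maps$dyad_id))
    ),
    class = "coherence_spectrum"
  )
}

#' @export
print.coherence_spectrum <- function(x, ...) {
  cat(sprintf(
    "<coherence_spectrum> %d ROIs x %d scales (%.3g-%.3g mHz), peak %.3g mHz\n",
    nrow(x$roi_by_scale), length(x$frequencies),
    1000 * min(x$frequencies), 1000 * max(x$frequencies),
    1000 * x$frequencies[which.max(x$mean_curve)]
  ))
  invisible(x)
}

#' Tidy a coherence spectrum
#'
#' @param x A `coherence_spectrum`.
#' @param ... Unused.
#' @return Long tibble with `roi`, `frequency`, `r2`, plus the ROI-mean rows
#'   tagged `roi = NA`.
#' @method tidy coherence_spectrum
#' @export
tidy.coherence_spectrum <- function(x, ...) {
  per_roi <- expand_grid(roi = x$rois, frequency = list(x$frequencies)) %>%
    tidyr::unnest("frequency") %>%
    mutate(r2 = as.vector(t(x$roi_by_scale)))
  bind_rows(
    per_roi,
    tibble(roi = NA_integer_, frequency = x$frequencies, r2 = x$mean_curve)
  )
}

#' Trim artifact-prone frequency extremes from a spectrum
#'
#' Removes scales above `high` and below `low`, where sampling limits and the
#' wavelet-coherence computation introduce edge artifacts.
#'
#' @param spectrum A `coherence_spectrum`.
#' @param low,high Retained band edges in Hz (defaults 9.6 and 220 mHz).
#' @return The trimmed `coherence_spectrum`.
#' @export
trim_spectrum <- function(spectrum, low = 0.0096, high = 0.220) {
  if (low >= high) abort("`low` must be below `high`.", class = "dyadcoh_domain_error")
  keep <- spectrum$frequencies >= low & spectrum$frequencies <= high
  if (!any(keep)) abort("trimming removed every scale.", class = "dyadcoh_domain_error")
  spectrum$roi_by_scale <- spectrum$roi_by_scale[, keep, drop = FALSE]
  spectrum$mean_curve <- spectrum$mean_curve[keep]
  spectrum$frequencies <- spectrum$frequencies[keep]
  spectrum
}

#' Select the frequency band of interest from a coherence spectrum
#'
#' Finds the peak of the ROI-mean coherence curve and places the band edges at
#' the points of steepest slope on either side - the absolute peak
#' differentials of the curve. Slopes are central differences on the scale
#' index (the grid is geometric, so index differences correspond to
#' d/d log f); the first and last points use one-sided differences. The
#' selection is invariant to adding a constant to the curve or scaling it by
#' a positive factor.
#'
#' @param spectrum A (typically trimmed) `coherence_spectrum` whose mean curve
#'   has a strict interior maximum.
#' @param presmooth Width of an optional moving-average presmoothing of the
#'   curve before differentiation (1 = off, the default).
#' @return A `band_selection` list: `f_low`, `f_high`, `f_peak` (Hz),
#'   `band = c(f_low, f_high)`, and the slope curve for inspection.
#' @export
select_band <- function(spectrum, presmooth = 1) {
  curve <- spectrum$mean_curve
  freqs <- spectrum$frequencies # descending
  ncrv <- length(curve)
  if (presmooth > 1) {
    curve <- as.numeric(stats::filter(curve, rep(1 / presmooth, presmooth), sides = 2))
    # edges: shrink the window rather than dropping points
    for (i in which(is.na(curve))) {
      lo <- max(1, i - floor(presmooth / 2))
      hi <- min(ncrv, i + floor(presmooth / 2))
      curve[i] <- mean(spectrum$mean_curve[lo:hi])
    }
  }
  peak <- which.max(curve)
  if (peak == 1 || peak == ncrv) {
    abort("mean curve has no strict interior maximum; cannot select a band.",
      class = "dyadcoh_no_band_error"
    )
  }
  slope <- numeric(ncrv)
  slope[1] <- curve[2] - curve[1]
  slope[ncrv] <- curve[ncrv] - curve[ncrv - 1]
  mid <- 2:(ncrv - 1)
  slope[mid] <- (curve[mid + 1] - curve[mid - 1]) / 2
  # index rises as frequency falls: high-frequency side = indices below the
  # peak (curve rising, slope > 0), low-frequency side = indices above it
  # ties (e.g. a linear ramp) resolve away from the peak, keeping the band
  # inclusive on both sides
  hi_side <- seq_len(peak - 1)
  lo_side <- (peak + 1):ncrv
  i_high <- hi_side[min(which(slope[hi_side] == max(slope[hi_side])))]
  i_low <- lo_side[max(which(-slope[lo_side] == max(-slope[lo_side])))]
  structure(
    list(
      f_low = freqs[i_low], f_high = freqs[i_high], f_peak = freqs[peak],
      band = c(freqs[i_low], freqs[i_high]),
      frequencies = freqs, curve = curve, slope = slope
    ),
    class = "band_selection"
  )
}

#' @export
print.band_selection <- function(x, ...) {
  cat(sprintf(
    "<band_selection> %.3g-%.3g mHz (peak %.3g mHz; periods %.1f-%.1f s)\n",
    1000 * x$f_low, 1000 * x$f_high, 1000 * x$f_peak,
    1 / x$f_high, 1 / x$f_low
  ))
  invisible(x)
}

#' Plot a coherence spectrum with its selected band
#'
#' Draws the per-ROI spectrum as a heat map with the ROI-mean curve overlaid,
#' and, when a band selection is supplied, marks the peak and band edges.
#'
#' @param spectrum A `coherence_spectrum`.
#' @param band Optional `band_selection` from [select_band()].
#' @return A ggplot object.
#' @export
plot_coherence_spectrum <- function(spectrum, band = NULL) {
  df <- tidy(spectrum)
  heat <- dplyr::filter(df, !is.na(.data$roi))
  curve <- dplyr::filter(df, is.na(.data$roi))
  p <- ggplot(heat, aes(x = .data$frequency * 1000, y = .data$roi)) +
    geom_tile(aes(fill = .data$r2)) +
    scale_fill_viridis_c() +
    scale_x_log10() +
    labs(x = "frequency (mHz)", y = "ROI", fill = expression(bar(r)^2)) +
    theme_minimal()
  p <- p + geom_line(
    data = curve,
    aes(
      x = .data$frequency * 1000,
      y = 1 + (length(spectrum$rois) - 1) * (.data$r2 - min(.data$r2)) /
        max(1e-12, diff(range(.data$r2)))
    ),
    colour = "red", linewidth = 0.8
  )
  if (!is.null(band)) {
    p <- p + geom_vline(
      xintercept = 1000 * c(band$f_low, band$f_peak, band$f_high),
      linetype = c("dashed", "solid", "dashed"), colour = "white"
    )
  }
  p
}
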