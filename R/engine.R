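# Internal batch engine: computes per-block coherence terms for an arbitrary
# set of subject pairs, reusing each subject's wavelet transform and smoothed
# auto-spectrum across every pair it appears in. This is what makes the
# surrogate ("fake dyad") baseline affordable: with n dyads each subject's
# transform is computed once and shared by up to n - 1 surrogate pairings.
#
# To keep the band extraction exact while transforming only the scales that
# matter, the engine works on the sub-grid spanning the band plus the
# scale-smoothing half-widths; boxcar smoothing at the band rows then equals
# the full-grid computation (the boxcar is local and the Gaussian time kernel
# is per-scale).

# sub-grid of `grid` covering `band` plus the smoothing margin; returns the
# grid plus index bookkeeping
.band_subgrid <- function(grid, band, n_scales_smooth) {
  rows <- .band_rows(grid, band)
  lo_off <- floor((n_scales_smooth - 1) / 2)
  hi_off <- floor(n_scales_smooth / 2)
  ext <- max(1, min(rows) - lo_off):min(grid$n_scales, max(rows) + hi_off)
  sub <- grid
  sub$frequencies <- grid$frequencies[ext]
  sub$scales <- grid$scales[ext]
  sub$periods <- grid$periods[ext]
  sub$n_scales <- length(ext)
  list(grid = sub, rows_full = ext, band_cols = match(rows, ext))
}

# per-block window intersection of two subjects' own dyad windows, matched on
# (run, block); conditions coincide because the block order is fixed
.intersect_windows <- function(wx, wy) {
  inner_join(
    wx %>% select("run", "block", "condition",
      sx = "start_index", ex = "end_index"
    ),
    wy %>% select("run", "block", sy = "start_index", ey = "end_index"),
    by = c("run", "block")
  ) %>%
    mutate(
      start_index = pmax(.data$sx, .data$sy),
      end_index = pmin(.data$ex, .data$ey)
    ) %>%
    dplyr::filter(.data$start_index < .data$end_index) %>%
    select("run", "block", "condition", "start_index", "end_index")
}

# pairs: tibble(subject_x, subject_y, pair_id). windows_by_subject: named list
# of per-subject window tibbles (columns run, block, condition, start_index,
# end_index). Returns tibble(pair_id, run, block, condition, roi, value).
.pair_terms <- function(cohort, pairs, grid, band, n_scales_smooth = 12,
                        rois = NULL, progress = FALSE) {
  cfg <- cohort$config
  n <- cfg$n_volumes_per_run
  if (is.null(rois)) rois <- seq_len(cfg$n_rois)
  sg <- .band_subgrid(grid, band, n_scales_smooth)
  sub <- sg$grid
  # pin the padded length to the full grid's so sub-grid results match a
  # full-grid wtc() exactly (near-Nyquist rows are padding-sensitive)
  npad_full <- .pad_length(n, min(ceiling(5 * max(grid$scales) / grid$dt), n))
  sm <- .smoother(sub, n, npad = npad_full)
  filters <- .morlet_filters(sub, sm$npad)
  inv_s <- matrix(1 / sub$scales, n, sub$n_scales, byrow = TRUE)

  # per-subject windows from their own dyad's events
  subjects <- unique(c(pairs$subject_x, pairs$subject_y))
  win_of <- lapply(setNames(subjects, subjects), function(sid) {
    d <- cohort$manifest$dyad_id[match(sid, cohort$manifest$subject_id)]
    ev <- dplyr::filter(cohort$events, .data$dyad_id == d)
    list_rbind(lapply(unique(ev$run), function(r) {
      block_windows(dplyr::filter(ev, .data$run == r),
        hemo_exclusion = attr(pairs, "hemo_exclusion") %||% 5, tr = cfg$tr
      ) %>% mutate(run = r)
    }))
  })
  pair_windows <- lapply(seq_len(nrow(pairs)), function(i) {
    .intersect_windows(win_of[[pairs$subject_x[i]]], win_of[[pairs$subject_y[i]]])
  })

  series_key <- paste(cohort$series$subject_id, cohort$series$run)
  out <- vector("list", cfg$n_runs * length(rois))
  oi <- 0
  for (r in seq_len(cfg$n_runs)) {
    for (roi in rois) {
      W_of <- vector("list", length(subjects))
      names(W_of) <- subjects
      Sauto <- vector("list", length(subjects))
      names(Sauto) <- subjects
      for (sid in subjects) {
        x <- cohort$series$series[[match(paste(sid, r), series_key)]][, roi]
        W <- .cwt_engine(x, sub, filters, sm$npad)
        W_of[[sid]] <- W
        Sauto[[sid]] <- .smooth_scale(.smooth_time(Mod(W)^2 * inv_s, sm), n_scales_smooth)
      }
      rows_list <- vector("list", nrow(pairs))
      for (i in seq_len(nrow(pairs))) {
        pw <- pair_windows[[i]]
        pw <- pw[pw$run == r, , drop = FALSE]
        if (nrow(pw) == 0) next
        Wx <- W_of[[pairs$subject_x[i]]]
        Wy <- W_of[[pairs$subject_y[i]]]
        Sxy <- .smooth_scale(.smooth_time(Wx * Conj(Wy) * inv_s, sm), n_scales_smooth)
        denom <- Sauto[[pairs$subject_x[i]]] * Sauto[[pairs$subject_y[i]]]
        r2 <- ifelse(denom > 0, Mod(Sxy)^2 / denom, 0)
        vals <- vapply(seq_len(nrow(pw)), function(k) {
          mean(r2[(pw$start_index[k] + 1):pw$end_index[k], sg$band_cols])
        }, numeric(1))
        rows_list[[i]] <- tibble(
          pair_id = pairs$pair_id[i], run = r, block = pw$block,
          condition = pw$condition, roi = roi, value = vals
        )
      }
      oi <- oi + 1
      out[[oi]] <- list_rbind(rows_list)
    }
    if (progress) message(sprintf("  run %d/%d done (%d ROIs)", r, cfg$n_runs, length(rois)))
  }
  list_rbind(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
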