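#' Run the full interbrain coherence pipeline
#'
#' Executes every analysis stage on a cohort: wavelet coherence per dyad and
#' ROI, the dyad-averaged coherence spectrum with empirical band selection,
#' per-block coherence extraction with hemodynamic-delay exclusion, the
#' surrogate-dyad baseline and its subtraction, and the per-ROI
#' repeated-measures statistics with FDR control. All stages share one scale
#' grid and one set of block windows; the surrogate stage reuses each
#' subject's wavelet transform across all of its pairings.
#'
#' @param cohort A `dyad_cohort` from [simulate_cohort()] or [read_cohort()].
#' @param f_min,f_max Scale-grid frequency limits in Hz.
#' @param voices Voices per octave of the scale grid.
#' @param n_scales_smooth Coherence smoothing width in scales.
#' @param trim_low,trim_high Spectrum trim bounds in Hz (artifact-prone
#'   extremes removed before band selection).
#' @param hemo_exclusion Seconds excluded at each block start.
#' @param band Optional band override `c(low, high)` in Hz; when supplied the
#'   spectrum/band-selection stage is skipped.
#' @param n_permutations Surrogate partners per subject (`NULL` =
#'   exhaustive).
#' @param fdr_q Target false-discovery rate.
#' @param baseline_method Dyad-baseline combination rule, see
#'   [subtract_baseline()].
#' @param transform Transform before inference, see [roi_stats()].
#' @param seed Seed for surrogate-partner sampling (only used when the plan
#'   is not exhaustive).
#' @param out_dir Optional directory; when given, every stage table is
#'   written there as TSV.
#' @param progress Emit progress messages?
#' @return A `dyad_pipeline` list: `grid`, `spectrum`, `band`, `plan`,
#'   `raw`, `baseline`, `corrected`, `stats`, `kept_rois`, `params`.
#' @export
run_dyad_pipeline <- function(cohort,
                              f_min = 0.0039, f_max = 0.2894, voices = 12,
                              n_scales_smooth = 12,
                              trim_low = 0.0096, trim_high = 0.220,
                              hemo_exclusion = 5,
                              band = NULL,
                              n_permutations = NULL,
                              fdr_q = 0.05,
                              baseline_method = "mean",
                              transform = "atanh",
                              seed = 1,
                              out_dir = NULL,
                              progress = FALSE) {
  stopifnot(inherits(cohort, "dyad_cohort"))
  cfg <- cohort$config
  grid <- build_scale_grid(f_min, f_max, voices, cfg$tr)
  kept_rois <- exclude_rois(cohort$roi_missing, cohort$manifest)
  n <- cfg$n_volumes_per_run

  # block windows per dyad and run (both members share the schedule)
  windows <- cohort$events %>%
    dplyr::group_split(.data$dyad_id, .data$run) %>%
    purrr::map(function(ev) {
      block_windows(ev, hemo_exclusion, cfg$tr) %>%
        mutate(dyad_id = ev$dyad_id[1], run = ev$run[1])
    }) %>%
    list_rbind()

  spectrum <- NULL
  band_sel <- NULL
  if (is.null(band)) {
    if (progress) message("pass 1: coherence spectrum over full grid")
    sm <- .smoother(grid, n)
    filters <- .morlet_filters(grid, sm$npad)
    acc <- matrix(0, length(kept_rois), grid$n_scales)
    cnt <- numeric(length(kept_rois))
    series_key <- paste(cohort$series$subject_id, cohort$series$run)
    for (d in seq_len(cfg$n_dyads)) {
      sid_a <- cohort$manifest$subject_id[cohort$manifest$dyad_id == d &
        cohort$manifest$role == "a"]
      sid_b <- cohort$manifest$subject_id[cohort$manifest$dyad_id == d &
        cohort$manifest$role == "b"]
      for (r in seq_len(cfg$n_runs)) {
        w <- windows %>% dplyr::filter(.data$dyad_id == d, .data$run == r)
        cols <- unlist(lapply(seq_len(nrow(w)), function(k) {
          (w$start_index[k] + 1):w$end_index[k]
        }))
        cols <- cols[cols >= 1 & cols <= n]
        ia <- match(paste(sid_a, r), series_key)
        ib <- match(paste(sid_b, r), series_key)
        for (ri in seq_along(kept_rois)) {
          roi <- kept_rois[ri]
          Wx <- .cwt_engine(cohort$series$series[[ia]][, roi], grid, filters, sm$npad)
          Wy <- .cwt_engine(cohort$series$series[[ib]][, roi], grid, filters, sm$npad)
          r2 <- .wtc_engine(Wx, Wy, grid, sm, n_scales_smooth)$r2 # time x scale
          acc[ri, ] <- acc[ri, ] + colSums(r2[cols, , drop = FALSE])
          cnt[ri] <- cnt[ri] + length(cols)
        }
      }
      if (progress) message(sprintf("  dyad %d/%d", d, cfg$n_dyads))
    }
    roi_by_scale <- acc / cnt
    spectrum <- structure(
      list(
        roi_by_scale = roi_by_scale, mean_curve = colMeans(roi_by_scale),
        frequencies = grid$frequencies, grid = grid, rois = kept_rois,
        n_dyads = cfg$n_dyads
      ),
      class = "coherence_spectrum"
    )
    band_sel <- select_band(trim_spectrum(spectrum, trim_low, trim_high))
    band <- band_sel$band
  } else if (progress) {
    message("band override supplied; spectrum/band-selection stage skipped")
  }

  if (progress) {
    message(sprintf(
      "pass 2: extraction in band %.3g-%.3g mHz (real + surrogate pairs)",
      1000 * band[1], 1000 * band[2]
    ))
  }
  plan <- make_surrogate_plan(cohort$manifest, n_permutations, seed)
  real_pairs <- cohort$manifest %>%
    select("dyad_id", "subject_id", "role") %>%
    pivot_wider(names_from = "role", values_from = "subject_id") %>%
    mutate(
      subject_x = .data$a, subject_y = .data$b,
      pair_id = paste0("real:", .data$dyad_id)
    ) %>%
    select("subject_x", "subject_y", "pair_id")
  surr_pairs <- .plan_pairs(plan, cohort$manifest)
  pairs <- bind_rows(real_pairs, surr_pairs)
  attr(pairs, "hemo_exclusion") <- hemo_exclusion
  terms <- .pair_terms(
    cohort, pairs, grid, band, n_scales_smooth,
    rois = kept_rois, progress = progress
  )

  real_terms <- terms %>%
    dplyr::filter(startsWith(.data$pair_id, "real:")) %>%
    mutate(dyad_id = as.integer(sub("^real:", "", .data$pair_id))) %>%
    select("dyad_id", "run", "block", "condition", "roi", "value")
  raw <- aggregate_table(real_terms)
  baseline <- .baseline_from_pair_terms(
    terms %>% dplyr::filter(!startsWith(.data$pair_id, "real:")), plan
  )
  corrected <- subtract_baseline(raw, baseline, cohort$manifest, baseline_method)
  stats <- roi_stats(corrected, q = fdr_q, transform = transform)

  out <- structure(
    list(
      grid = grid, spectrum = spectrum, band = band, band_selection = band_sel,
      plan = plan, windows = windows, raw = raw, baseline = baseline,
      corrected = corrected, stats = stats, kept_rois = kept_rois,
      params = list(
        f_min = f_min, f_max = f_max, voices = voices,
        n_scales_smooth = n_scales_smooth, trim_low = trim_low,
        trim_high = trim_high, hemo_exclusion = hemo_exclusion,
        n_permutations = attr(plan, "n_permutations"), fdr_q = fdr_q,
        baseline_method = baseline_method, transform = transform, seed = seed
      )
    ),
    class = "dyad_pipeline"
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_coherence_table(raw, file.path(out_dir, "coherence_raw.tsv"))
    readr::write_tsv(baseline, file.path(out_dir, "baseline.tsv"))
    write_coherence_table(corrected, file.path(out_dir, "coherence_corrected.tsv"))
    readr::write_tsv(stats$omnibus, file.path(out_dir, "stats_omnibus.tsv"))
    readr::write_tsv(stats$posthoc, file.path(out_dir, "stats_posthoc.tsv"))
    readr::write_tsv(stats$removals, file.path(out_dir, "outlier_log.tsv"))
    readr::write_tsv(plan, file.path(out_dir, "surrogate_plan.tsv"))
    if (!is.null(spectrum)) {
      readr::write_tsv(
        tidy(spectrum) %>% mutate(frequency_mhz = 1000 * .data$frequency),
        file.path(out_dir, "coherence_spectrum.tsv")
      )
    }
    readr::write_tsv(
      tibble(
        f_low_mhz = 1000 * band[1], f_high_mhz = 1000 * band[2],
        f_peak_mhz = if (!is.null(band_sel)) 1000 * band_sel$f_peak else NA_real_
      ),
      file.path(out_dir, "band.tsv")
    )
  }
  out
}

#' @export
print.dyad_pipeline <- function(x, ...) {
  cat(sprintf(
    "<dyad_pipeline> band %.3g-%.3g mHz; %d ROIs; %d dyads; %d significant ROI(s)\n",
    1000 * x$band[1], 1000 * x$band[2], length(x$kept_rois),
    length(unique(x$raw$dyad_id)), sum(x$stats$omnibus$significant)
  ))
  invisible(x)
}

#' @rdname run_dyad_pipeline
#' @param x A `dyad_pipeline` object.
#' @param ... Unused.
#' @method tidy dyad_pipeline
#' @export
tidy.dyad_pipeline <- function(x, ...) {
  x$corrected %>% mutate(stage = "corrected")
}

#' @rdname run_dyad_pipeline
#' @method glance dyad_pipeline
#' @export
glance.dyad_pipeline <- function(x, ...) {
  tibble(
    f_low = x$band[1], f_high = x$band[2],
    n_rois = length(x$kept_rois),
    n_dyads = length(unique(x$raw$dyad_id)),
    n_permutations = x$params$n_permutations,
    n_significant = sum(x$stats$omnibus$significant),
    mean_corrected = mean(x$corrected$value)
  )
}
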