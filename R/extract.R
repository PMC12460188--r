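#' Block extraction windows with hemodynamic-delay exclusion
#'
#' Converts an event table into per-block extraction windows: each window runs
#' from the first trial's onset plus `hemo_exclusion` seconds (the peak delay
#' of the canonical hemodynamic response) to the offset of the last trial
#' (end of its feedback). Volume indices are 0-based and half-open
#' `[start_index, end_index)`, with `ceil` at the start and `floor` at the end
#' so no sample outside the block contributes.
#'
#' @param events Event tibble for one run (columns `onset`, `duration`,
#'   `event`, `condition`, `block`); block-level rows (`event == "block"`) are
#'   used when present, otherwise spans are taken from the trial-level rows.
#' @param hemo_exclusion Seconds discarded at each block start.
#' @param tr Sampling interval in seconds.
#' @return A tibble of `block_window` rows: `condition`, `block`, `start`,
#'   `end` (seconds), `start_index`, `end_index` (volumes). Blocks shorter
#'   than the exclusion are dropped with a warning.
#' @export
block_windows <- function(events, hemo_exclusion = 5, tr = 1.5) {
  stopifnot(all(c("onset", "duration", "condition", "block") %in% names(events)))
  spans <- if ("event" %in% names(events) && any(events$event == "block")) {
    events %>%
      dplyr::filter(.data$event == "block") %>%
      group_by(.data$condition, .data$block) %>%
      summarise(
        start = min(.data$onset), end = max(.data$onset + .data$duration),
        .groups = "drop"
      )
  } else {
    events %>%
      group_by(.data$condition, .data$block) %>%
      summarise(
        start = min(.data$onset), end = max(.data$onset + .data$duration),
        .groups = "drop"
      )
  }
  out <- spans %>%
    mutate(
      start = .data$start + hemo_exclusion,
      start_index = as.integer(ceiling(.data$start / tr)),
      end_index = as.integer(floor(.data$end / tr))
    ) %>%
    arrange(.data$block)
  short <- out$start >= out$end | out$start_index >= out$end_index
  if (any(short)) {
    warn(sprintf(
      "%d block(s) shorter than the hemodynamic exclusion were dropped.",
      sum(short)
    ))
    out <- out[!short, , drop = FALSE]
  }
  out
}

# band rows (scale indices) of a grid for an inclusive frequency band
.band_rows <- function(grid, band) {
  rows <- which(grid$frequencies >= band[1] & grid$frequencies <= band[2])
  if (length(rows) == 0) {
    abort("no grid scales fall inside the requested band.", class = "dyadcoh_domain_error")
  }
  rows
}

#' Extract one scalar coherence term from a map
#'
#' Averages the magnitude-squared coherence over all scales inside the
#' frequency band and all volumes inside the block window. Points outside the
#' cone of influence are included by default (set `mask_coi = TRUE` for a
#' sensitivity analysis that excludes them).
#'
#' @param map A `coherence_map` from [wtc()].
#' @param window One row of [block_windows()] (or any list with
#'   `start_index`, `end_index`).
#' @param band Frequency band `c(low, high)` in Hz, edges inclusive.
#' @param mask_coi Exclude out-of-cone points?
#' @return A single coherence value in `[0, 1]`.
#' @export
extract_term <- function(map, window, band, mask_coi = FALSE) {
  rows <- .band_rows(map$grid, band)
  cols <- (window$start_index + 1):window$end_index # 0-based half-open -> R
  if (length(cols) < 1 || window$end_index > map$n_samples) {
    abort("window is empty or exceeds the record.", class = "dyadcoh_domain_error")
  }
  vals <- map$r2[rows, cols, drop = FALSE]
  if (mask_coi) {
    keep <- map$coi[rows, cols, drop = FALSE]
    if (!any(keep)) return(NA_real_)
    mean(vals[keep])
  } else {
    mean(vals)
  }
}

#' Aggregate per-block coherence terms into a raw coherence table
#'
#' Averages block terms over runs to one value per dyad, condition and ROI,
#' and merges the solo and watch blocks into a single overarching "solo"
#' condition (the two cannot be uniquely attributed: while one member
#' performs solo the other always watches).
#'
#' @param terms Tibble with columns `dyad_id`, `run`, `condition`, `roi`,
#'   `value` (one row per block term).
#' @return A coherence table: tibble `dyad_id`, `condition` (cooperation,
#'   communication, competition, solo), `roi`, `value`, `n_blocks`, with
#'   attribute `stage = "raw"`. Cells with no contributing block are absent
#'   (treat as missing).
#' @export
aggregate_table <- function(terms) {
  stopifnot(all(c("dyad_id", "run", "condition", "roi", "value") %in% names(terms)))
  out <- terms %>%
    mutate(condition = if_else(.data$condition == "watch", "solo", .data$condition)) %>%
    dplyr::filter(!is.na(.data$value)) %>%
    group_by(.data$dyad_id, .data$condition, .data$roi) %>%
    summarise(
      value = mean(.data$value), n_blocks = dplyr::n(),
      .groups = "drop"
    )
  attr(out, "stage") <- "raw"
  out
}

#' Exclude ROIs with excessive missing data
#'
#' An ROI is dropped from the analysis entirely when the fraction of dyads
#' with unusable data for it exceeds the threshold (more than 33 percent by
#' default). A dyad counts as unusable for an ROI when either member's
#' missing-data fraction exceeds `cell_threshold`.
#'
#' @param roi_missing Tibble of per subject x ROI missing fractions
#'   (`subject_id`, `roi`, `missing_frac`), as carried by a `dyad_cohort`;
#'   alternatively per dyad (`dyad_id`, `roi`, `unusable` logical).
#' @param manifest Subject-to-dyad manifest (needed for the per-subject form).
#' @param threshold Maximum tolerated fraction of unusable dyads.
#' @param cell_threshold Missing fraction above which a subject's ROI data
#'   counts as unusable.
#' @return Integer vector of retained ROI indices.
#' @export
exclude_rois <- function(roi_missing, manifest = NULL, threshold = 1 / 3,
                         cell_threshold = 0) {
  if ("unusable" %in% names(roi_missing)) {
    per_dyad <- roi_missing
  } else {
    stopifnot(!is.null(manifest))
    per_dyad <- roi_missing %>%
      left_join(manifest[, c("subject_id", "dyad_id")], by = "subject_id") %>%
      group_by(.data$dyad_id, .data$roi) %>%
      summarise(
        unusable = any(.data$missing_frac > cell_threshold),
        .groups = "drop"
      )
  }
  keep <- per_dyad %>%
    group_by(.data$roi) %>%
    summarise(frac = mean(.data$unusable), .groups = "drop") %>%
    dplyr::filter(.data$frac <= threshold) %>%
    pull(.data$roi)
  sort(keep)
}
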