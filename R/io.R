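# On-disk artifacts are plain TSV throughout: BIDS-style events tables,
# one series file per subject x run (header = ROI labels, sampling interval
# on a comment line), and long-format coherence/stats tables.

#' Write / read a BIDS-style events table
#'
#' Events are stored as `events.tsv` with columns `onset`, `duration`,
#' `trial_type`, `event`, `block`, `trial`, `response_time_a`,
#' `response_time_b` (n/a for missing responses, per the BIDS convention).
#'
#' @param events Event tibble (internal column names, as produced by
#'   [simulate_cohort()]).
#' @param path File path.
#' @return `write_events` returns `path` invisibly; `read_events` returns the
#'   validated event tibble with internal column names.
#' @export
write_events <- function(events, path) {
  out <- events %>%
    rename(
      trial_type = "condition",
      response_time_a = "rt_a", response_time_b = "rt_b"
    )
  readr::write_tsv(out, path, na = "n/a")
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  df <- readr::read_tsv(path, na = c("n/a", "NA", ""), show_col_types = FALSE)
  required <- c("onset", "duration", "trial_type")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    abort(
      sprintf("events file lacks required column(s): %s", paste(missing, collapse = ", ")),
      class = "dyadcoh_io_error"
    )
  }
  bad <- which(!is.finite(df$onset) | !is.finite(df$duration) | df$duration < 0)
  if (length(bad) > 0) {
    abort(
      sprintf("malformed onset/duration at line(s): %s",
        paste(utils::head(bad + 1, 5), collapse = ", ")
      ),
      class = "dyadcoh_io_error"
    )
  }
  # onsets must be non-decreasing within each run apart from block rows,
  # which span their trials and repeat the first trial's onset
  trial_rows <- if ("event" %in% names(df)) df$event != "block" else rep(TRUE, nrow(df))
  split_keys <- interaction(
    if ("dyad_id" %in% names(df)) df$dyad_id[trial_rows] else 0,
    if ("run" %in% names(df)) df$run[trial_rows] else 0
  )
  if (any(vapply(split(df$onset[trial_rows], split_keys), is.unsorted, logical(1)))) {
    abort("event onsets are not non-decreasing within a run.", class = "dyadcoh_io_error")
  }
  df %>%
    rename(
      condition = "trial_type",
      rt_a = "response_time_a", rt_b = "response_time_b"
    )
}

#' Write / read an ROI time-series matrix
#'
#' One TSV per subject and run: header row of ROI labels, one row per volume;
#' the sampling interval is carried on a leading comment line `# tr: <s>`.
#' `NaN` cells are rejected on read - missing data must be declared through
#' the per-subject `roi_missing` table, never as holes in the series.
#'
#' @param series Numeric matrix, volumes x ROIs.
#' @param path File path.
#' @param tr Sampling interval in seconds.
#' @param roi_labels Optional ROI column labels.
#' @return `write_series` returns `path` invisibly; `read_series` returns the
#'   matrix with attribute `tr`.
#' @export
write_series <- function(series, path, tr, roi_labels = NULL) {
  if (is.null(roi_labels)) {
    roi_labels <- sprintf("roi_%03d", seq_len(ncol(series)))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# tr: %.10g", tr), con)
  writeLines(paste(roi_labels, collapse = "\t"), con)
  utils::write.table(series, con,
    sep = "\t", row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}

#' @rdname write_series
#' @export
read_series <- function(path) {
  first <- readLines(path, n = 1)
  m <- regmatches(first, regexec("^#\\s*tr:\\s*([0-9.eE+-]+)", first))[[1]]
  if (length(m) < 2) {
    abort("series file lacks the '# tr: <seconds>' header line.",
      class = "dyadcoh_io_error"
    )
  }
  tr <- as.numeric(m[2])
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  mat <- as.matrix(df)
  if (any(!is.finite(mat))) {
    abort("series contains non-finite values; encode missingness via roi_missing.",
      class = "dyadcoh_io_error"
    )
  }
  attr(mat, "tr") <- tr
  mat
}

#' Write a long-format coherence table
#'
#' @param table Coherence table (from [aggregate_table()],
#'   [subtract_baseline()] or the z stage), with its `stage` attribute.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_coherence_table <- function(table, path) {
  out <- table %>% mutate(stage = attr(table, "stage") %||% "unknown")
  readr::write_tsv(out, path, na = "n/a")
  invisible(path)
}

#' Persist a cohort to a directory of TSV files
#'
#' Writes the manifest, per-dyad-and-run event tables, per-subject-and-run
#' series, ground truth and missing-data table - everything needed to rebuild
#' the cohort with [read_cohort()].
#'
#' @param cohort A `dyad_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(cohort$manifest, file.path(dir, "manifest.tsv"))
  write_events(cohort$events, file.path(dir, "events.tsv"))
  readr::write_tsv(cohort$ground_truth, file.path(dir, "ground_truth.tsv"))
  readr::write_tsv(cohort$roi_missing, file.path(dir, "roi_missing.tsv"))
  cfg <- cohort$config
  readr::write_tsv(
    tibble(
      key = c("tr", "n_volumes_per_run", "n_runs", "n_dyads", "n_rois", "seed"),
      value = c(cfg$tr, cfg$n_volumes_per_run, cfg$n_runs, cfg$n_dyads, cfg$n_rois, cfg$seed)
    ),
    file.path(dir, "config.tsv")
  )
  for (i in seq_len(nrow(cohort$series))) {
    row <- cohort$series[i, ]
    write_series(
      row$series[[1]],
      file.path(dir, sprintf("%s_run-%d_series.tsv", row$subject_id, row$run)),
      tr = cfg$tr
    )
  }
  invisible(dir)
}

#' Rebuild a cohort from a directory written by [write_cohort()]
#'
#' @param dir Directory path.
#' @return A `dyad_cohort` (with a minimal config carrying the stored
#'   geometry).
#' @export
read_cohort <- function(dir) {
  manifest <- readr::read_tsv(file.path(dir, "manifest.tsv"), show_col_types = FALSE)
  events <- read_events(file.path(dir, "events.tsv"))
  ground_truth <- readr::read_tsv(file.path(dir, "ground_truth.tsv"), show_col_types = FALSE)
  roi_missing <- readr::read_tsv(file.path(dir, "roi_missing.tsv"), show_col_types = FALSE)
  cfgtab <- readr::read_tsv(file.path(dir, "config.tsv"), show_col_types = FALSE)
  cfg <- as.list(setNames(cfgtab$value, cfgtab$key))
  series <- list_rbind(lapply(seq_len(nrow(manifest)), function(i) {
    sid <- manifest$subject_id[i]
    list_rbind(lapply(seq_len(cfg$n_runs), function(r) {
      mat <- read_series(file.path(dir, sprintf("%s_run-%d_series.tsv", sid, r)))
      attributes(mat) <- list(dim = dim(mat))
      tibble(
        dyad_id = manifest$dyad_id[i], subject_id = sid,
        role = manifest$role[i], run = r, series = list(mat)
      )
    }))
  }))
  config <- structure(
    list(
      n_dyads = as.integer(cfg$n_dyads), n_rois = as.integer(cfg$n_rois),
      tr = cfg$tr, n_volumes_per_run = as.integer(cfg$n_volumes_per_run),
      n_runs = as.integer(cfg$n_runs), seed = as.integer(cfg$seed)
    ),
    class = "sim_config"
  )
  structure(
    list(
      manifest = manifest, series = series, events = events,
      ground_truth = ground_truth, roi_missing = roi_missing, config = config
    ),
    class = "dyad_cohort"
  )
}
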