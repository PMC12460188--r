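#' Surrogate ("fake dyad") pairing plan
#'
#' Builds, for every subject, the list of surrogate partners used to estimate
#' the task-structure coherence baseline. Partners are always drawn from the
#' opposite scanner (never two subjects of the same scanner, avoiding
#' scanner-specific bias) and never include the subject's true partner. With
#' scanner groups of size n, at most n - 1 partners exist; requesting all of
#' them (the default) makes the plan exhaustive and seed-independent.
#'
#' @param manifest Tibble with `dyad_id`, `subject_id`, `scanner` (two
#'   distinct scanner labels, equal group sizes).
#' @param n_permutations Surrogate partners per subject; `NULL` means the
#'   exhaustive n - 1.
#' @param seed Seed for partner sampling when the plan is not exhaustive.
#' @return A `surrogate_plan` tibble: `subject_id`, `partner_id`, plus the
#'   `n_permutations` attribute.
#' @export
make_surrogate_plan <- function(manifest, n_permutations = NULL, seed = 1) {
  scanners <- unique(manifest$scanner)
  if (length(scanners) != 2) {
    abort("manifest must contain exactly two scanner groups.", class = "dyadcoh_config_error")
  }
  g1 <- manifest$subject_id[manifest$scanner == scanners[1]]
  g2 <- manifest$subject_id[manifest$scanner == scanners[2]]
  if (length(g1) != length(g2) || length(g1) < 2) {
    abort("scanner groups must have equal size >= 2.", class = "dyadcoh_config_error")
  }
  n_avail <- length(g1) - 1L
  n_permutations <- if (is.null(n_permutations)) n_avail else as.integer(n_permutations)
  if (n_permutations > n_avail) {
    abort(sprintf(
      "n_permutations (%d) exceeds available cross-scanner partners (%d).",
      n_permutations, n_avail
    ), class = "dyadcoh_infeasible_error")
  }
  partner_of <- function(sid) {
    d <- manifest$dyad_id[match(sid, manifest$subject_id)]
    manifest$subject_id[manifest$dyad_id == d & manifest$subject_id != sid]
  }
  plan <- list_rbind(lapply(manifest$subject_id, function(sid) {
    opposite <- if (sid %in% g1) g2 else g1
    candidates <- sort(setdiff(opposite, partner_of(sid)))
    chosen <- if (n_permutations == n_avail) {
      candidates
    } else {
      .with_seed(
        .derive_seed(seed, match(sid, manifest$subject_id)),
        sort(sample(candidates, n_permutations))
      )
    }
    tibble(subject_id = sid, partner_id = chosen)
  }))
  structure(plan, class = c("surrogate_plan", class(plan)), n_permutations = n_permutations)
}

# unordered unique cross-scanner pairs covered by a plan, oriented as
# (scanner-1 member, scanner-2 member)
.plan_pairs <- function(plan, manifest) {
  scanners <- unique(manifest$scanner)
  sc <- setNames(manifest$scanner, manifest$subject_id)
  plan %>%
    mutate(
      subject_x = if_else(sc[.data$subject_id] == scanners[1],
        .data$subject_id, .data$partner_id
      ),
      subject_y = if_else(sc[.data$subject_id] == scanners[1],
        .data$partner_id, .data$subject_id
      )
    ) %>%
    distinct(.data$subject_x, .data$subject_y) %>%
    mutate(pair_id = paste(.data$subject_x, .data$subject_y, sep = "~"))
}

#' Subject-specific surrogate coherence baseline
#'
#' Runs the full coherence-extraction procedure on every surrogate pairing of
#' the plan (same scale grid, band, smoothing and block windows as the real
#' dyads, using the per-block intersection of the two subjects' windows) and
#' averages, per subject, the resulting terms over that subject's surrogate
#' partners. The result describes the coherence a subject shows with
#' non-partners performing the identical task - the component driven by the
#' shared task structure rather than the interaction.
#'
#' @param cohort A `dyad_cohort` (see [simulate_cohort()] / [read_cohort()]).
#' @param plan A [make_surrogate_plan()] result.
#' @param grid A [build_scale_grid()] object.
#' @param band Frequency band `c(low, high)` in Hz.
#' @param n_scales_smooth Smoothing width in scales.
#' @param hemo_exclusion Seconds excluded at each block start.
#' @param rois ROI indices to process (default all).
#' @param progress Emit progress messages?
#' @return A tibble `subject_id`, `condition`, `roi`, `baseline`,
#'   `n_partners`.
#' @export
compute_baseline <- function(cohort, plan, grid, band, n_scales_smooth = 12,
                             hemo_exclusion = 5, rois = NULL, progress = FALSE) {
  pairs <- .plan_pairs(plan, cohort$manifest)
  attr(pairs, "hemo_exclusion") <- hemo_exclusion
  terms <- .pair_terms(cohort, pairs, grid, band, n_scales_smooth, rois, progress)
  .baseline_from_pair_terms(terms, plan)
}

# aggregate each surrogate pair exactly like a real dyad (runs averaged,
# watch merged into solo), then average per subject over its planned partners
.baseline_from_pair_terms <- function(terms, plan) {
  per_pair <- terms %>%
    rename(dyad_id = "pair_id") %>%
    aggregate_table() %>%
    tidyr::separate_wider_delim("dyad_id",
      delim = "~", names = c("subject_x", "subject_y")
    )
  # a pair contributes to a subject's baseline only if the partner is in that
  # subject's plan (for exhaustive plans every pair serves both members)
  planned <- plan %>%
    mutate(subject_id = .data$subject_id, other = .data$partner_id) %>%
    select("subject_id", "other")
  bind_rows(
    per_pair %>% mutate(subject_id = .data$subject_x, other = .data$subject_y),
    per_pair %>% mutate(subject_id = .data$subject_y, other = .data$subject_x)
  ) %>%
    semi_join(planned, by = c("subject_id", "other")) %>%
    group_by(.data$subject_id, .data$condition, .data$roi) %>%
    summarise(
      baseline = mean(.data$value), n_partners = dplyr::n(),
      .groups = "drop"
    )
}

#' Subtract the surrogate baseline from raw coherence terms
#'
#' For each dyad, condition and ROI, subtracts the dyad-level baseline from
#' the raw coherence term. The dyad baseline combines the two members'
#' subject-specific baselines; the symmetric arithmetic mean is the default,
#' with either single member's baseline available as an alternative strategy.
#'
#' @param raw Raw coherence table from [aggregate_table()].
#' @param baseline Subject-level baseline from [compute_baseline()].
#' @param manifest Subject-to-dyad manifest.
#' @param method `"mean"` (average of the two members' baselines),
#'   `"subject_a"` or `"subject_b"`.
#' @return Coherence table with `value = raw - dyad baseline` (stage
#'   `"corrected"`); cells with no baseline are dropped (masked).
#' @export
subtract_baseline <- function(raw, baseline, manifest,
                              method = c("mean", "subject_a", "subject_b")) {
  method <- match.arg(method)
  dyad_base <- baseline %>%
    left_join(manifest[, c("subject_id", "dyad_id", "role")], by = "subject_id") %>%
    dplyr::filter(
      method == "mean" |
        (method == "subject_a" & .data$role == "a") |
        (method == "subject_b" & .data$role == "b")
    ) %>%
    group_by(.data$dyad_id, .data$condition, .data$roi) %>%
    summarise(baseline = mean(.data$baseline), .groups = "drop")
  out <- raw %>%
    inner_join(dyad_base, by = c("dyad_id", "condition", "roi")) %>%
    mutate(value = .data$value - .data$baseline) %>%
    select("dyad_id", "condition", "roi", "value")
  attr(out, "stage") <- "corrected"
  out
}
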