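#' Response-time adjustment for fast responses
#'
#' The joint button-press task discourages reflex-fast responding by shrinking
#' the synchrony margin for fast presses. Response times of at least 1.6 s are
#' used as-is; faster responses are mapped through `(exp(rt) - 1) / 2.5`,
#' which is strictly increasing and meets the identity branch at the 1.6 s
#' breakpoint to within 1.2 percent, so there is no noticeable cut-off.
#'
#' @param rt Response time(s) in seconds; must be positive. `NA` (no response)
#'   passes through as `NA`.
#' @param breakpoint Difficulty breakpoint in seconds below which the
#'   adjustment applies.
#' @param fun Adjustment applied below the breakpoint, as a function of `rt`.
#' @return Adjusted response time(s) in seconds.
#' @examples
#' adjust_rt(c(2, 1.6, 1.0))
#' @export
adjust_rt <- function(rt, breakpoint = 1.6, fun = function(r) (exp(r) - 1) / 2.5) {
  if (any(!is.na(rt) & rt <= 0)) {
    abort("response times must be positive.", class = "dyadcoh_domain_error")
  }
  ifelse(!is.na(rt) & rt < breakpoint, fun(rt), rt)
}

#' Margin of error for simultaneous responses
#'
#' The margin within which two button presses count as simultaneous during
#' cooperation and communication blocks: the sum of the two (adjusted)
#' response times divided by 8. Slower trials earn a wider margin; responses
#' below the 1.6 s breakpoint shrink it more than proportionally via
#' [adjust_rt()].
#'
#' @param rt_a,rt_b Response times of the two participants in seconds.
#' @param ... Passed on to [adjust_rt()].
#' @return Margin in seconds.
#' @examples
#' margin_of_error(2.0, 2.3) # 0.5375
#' @export
margin_of_error <- function(rt_a, rt_b, ...) {
  (adjust_rt(rt_a, ...) + adjust_rt(rt_b, ...)) / 8
}

.invalid_response <- function(rt, timeout, premature) {
  is.na(rt) | rt > timeout | premature
}

.outcome_row <- function(judged, points_a, points_b, margin = NA_real_, rt_difference = NA_real_) {
  tibble(
    judged = judged, points_a = as.integer(points_a), points_b = as.integer(points_b),
    margin = margin, rt_difference = rt_difference
  )
}

#' Judge a cooperation (or communication) trial
#'
#' Success requires both participants to respond validly (no time-out past
#' `timeout` seconds, no premature press) with an absolute response-time
#' difference within the [margin_of_error()]. Success awards +1 to each;
#' ordinary failure deducts 1 from each; an invalid response carries the
#' larger `invalid_penalty` for the offender (the partner of an invalid
#' responder takes the ordinary failure deduction).
#'
#' @param rt_a,rt_b Response times in seconds; `NA` means no response.
#' @param timeout Time-out limit in seconds.
#' @param premature_a,premature_b Whether each participant pressed before the
#'   go stimulus.
#' @param strict If `TRUE` the margin comparison is strict (`<`) rather than
#'   non-strict (`<=`).
#' @param invalid_penalty Points deducted for an invalid (time-out or
#'   premature) response.
#' @return A one-row tibble: `judged` (success/failure/invalid), `points_a`,
#'   `points_b`, `margin`, `rt_difference`.
#' @examples
#' judge_cooperation(2.0, 2.3)$judged # success: |0.3| <= 0.5375
#' @export
judge_cooperation <- function(rt_a, rt_b, timeout = 6, premature_a = FALSE,
                              premature_b = FALSE, strict = FALSE,
                              invalid_penalty = 2L) {
  inv_a <- .invalid_response(rt_a, timeout, premature_a)
  inv_b <- .invalid_response(rt_b, timeout, premature_b)
  if (inv_a || inv_b) {
    return(.outcome_row(
      "invalid",
      if (inv_a) -invalid_penalty else -1L,
      if (inv_b) -invalid_penalty else -1L,
      rt_difference = if (!is.na(rt_a) && !is.na(rt_b)) abs(rt_a - rt_b) else NA_real_
    ))
  }
  marg <- margin_of_error(rt_a, rt_b)
  diff <- abs(rt_a - rt_b)
  ok <- if (strict) diff < marg else diff <= marg
  if (ok) {
    .outcome_row("success", 1L, 1L, marg, diff)
  } else {
    .outcome_row("failure", -1L, -1L, marg, diff)
  }
}

#' Judge a competition trial
#'
#' The faster valid responder wins a point and the slower loses one. An
#' invalid response (time-out or premature press) loses with the larger
#' deduction while a valid opponent wins. Exact ties (a probability-zero
#' event for continuous response times) score zero for both by default.
#'
#' @inheritParams judge_cooperation
#' @param tie_points Points awarded to each on an exact tie.
#' @return A one-row tibble as in [judge_cooperation()].
#' @export
judge_competition <- function(rt_a, rt_b, timeout = 6, premature_a = FALSE,
                              premature_b = FALSE, invalid_penalty = 2L,
                              tie_points = 0L) {
  inv_a <- .invalid_response(rt_a, timeout, premature_a)
  inv_b <- .invalid_response(rt_b, timeout, premature_b)
  diff <- if (!is.na(rt_a) && !is.na(rt_b)) abs(rt_a - rt_b) else NA_real_
  if (inv_a || inv_b) {
    return(.outcome_row(
      "invalid",
      if (inv_a) -invalid_penalty else 1L,
      if (inv_b) -invalid_penalty else 1L,
      rt_difference = diff
    ))
  }
  if (rt_a == rt_b) {
    .outcome_row("failure", tie_points, tie_points, rt_difference = 0)
  } else if (rt_a < rt_b) {
    .outcome_row("success", 1L, -1L, rt_difference = diff)
  } else {
    .outcome_row("success", -1L, 1L, rt_difference = diff)
  }
}

#' Judge a solo trial
#'
#' Any valid press (after the go stimulus, within the time-out) earns a point;
#' a time-out or premature press carries the invalid deduction. The watching
#' partner does not respond and is not scored.
#'
#' @inheritParams judge_cooperation
#' @param rt Response time of the performing participant.
#' @param premature Whether the press came before the go stimulus.
#' @return A one-row tibble; `points_b` is 0 (the watcher).
#' @export
judge_solo <- function(rt, timeout = 6, premature = FALSE, invalid_penalty = 2L) {
  if (.invalid_response(rt, timeout, premature)) {
    .outcome_row("invalid", -invalid_penalty, 0L)
  } else {
    .outcome_row("success", 1L, 0L)
  }
}

#' Score every trial of an event table
#'
#' Applies the condition-appropriate judging rule to each trial row of a
#' BIDS-style event table (see [simulate_cohort()] / [read_events()]).
#'
#' @param events Tibble with at least `condition`, `block`, `trial`, `rt_a`,
#'   `rt_b`; one row per trial (rows with `event == "trial"` if an `event`
#'   column is present).
#' @param ... Passed to the judge functions (e.g. `strict`, `invalid_penalty`).
#' @return `events` trial rows with `judged`, `points_a`, `points_b`,
#'   `margin`, `rt_difference` columns appended.
#' @export
score_trials <- function(events, ...) {
  if ("event" %in% names(events)) {
    events <- dplyr::filter(events, .data$event %in% c("trial", "stimulus"))
  }
  out <- purrr::pmap(
    list(events$condition, events$rt_a, events$rt_b),
    function(cond, ra, rb, ...) {
      switch(cond,
        cooperation = ,
        communication = judge_cooperation(ra, rb, ...),
        competition = judge_competition(ra, rb, ...),
        solo = judge_solo(if (is.na(ra)) rb else ra, ...),
        watch = judge_solo(if (is.na(ra)) rb else ra, ...),
        abort(sprintf("unknown condition '%s'", cond))
      )
    },
    ...
  ) %>% list_rbind()
  dplyr::bind_cols(events, out)
}

#' Block accuracy
#'
#' Proportion of trials judged successful: for cooperation and communication
#' blocks this is the share of trials whose response-time difference fell
#' within the margin of error.
#'
#' @param outcomes Tibble of trial outcomes (needs a `judged` column), or a
#'   character vector of judged labels.
#' @return Fraction in `[0, 1]`.
#' @export
block_accuracy <- function(outcomes) {
  judged <- if (is.character(outcomes)) outcomes else outcomes$judged
  if (length(judged) < 1) {
    abort("accuracy is undefined for an empty trial list.", class = "dyadcoh_domain_error")
  }
  mean(judged == "success")
}
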