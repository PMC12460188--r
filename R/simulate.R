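CONDITIONS <- c("cooperation", "communication", "competition", "solo", "watch")

# run a block of code under a temporary RNG seed, restoring caller state
.with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

# deterministic 32-bit sub-seed from a master seed and a few small indices;
# keeps every product within exact double range and the result below 2^31
.derive_seed <- function(seed, ...) {
  idx <- c(...)
  m <- 2147483629
  acc <- seed %% m
  mult <- c(104729, 1299709, 15485863, 32452843, 49979687, 86028121)
  for (i in seq_along(idx)) {
    acc <- (acc * 3457 + idx[i] * mult[((i - 1) %% length(mult)) + 1]) %% m
  }
  as.integer(acc)
}

#' Coupling specification for the synthetic cohort
#'
#' Declares which (ROI, condition) cells of a simulated cohort carry a shared
#' band-limited oscillatory component between the two members of every dyad.
#'
#' @param rois Integer ROI indices receiving the coupled component.
#' @param conditions Condition labels during which the coupling is active.
#' @param band Frequency band `c(low, high)` of the shared component in Hz.
#' @param amplitude Amplitude of the shared component as a multiple of the
#'   background-noise standard deviation.
#' @param phase_lag Phase lag (radians) applied to the second subject's copy.
#' @return A tibble with one row per (ROI, condition) cell.
#' @export
coupling_spec <- function(rois, conditions = "cooperation", band = c(0.08, 0.15),
                          amplitude = 1.5, phase_lag = 0) {
  stopifnot(length(band) == 2, band[1] < band[2])
  if (!all(conditions %in% CONDITIONS)) {
    abort("coupling conditions must be drawn from the five task conditions.",
      class = "dyadcoh_config_error"
    )
  }
  expand_grid(roi = as.integer(rois), condition = conditions) %>%
    mutate(
      band_low = band[1], band_high = band[2],
      amplitude = amplitude, phase_lag = phase_lag
    )
}

#' Simulation configuration
#'
#' Bundles every parameter of the synthetic dyadic-fMRI generator. Defaults
#' mirror the acquisition and task design the pipeline targets: TR 1.5 s, two
#' runs of 775 volumes, five task blocks per run in fixed order (the solo and
#' watch blocks swap between runs), 5 s planning phase, stimulus delay
#' averaging 1.05 s and feedback averaging 2.55 s with delay and feedback
#' jitter coupled so trial durations stay constant.
#'
#' @param n_dyads Number of dyads (two subjects each, one per scanner).
#' @param n_rois Number of regions of interest per subject.
#' @param tr Sampling interval (repetition time) in seconds.
#' @param n_volumes_per_run Volumes acquired per run.
#' @param n_runs Number of runs.
#' @param block_order Condition order of the first run's five blocks.
#' @param trial_count_per_block Trials per block.
#' @param planning_duration Planning-phase duration (s).
#' @param mean_stim_delay Mean pseudo-random delay before the go stimulus (s);
#'   the delay is uniform on `mean_stim_delay + c(-0.45, 0.45)`.
#' @param mean_feedback_duration Mean feedback duration (s); feedback absorbs
#'   the delay jitter so planning + delay + feedback is constant.
#' @param instruction_duration Instruction/rest screen before each block (s).
#' @param timeout Response time-out (s).
#' @param coupling A [coupling_spec()] tibble, or `NULL` for an uncoupled
#'   (null) cohort.
#' @param noise Background-noise model: list with `ar` (AR(1) coefficient),
#'   `sd` (stationary standard deviation) and `one_over_f` (power-law
#'   exponent of an optional 1/f spectral shaping; 0 disables it).
#' @param rt_params Per-condition response-time model parameters; a named list
#'   of lists with `means`, `sds`, `correlation` (see [simulate_rts()]).
#' @param seed Master integer seed; all per-subject and per-dyad RNG streams
#'   are derived from it so adding dyads never perturbs existing ones.
#' @return A `sim_config` list, validated.
#' @export
sim_config <- function(n_dyads = 12, n_rois = 10, tr = 1.5,
                       n_volumes_per_run = 775, n_runs = 2,
                       block_order = CONDITIONS,
                       trial_count_per_block = 18,
                       planning_duration = 5,
                       mean_stim_delay = 1.05,
                       mean_feedback_duration = 2.55,
                       instruction_duration = 10,
                       timeout = 6,
                       coupling = NULL,
                       noise = list(ar = 0.3, sd = 1, one_over_f = 0),
                       rt_params = NULL,
                       seed = 1) {
  if (tr <= 0) abort("`tr` must be positive.", class = "dyadcoh_config_error")
  if (!setequal(block_order, CONDITIONS)) {
    abort("`block_order` must contain each of the five conditions once.",
      class = "dyadcoh_config_error"
    )
  }
  nyquist <- 1 / (2 * tr)
  if (!is.null(coupling)) {
    if (any(coupling$band_low <= 0) || any(coupling$band_high >= nyquist)) {
      abort(sprintf(
        "coupling band must lie within (0, Nyquist = %.4g Hz).", nyquist
      ), class = "dyadcoh_config_error")
    }
    if (any(!coupling$condition %in% CONDITIONS)) {
      abort("coupling conditions must be task conditions.", class = "dyadcoh_config_error")
    }
    if (any(coupling$roi > n_rois)) {
      abort("coupling ROI index exceeds `n_rois`.", class = "dyadcoh_config_error")
    }
  }
  defaults <- list(
    cooperation = list(means = c(1.9, 1.9), sds = c(0.45, 0.45), correlation = 0.4),
    communication = list(means = c(1.9, 1.9), sds = c(0.45, 0.45), correlation = 0.4),
    competition = list(means = c(0.55, 0.55), sds = c(0.12, 0.12), correlation = 0.1),
    solo = list(means = c(0.9, 0.9), sds = c(0.3, 0.3), correlation = 0),
    watch = list(means = c(0.9, 0.9), sds = c(0.3, 0.3), correlation = 0)
  )
  if (!is.null(rt_params)) defaults[names(rt_params)] <- rt_params
  cfg <- list(
    n_dyads = as.integer(n_dyads), n_rois = as.integer(n_rois), tr = tr,
    n_volumes_per_run = as.integer(n_volumes_per_run), n_runs = as.integer(n_runs),
    block_order = block_order, trial_count_per_block = as.integer(trial_count_per_block),
    planning_duration = planning_duration, mean_stim_delay = mean_stim_delay,
    mean_feedback_duration = mean_feedback_duration,
    instruction_duration = instruction_duration, timeout = timeout,
    coupling = coupling, noise = noise, rt_params = defaults, seed = as.integer(seed)
  )
  # schedule must fit in the run: worst-case trial = planning + delay + timeout
  # jitter absorbed by feedback, so per-trial span = planning + mean_delay +
  # mean_feedback + response phase (bounded by timeout)
  worst <- 5 * (instruction_duration +
    trial_count_per_block * (planning_duration + mean_stim_delay +
      mean_feedback_duration + timeout))
  typical <- 5 * (instruction_duration +
    trial_count_per_block * (planning_duration + mean_stim_delay +
      mean_feedback_duration + 2.5))
  if (typical > n_volumes_per_run * tr) {
    abort(sprintf(
      "block schedule (~%.0f s) does not fit in a run of %d volumes x %.2g s.",
      typical, n_volumes_per_run, tr
    ), class = "dyadcoh_config_error")
  }
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> %d dyads, %d ROIs, %d runs x %d volumes @ TR %g s, %d coupled cells, seed %d\n",
    x$n_dyads, x$n_rois, x$n_runs, x$n_volumes_per_run, x$tr,
    if (is.null(x$coupling)) 0L else nrow(x$coupling), x$seed
  ))
  invisible(x)
}

#' Simulate correlated response-time pairs
#'
#' Draws `(rt_a, rt_b)` pairs from a bivariate normal model with configurable
#' means, standard deviations and within-trial correlation, truncated below at
#' 0.2 s. Means below 1.6 s put the pair in the fast-responder regime that
#' triggers the margin-shrinking response-time adjustment.
#'
#' @param condition Task condition; selects default parameters (cooperative
#'   conditions are slow and correlated, competition fast and nearly
#'   independent).
#' @param n_trials Number of trials (>= 1).
#' @param means,sds Length-2 numeric: per-subject mean and SD in seconds.
#' @param correlation Within-trial correlation of the two response times.
#' @param seed Optional integer seed (caller RNG state is preserved).
#' @return A tibble with `trial`, `rt_a`, `rt_b`.
#' @export
simulate_rts <- function(condition = "cooperation", n_trials = 18,
                         means = NULL, sds = NULL, correlation = NULL,
                         seed = NULL) {
  if (n_trials < 1) abort("`n_trials` must be >= 1.", class = "dyadcoh_config_error")
  p <- sim_config()$rt_params[[condition]]
  if (is.null(p)) abort(sprintf("unknown condition '%s'", condition), class = "dyadcoh_config_error")
  if (!is.null(means)) p$means <- rep(means, length.out = 2)
  if (!is.null(sds)) p$sds <- rep(sds, length.out = 2)
  if (!is.null(correlation)) p$correlation <- correlation
  if (any(p$sds < 0)) abort("`sds` must be non-negative.", class = "dyadcoh_config_error")
  if (abs(p$correlation) > 1) abort("`correlation` must be in [-1, 1].", class = "dyadcoh_config_error")
  .with_seed(seed, {
    z1 <- rnorm(n_trials)
    z2 <- p$correlation * z1 + sqrt(1 - p$correlation^2) * rnorm(n_trials)
    tibble(
      trial = seq_len(n_trials),
      rt_a = pmax(0.2, p$means[1] + p$sds[1] * z1),
      rt_b = pmax(0.2, p$means[2] + p$sds[2] * z2)
    )
  })
}

# one run's event table for one dyad. Roles: in a run whose order lists
# "solo" the first member (a) performs it and watches during "watch"; roles
# swap with the swapped block order of the next run.
.simulate_run_events <- function(config, dyad, run) {
  order <- config$block_order
  if (run %% 2 == 0) { # solo/watch reversed for even runs
    i_s <- match("solo", order)
    i_w <- match("watch", order)
    order[c(i_s, i_w)] <- order[c(i_w, i_s)]
  }
  set.seed(.derive_seed(config$seed, dyad, run, 1))
  rows <- vector("list", length(order))
  t_now <- 0
  for (b in seq_along(order)) {
    cond <- order[b]
    t_now <- t_now + config$instruction_duration
    rts <- simulate_rts(cond, config$trial_count_per_block,
      means = config$rt_params[[cond]]$means,
      sds = config$rt_params[[cond]]$sds,
      correlation = config$rt_params[[cond]]$correlation
    )
    if (cond == "solo") rts$rt_b <- NA_real_
    if (cond == "watch") rts$rt_a <- NA_real_
    delays <- runif(config$trial_count_per_block,
      config$mean_stim_delay - 0.45, config$mean_stim_delay + 0.45
    )
    trial_rows <- vector("list", config$trial_count_per_block)
    for (k in seq_len(config$trial_count_per_block)) {
      plan_on <- t_now
      stim_on <- plan_on + config$planning_duration + delays[k]
      resp_end <- min(max(rts$rt_a[k], rts$rt_b[k], na.rm = TRUE), config$timeout)
      fb_on <- stim_on + resp_end
      fb_dur <- config$mean_feedback_duration + (config$mean_stim_delay - delays[k])
      trial_rows[[k]] <- tibble(
        onset = c(plan_on, stim_on, fb_on),
        duration = c(config$planning_duration + delays[k], resp_end, fb_dur),
        event = c("planning", "stimulus", "feedback"),
        condition = cond, block = b, trial = k,
        rt_a = rts$rt_a[k], rt_b = rts$rt_b[k]
      )
      t_now <- fb_on + fb_dur
    }
    trial_tbl <- list_rbind(trial_rows)
    block_row <- tibble(
      onset = trial_tbl$onset[1],
      duration = t_now - trial_tbl$onset[1],
      event = "block", condition = cond, block = b, trial = NA_integer_,
      rt_a = NA_real_, rt_b = NA_real_
    )
    rows[[b]] <- bind_rows(block_row, trial_tbl)
  }
  out <- list_rbind(rows)
  if (max(out$onset + out$duration) > config$n_volumes_per_run * config$tr) {
    abort("simulated schedule overran the run; increase `n_volumes_per_run`.",
      class = "dyadcoh_config_error"
    )
  }
  out
}

# AR(1) background noise with optional 1/f spectral shaping, unit variance
# then scaled to `sd`
.bold_noise <- function(n, ar, sd, one_over_f, dt) {
  x <- rnorm(n)
  if (one_over_f > 0) {
    xh <- fft(x)
    f <- c(0, pmin(seq_len(n - 1), n - seq_len(n - 1))) / (n * dt)
    shape <- c(0, f[-1]^(-one_over_f / 2))
    x <- Re(fft(xh * shape, inverse = TRUE)) / n
  }
  x <- as.numeric(stats::filter(x, ar, method = "recursive"))
  sd * x / stats::sd(x)
}

# shared band-limited component of length n samples, unit SD, plus a
# phase-lagged copy (positive-frequency phases rotated by -phase_lag)
.bandlimited_pair <- function(n, dt, f_low, f_high, phase_lag) {
  w <- rnorm(n)
  wh <- fft(w)
  f <- c(0, pmin(seq_len(n - 1), n - seq_len(n - 1))) / (n * dt)
  keep <- f >= f_low & f <= f_high
  wh[!keep] <- 0
  base <- Re(fft(wh, inverse = TRUE)) / n
  pos <- seq(2, ceiling(n / 2)) # positive-frequency bins
  wh_lag <- wh
  wh_lag[pos] <- wh_lag[pos] * exp(-1i * phase_lag)
  neg <- n + 2 - pos
  wh_lag[neg] <- Conj(wh_lag[pos])
  lagged <- Re(fft(wh_lag, inverse = TRUE)) / n
  s <- stats::sd(base)
  list(a = base / s, b = lagged / s)
}

#' Simulate a dyadic hyperscanning cohort
#'
#' Generates a full synthetic dataset: for every dyad, two subjects' per-run
#' ROI time series (independent AR(1)/1-over-f background noise), BIDS-style
#' event tables following the five-block task schedule, and - in the (ROI,
#' condition) cells named by the coupling specification - an additive shared
#' band-limited component with configurable amplitude and phase lag, injected
#' over that condition's block span. Ground truth records exactly which cells
#' are coupled. All randomness derives from per-subject / per-dyad streams
#' seeded from `config$seed`, so output is reproducible bit for bit and
#' adding dyads never changes existing ones.
#'
#' @param config A [sim_config()] object.
#' @return A `dyad_cohort` list: `manifest` (subject/dyad/scanner tibble),
#'   `series` (tibble subject_id, run, series matrix of volumes x ROIs),
#'   `events` (tibble with dyad_id, run and event columns), `ground_truth`,
#'   `roi_missing` (per subject x ROI missing-data fraction, all zero here),
#'   and `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  manifest <- tibble(
    dyad_id = rep(seq_len(config$n_dyads), each = 2),
    subject_id = sprintf(
      "sub-%03d%s", rep(seq_len(config$n_dyads), each = 2),
      rep(c("a", "b"), config$n_dyads)
    ),
    role = rep(c("a", "b"), config$n_dyads),
    scanner = rep(c("scanner_A", "scanner_B"), config$n_dyads)
  )
  n <- config$n_volumes_per_run

  events <- list_rbind(lapply(seq_len(config$n_dyads), function(d) {
    list_rbind(lapply(seq_len(config$n_runs), function(r) {
      .simulate_run_events(config, d, r) %>%
        mutate(dyad_id = d, run = r, .before = 1)
    }))
  }))

  series <- list_rbind(lapply(seq_len(config$n_dyads), function(d) {
    list_rbind(lapply(c("a", "b"), function(role) {
      subj_idx <- 2 * (d - 1) + match(role, c("a", "b"))
      list_rbind(lapply(seq_len(config$n_runs), function(r) {
        set.seed(.derive_seed(config$seed, subj_idx, r, 2))
        mat <- vapply(
          seq_len(config$n_rois),
          function(roi) {
            .bold_noise(
              n, config$noise$ar, config$noise$sd,
              config$noise$one_over_f, config$tr
            )
          },
          numeric(n)
        )
        tibble(
          dyad_id = d, subject_id = manifest$subject_id[subj_idx], role = role,
          run = r, series = list(mat)
        )
      }))
    }))
  }))

  if (!is.null(config$coupling) && nrow(config$coupling) > 0) {
    blocks <- dplyr::filter(events, .data$event == "block")
    for (d in seq_len(config$n_dyads)) {
      for (ci in seq_len(nrow(config$coupling))) {
        cp <- config$coupling[ci, ]
        for (r in seq_len(config$n_runs)) {
          blk <- dplyr::filter(
            blocks, .data$dyad_id == d, .data$run == r,
            .data$condition == cp$condition
          )
          if (nrow(blk) == 0) next
          i0 <- max(1L, ceiling(blk$onset / config$tr) + 1L)
          i1 <- min(n, floor((blk$onset + blk$duration) / config$tr))
          if (i1 <= i0) next
          len <- i1 - i0 + 1L
          set.seed(.derive_seed(config$seed, d, ci, r, 3))
          comp <- .bandlimited_pair(
            len, config$tr, cp$band_low, cp$band_high, cp$phase_lag
          )
          amp <- cp$amplitude * config$noise$sd
          ia <- which(series$dyad_id == d & series$role == "a" & series$run == r)
          ib <- which(series$dyad_id == d & series$role == "b" & series$run == r)
          series$series[[ia]][i0:i1, cp$roi] <-
            series$series[[ia]][i0:i1, cp$roi] + amp * comp$a
          series$series[[ib]][i0:i1, cp$roi] <-
            series$series[[ib]][i0:i1, cp$roi] + amp * comp$b
        }
      }
    }
  }

  ground_truth <- expand_grid(
    dyad_id = seq_len(config$n_dyads),
    roi = seq_len(config$n_rois),
    condition = CONDITIONS
  ) %>%
    left_join(
      if (is.null(config$coupling) || nrow(config$coupling) == 0) {
        tibble(
          roi = integer(), condition = character(), amplitude = double(),
          band_low = double(), band_high = double(), phase_lag = double()
        )
      } else {
        config$coupling
      },
      by = c("roi", "condition")
    ) %>%
    mutate(
      coupled = !is.na(.data$amplitude),
      amplitude = dplyr::coalesce(.data$amplitude, 0)
    )

  roi_missing <- expand_grid(
    subject_id = manifest$subject_id, roi = seq_len(config$n_rois)
  ) %>% mutate(missing_frac = 0)

  structure(
    list(
      manifest = manifest, series = series, events = events,
      ground_truth = ground_truth, roi_missing = roi_missing, config = config
    ),
    class = "dyad_cohort"
  )
}

#' @export
print.dyad_cohort <- function(x, ...) {
  cat(sprintf(
    "<dyad_cohort> %d dyads, %d ROIs, %d runs x %d volumes @ TR %g s (%d coupled cells)\n",
    x$config$n_dyads, x$config$n_rois, x$config$n_runs,
    x$config$n_volumes_per_run, x$config$tr,
    sum(x$ground_truth$coupled) / x$config$n_dyads
  ))
  invisible(x)
}

#' Two-tone demonstration signal pair
#'
#' Builds the classic wavelet-coherence demonstration pair: signal X is a sum
#' of sine components at a slow and a fast frequency, each active over a
#' configurable, partially overlapping sub-interval; signal Y carries the
#' matching cosine components (a quarter-cycle phase offset) plus independent
#' Gaussian noise. Their coherence shows two phase-locked clusters, one per
#' tone, with a cross-phase of magnitude pi/2.
#'
#' @param duration Record length in seconds; must cover at least three cycles
#'   of the slow component.
#' @param dt Sampling interval in seconds.
#' @param noise_sd Standard deviation of the additive Gaussian noise (0 gives
#'   exact quadrature sinusoids).
#' @param f_slow,f_fast Component frequencies in Hz.
#' @param slow_span,fast_span Active sub-intervals as fractions `c(from, to)`
#'   of the record.
#' @param seed Optional seed for the noise.
#' @return A tibble with `time`, `x`, `y`.
#' @export
demo_signal_pair <- function(duration = 1600, dt = 1, noise_sd = 0.25,
                             f_slow = 0.005, f_fast = 0.04,
                             slow_span = c(0, 0.65), fast_span = c(0.35, 1),
                             seed = NULL) {
  if (duration < 3 / f_slow) {
    abort("`duration` must cover at least three cycles of the slow component.",
      class = "dyadcoh_config_error"
    )
  }
  t <- seq(0, duration - dt, by = dt)
  on_slow <- t >= slow_span[1] * duration & t < slow_span[2] * duration
  on_fast <- t >= fast_span[1] * duration & t < fast_span[2] * duration
  .with_seed(seed, {
    x <- sin(2 * pi * f_slow * t) * on_slow + sin(2 * pi * f_fast * t) * on_fast +
      rnorm(length(t), 0, noise_sd)
    y <- cos(2 * pi * f_slow * t) * on_slow + cos(2 * pi * f_fast * t) * on_fast +
      rnorm(length(t), 0, noise_sd)
    tibble(time = t, x = x, y = y)
  })
}
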