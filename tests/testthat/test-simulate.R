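test_that("simulation is deterministic and dyad-stable given a seed", {
  cfg <- tiny_config()
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$series$series, b$series$series)
  expect_identical(a$events, b$events)
  # adding dyads never perturbs existing ones
  big <- simulate_cohort(tiny_config(n_dyads = 5))
  for (i in seq_len(nrow(a$series))) {
    key <- paste(a$series$subject_id[i], a$series$run[i])
    j <- match(key, paste(big$series$subject_id, big$series$run))
    expect_identical(a$series$series[[i]], big$series$series[[j]])
  }
})

test_that("cohort geometry matches its configuration", {
  cfg <- tiny_config(n_dyads = 2, n_rois = 3)
  coh <- simulate_cohort(cfg)
  expect_identical(nrow(coh$manifest), 4L)
  expect_identical(length(unique(coh$manifest$scanner)), 2L)
  expect_true(all(table(coh$manifest$dyad_id) == 2))
  expect_identical(nrow(coh$series), 2L * 2L * cfg$n_runs)
  for (m in coh$series$series) {
    expect_identical(dim(m), c(cfg$n_volumes_per_run, cfg$n_rois))
    expect_true(all(is.finite(m)))
  }
  # five blocks per run, solo/watch swapped in run 2
  blocks1 <- coh$events %>%
    dplyr::filter(dyad_id == 1, run == 1, event == "block") %>%
    dplyr::pull(condition)
  blocks2 <- coh$events %>%
    dplyr::filter(dyad_id == 1, run == 2, event == "block") %>%
    dplyr::pull(condition)
  expect_identical(sort(blocks1), sort(c(
    "cooperation", "communication", "competition", "solo", "watch"
  )))
  expect_identical(
    which(blocks1 == "solo") == which(blocks2 == "watch"), TRUE
  )
})

test_that("event tables satisfy their ordering and span invariants", {
  coh <- simulate_cohort(tiny_config())
  ev <- coh$events %>% dplyr::filter(dyad_id == 2, run == 1)
  trials <- ev %>% dplyr::filter(event != "block")
  expect_true(!is.unsorted(trials$onset))
  expect_true(all(ev$rt_a > 0, na.rm = TRUE))
  expect_true(all(ev$rt_b > 0, na.rm = TRUE))
  # block rows span their trial rows
  for (b in unique(ev$block)) {
    blk <- ev %>% dplyr::filter(block == b, event == "block")
    tr <- ev %>% dplyr::filter(block == b, event != "block")
    expect_lte(blk$onset, min(tr$onset))
    expect_gte(blk$onset + blk$duration, max(tr$onset + tr$duration))
  }
  # solo blocks have only the performer's response times
  solo <- ev %>% dplyr::filter(condition == "solo", event == "stimulus")
  watch <- ev %>% dplyr::filter(condition == "watch", event == "stimulus")
  expect_true(all(!is.na(solo$rt_a)) && all(is.na(solo$rt_b)))
  expect_true(all(is.na(watch$rt_a)) && all(!is.na(watch$rt_b)))
})

test_that("coupling bands outside (0, Nyquist) are rejected", {
  expect_error(
    tiny_config(coupling = coupling_spec(1, band = c(0.2, 0.5))),
    class = "dyadcoh_config_error"
  )
  expect_error(
    sim_config(trial_count_per_block = 100, n_volumes_per_run = 300),
    class = "dyadcoh_config_error"
  )
})

test_that("coupled cells share band-limited signal, uncoupled cells do not", {
  cfg <- sim_config(
    n_dyads = 1, n_rois = 2, n_volumes_per_run = 700,
    trial_count_per_block = 12,
    coupling = coupling_spec(1, "cooperation", band = c(0.08, 0.15), amplitude = 8),
    seed = 3
  )
  coh <- simulate_cohort(cfg)
  g <- build_scale_grid(0.01, 0.28, voices = 12, dt = 1.5)
  win <- block_windows(
    dplyr::filter(coh$events, dyad_id == 1, run == 1),
    hemo_exclusion = 5, tr = 1.5
  )
  coop <- win[win$condition == "cooperation", ]
  a <- coh$series$series[[1]]
  b <- coh$series$series[[3]]
  m1 <- wtc(a[, 1], b[, 1], g)
  m2 <- wtc(a[, 2], b[, 2], g)
  in_band <- extract_term(m1, coop, c(0.08, 0.15))
  out_band <- extract_term(m1, coop, c(0.02, 0.0375)) # two octaves below
  uncoupled <- extract_term(m2, coop, c(0.08, 0.15))
  expect_gt(in_band, 0.9)
  expect_lt(out_band, 0.7)
  expect_lt(uncoupled, 0.7)
  expect_gt(in_band - max(out_band, uncoupled), 0.25)
})

test_that("a configured phase lag appears in the cross-phase", {
  lag <- pi / 3
  cfg <- sim_config(
    n_dyads = 1, n_rois = 1, n_volumes_per_run = 700,
    trial_count_per_block = 12,
    coupling = coupling_spec(1, "cooperation",
      band = c(0.09, 0.11), amplitude = 10, phase_lag = lag
    ),
    seed = 9
  )
  coh <- simulate_cohort(cfg)
  g <- build_scale_grid(0.02, 0.2, voices = 12, dt = 1.5)
  win <- block_windows(
    dplyr::filter(coh$events, dyad_id == 1, run == 1), 5, 1.5
  )
  coop <- win[win$condition == "cooperation", ]
  b_run1 <- which(coh$series$role == "b" & coh$series$run == 1)
  m <- wtc(coh$series$series[[1]][, 1], coh$series$series[[b_run1]][, 1], g)
  j <- which.min(abs(g$frequencies - 0.1))
  cols <- (coop$start_index + 1):coop$end_index
  expect_lt(abs(circ_mean(m$phase[j, cols]) - lag), 0.25)
})

test_that("response-time simulation validates inputs and reproduces", {
  expect_error(simulate_rts(n_trials = 0), class = "dyadcoh_config_error")
  expect_error(simulate_rts(sds = c(-1, 1)), class = "dyadcoh_config_error")
  r1 <- simulate_rts("competition", 10, seed = 2)
  r2 <- simulate_rts("competition", 10, seed = 2)
  expect_identical(r1, r2)
  expect_true(all(r1$rt_a >= 0.2))
  # fast-responder regime sits below the adjustment breakpoint
  expect_lt(mean(c(r1$rt_a, r1$rt_b)), 1.6)
})

test_that("demonstration signals are exact quadrature sinusoids when noise-free", {
  sig <- demo_signal_pair(duration = 800, noise_sd = 0)
  t <- sig$time
  slow_on <- t < 0.65 * 800 # default slow span, fast span starts at 0.35
  pure <- t < 0.35 * 800
  expect_equal(sig$x[pure], sin(2 * pi * 0.005 * t[pure]), tolerance = 1e-12)
  expect_equal(sig$y[pure], cos(2 * pi * 0.005 * t[pure]), tolerance = 1e-12)
  expect_error(demo_signal_pair(duration = 100), class = "dyadcoh_config_error")
})
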