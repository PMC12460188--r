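# build a coherence_spectrum directly for unit tests
make_spectrum <- function(curve, grid, n_rois = 3) {
  structure(
    list(
      roi_by_scale = matrix(rep(curve, each = n_rois), n_rois, length(curve)),
      mean_curve = curve,
      frequencies = grid$frequencies,
      grid = grid, rois = seq_len(n_rois), n_dyads = 1
    ),
    class = "coherence_spectrum"
  )
}

test_that("spectrum averaging reduces to the right identities", {
  g <- build_scale_grid(0.02, 0.2, voices = 6, dt = 1)
  const_map <- structure(
    list(
      r2 = matrix(0.4, g$n_scales, 100),
      phase = matrix(0, g$n_scales, 100),
      coi = cone_of_influence(g, 100), grid = g, n_samples = 100
    ),
    class = "coherence_map"
  )
  maps <- tibble::tibble(dyad_id = 1L, roi = 1L, map = list(const_map))
  win <- tibble::tibble(start_index = 10L, end_index = 60L)
  sp <- mean_coherence_spectrum(maps, win)
  expect_equal(unname(sp$mean_curve), rep(0.4, g$n_scales))
  # single map: spectrum equals that map's windowed time-mean per scale
  set.seed(1)
  m2 <- const_map
  m2$r2 <- matrix(runif(g$n_scales * 100), g$n_scales, 100)
  maps2 <- tibble::tibble(dyad_id = 1L, roi = 1L, map = list(m2))
  sp2 <- mean_coherence_spectrum(maps2, win)
  expect_equal(sp2$roi_by_scale[1, ], rowMeans(m2$r2[, 11:60]))
  expect_error(mean_coherence_spectrum(maps2, win[0, ]), class = "dyadcoh_domain_error")
})

test_that("trimming drops artifact extremes and is idempotent", {
  g <- build_scale_grid(0.0039, 0.2894, voices = 12, dt = 1.5)
  sp <- make_spectrum(seq_len(g$n_scales) / g$n_scales, g)
  tr <- trim_spectrum(sp) # defaults 9.6-220 mHz
  expect_true(all(tr$frequencies >= 0.0096 & tr$frequencies <= 0.220))
  expect_lt(length(tr$frequencies), length(sp$frequencies))
  tr2 <- trim_spectrum(tr)
  expect_identical(tr$mean_curve, tr2$mean_curve)
  # trim at the grid extremes is the identity
  full <- trim_spectrum(sp, min(g$frequencies), max(g$frequencies))
  expect_identical(full$mean_curve, sp$mean_curve)
  expect_error(trim_spectrum(sp, 0.5, 0.6), class = "dyadcoh_domain_error")
})

test_that("band edges sit at the steepest slopes around a Gaussian peak", {
  g <- build_scale_grid(0.005, 0.25, voices = 12, dt = 1.5)
  i0 <- 34
  sigma <- 4
  curve <- exp(-((seq_len(g$n_scales) - i0)^2) / (2 * sigma^2))
  sp <- make_spectrum(curve, g)
  sel <- select_band(sp)
  # inflection points of a Gaussian lie one sigma either side of the peak
  expect_equal(sel$f_peak, g$frequencies[i0])
  expect_equal(sel$f_high, g$frequencies[i0 - sigma])
  expect_equal(sel$f_low, g$frequencies[i0 + sigma])
  expect_true(sel$f_low < sel$f_peak && sel$f_peak < sel$f_high)
})

test_that("a triangular peak puts the edges at its feet", {
  g <- build_scale_grid(0.005, 0.25, voices = 12, dt = 1.5)
  curve <- rep(0.2, g$n_scales)
  apex <- 30
  ramp <- 6
  idx <- (apex - ramp):(apex + ramp)
  curve[idx] <- 0.2 + (ramp - abs(idx - apex)) * 0.05
  sel <- select_band(make_spectrum(curve, g))
  expect_equal(sel$f_peak, g$frequencies[apex])
  # steepest discrete slope of a triangle lies just inside its feet, where
  # the central difference still sees the full ramp on one side
  expect_equal(sel$f_high, g$frequencies[apex - ramp + 1])
  expect_equal(sel$f_low, g$frequencies[apex + ramp - 1])
})

test_that("band selection is invariant to affine rescaling of the curve", {
  g <- build_scale_grid(0.005, 0.25, voices = 12, dt = 1.5)
  curve <- exp(-((seq_len(g$n_scales) - 30)^2) / 32)
  s1 <- select_band(make_spectrum(curve, g))
  s2 <- select_band(make_spectrum(5 * curve + 0.3, g))
  expect_identical(s1$band, s2$band)
  expect_identical(s1$f_peak, s2$f_peak)
})

test_that("monotone curves yield a no-band error", {
  g <- build_scale_grid(0.005, 0.25, voices = 12, dt = 1.5)
  expect_error(
    select_band(make_spectrum(seq_len(g$n_scales) / g$n_scales, g)),
    class = "dyadcoh_no_band_error"
  )
})

test_that("a coupled cohort's spectrum peaks within a voice of the coupling band", {
  cfg <- sim_config(
    n_dyads = 4, n_rois = 2, n_volumes_per_run = 700, trial_count_per_block = 12,
    coupling = coupling_spec(1:2, CONDS <- c(
      "cooperation", "communication", "competition", "solo", "watch"
    ), band = c(0.095, 0.105), amplitude = 3),
    seed = 21
  )
  coh <- simulate_cohort(cfg)
  g <- build_scale_grid(0.0039, 0.28, voices = 12, dt = 1.5)
  maps <- list()
  k <- 0
  for (d in 1:4) {
    wa <- which(coh$series$dyad_id == d & coh$series$role == "a" & coh$series$run == 1)
    wb <- which(coh$series$dyad_id == d & coh$series$role == "b" & coh$series$run == 1)
    for (roi in 1:2) {
      k <- k + 1
      maps[[k]] <- tibble::tibble(
        dyad_id = d, roi = roi,
        map = list(wtc(
          coh$series$series[[wa]][, roi], coh$series$series[[wb]][, roi], g
        ))
      )
    }
  }
  win <- block_windows(dplyr::filter(coh$events, dyad_id == 1, run == 1), 5, 1.5)
  sp <- mean_coherence_spectrum(purrr::list_rbind(maps), win)
  f_peak <- sp$frequencies[which.max(sp$mean_curve)]
  expect_lt(abs(log2(f_peak / 0.1)), 1 / 12 + 1e-9)
})
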