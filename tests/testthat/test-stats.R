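test_that("Fisher z matches atanh and its symmetry", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), 0.5 * log(3)) # 0.5493
  expect_equal(fisher_z(0.5), 0.5493, tolerance = 1e-4)
  expect_equal(fisher_z(-0.5), -fisher_z(0.5))
  x <- seq(-0.95, 0.95, by = 0.05)
  expect_true(all(diff(fisher_z(x)) > 0))
  expect_error(fisher_z(NA_real_), class = "dyadcoh_domain_error")
  expect_true(is.finite(fisher_z(1))) # clipped before atanh
})

test_that("IQR fence removes gross outliers; clean samples are untouched", {
  v <- c(0.1, 0.11, 0.09, 0.1, 0.12, 5.0)
  out <- remove_outliers(v)
  expect_identical(out$log$reason, "iqr_fence")
  expect_identical(out$log$value, 5.0)
  expect_identical(out$kept, v[-6])
  same <- rep(0.2, 8)
  out2 <- remove_outliers(same)
  expect_identical(nrow(out2$log), 0L)
  expect_identical(out2$kept, same)
  expect_error(remove_outliers(1:3), class = "dyadcoh_domain_error")
})

test_that("moment-criteria removal rarely triggers on Gaussian samples", {
  set.seed(14)
  triggered <- replicate(100, {
    out <- remove_outliers(rnorm(30))
    any(out$log$reason == "moment_criteria")
  })
  expect_lt(mean(triggered), 0.2)
})

test_that("moment-criteria removal respects the 70 percent floor", {
  set.seed(15)
  v <- c(rnorm(14), rexp(6) * 20) # heavily skewed tail
  out <- remove_outliers(v)
  expect_gte(length(out$kept), ceiling(0.7 * 20))
})

test_that("rm-ANOVA reproduces the hand-computed 5 x 4 fixture term by term", {
  Y <- rbind(
    c(8, 7, 6, 7), c(9, 8, 7, 8), c(7, 6, 5, 6), c(8, 8, 7, 9), c(9, 8, 8, 8)
  )
  colnames(Y) <- c("cooperation", "communication", "competition", "solo")
  df <- tidyr::pivot_longer(
    dplyr::mutate(as.data.frame(Y), dyad_id = 1:5),
    -dplyr::all_of("dyad_id"),
    names_to = "condition", values_to = "value"
  )
  a <- rm_anova(df)
  # frozen from the definition: grand mean 7.45; SS_total = 22.95;
  # SS_subject = 4 * sum((rowmeans - grand)^2) = 14.2;
  # SS_condition = 5 * sum((colmeans - grand)^2) = 6.55; SS_error = 2.2
  expect_equal(a$ss_total, 22.95)
  expect_equal(a$ss_subject, 14.2)
  expect_equal(a$ss_condition, 6.55)
  expect_equal(a$ss_error, 2.2, tolerance = 1e-12)
  expect_equal(a$F, (6.55 / 3) / (2.2 / 12)) # 11.9090...
  expect_equal(a$n_subjects, 5L)
  expect_true(a$epsilon >= 1 / 3 && a$epsilon <= 1)
  # cross-check against the stock aov decomposition
  aov_fit <- summary(stats::aov(
    value ~ condition + Error(factor(dyad_id) / condition), data = df
  ))
  aov_tab <- aov_fit[["Error: factor(dyad_id):condition"]][[1]]
  expect_equal(a$F, aov_tab["condition", "F value"], tolerance = 1e-10)
})

test_that("Mauchly W and Greenhouse-Geisser epsilon match the car oracle", {
  skip_if_not_installed("car")
  set.seed(3)
  n <- 10
  Y <- matrix(rnorm(n * 4), n, 4) +
    matrix(rep(c(0, 0.3, 0.1, -0.2), each = n), n, 4)
  colnames(Y) <- c("cooperation", "communication", "competition", "solo")
  df <- tidyr::pivot_longer(
    dplyr::mutate(as.data.frame(Y), dyad_id = 1:n),
    -dplyr::all_of("dyad_id"),
    names_to = "condition", values_to = "value"
  )
  mine <- rm_anova(df)
  mod <- stats::lm(Y ~ 1)
  idata <- data.frame(cond = factor(colnames(Y), levels = colnames(Y)))
  s <- summary(car::Anova(mod, idata = idata, idesign = ~cond, type = 3),
    multivariate = FALSE
  )
  expect_equal(mine$mauchly_w, unname(s$sphericity.tests[1, 1]), tolerance = 1e-6)
  expect_equal(mine$mauchly_p, unname(s$sphericity.tests[1, 2]), tolerance = 2e-3)
  expect_equal(mine$epsilon, unname(s$pval.adjustments[1, "GG eps"]), tolerance = 1e-6)
  expect_equal(
    unname(s$univariate.tests["cond", "F value"]), mine$F,
    tolerance = 1e-8
  )
})

test_that("rm-ANOVA p-values are uniform under the null", {
  set.seed(16)
  n <- 12
  ps <- replicate(500, {
    df <- tidyr::expand_grid(dyad_id = 1:n, condition = letters[1:4]) %>%
      dplyr::mutate(value = rnorm(n * 4) + rep(rnorm(n), each = 4))
    rm_anova(df)$p_value
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
  expect_lt(abs(mean(ps < 0.05) - 0.05), 0.03)
})

test_that("rm-ANOVA detects a shifted condition", {
  set.seed(17)
  n <- 30
  hits <- replicate(50, {
    df <- tidyr::expand_grid(dyad_id = 1:n, condition = letters[1:4]) %>%
      dplyr::mutate(
        value = rnorm(n * 4) + rep(rnorm(n), each = 4) +
          ifelse(condition == "a", 1, 0)
      )
    rm_anova(df)$p_value < 0.05
  })
  expect_gt(mean(hits), 0.9)
})

test_that("epsilon stays within its theoretical bounds for k = 4", {
  set.seed(18)
  for (i in 1:20) {
    df <- tidyr::expand_grid(dyad_id = 1:8, condition = letters[1:4]) %>%
      dplyr::mutate(value = rnorm(32))
    a <- rm_anova(df)
    expect_gte(a$epsilon, 1 / 3)
    expect_lte(a$epsilon, 1)
  }
})

test_that("BH FDR matches the brute-force step-up on exhaustive small inputs", {
  set.seed(19)
  for (i in 1:200) {
    m <- sample(1:12, 1)
    p <- runif(m)^sample(1:3, 1)
    q <- sample(c(0.01, 0.05, 0.1), 1)
    got <- fdr_bh(p, q)
    expect_identical(got$reject, oracle_bh_reject(p, q))
    expect_true(all(got$q_value >= got$p - 1e-12))
  }
  worked <- fdr_bh(c(0.001, 0.01, 0.02, 0.04, 0.5), 0.05)
  expect_identical(worked$reject, c(TRUE, TRUE, TRUE, TRUE, FALSE))
  expect_identical(fdr_bh(rep(1, 4))$reject, rep(FALSE, 4))
  expect_identical(fdr_bh(0.04)$reject, TRUE) # m = 1 reduces to p <= q
  expect_identical(fdr_bh(0.06)$reject, FALSE)
  expect_identical(nrow(fdr_bh(double())), 0L)
})

test_that("post hoc contrasts handle identical and degenerate pairs", {
  d <- tidyr::expand_grid(
    dyad_id = 1:6,
    condition = c("cooperation", "communication", "competition", "solo")
  ) %>% dplyr::mutate(roi = 1L, value = rep(c(0.4, 0.4, 0.4, 0.4), 6))
  rows <- posthoc_cooperation_tests(d, 1L)
  expect_identical(nrow(rows), 3L)
  expect_true(all(rows$t == 0))
  expect_true(all(rows$p == 1))
  # constant positive difference: p approaches 0, direction positive
  d2 <- d %>% dplyr::mutate(
    value = ifelse(condition == "cooperation", 0.5, 0.1)
  )
  rows2 <- posthoc_cooperation_tests(d2, 1L)
  expect_true(all(rows2$p == 0))
  expect_true(all(rows2$direction == 1L))
})

test_that("the stats stage runs transform, screening, omnibus and post hocs in order", {
  set.seed(20)
  n <- 16
  corrected <- tidyr::expand_grid(
    dyad_id = 1:n,
    condition = c("cooperation", "communication", "competition", "solo"),
    roi = 1:3
  ) %>%
    dplyr::mutate(
      value = 0.05 * rnorm(dplyr::n()) +
        ifelse(roi == 2 & condition == "cooperation", 0.25, 0)
    )
  st <- roi_stats(corrected)
  expect_identical(nrow(st$omnibus), 3L)
  expect_true(st$omnibus$significant[st$omnibus$roi == 2])
  expect_true(all(st$posthoc$roi == 2))
  coop_solo <- st$posthoc[st$posthoc$contrast == "coop-solo", ]
  expect_true(coop_solo$significant && coop_solo$direction == 1L)
  # q-values never undercut p-values
  ok <- !is.na(st$omnibus$q_value)
  expect_true(all(st$omnibus$q_value[ok] >= st$omnibus$p[ok]))
  # cells actually got the Fisher transform (values exceed raw bounds scale)
  expect_equal(
    sort(unique(st$cells$condition)),
    sort(unique(corrected$condition))
  )
})
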