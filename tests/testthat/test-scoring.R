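test_that("response-time adjustment matches its closed form", {
  expect_identical(adjust_rt(2.0), 2.0)
  # the adjustment applies strictly below the 1.6 s breakpoint; the formula
  # evaluated there, (e^1.6 - 1)/2.5 = 1.5812, shows the transition is smooth
  expect_identical(adjust_rt(1.6), 1.6)
  expect_equal((exp(1.6) - 1) / 2.5, 1.5812, tolerance = 1e-3)
  expect_equal(adjust_rt(1.0), (exp(1) - 1) / 2.5)
  expect_equal(adjust_rt(1.0), 0.6873, tolerance = 1e-3)
  expect_error(adjust_rt(0), class = "dyadcoh_domain_error")
  expect_error(adjust_rt(-1), class = "dyadcoh_domain_error")
})

test_that("adjustment is monotone, identity above the breakpoint, and smooth", {
  rts <- seq(0.05, 4, by = 0.05)
  adj <- adjust_rt(rts)
  expect_true(all(diff(adj) > 0))
  expect_identical(adj[rts >= 1.6], rts[rts >= 1.6])
  # continuity gap at the breakpoint below 1.2 percent
  expect_lt(abs(adjust_rt(1.6 - 1e-9) - 1.6) / 1.6, 0.012)
})

test_that("margin of error is symmetric and matches worked values", {
  expect_equal(margin_of_error(2.0, 2.0), 0.5)
  expect_equal(margin_of_error(1.0, 1.0), 2 * (exp(1) - 1) / 2.5 / 8)
  expect_equal(margin_of_error(1.0, 1.0), 0.1718, tolerance = 1e-3)
  expect_equal(margin_of_error(2.0, 2.3), 0.5375)
  set.seed(1)
  a <- runif(20, 0.3, 5)
  b <- runif(20, 0.3, 5)
  expect_equal(margin_of_error(a, b), margin_of_error(b, a))
})

test_that("fast responses are penalised more than proportionally", {
  expect_lt(margin_of_error(1, 1), margin_of_error(1.6, 1.6) * (1.0 / 1.6))
})

test_that("cooperation judging applies the margin rule", {
  expect_identical(judge_cooperation(2.0, 2.3)$judged, "success") # 0.3 <= 0.5375
  expect_identical(judge_cooperation(1.0, 1.0)$judged, "success") # zero diff
  out <- judge_cooperation(2.0, 2.8) # 0.8 > 0.6
  expect_identical(out$judged, "failure")
  expect_identical(c(out$points_a, out$points_b), c(-1L, -1L))
  # success is invariant under common scaling above the breakpoint
  for (c_scale in c(1, 1.5, 2)) {
    expect_identical(judge_cooperation(2.0 * c_scale, 2.3 * c_scale)$judged, "success")
    expect_identical(judge_cooperation(2.0 * c_scale, 2.8 * c_scale)$judged, "failure")
  }
})

test_that("invalid cooperation trials carry the larger deduction", {
  out <- judge_cooperation(NA, 2.0)
  expect_identical(out$judged, "invalid")
  expect_identical(c(out$points_a, out$points_b), c(-2L, -1L))
  out2 <- judge_cooperation(7.0, 2.0) # past the 6 s time-out
  expect_identical(out2$judged, "invalid")
  expect_identical(out2$points_a, -2L)
  out3 <- judge_cooperation(2.0, 2.1, premature_b = TRUE)
  expect_identical(c(out3$points_a, out3$points_b), c(-1L, -2L))
})

test_that("competition judging rewards the faster valid responder", {
  out <- judge_competition(1.2, 1.5)
  expect_identical(c(out$points_a, out$points_b), c(1L, -1L))
  tie <- judge_competition(1.2, 1.2)
  expect_identical(c(tie$points_a, tie$points_b), c(0L, 0L))
  to <- judge_competition(NA, 1.5) # a timed out: b wins, a deducted
  expect_identical(c(to$points_a, to$points_b), c(-2L, 1L))
})

test_that("solo judging awards any valid press", {
  expect_identical(judge_solo(3.0)$points_a, 1L)
  expect_identical(judge_solo(NA)$points_a, -2L)
  expect_identical(judge_solo(1.0, premature = TRUE)$points_a, -2L)
})

test_that("block accuracy is the success fraction", {
  outcomes <- c(rep("success", 3), rep("failure", 4), "invalid")
  expect_equal(block_accuracy(outcomes), 0.375)
  expect_equal(block_accuracy(rep("success", 5)), 1.0)
  expect_equal(block_accuracy(rep("failure", 5)), 0.0)
  expect_error(block_accuracy(character(0)), class = "dyadcoh_domain_error")
})

test_that("perfectly correlated equal response times always succeed", {
  rts <- simulate_rts("cooperation", 20, means = c(1.8, 1.8), sds = c(0.3, 0.3),
    correlation = 1, seed = 4
  )
  sc <- purrr::map2(rts$rt_a, rts$rt_b, judge_cooperation) %>% purrr::list_rbind()
  expect_true(all(sc$judged == "success"))
})

test_that("independent high-variance responders miss the margin often", {
  # Monte-Carlo: with sd 1 and no correlation the margin E ~ (rt_a + rt_b)/8
  # is far smaller than typical |difference|
  rts <- simulate_rts("cooperation", 400, means = c(2.5, 2.5), sds = c(1, 1),
    correlation = 0, seed = 5
  )
  sc <- purrr::map2(rts$rt_a, rts$rt_b, judge_cooperation) %>% purrr::list_rbind()
  expect_lt(block_accuracy(sc), 0.8)
  expect_gt(block_accuracy(sc), 0.05)
})
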