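test_that("ICER reports the ratio with a dominance flag", {
  r <- icer(229.99, 0.068)
  expect_equal(r$ratio, 229.99 / 0.068, tolerance = 1e-12)
  expect_equal(r$flag, "ratio")
  d <- icer(-2237.30, 0.477)
  expect_equal(d$flag, "dominant")
  expect_equal(d$ratio, -2237.30 / 0.477, tolerance = 1e-12)
  expect_equal(icer(10, -0.1)$flag, "dominated")
  u <- icer(0, 0)
  expect_equal(u$flag, "undefined")
  expect_true(is.na(u$ratio))
  expect_equal(icer(0, 1)$ratio, 0)
})

test_that("net benefit formulas match the printed decision arithmetic", {
  wtp <- 1599.16
  # published incremental rows, compared within rounding of printed inputs
  expect_equal(nmb(-2007.31, 0.545, wtp), 2879.42, tolerance = 0.01)
  expect_equal(nmb(-2237.30, 0.477, wtp), 3000.40, tolerance = 0.01)
  expect_equal(nhb(-2007.31, 0.545, wtp), 1.801, tolerance = 0.01)
  expect_equal(nhb(229.99, 0.068, wtp), -0.0756, tolerance = 0.01)
  expect_equal(nmb(0, 0, wtp), 0)
  expect_equal(nhb(0, 0.3, wtp), 0.3)
  expect_error(nmb(1, 1, 0), "positive")
})

test_that("NMB = WTP * NHB identity and antisymmetry hold", {
  set.seed(11)
  for (i in 1:25) {
    dc <- runif(1, -5000, 5000)
    dq <- runif(1, -2, 2)
    w <- runif(1, 100, 5000)
    expect_equal(nmb(dc, dq, w), w * nhb(dc, dq, w), tolerance = 1e-9)
    # swapping comparator order negates both benefits
    expect_equal(nmb(-dc, -dq, w), -nmb(dc, dq, w), tolerance = 1e-9)
    expect_equal(nhb(-dc, -dq, w), -nhb(dc, dq, w), tolerance = 1e-9)
    # sign coherence
    expect_equal(nmb(dc, dq, w) > 0, nhb(dc, dq, w) > 0)
  }
})

test_that("pairwise comparison reproduces the published incremental table", {
  out <- list(usual = c(cost = 10999.55, qaly = 15.263),
              option1 = c(cost = 11229.54, qaly = 15.331),
              option2 = c(cost = 8992.24, qaly = 15.808))
  cmp <- compare_strategies(out, wtp = 1599.16)
  x <- cmp$comparisons
  expect_equal(nrow(x), 3L)
  expect_equal(paste(x$intervention, x$comparator),
               c("option1 usual", "option2 usual", "option2 option1"))
  expect_equal(x$delta_cost, c(229.99, -2007.31, -2237.30), tolerance = 1e-9)
  expect_equal(x$delta_qaly, c(0.068, 0.545, 0.477), tolerance = 1e-9)
  expect_equal(x$icer, c(229.99 / 0.068, -2007.31 / 0.545, -2237.30 / 0.477),
               tolerance = 1e-9)
  expect_equal(x$verdict,
               c("not_cost_effective_at_wtp", "dominant", "dominant"))
  # option2 is the only non-dominated strategy in these totals
  expect_equal(cmp$frontier, "option2")
})

test_that("degenerate and dominant comparisons are classified", {
  same <- list(a = c(cost = 100, qaly = 1), b = c(cost = 100, qaly = 1))
  cmp <- compare_strategies(same, wtp = 500)
  expect_equal(cmp$comparisons$icer_flag, "undefined")
  expect_equal(cmp$comparisons$delta_cost, 0)
  dup <- list(a = c(cost = 1, qaly = 1), a = c(cost = 2, qaly = 2))
  expect_error(compare_strategies(dup, wtp = 500), "unique")
  dom <- list(old = c(cost = 200, qaly = 1), new = c(cost = 100, qaly = 2))
  expect_equal(compare_strategies(dom, 500)$comparisons$verdict, "dominant")
})
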