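test_that("probability-to-rate and rate-to-probability match closed forms", {
  # oracle: direct evaluation of -(1/t) ln(1-p) and 1 - exp(-r)
  expect_equal(probability_to_rate(0.3069, 2), 0.183290495, tolerance = 1e-8)
  expect_equal(probability_to_rate(0.0809, 2), 0.0421801743, tolerance = 1e-8)
  expect_equal(probability_to_rate(0, 2), 0)
  expect_equal(rate_to_annual_probability(0), 0)
  expect_equal(rate_to_annual_probability(0.183290495), 0.1674737,
               tolerance = 1e-6)
  expect_error(probability_to_rate(1, 2), "finite rate")
  expect_error(probability_to_rate(-0.1, 2), "non-negative")
  expect_error(probability_to_rate(0.5, 0), "positive")
  expect_error(rate_to_annual_probability(-1), "non-negative")
})

test_that("annualization over a 2-year window reproduces the published table", {
  # all 12 blood-pressure rows: study probability -> annual probability
  study <- c("p0.5_1" = 0.0809, "p0.5_2" = 0.0112, "p0.5_3" = 0.0032,
             "p1_0.5" = 0.3069, "p1_2" = 0.0144, "p1_3" = 0.0032,
             "p2_0.5" = 0.0449, "p2_1" = 0.0569, "p2_3" = 0.0016,
             "p3_0.5" = 0.0120, "p3_1" = 0.0120, "p3_2" = 0.0016)
  tp <- transition_probability_table()
  published <- setNames(tp$value, tp$name)[names(study)]
  expect_equal(round(annualize_study_probability(study, t = 2), 4),
               published, tolerance = 1e-12)
})

test_that("rate conversion round-trips and is monotone", {
  p <- seq(0.001, 0.95, length.out = 40)
  expect_equal(rate_to_annual_probability(probability_to_rate(p, 1)), p,
               tolerance = 1e-12)
  # strictly increasing in p, decreasing in t
  a <- annualize_study_probability(p, 2)
  expect_true(all(diff(a) > 0))
  expect_true(all(annualize_study_probability(0.3, c(1)) >
                  annualize_study_probability(0.3, c(2))))
  expect_true(all(annualize_study_probability(0.3, 2) <
                  annualize_study_probability(0.3, 1.5)))
})

test_that("annual-to-step conversion composes back to the annual probability", {
  p2m <- annual_to_step_probability(0.1675, 1 / 6)
  expect_equal(p2m, 1 - (1 - 0.1675)^(1 / 6), tolerance = 1e-12)
  expect_equal(1 - (1 - p2m)^6, 0.1675, tolerance = 1e-12)
  expect_equal(annual_to_step_probability(0, 1 / 6), 0)
  expect_equal(annual_to_step_probability(0.42, 1), 0.42)
  expect_error(annual_to_step_probability(1, 0.5), "< 1")
})
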