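test_that("baseline-to-final transition counting follows the endpoint rule", {
  rec <- make_cohort(3, from = "L1", to = "L1")
  counts <- count_transitions(rec)
  expect_s3_class(counts, "transition_counts")
  expect_equal(counts$count, 3L)
  expect_equal(attr(counts, "total_n"), 3L)

  # a patient with only a baseline visit is excluded and total_n drops
  rec2 <- rbind(rec, record_row("p_lost", 0L, state = "L2"))
  expect_message(c2 <- count_transitions(rec2), "excluded")
  expect_equal(attr(c2, "total_n"), 3L)
  expect_equal(attr(c2, "excluded"), "p_lost")

  # visit-to-visit pairs count every consecutive step
  rec3 <- rbind(record_row("q1", 0L, state = "L1"),
                record_row("q1", 1L, state = "prehypertension"),
                record_row("q1", 2L, state = "prehypertension"))
  c3 <- count_transitions(rec3, pairs = TRUE)
  expect_equal(attr(c3, "total_n"), 2L)
  expect_setequal(c3$count, c(1L, 1L))
})

test_that("study probabilities use the whole-cohort denominator", {
  counts <- cmboc_transition_counts()
  expect_equal(attr(counts, "total_n"), 1248L)
  expect_equal(study_probability(counts, "L1", "prehypertension"),
               383 / 1248, tolerance = 1e-12)
  expect_equal(round(study_probability(counts, "L1", "prehypertension"), 4),
               0.3069)
  expect_equal(round(study_probability(counts, "prehypertension", "L1"), 4),
               0.0809)
  # unobserved pair is zero, not an error
  expect_equal(study_probability(counts, "L3", "L3"), 0)
  # origin-conditional alternative divides by the origin row count
  expect_equal(study_probability(counts, "L1", "prehypertension",
                                 denominator = "origin"),
               383 / (17 + 383 + 234 + 18 + 4), tolerance = 1e-12)
  empty <- counts
  attr(empty, "total_n") <- 0L
  expect_error(study_probability(empty, "L1", "L2"), "total_n is zero")
})

test_that("control rate is the share of post-baseline SBP strictly below 120", {
  rec <- make_cohort(4, final_visit = 3L)
  rec$sbp[rec$visit_index > 0] <- 118
  expect_equal(estimate_control_rate(rec, "usual")$control_rate, 1)
  rec$sbp[rec$visit_index > 0] <- 120 # boundary is not controlled
  expect_equal(estimate_control_rate(rec, "usual")$control_rate, 0)
  rec$sbp[rec$visit_index > 0][1:2] <- 110
  est <- estimate_control_rate(rec, "usual")
  expect_equal(est$control_rate, 0.5)
  expect_equal(est$n_measurements, 4L)
  expect_error(estimate_control_rate(rec, "missing_arm"), "no post-baseline")
})

test_that("state utilities are mean mapped EQ-5D with a normal CI", {
  rec <- make_cohort(5, from = "L2", to = "L2")
  # flat scores of 70 map to a constant utility: zero-width CI
  u70 <- 0.03256 + 70 * 0.01012
  est <- estimate_state_utility(rec, "L2")
  expect_equal(est$utility, u70, tolerance = 1e-12)
  expect_equal(est$low, est$high)
  expect_error(estimate_state_utility(rec[1, ], "L2"), "at least 2")
})

test_that("full estimation pipeline annualizes over the study window", {
  # 100 patients: 60 stay L1, 30 improve to prehypertension, 10 worsen to L2
  rec <- rbind(make_cohort(60, "L1", "L1"),
               make_cohort(30, "L1", "prehypertension"),
               make_cohort(10, "L1", "L2"))
  rec$patient_id <- paste0(rec$patient_id, rep(c("a", "b", "c"),
                                               c(120, 60, 20)))
  est <- estimate_parameters(rec, window_years = 2)
  expect_s3_class(est, "trial_estimates")
  tr <- est$transitions
  expect_setequal(tr$name, c("p1_0.5", "p1_2"))
  expect_equal(tr$study_probability[tr$name == "p1_0.5"], 0.30)
  expect_equal(tr$annual_probability[tr$name == "p1_0.5"],
               1 - sqrt(1 - 0.30), tolerance = 1e-12)
  expect_equal(unname(coef(est)["p1_2"]), 1 - sqrt(1 - 0.10),
               tolerance = 1e-12)
})

test_that("transitions into normotension are dropped by default, folded on request", {
  rec <- rbind(make_cohort(8, "L1", "L1"),
               make_cohort(2, "L1", "normotension"))
  rec$patient_id <- paste0(rec$patient_id, rep(c("a", "b"), c(16, 4)))
  est_drop <- estimate_parameters(rec)
  expect_false("normotension" %in% est_drop$transitions$destination)
  expect_equal(nrow(est_drop$transitions), 0L)
  est_fold <- estimate_parameters(rec, normotension = "fold")
  expect_equal(est_fold$transitions$name, "p1_0.5")
  expect_equal(est_fold$transitions$study_probability, 0.2)
})

test_that("estimates overlay a template into a runnable parameter set", {
  rec <- rbind(make_cohort(70, "L1", "L1"), make_cohort(30, "L1", "L2"))
  rec$patient_id <- paste0(rec$patient_id, rep(c("a", "b"), c(140, 60)))
  rec$sbp[rec$visit_index > 0][1:50] <- 110
  est <- estimate_parameters(rec)
  ps <- parameters_from_estimates(est, "usual")
  expect_s3_class(ps, "markov_parameters")
  expect_equal(ps$transitions[["p1_2"]], 1 - sqrt(1 - 0.30),
               tolerance = 1e-12)
  expect_equal(ps$control_rate, 0.5)
  expect_equal(ps$utilities[["U_1"]], 0.03256 + 70 * 0.01012,
               tolerance = 1e-9)
  # non-estimated quantities retained from the template
  expect_equal(ps$transitions[["pESRD_Death"]], 0.0552)
  expect_no_error(run_cohort(ps, horizon = 3))
})
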