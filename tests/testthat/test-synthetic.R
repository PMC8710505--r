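test_that("generator output is deterministic and correctly shaped", {
  cfg <- generator_config(n_patients = 40, dropout_per_visit = 0, seed = 77)
  rec1 <- generate_cohort(cfg)
  rec2 <- generate_cohort(cfg)
  expect_identical(rec1, rec2)
  # no dropout: every patient has 13 visits in each of 3 arms
  expect_equal(nrow(rec1), 3 * 40 * 13)
  expect_equal(sort(unique(rec1$visit_index)), 0:12)
  expect_setequal(unique(rec1$arm), c("usual", "option1", "option2"))
  expect_true(all(rec1$state %in% hypertension_states()))
  sf <- as.matrix(rec1[c("pf", "rp", "bp", "gh", "vt", "sf", "re", "mh")])
  expect_true(all(sf >= 0 & sf <= 100))
  expect_true(all(rec1$sbp > rec1$dbp))
  # a different seed moves the data
  rec3 <- generate_cohort(generator_config(n_patients = 40,
                                           dropout_per_visit = 0, seed = 78))
  expect_false(identical(rec1$sbp, rec3$sbp))
})

test_that("degenerate identity dynamics freeze every patient in its state", {
  S <- diag(4)
  dimnames(S) <- list(hypertension_states(), hypertension_states())
  cfg <- generator_config(
    n_patients = 25, step_matrix = S, dropout_per_visit = 0,
    baseline_distribution = c(prehypertension = 0, L1 = 1, L2 = 0, L3 = 0),
    seed = 5)
  rec <- generate_cohort(cfg)
  expect_true(all(rec$state == "L1"))
})

test_that("blood pressure respects state bands except on controlled visits", {
  cfg <- generator_config(n_patients = 120, dropout_per_visit = 0, seed = 21)
  rec <- generate_cohort(cfg)
  # baseline visits are never controlled: SBP in the state's band
  base <- rec[rec$visit_index == 0, ]
  expect_true(all(base$sbp >= 120))
  expect_true(all(base$sbp[base$state == "L1"] >= 140 &
                  base$sbp[base$state == "L1"] < 160))
  # post-baseline: either in band or controlled below 120
  post <- rec[rec$visit_index > 0 & rec$state == "L3", ]
  expect_true(all(post$sbp >= 180 | post$sbp < 120))
})

test_that("dropout calibration yields the configured overall loss", {
  cfg <- generator_config(n_patients = 1500, seed = 31)
  rec <- generate_cohort(cfg)
  n <- 3 * 1500
  retained <- sum(tapply(rec$visit_index, rec$patient_id, max) == 12)
  loss <- 1 - retained / n
  se <- sqrt(0.1263 * (1 - 0.1263) / n)
  expect_lt(abs(loss - 0.1263), 3 * se)
})

test_that("arm control frequencies are recovered from the records", {
  cfg <- generator_config(n_patients = 400, dropout_per_visit = 0, seed = 13)
  rec <- generate_cohort(cfg)
  for (a in c("usual", "option1", "option2")) {
    est <- estimate_control_rate(rec, a)
    truth <- cfg$arms[[a]]
    se <- sqrt(truth * (1 - truth) / est$n_measurements)
    expect_lt(abs(est$control_rate - truth), 3 * se)
  }
})

test_that("baseline state mix matches the configured distribution", {
  cfg <- generator_config(n_patients = 1700, dropout_per_visit = 0, seed = 55)
  rec <- generate_cohort(cfg)
  base <- rec[rec$visit_index == 0, ]
  obs <- table(factor(base$state, levels = hypertension_states()))
  gof <- chisq.test(obs, p = cfg$baseline_distribution)
  expect_gt(gof$p.value, 0.01)
})

test_that("state utilities are recovered from mapped SF-36 scores", {
  cfg <- generator_config(n_patients = 600, dropout_per_visit = 0, seed = 91)
  rec <- generate_cohort(cfg)
  targets <- c(prehypertension = 0.651375, L1 = 0.65525, L2 = 0.683)
  for (s in names(targets)) {
    est <- estimate_state_utility(rec, s)
    se <- (est$high - est$low) / 2 / 1.96
    expect_lt(abs(est$utility - targets[[s]]), 3 * se + 1e-3)
  }
})
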