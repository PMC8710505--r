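test_that("mortality lookup returns the containing age band", {
  mt <- china_mortality()
  expect_equal(mortality_lookup(mt, 67), 0.0172)
  expect_equal(mortality_lookup(mt, 35), 0.0012)
  expect_equal(mortality_lookup(mt, 102), 0.4543)
  expect_equal(mortality_lookup(mt, 39.9), 0.0012)
  expect_error(mortality_lookup(mt, 34), "below the mortality table")
})

test_that("discount factor is 1/(1+r)^cycle with cycle 0 undiscounted", {
  expect_equal(discount_factor(0.05, 0), 1)
  expect_equal(discount_factor(0.05, 1), 1 / 1.05)
  expect_equal(discount_factor(0, 17), 1)
  expect_error(discount_factor(0.05, -1), ">= 0")
})

test_that("transition matrix rows are stochastic with mortality folded in", {
  tp <- transition_probability_table()
  transitions <- setNames(tp$value, tp$name)
  M <- build_transition_matrix(transitions, china_mortality(), age = 35)
  expect_equal(dim(M), c(9L, 9L))
  expect_equal(unname(rowSums(M)), rep(1, 9), tolerance = 1e-12)
  # death row absorbing
  expect_equal(unname(M["death", ]), c(rep(0, 8), 1))
  # prehypertension row at age 35: hand-summed off-diagonals 0.0524
  expect_equal(M["prehypertension", "prehypertension"], 0.9476,
               tolerance = 1e-12)
  expect_equal(M["prehypertension", "death"], 0.0012)
  expect_equal(M["prehypertension", "L1"], 0.0413)
  # complication states: disease-specific death plus background mortality
  expect_equal(M["ESRD", "death"], 0.0552 + 0.0012, tolerance = 1e-12)
  expect_equal(M["ESRD", "ESRD"], 1 - 0.0552 - 0.0012, tolerance = 1e-12)
})

test_that("control-rate scaling acts on improvement transitions only", {
  tp <- transition_probability_table()
  transitions <- setNames(tp$value, tp$name)
  M1 <- build_transition_matrix(transitions, china_mortality(), 50)
  M2 <- build_transition_matrix(transitions, china_mortality(), 50,
                                control_scale = 0.69 / 0.61)
  expect_equal(M2["L1", "prehypertension"],
               M1["L1", "prehypertension"] * 0.69 / 0.61, tolerance = 1e-12)
  # worsening transitions untouched; residual absorbs the change
  expect_equal(M2["prehypertension", "L1"], M1["prehypertension", "L1"])
  expect_equal(M2["L1", "L2"], M1["L1", "L2"])
  expect_equal(unname(rowSums(M2)), rep(1, 9), tolerance = 1e-12)
  expect_lt(M2["L1", "L1"], M1["L1", "L1"])
})

test_that("degenerate matrices behave: identity and inconsistent rows", {
  zero <- setNames(rep(0, 31), transition_probability_table()$name)
  mt0 <- data.frame(age_lower = 35, probability = 0)
  M <- build_transition_matrix(zero, mt0, 40)
  expect_equal(unname(M), diag(9))
  big <- zero; big[["p1_0.5"]] <- 0.9; big[["p1_ESRD"]] <- 0.2
  expect_error(build_transition_matrix(big, mt0, 40), "exceed 1")
})

test_that("cohort trace conserves mass and absorbs into death", {
  tr <- run_cohort(default_parameters("usual"))
  occ <- as.matrix(tr$trace[ht_states()])
  expect_equal(unname(rowSums(occ)), rep(1, nrow(occ)), tolerance = 1e-12)
  expect_true(all(diff(tr$trace$death) >= 0))
  expect_true(all(occ >= 0))
  # lifetime horizon: nearly everyone dead after 65 cycles from age 35
  expect_gt(tr$trace$death[66], 0.95)
})

test_that("trivial engines match closed forms", {
  ps <- default_parameters("usual")
  # identity dynamics, utility 1 everywhere, no discounting: QALYs = horizon
  ps0 <- ps
  ps0$transitions[] <- 0
  ps0$utilities[] <- 1
  ps0$costs[] <- 0
  ps0$human_cost <- ps0$project_cost <- 0
  ps0$mortality <- data.frame(age_lower = 35, probability = 0)
  ps0$economics$discount_rate <- 0
  tr0 <- run_cohort(ps0)
  expect_equal(unname(total_outcomes(tr0)[c("ly", "qaly")]), c(65, 65),
               tolerance = 1e-12)
  expect_equal(unname(total_outcomes(tr0)["cost"]), 0)

  # certain death in one cycle: a single life-year accrues
  ps1 <- ps0
  ps1$mortality <- data.frame(age_lower = 35, probability = 1)
  tr1 <- run_cohort(ps1)
  expect_equal(unname(total_outcomes(tr1)["ly"]), 1)
  expect_equal(tr1$trace$death[2], 1)

  # two-state reduction, constant hazard q, no discounting:
  # total LYs equal the geometric series sum over the horizon
  q <- 0.07
  ps2 <- ps0
  ps2$mortality <- data.frame(age_lower = 35, probability = q)
  tr2 <- run_cohort(ps2)
  expect_equal(unname(total_outcomes(tr2)["ly"]),
               sum((1 - q)^(0:64)), tolerance = 1e-10)
})

test_that("totals respond to discounting and control rate as expected", {
  ps <- default_parameters("usual")
  rates <- c(0, 0.03, 0.05, 0.08)
  tot <- sapply(rates, function(r) {
    ps$economics$discount_rate <- r
    total_outcomes(run_cohort(ps))
  })
  # discounted totals non-increasing in the discount rate
  expect_true(all(diff(tot["cost", ]) < 0))
  expect_true(all(diff(tot["qaly", ]) < 0))
  expect_true(all(diff(tot["ly", ]) < 0))

  # QALY totals ordered by arm control rate (0.69 > 0.62 > 0.61)
  strat <- default_strategies()
  q <- vapply(strat, function(p) total_outcomes(run_cohort(p))[["qaly"]],
              numeric(1))
  expect_gt(q[["option2"]], q[["option1"]])
  expect_gt(q[["option1"]], q[["usual"]])
})

test_that("intervention cost accrues per person-year alive", {
  ps <- default_parameters("usual")
  ps$costs[] <- 0
  ps$economics$discount_rate <- 0
  tr <- run_cohort(ps)
  ivc <- intervention_cost_per_cycle(ps)
  expect_equal(unname(total_outcomes(tr)[["cost"]]),
               ivc * total_outcomes(tr)[["ly"]], tolerance = 1e-9)
  # single-cycle accounting: cost = state cost + intervention, QALY = utility
  ps1 <- default_parameters("usual")
  ps1$economics$initial_distribution <-
    c(prehypertension = 0, L1 = 1, L2 = 0, L3 = 0)
  tr1 <- run_cohort(ps1, horizon = 1)
  expect_equal(tr1$totals[["cost"]],
               150.87 + intervention_cost_per_cycle(ps1), tolerance = 1e-9)
  expect_equal(tr1$totals[["qaly"]], 0.65525)
  expect_equal(tr1$totals[["ly"]], 1)
})
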