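test_that("beta moment matching hits the requested mean", {
  # hand method-of-moments: SD = (0.92 - 0.33)/3.92, nu = m(1-m)/SD^2 - 1
  ab <- beta_from_mean_ci(0.62, 0.33, 0.92)
  expect_equal(unname(ab), c(5.828149, 3.572092), tolerance = 1e-5)
  expect_equal(ab[["alpha"]] / sum(ab), 0.62, tolerance = 1e-12)
  set.seed(3)
  draws <- rbeta(1e5, ab[["alpha"]], ab[["beta"]])
  se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - 0.62), 3 * se)
  expect_error(beta_from_mean_ci(0.5, 0, 4), "too wide")
  expect_error(beta_from_mean_ci(1.2, 0.1, 0.9), "in \\(0, 1\\)")
})

test_that("gamma moment matching hits the requested mean", {
  # hand method-of-moments with SD = (23287.63 - 15525.09)/3.92
  ss <- gamma_from_mean_ci(19406.36, 15525.09, 23287.63)
  expect_equal(unname(ss), c(96.0401, 202.0652), tolerance = 1e-3)
  expect_equal(ss[["shape"]] * ss[["scale"]], 19406.36, tolerance = 1e-6)
  set.seed(4)
  draws <- rgamma(1e5, shape = ss[["shape"]], scale = ss[["scale"]])
  se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - 19406.36), 3 * se)
  expect_error(gamma_from_mean_ci(-1, 0, 1), "positive")
})

test_that("fixed and zero-width specs sample as point masses", {
  sp <- data.frame(name = "x", base = 0.5, low = 0.5, high = 0.5,
                   distribution = "beta")
  expect_equal(sample_parameter(sp, 5), rep(0.5, 5))
  spf <- data.frame(name = "discount_rate", base = 0.05, low = 0,
                    high = 0.08, distribution = "fixed")
  expect_equal(sample_parameter(spf, 3), rep(0.05, 3))
})

test_that("one-way analysis produces a sorted tornado with sane swings", {
  strat <- default_strategies()
  specs <- default_parameter_specs()
  sel <- specs[specs$name %in% c("cESRD", "discount_rate", "U_2"), ]
  # zero-range spec has zero swing
  sel <- rbind(sel, data.frame(name = "chy1", base = 150.87, low = 150.87,
                               high = 150.87, distribution = "gamma"))
  tor <- one_way_analysis(strat, sel)
  expect_s3_class(tor, "tornado_table")
  expect_true(all(diff(tor$swing) <= 0))
  expect_equal(tor$swing[tor$name == "chy1"], 0)
  expect_gt(tor$swing[tor$name == "discount_rate"], 0)
  expect_gt(tor$swing[tor$name == "cESRD"], 0)
  # outcome at 0% discount differs from the 5% base outcome
  expect_false(isTRUE(all.equal(
    tor$outcome_low[tor$name == "discount_rate"],
    attr(tor, "base_outcome"))))
  expect_error(one_way_analysis(strat, data.frame(
    name = "nope", base = 1, low = 0, high = 2, distribution = "gamma")),
    "unknown parameter")
})

test_that("a parameter of a never-visited pathway has zero swing", {
  strat <- default_strategies()
  # cut all inflow into ESRD: its treatment cost cannot move the outcome
  for (nm in c("p1_ESRD", "p2_ESRD", "p3_ESRD")) {
    strat <- set_model_parameter(strat, nm, 0)
  }
  specs <- default_parameter_specs()
  tor <- one_way_analysis(strat, specs[specs$name == "cESRD", ])
  expect_equal(tor$swing, 0, tolerance = 1e-9)
})

test_that("degenerate PSA reproduces the base case bit-for-bit", {
  strat <- default_strategies()
  specs <- default_parameter_specs()
  specs$distribution <- "fixed"
  psa <- run_psa(strat, specs, n_iter = 3, seed = 9)
  base <- vapply(strat, function(p) total_outcomes(run_cohort(p))[["qaly"]],
                 numeric(1))
  for (a in names(strat)) {
    got <- psa$iterations$qaly[psa$iterations$arm == a]
    expect_identical(got, rep(base[[a]], 3))
  }
  # step-function CEAC: a single arm takes probability 1 at each threshold
  expect_true(all(psa$ceac$probability %in% c(0, 1)))
})

test_that("PSA is seed-deterministic and its CEAC partitions to one", {
  strat <- default_strategies()
  p1 <- run_psa(strat, n_iter = 5, seed = 123)
  p2 <- run_psa(strat, n_iter = 5, seed = 123)
  expect_identical(p1$iterations, p2$iterations)
  expect_identical(p1$ceac, p2$ceac)
  tot <- tapply(p1$ceac$probability, p1$ceac$wtp, sum)
  expect_equal(as.vector(tot), rep(1, length(tot)), tolerance = 1e-12)
  expect_true(all(p1$ceac$probability >= 0 & p1$ceac$probability <= 1))
  # the base threshold sits on the grid exactly
  expect_true(1599.16 %in% p1$ceac$wtp)
  p <- ce_probability(p1)
  expect_equal(sum(p), 1, tolerance = 1e-12)
})
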