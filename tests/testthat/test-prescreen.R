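test_that("relative invitations take the top (1-q) fraction with stable ties", {
  expect_identical(invite_relative(c(0.1, 0.2, 0.3, 0.4), 0.5),
                   c(FALSE, FALSE, TRUE, TRUE))
  expect_true(all(invite_relative(runif(10), 0)))
  # exact invited count on randomized inputs, against a sort-based oracle
  set.seed(55)
  for (i in 1:50) {
    n <- sample(1:400, 1)
    q <- runif(1, 0, 0.999)
    risks <- round(runif(n), 2) # ties likely
    mask <- invite_relative(risks, q)
    expect_identical(sum(mask), as.integer(ceiling((1 - q) * n)))
    # no uninvited participant outranks an invited one
    expect_gte(min(risks[mask]), max(c(-Inf, risks[!mask])) - 1e-12)
  }
  # boundary ties broken by input order: first-seen tied value is invited
  mask <- invite_relative(c(0.5, 0.5, 0.5, 0.9), q = 0.5)
  expect_identical(mask, c(TRUE, FALSE, FALSE, TRUE))
  expect_error(invite_relative(numeric(0), 0.5), "non-empty")
  expect_error(invite_relative(c(0.2, 0.3), 1), "\\[0, 1\\)")
})

test_that("absolute invitations threshold the predicted probability", {
  expect_identical(invite_absolute(c(0.2, 0.5, 0.8), 0.5), c(FALSE, TRUE, TRUE))
  expect_true(all(invite_absolute(runif(20), 0)))
  mask <- invite_absolute(c(0.1, 0.2), 0.9)
  expect_false(any(mask))
  expect_error(yield_ppv(mask, c(1, 0)), "empty invitation")
})

test_that("yield equals prevalence at full invitation and is exact on counts", {
  status <- c(rep(1, 52), rep(0, 128)) # the in-study composition
  expect_equal(yield_ppv(rep(TRUE, 180), status), 52 / 180)
  expect_equal(round(100 * yield_ppv(rep(TRUE, 180), status), 1), 28.9)
  expect_equal(yield_ppv(status == 1, status), 1)
  # random mask on a large null cohort gives ~prevalence (binomial oracle)
  set.seed(66)
  st <- rbinom(5e4, 1, 0.3)
  mask <- runif(5e4) < 0.5
  half <- 3.29 * sqrt(0.3 * 0.7 / sum(mask))
  expect_lt(abs(yield_ppv(mask, st) - 0.3), half)
})

test_that("required test counts reproduce the study's recruitment arithmetic", {
  # 500 PET+ participants at the unscreened 28.6% rate: 1749 scans, no plasma
  expect_identical(required_tests(0.286, 1, 500),
                   c(n_pet = 1749, n_plasma = 0))
  # 75th percentile: 796 scans among the top 25% => 3184 plasma tests
  expect_identical(unname(required_tests(500 / 796, 0.25, 500)[["n_plasma"]]),
                   3184)
  # 25th percentile: 1312 scans among the top 75% => 1750 plasma tests
  expect_identical(unname(required_tests(500 / 1312, 0.75, 500)[["n_plasma"]]),
                   1750)
  # perfect marker without pre-screening
  expect_identical(required_tests(1, 1, 500), c(n_pet = 500, n_plasma = 0))
  expect_error(required_tests(0, 1, 500), "impossible")
  expect_error(required_tests(0.5, 0, 500), "invited_fraction")
})

test_that("threshold sweep: point estimates, invariants and degenerate grid values", {
  co <- generate_cohort(generator_config(seed = 13))
  sc <- screen_sweep(co, mode = "relative", grid = seq(0, 0.9, 0.15),
                     B = 0)
  n <- nrow(co)
  expect_equal(sc$invited_fraction, ceiling((1 - sc$threshold) * n) / n)
  expect_equal(sc$ppv[sc$threshold == 0], mean(co$pet_status))
  expect_true(all(sc$n_plasma >= sc$n_pet | sc$n_plasma == 0, na.rm = TRUE))
  expect_true(all(sc$n_pet >= 500, na.rm = TRUE))

  # single-value grid (0) equals the no-pre-screening scenario
  sc0 <- screen_sweep(co, mode = "relative", grid = 0, B = 0)
  expect_equal(sc0$ppv, mean(co$pet_status))
  expect_equal(sc0$n_plasma, 0)
  expect_equal(sc0$n_pet, ceiling(500 / mean(co$pet_status)))

  # absolute cutoffs above the maximum risk give NA rows plus a warning
  expect_warning(
    sca <- screen_sweep(co, mode = "absolute",
                        grid = c(0, max(predict_risk(fit_risk_model(co), co)) + 0.01),
                        B = 0),
    "empty invitations")
  expect_true(is.na(sca$ppv[2]))
  expect_error(screen_sweep(co, grid = c(0.5, 0.2)), "sorted")
})

test_that("relative and absolute modes agree when the cutoff is the risk quantile", {
  co <- generate_cohort(generator_config(n = 1000, seed = 29))
  m <- fit_risk_model(co)
  risks <- predict_risk(m, co)
  q <- 0.5
  cq <- unname(quantile(risks, q, type = 1))
  rel <- invite_relative(risks, q)
  abs_ <- invite_absolute(risks, cq)
  # identical up to boundary ties at the quantile itself
  disagree <- sum(rel != abs_)
  expect_lte(disagree, sum(risks == cq))
})

test_that("yield is non-decreasing along the grid for a calibrated score", {
  co <- generate_cohort(generator_config(n = 2e4, seed = 37))
  sc <- screen_sweep(co, mode = "relative", grid = seq(0, 0.9, 0.1), B = 0)
  expect_true(all(diff(sc$ppv) > -0.005)) # analytic monotonicity up to noise
})

test_that("bootstrap sweep summaries behave like the study's headline numbers", {
  co <- generate_cohort(generator_config(seed = 47))
  sc <- screen_sweep(co, mode = "relative", grid = c(0, 0.25, 0.5, 0.75),
                     B = 300, seed = 3)
  # Jensen: the bootstrap mean of the per-resample scan count exceeds the
  # count computed from the bootstrap-mean yield (E[1/p] >= 1/E[p]), up to
  # one scan of ceiling slack; at threshold 0 (no refitting) it also exceeds
  # the full-cohort plug-in count
  expect_true(all(sc$n_pet_boot >= ceiling(500 / sc$ppv_boot) - 1))
  expect_gte(sc$n_pet_boot[sc$threshold == 0], sc$n_pet[sc$threshold == 0])
  # paired p-value: pre-screening beats no pre-screening at q = 0.5
  expect_lt(sc$p_vs_none[sc$threshold == 0.5], 0.05)
  expect_equal(sc$p_vs_none[sc$threshold == 0], 1)
  # CI brackets the bootstrap mean
  expect_true(all(sc$ppv_lo <= sc$ppv_boot & sc$ppv_boot <= sc$ppv_hi))
  # replicates attached for the cost stage
  reps <- attr(sc, "replicates")
  expect_equal(dim(reps$ppv), c(300, 4))
})
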