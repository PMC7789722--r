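test_that("unit cost averages urban and rural delivery costs", {
  p <- fixed_params()
  expect_equal(cost_per_treatment(1, p), 45)
  expect_equal(cost_per_treatment(0, p), 45 * 7.2)
  expect_equal(cost_per_treatment(0.5, p), 184.5)
  expect_error(cost_per_treatment(1.5, p), "\\[0, 1\\]")
  expect_error(cost_per_treatment(-0.1, p), "\\[0, 1\\]")
})

test_that("ICER is a guarded ratio with distinct degenerate errors", {
  expect_equal(icer(100, 4), 25)
  expect_equal(icer(0, 4), 0)
  expect_error(icer(100, 0), "no incremental effect")
  expect_error(icer(100, -1), "dominated")
})

test_that("single-region scale-up matches a hand-enumerated cohort", {
  # all mortality pneumonia-attributable: incidence * cfr = 0.02, efficacy 0.5,
  # scale-up from zero to full coverage over a flat reference schedule
  params <- fixed_params(
    cfr_untreated = 0.02, efficacy = 0.5, target_coverage = 1,
    duration_days = 4.6
  )
  region <- toy_region(
    q_infant = 0.02, q_child = 0.02, incidence = 1,
    baseline_coverage = 0, cost_per_treatment = 10, birth_cohort = 100
  )
  refs <- list(flat_life_table(0.02))
  res <- suppressWarnings(
    scale_up_region(region, refs, params, match_on = "derived")
  )

  # independent enumeration: explicit 120-cycle loop per arm
  enumerate <- function(coverage) {
    q <- rep(1 - 0.98^1, 120) # flat reference, constant hazard split is exact
    q[120] <- 1
    q[1:5] <- 0.02 # region overlay
    q[1:5] <- (0.02 - 0.02 * (1 - 0.5 * 0)) + 0.02 * (1 - 0.5 * coverage)
    S <- 1
    le <- 0
    dly <- 0
    cost <- 0
    surv <- numeric(121)
    surv[1] <- 1
    for (a in 0:119) {
      if (a < 5) cost <- cost + S * 1 * coverage * 10 * 1.03^(-a)
      S_next <- S * (1 - q[a + 1])
      le <- le + S_next
      dly <- dly + S_next * 1.03^(-(a + 1))
      surv[a + 2] <- S_next
      S <- S_next
    }
    list(
      le = le + 0.5, dly = dly + 0.5, cost = cost,
      u5mr = 1 - surv[6], surv = surv
    )
  }
  base <- enumerate(0)
  targ <- enumerate(1)
  expect_equal(res$le_baseline, base$le, tolerance = 1e-9)
  expect_equal(res$le_target, targ$le, tolerance = 1e-9)
  expect_equal(res$incremental_discounted_ly, targ$dly - base$dly, tolerance = 1e-9)
  expect_equal(res$u5mr_baseline, base$u5mr, tolerance = 1e-9)
  expect_equal(res$u5mr_target, targ$u5mr, tolerance = 1e-9)
  expect_equal(res$cost_per_child_target, targ$cost, tolerance = 1e-9)
  expect_equal(res$baseline$survival, base$surv, tolerance = 1e-9)
  expect_equal(res$icer, (targ$cost - base$cost) / (targ$dly - base$dly),
    tolerance = 1e-9
  )
})

test_that("degenerate scale-ups are flagged rather than inverted", {
  params <- fixed_params()
  refs <- list(flat_life_table(0.01))
  region <- toy_region(baseline_coverage = 0.5)

  same <- scale_up_region(region, refs, params,
    target_coverage = 0.5, match_on = "derived"
  )
  expect_equal(same$incremental_le, 0)
  expect_equal(same$incremental_cost, 0)
  expect_true(is.na(same$icer))

  p0 <- fixed_params(efficacy = 0)
  futile <- scale_up_region(toy_region(incidence = 0.1, baseline_coverage = 0.5),
    refs, p0,
    match_on = "derived"
  )
  expect_equal(futile$incremental_le, 0)
  expect_gt(futile$incremental_cost, 0) # more treatment, no effect: dominated
  expect_true(is.na(futile$icer))

  expect_error(
    scale_up_region(region, refs, params, target_coverage = 0.3),
    "decremental"
  )
  expect_error(scale_up_region(region, list(), params), "empty")
})

test_that("ICER ignores cohort size while totals scale linearly", {
  params <- fixed_params()
  refs <- ethiopia_reference_set()
  small <- toy_region(reported_u5mr = 80, birth_cohort = 1000)
  big <- toy_region(reported_u5mr = 80, birth_cohort = 250000)
  r1 <- scale_up_region(small, refs, params)
  r2 <- scale_up_region(big, refs, params)
  expect_equal(r1$icer, r2$icer, tolerance = 1e-12)
  expect_equal(r2$incremental_cost / r1$incremental_cost, 250, tolerance = 1e-9)

  dearer <- toy_region(
    reported_u5mr = 80, birth_cohort = 1000,
    cost_per_treatment = 90
  )
  r3 <- scale_up_region(dearer, refs, params)
  expect_equal(r3$incremental_cost / r1$incremental_cost, 2, tolerance = 1e-9)
})

test_that("undiscounted ICERs track the closed-form unit-cost approximation", {
  # For small incidence * CFR, the ICER is approximately
  # cost_per_treatment / (cfr * efficacy * baseline life expectancy).
  run <- run_fixture_pipeline()
  fx <- ethiopia_fixture()
  p <- fx$params
  tab <- run$table
  cost <- fx$regions$cost_per_treatment[match(tab$region, fx$regions$region)]
  approx <- cost / (p$cfr_untreated * p$efficacy * tab$le_baseline)
  rel <- abs(tab$icer_undiscounted - approx) / approx
  expect_true(all(rel < 0.15))
})

test_that("cost-effectiveness verdict uses an inclusive GDP-fraction threshold", {
  p <- fixed_params() # GDP per capita 713
  expect_true(cost_effectiveness_flag(26.15, p, 0.5))
  expect_true(cost_effectiveness_flag(0.5 * 713, p, 0.5)) # boundary inclusive
  expect_false(cost_effectiveness_flag(1000, p, 0.5))
  expect_error(cost_effectiveness_flag(26, p, 0), "positive")
})
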