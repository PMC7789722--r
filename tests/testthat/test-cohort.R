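test_that("incidence follows prevalence / duration and inverts", {
  expect_equal(incidence_from_prevalence(0.005, 4.6), 0.005 * 365 / 4.6)
  expect_equal(round(incidence_from_prevalence(0.005, 4.6), 4), 0.3967)
  expect_equal(incidence_from_prevalence(0, 4.6), 0)
  expect_error(incidence_from_prevalence(0.01, 0), "positive")
  # inversion: the published Amhara incidence implies its survey prevalence
  expect_equal(0.453 * 4.6 / 365, 0.005709, tolerance = 1e-4)
  expect_equal(incidence_from_prevalence(0.453 * 4.6 / 365, 4.6), 0.453)
})

test_that("all-cause mortality decomposes into pneumonia and other causes", {
  params <- fixed_params()
  nat <- toy_region(incidence = 0.397, baseline_coverage = 0.33)
  dec <- pneumonia_decomposition(0.0485, nat, params)
  expect_equal(dec$q_pneumonia_baseline,
    0.397 * 0.0351 * (1 - 0.7 * 0.33),
    tolerance = 1e-12
  )
  expect_equal(round(dec$q_pneumonia_baseline, 6), 0.010716)
  expect_equal(round(dec$q_nonpneumonia, 6), 0.037784)
  expect_equal(dec$q_nonpneumonia + dec$q_pneumonia_baseline, 0.0485)

  none <- pneumonia_decomposition(0.0485, toy_region(incidence = 0), params)
  expect_equal(none$q_nonpneumonia, 0.0485)
  expect_equal(none$q_pneumonia_baseline, 0)

  # inconsistent inputs clamp with a warning naming the region
  big <- toy_region(region = "Clampland", incidence = 0.45, baseline_coverage = 0.2)
  expect_warning(dec2 <- pneumonia_decomposition(0.004, big, params), "Clampland")
  expect_equal(dec2$q_nonpneumonia, 0)
})

test_that("coverage counterfactuals shift only the intervention ages", {
  params <- fixed_params()
  nat <- toy_region(incidence = 0.397, baseline_coverage = 0.33)
  sched <- apply_region_under5(
    expand_to_annual(synthetic_base_life_table()),
    toy_region(q_infant = 0.0485, q_child = 0.0051)
  )
  # the national-level inputs clamp at child ages (pneumonia share exceeds
  # the child all-cause probability), which is warned about
  expect_warning(at90 <- mortality_at_coverage(sched, nat, params, 0.90), "clamping")
  drop <- 0.397 * 0.0351 * 0.70 * (0.90 - 0.33)
  expect_equal(unname(sched[1] - at90[1]), drop, tolerance = 1e-12)
  expect_equal(round(drop, 6), 0.00556)
  expect_equal(at90[6:120], sched[6:120])

  # identity at baseline coverage for inputs that do not clamp
  mild <- toy_region(incidence = 0.1, baseline_coverage = 0.33)
  expect_equal(mortality_at_coverage(sched, mild, params, 0.33), sched)
  # zero efficacy: coverage cannot matter
  p0 <- fixed_params(efficacy = 0)
  expect_equal(
    mortality_at_coverage(sched, mild, p0, 0.9),
    mortality_at_coverage(sched, mild, p0, 0.1)
  )
  expect_error(mortality_at_coverage(sched, nat, params, 1.2), "\\[0, 1\\]")
})

test_that("cohort engine matches geometric and annuity closed forms", {
  params <- fixed_params(
    discount_effects = 0, discount_costs = 0,
    half_cycle_correction = FALSE
  )
  inert <- toy_region(incidence = 0) # engine applies no mortality shift

  half <- annual_mortality_schedule(rep(0.5, 120))
  res <- run_cohort(half, inert, params, 0.9)
  expect_equal(res$life_expectancy, sum(0.5^(1:120)), tolerance = 1e-9)
  expect_equal(round(res$life_expectancy, 4), 1.0000)

  one_pct <- annual_mortality_schedule(rep(0.01, 120))
  res <- run_cohort(one_pct, inert, params, 0.9)
  expect_equal(res$life_expectancy,
    0.99 * (1 - 0.99^120) / 0.01,
    tolerance = 1e-9
  )

  # 119-year annuity: certain survival until death during the final cycle
  disc <- fixed_params(discount_effects = 0.03, half_cycle_correction = FALSE)
  ann <- annual_mortality_schedule(c(rep(0, 119), 1))
  res <- run_cohort(ann, inert, disc, 0.9)
  expect_equal(res$discounted_life_years,
    (1 - 1.03^(-119)) / 0.03,
    tolerance = 1e-9
  )
  expect_equal(res$life_expectancy, 119)

  # undiscounted treatment cost: 5 cycles * incidence * coverage * unit cost
  # (zero CFR keeps survival flat so everyone is alive in all five cycles)
  p_cost <- fixed_params(
    cfr_untreated = 0, discount_costs = 0, discount_effects = 0,
    half_cycle_correction = FALSE
  )
  alive <- annual_mortality_schedule(c(rep(0, 119), 1))
  res <- run_cohort(
    alive,
    toy_region(incidence = 0.4, cost_per_treatment = 100, baseline_coverage = 0.9),
    p_cost, 0.9
  )
  expect_equal(res$treatment_cost_per_child, 5 * 0.4 * 0.9 * 100)
})

test_that("cohort accounting conserves mass and orders effects correctly", {
  params <- fixed_params()
  # incidence low enough that the pneumonia share stays below child
  # all-cause mortality: no clamping anywhere
  region <- toy_region(incidence = 0.12, baseline_coverage = 0.3)
  sched <- apply_region_under5(
    expand_to_annual(synthetic_base_life_table()), region
  )

  res <- run_cohort(sched, region, params, 0.9)
  expect_equal(sum(res$deaths_by_age), 1, tolerance = 1e-9)
  expect_equal(res$u5mr, 1 - res$survival[6])
  expect_equal(res$life_expectancy, sum(res$survival[2:121]) + 0.5)

  # LE and discounted LY strictly increase in coverage; U5MR strictly falls
  covs <- c(0.3, 0.5, 0.7, 0.9)
  runs <- lapply(covs, function(cv) run_cohort(sched, region, params, cv))
  le <- vapply(runs, function(r) r$life_expectancy, numeric(1))
  dly <- vapply(runs, function(r) r$discounted_life_years, numeric(1))
  u5 <- vapply(runs, function(r) r$u5mr, numeric(1))
  expect_true(all(diff(le) > 0))
  expect_true(all(diff(dly) > 0))
  expect_true(all(diff(u5) < 0))

  # discounting can only shrink life years; equality iff rate is zero
  expect_true(all(dly < le))
  p0 <- fixed_params(discount_effects = 0)
  r0 <- run_cohort(sched, region, p0, 0.9)
  expect_equal(r0$discounted_life_years, r0$life_expectancy)

  # baseline-coverage run reproduces the unmodified schedule bit-for-bit
  base_run <- run_cohort(sched, region, params, region$baseline_coverage)
  expect_identical(base_run$survival, survival_from_schedule(sched))

  # half-cycle correction adds a flat half year
  on <- run_cohort(sched, region, fixed_params(half_cycle_correction = TRUE), 0.9)
  off <- run_cohort(sched, region, fixed_params(half_cycle_correction = FALSE), 0.9)
  expect_equal(on$life_expectancy - off$life_expectancy, 0.5)
  expect_equal(on$discounted_life_years - off$discounted_life_years, 0.5)
})

test_that("under-five mortality combines infant and child probabilities", {
  expect_equal(u5mr_from_rates(0.0485, 0.0051), 1 - 0.9515 * 0.9949^4)
  expect_equal(round(u5mr_from_rates(0.0485, 0.0051), 5), 0.06776)
  expect_equal(round(u5mr_from_rates(0.0767, 0.0115), 5), 0.11844)
  expect_equal(u5mr_from_rates(0, 0), 0)
})
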