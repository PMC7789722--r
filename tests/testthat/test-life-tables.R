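test_that("under-five mortality of an abridged table multiplies interval survival", {
  lt <- abridged_life_table("t",
    start_age = c(0, 1, 5), width = c(1, 4, Inf), nqx = c(0.05, 0.02, 1)
  )
  expect_equal(table_u5mr(lt), 1 - 0.95 * 0.98)

  zero <- abridged_life_table("z",
    start_age = c(0, 1, 5), width = c(1, 4, Inf), nqx = c(0, 0, 1)
  )
  expect_equal(table_u5mr(zero), 0)

  single <- abridged_life_table("s",
    start_age = c(0, 5), width = c(5, Inf), nqx = c(0.1, 1)
  )
  expect_equal(table_u5mr(single), 0.1)

  # interval straddling age 5 contributes its annualized q for covered years
  straddle <- abridged_life_table("st",
    start_age = c(0, 10), width = c(10, Inf), nqx = c(0.2, 1)
  )
  qa <- 1 - 0.8^(1 / 10)
  expect_equal(table_u5mr(straddle), 1 - (1 - qa)^5)

  no5 <- abridged_life_table("n", start_age = 0, width = Inf, nqx = 1)
  expect_error(table_u5mr(no5), "0-5")
})

test_that("life-table matching is nearest-neighbour with lower-U5MR tie-break", {
  set <- list(flat_life_table(0.0102, "a"), flat_life_table(0.0206, "b"),
    flat_life_table(0.0315, "c"))
  u <- vapply(set, table_u5mr, numeric(1)) # ~0.05, 0.10, 0.15
  expect_equal(match_life_table(0.118, set)$label, "b")
  expect_equal(match_life_table(u[3], set)$label, "c")
  # exact midpoint: pick the lower-U5MR table
  expect_equal(match_life_table(mean(u[1:2]), set)$label, "a")
  # order independence
  for (perm in list(c(3, 1, 2), c(2, 3, 1), 3:1)) {
    expect_equal(match_life_table(0.118, set[perm])$label, "b")
  }
  expect_error(match_life_table(0.1, list()), "empty")
})

test_that("expansion to single years uses an exactly invertible constant-hazard split", {
  lt <- abridged_life_table("t",
    start_age = c(0, 1, 5), width = c(1, 4, Inf), nqx = c(0.05, 0.04, 1)
  )
  sched <- expand_to_annual(lt)
  expect_s3_class(sched, "annual_mortality_schedule")
  expect_length(sched, 120L)
  expect_equal(sched[2], 1 - 0.96^0.25)
  expect_equal(unname(sched[2:5]), rep(1 - 0.96^0.25, 4))
  # inverse identity: the four expanded years reproduce the interval probability
  expect_equal(1 - prod(1 - sched[2:5]), 0.04, tolerance = 1e-12)
  # terminal open interval carries the last closed interval's annual q
  expect_equal(unname(sched[6]), unname(sched[5]))
  expect_equal(unname(sched[119]), unname(sched[5]))
  # cohort closes at the final modelled age
  expect_equal(unname(sched[120]), 1)

  zero <- abridged_life_table("z",
    start_age = c(0, 5), width = c(5, Inf), nqx = c(0, 1)
  )
  expect_true(all(expand_to_annual(zero)[1:119] == 0))
})

test_that("expanded schedules reproduce the abridged table's U5MR", {
  for (t in ethiopia_reference_set()) {
    sched <- expand_to_annual(t)
    u5 <- 1 - prod(1 - sched[1:5])
    expect_equal(u5, table_u5mr(t), tolerance = 1e-9)
  }
})

test_that("regional under-five overlay replaces ages 0-4 only", {
  sched <- expand_to_annual(synthetic_base_life_table())
  region <- toy_region(q_infant = 0.0485, q_child = 0.0051)
  out <- apply_region_under5(sched, region)
  expect_equal(unname(out[1]), 0.0485)
  expect_equal(unname(out[2:5]), rep(0.0051, 4))
  expect_equal(out[6:120], sched[6:120])
  zero <- apply_region_under5(sched, toy_region(q_infant = 0, q_child = 0))
  expect_true(all(zero[1:5] == 0))
})

test_that("survival curves follow the recursion and stay valid", {
  q <- annual_mortality_schedule(rep(0.5, 120))
  S <- survival_from_schedule(q)
  expect_equal(S, 0.5^(0:120))

  q1 <- annual_mortality_schedule(c(1, rep(0.2, 119)))
  expect_true(all(survival_from_schedule(q1)[-1] == 0))

  nat <- apply_region_under5(
    expand_to_annual(synthetic_base_life_table()),
    toy_region(q_infant = 0.0485, q_child = 0.0051)
  )
  S <- survival_from_schedule(nat)
  expect_equal(S[6], (1 - 0.0485) * (1 - 0.0051)^4)
  expect_true(all(diff(S) <= 0))
  expect_true(all(S >= 0 & S <= 1))
  expect_equal(S[121], 0)
})

test_that("life tables round-trip through CSV files and directories", {
  dir <- withr::local_tempdir()
  fam <- synthetic_reference_set(synthetic_base_life_table(), c(0.5, 1, 2))
  for (i in seq_along(fam)) {
    write_life_table(fam[[i]], file.path(dir, sprintf("lt_%d.csv", i)))
  }
  back <- read_life_table_dir(dir)
  expect_length(back, 3L)
  expect_equal(
    sort(vapply(back, table_u5mr, numeric(1))),
    sort(vapply(fam, table_u5mr, numeric(1)))
  )
  expect_error(read_life_table_dir(file.path(dir, "nope")), "reference set not found")
})
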