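#' Annual pneumonia incidence from point prevalence
#'
#' Converts a two-week-recall style point prevalence into episodes per
#' child-year using the mean episode duration:
#' `incidence = prevalence * 365 / duration_days`.
#'
#' @param prevalence Point prevalence of pneumonia symptoms, in `[0, 1]`.
#' @param duration_days Mean duration of one episode in days (> 0).
#' @return Episodes per child-year.
#' @examples
#' incidence_from_prevalence(0.005, 4.6)
#' @export
incidence_from_prevalence <- function(prevalence, duration_days) {
  if (any(duration_days <= 0)) stop("duration_days must be positive", call. = FALSE)
  stopifnot(all(prevalence >= 0 & prevalence <= 1))
  prevalence * 365 / duration_days
}

#' Decompose all-cause mortality into pneumonia and non-pneumonia parts
#'
#' Background mortality observed at the region's baseline treatment coverage
#' is all-cause. The pneumonia-attributable annual death probability at
#' baseline is `incidence * cfr_untreated * (1 - efficacy * baseline_coverage)`;
#' the remainder is attributed to other causes. If the pneumonia component
#' exceeds the all-cause probability (inconsistent inputs), the non-pneumonia
#' part is clamped to zero with a warning.
#'
#' @param q_allcause All-cause annual death probability, per 1.
#' @param region A single-row [region_table()] row (list-like).
#' @param params A [fixed_params()] object.
#' @return A list with `q_nonpneumonia` and `q_pneumonia_baseline`.
#' @export
pneumonia_decomposition <- function(q_allcause, region, params) {
  stopifnot(all(q_allcause >= 0 & q_allcause <= 1))
  q_pneu <- region$incidence * params$cfr_untreated *
    (1 - params$efficacy * region$baseline_coverage)
  q_non <- q_allcause - q_pneu
  if (any(q_non < 0)) {
    warning(sprintf(
      "region %s: baseline pneumonia mortality (%.4f) exceeds all-cause mortality; clamping non-pneumonia mortality to 0",
      region$region, q_pneu
    ), call. = FALSE)
    q_non <- pmax(0, q_non)
  }
  list(q_nonpneumonia = q_non, q_pneumonia_baseline = rep(q_pneu, length(q_non)))
}

#' Mortality schedule at a counterfactual treatment coverage
#'
#' For the intervention ages (the first `params$intervention_ages` cycles),
#' rebuilds the annual death probability as non-pneumonia mortality plus
#' pneumonia mortality at the requested coverage:
#' `q'(a) = q_nonpneumonia(a) + incidence * cfr * (1 - efficacy * coverage)`,
#' clamped to `[0, 1]`. Older ages are untouched. At the region's baseline
#' coverage this reproduces the input schedule exactly (absent clamping).
#'
#' @inheritParams pneumonia_decomposition
#' @param schedule All-cause [annual_mortality_schedule()] observed at the
#'   region's baseline coverage.
#' @param coverage Treatment coverage to evaluate, in `[0, 1]`.
#' @return The adjusted [annual_mortality_schedule()].
#' @export
mortality_at_coverage <- function(schedule, region, params, coverage) {
  stopifnot(inherits(schedule, "annual_mortality_schedule"))
  if (!is.numeric(coverage) || length(coverage) != 1L || is.na(coverage) ||
    coverage < 0 || coverage > 1) {
    stop("coverage must be a single probability in [0, 1]", call. = FALSE)
  }
  q <- unclass(schedule)
  ia <- params$intervention_ages
  if (ia < 1L) {
    return(schedule)
  }
  idx <- seq_len(min(ia, length(q)))
  dec <- pneumonia_decomposition(q[idx], region, params)
  q_new <- dec$q_nonpneumonia +
    region$incidence * params$cfr_untreated * (1 - params$efficacy * coverage)
  q[idx] <- pmin(1, pmax(0, q_new))
  annual_mortality_schedule(q)
}

#' Run one arm of the Markov cohort model
#'
#' Follows a birth cohort through `length(schedule)` annual cycles at the
#' given treatment coverage. Survivors of each cycle are credited one life
#' year; with half-cycle correction a flat half year is added (undiscounted)
#' to account for mid-cycle deaths. Treatment costs accrue at cycle start
#' among those alive, during the intervention ages only, and are discounted
#' at `discount_costs`.
#'
#' @inheritParams mortality_at_coverage
#' @return An object of class `cohort_result`: a list with
#'   `survival` (length `A + 1`), `life_expectancy` (undiscounted years),
#'   `discounted_life_years`, `u5mr` (probability, `1 - S(5)`),
#'   `deaths_by_age` (length `A`), `treatment_cost_per_child` (discounted
#'   USD) and `coverage`.
#' @examples
#' lt <- abridged_life_table("flat",
#'   start_age = c(0, 5), width = c(5, Inf), nqx = c(0.05, 1)
#' )
#' sched <- expand_to_annual(lt)
#' region <- list(
#'   region = "Toy", q_infant = 0.03, q_child = 0.005,
#'   cost_per_treatment = 45, incidence = 0.15, baseline_coverage = 0.5
#' )
#' sched <- apply_region_under5(sched, region)
#' run_cohort(sched, region, fixed_params(), coverage = 0.9)$life_expectancy
#' @export
run_cohort <- function(schedule, region, params, coverage) {
  sched <- mortality_at_coverage(schedule, region, params, coverage)
  S <- survival_from_schedule(sched)
  A <- length(sched)
  hc <- if (params$half_cycle_correction) 0.5 else 0
  ages <- seq_len(A) # exact ages 1..A at which completed life years are counted
  le <- sum(S[ages + 1L]) + hc
  dly <- sum(S[ages + 1L] * (1 + params$discount_effects)^(-ages)) + hc
  u5 <- 1 - S[6L]
  deaths <- S[seq_len(A)] - S[seq_len(A) + 1L]
  cost_ages <- seq_len(min(params$intervention_ages, A)) - 1L # ages 0..ia-1
  cost <- sum(
    S[cost_ages + 1L] * region$incidence * coverage *
      region$cost_per_treatment * (1 + params$discount_costs)^(-cost_ages)
  )
  structure(
    list(
      survival = S,
      life_expectancy = le,
      discounted_life_years = dly,
      u5mr = u5,
      deaths_by_age = deaths,
      treatment_cost_per_child = cost,
      coverage = coverage
    ),
    class = "cohort_result"
  )
}

#' @export
print.cohort_result <- function(x, ...) {
  cat(sprintf(
    "Cohort result at coverage %.2f: LE %.2f y (discounted %.2f), U5MR %.1f/1000, cost/child %.2f USD\n",
    x$coverage, x$life_expectancy, x$discounted_life_years,
    1000 * x$u5mr, x$treatment_cost_per_child
  ))
  invisible(x)
}

#' Under-five mortality from infant and child probabilities
#'
#' `1 - (1 - q_infant) * (1 - q_child)^4`: death before age five given the
#' infant (age 0) probability and the annual probability at ages 1-4.
#'
#' @param q_infant Probability of death before age one, per 1.
#' @param q_child Annual probability of death at ages 1-4, per 1.
#' @return Probability of death before age five, per 1.
#' @examples
#' u5mr_from_rates(0.0485, 0.0051)
#' @export
u5mr_from_rates <- function(q_infant, q_child) {
  stopifnot(
    all(q_infant >= 0 & q_infant <= 1),
    all(q_child >= 0 & q_child <= 1)
  )
  1 - (1 - q_infant) * (1 - q_child)^4
}
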