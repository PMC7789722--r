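#' Average cost per treated episode from urban/rural mix
#'
#' Rural community health services are costlier to deliver than urban ones;
#' the regional unit cost is the residency-weighted average
#' `urban_unit_cost * x + urban_unit_cost * rural_multiplier * (1 - x)`.
#'
#' @param urban_fraction Proportion of the region's population with urban
#'   residency, in `[0, 1]`.
#' @param params A [fixed_params()] object.
#' @return Cost per treated episode in USD.
#' @examples
#' cost_per_treatment(1, fixed_params()) # fully urban: 45
#' cost_per_treatment(0, fixed_params()) # fully rural: 45 * 7.2
#' @export
cost_per_treatment <- function(urban_fraction, params) {
  if (any(is.na(urban_fraction)) || any(urban_fraction < 0 | urban_fraction > 1)) {
    stop("urban_fraction must lie in [0, 1]", call. = FALSE)
  }
  params$urban_unit_cost * urban_fraction +
    params$urban_unit_cost * params$rural_multiplier * (1 - urban_fraction)
}

#' Incremental cost-effectiveness ratio
#'
#' @param incremental_cost Incremental cost (USD).
#' @param incremental_effect Incremental effect (life years gained); must be
#'   strictly positive.
#' @return USD per life year gained.
#' @export
icer <- function(incremental_cost, incremental_effect) {
  if (length(incremental_effect) != 1L || is.na(incremental_effect)) {
    stop("incremental effect must be a single number", call. = FALSE)
  }
  if (incremental_effect == 0) {
    stop("no incremental effect: ICER undefined", call. = FALSE)
  }
  if (incremental_effect < 0) {
    stop("negative incremental effect: intervention is dominated", call. = FALSE)
  }
  incremental_cost / incremental_effect
}

#' Scale up CCM coverage in one region
#'
#' Runs the two-arm cohort model for a region: builds the region's mortality
#' schedule (match a reference life table by U5MR, expand to single years,
#' overlay the region's under-five mortality), evaluates it at baseline and
#' target coverage, and assembles costs, effects and ICERs.
#'
#' @param region One-row [region_table()] (or an equivalent list) for the
#'   region.
#' @param reference_set List of [abridged_life_table()] objects.
#' @param params A [fixed_params()] object.
#' @param target_coverage Coverage to scale up to; defaults to
#'   `params$target_coverage`. Must be at least the baseline coverage.
#' @param match_on `"reported"` matches the reference table on the region's
#'   `reported_u5mr` (falling back to the derived value when missing);
#'   `"derived"` always uses [u5mr_from_rates()] on the region's own
#'   probabilities.
#' @return An object of class `scale_up_result`: a list with the two
#'   [run_cohort()] arms (`baseline`, `target`) and the fields
#'   `region`, `le_baseline`, `le_target`, `incremental_le`,
#'   `incremental_discounted_ly`, `u5mr_baseline`, `u5mr_target`,
#'   `deaths_averted_per_child`, `cost_per_child_baseline`,
#'   `cost_per_child_target`, `total_cost_baseline`, `total_cost_target`,
#'   `incremental_cost` (totals are `NA` without a `birth_cohort`),
#'   `icer` (discounted life-year denominator) and `icer_undiscounted`.
#' @examples
#' fx <- ethiopia_fixture()
#' refs <- ethiopia_reference_set()
#' res <- scale_up_region(fx$regions[fx$regions$region == "Addis", ], refs, fx$params)
#' res$incremental_le
#' @export
scale_up_region <- function(region, reference_set, params,
                            target_coverage = params$target_coverage,
                            match_on = c("reported", "derived")) {
  match_on <- match.arg(match_on)
  if (is.data.frame(region)) {
    stopifnot(nrow(region) == 1L)
    region <- as.list(region)
  }
  if (target_coverage < region$baseline_coverage) {
    stop("decremental scale-up unsupported: target coverage below baseline",
      call. = FALSE
    )
  }
  u5 <- region_match_u5mr(region, match_on)
  matched <- match_life_table(u5, reference_set)
  sched <- expand_to_annual(matched, max_age = params$cycles)
  sched <- apply_region_under5(sched, region)

  base <- run_cohort(sched, region, params, region$baseline_coverage)
  targ <- run_cohort(sched, region, params, target_coverage)

  inc_le <- targ$life_expectancy - base$life_expectancy
  inc_dly <- targ$discounted_life_years - base$discounted_life_years
  bc <- if (!is.null(region$birth_cohort)) region$birth_cohort else NA_real_
  tc_base <- bc * base$treatment_cost_per_child
  tc_targ <- bc * targ$treatment_cost_per_child
  inc_cost_pc <- targ$treatment_cost_per_child - base$treatment_cost_per_child

  structure(
    list(
      region = region$region,
      matched_table = matched$label,
      baseline = base,
      target = targ,
      le_baseline = base$life_expectancy,
      le_target = targ$life_expectancy,
      incremental_le = inc_le,
      incremental_discounted_ly = inc_dly,
      u5mr_baseline = base$u5mr,
      u5mr_target = targ$u5mr,
      deaths_averted_per_child = base$u5mr - targ$u5mr,
      cost_per_child_baseline = base$treatment_cost_per_child,
      cost_per_child_target = targ$treatment_cost_per_child,
      total_cost_baseline = tc_base,
      total_cost_target = tc_targ,
      incremental_cost = tc_targ - tc_base,
      incremental_cost_per_child = inc_cost_pc,
      icer = if (inc_dly > 0) inc_cost_pc / inc_dly else NA_real_,
      icer_undiscounted = if (inc_le > 0) inc_cost_pc / inc_le else NA_real_
    ),
    class = "scale_up_result"
  )
}

region_match_u5mr <- function(region, match_on) {
  reported <- region$reported_u5mr
  if (match_on == "reported" && !is.null(reported) && !is.na(reported)) {
    reported / 1000
  } else {
    u5mr_from_rates(region$q_infant, region$q_child)
  }
}

#' @export
print.scale_up_result <- function(x, ...) {
  cat(sprintf(
    "%s: LE %.2f -> %.2f (+%.2f y), U5MR %.1f -> %.1f /1000, ICER %.2f USD/LY (undiscounted %.2f)\n",
    x$region, x$le_baseline, x$le_target, x$incremental_le,
    1000 * x$u5mr_baseline, 1000 * x$u5mr_target, x$icer, x$icer_undiscounted
  ))
  invisible(x)
}

#' Is an ICER cost-effective against a GDP-fraction threshold?
#'
#' @param icer ICER in USD per life year gained.
#' @param params A [fixed_params()] object (provides `gdp_per_capita`).
#' @param threshold_fraction Fraction of GDP per capita used as the
#'   willingness-to-pay threshold (e.g. 0.5).
#' @return Logical: `TRUE` when `icer <= threshold_fraction * gdp_per_capita`
#'   (inclusive).
#' @export
cost_effectiveness_flag <- function(icer, params, threshold_fraction = 0.5) {
  if (threshold_fraction <= 0) stop("threshold_fraction must be positive", call. = FALSE)
  icer <= threshold_fraction * params$gdp_per_capita
}
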