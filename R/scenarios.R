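#' Specify a scale-up scenario strategy
#'
#' Three static strategies for scaling CCM coverage to the target level:
#' * `health_max` — the `k` regions with the lowest ICER (most
#'   cost-effective first); default `k = 5`.
#' * `equity` — the `k` regions with the highest reported under-five
#'   mortality (worst-off first); default `k = 3`.
#' * `universal` — every region.
#' * `baseline` — no region (reference scenario for comparisons).
#'
#' @param strategy One of `"baseline"`, `"health_max"`, `"equity"`,
#'   `"universal"`.
#' @param k Number of regions to select (ignored for `universal` and
#'   `baseline`).
#' @return A list of class `scenario_spec`.
#' @export
scenario_spec <- function(strategy = c("baseline", "health_max", "equity", "universal"),
                          k = NULL) {
  strategy <- match.arg(strategy)
  if (is.null(k)) {
    k <- switch(strategy,
      health_max = 5L,
      equity = 3L,
      0L
    )
  }
  k <- as.integer(k)
  if (strategy %in% c("health_max", "equity") && k < 1L) {
    stop("k must be at least 1 for strategy ", strategy, call. = FALSE)
  }
  structure(list(strategy = strategy, k = k), class = "scenario_spec")
}

#' Rank regions for scenario selection
#'
#' Deterministic, stable ranking with alphabetical tie-break on the region
#' name. `key = "icer"` orders ascending (most cost-effective first) using
#' the per-region scale-up results; `key = "reported_u5mr"` orders
#' descending (worst-off first) using the region table.
#'
#' @param results List of [scale_up_region()] results, one per region.
#' @param regions The matching [region_table()].
#' @param key `"icer"` or `"reported_u5mr"`.
#' @return Character vector of region names, best-first.
#' @export
rank_regions <- function(results, regions, key = c("icer", "reported_u5mr")) {
  key <- match.arg(key)
  if (key == "icer") {
    vals <- vapply(results, function(r) r$icer, numeric(1))
    names(vals) <- vapply(results, function(r) r$region, character(1))
    if (anyNA(vals)) {
      stop(
        "ICER unavailable for region(s): ",
        paste(names(vals)[is.na(vals)], collapse = ", "),
        call. = FALSE
      )
    }
    ord <- order(vals, names(vals))
    names(vals)[ord]
  } else {
    vals <- regions$reported_u5mr
    names(vals) <- regions$region
    if (anyNA(vals)) {
      stop(
        "reported_u5mr missing for region(s): ",
        paste(names(vals)[is.na(vals)], collapse = ", "),
        call. = FALSE
      )
    }
    ord <- order(-vals, names(vals))
    names(vals)[ord]
  }
}

#' Run one scale-up scenario and aggregate nationally
#'
#' Scales the selected regions to the target coverage while the remaining
#' regions stay at their baseline coverage, then aggregates with
#' birth-cohort weights: total incremental cost, population-weighted life
#' expectancy gain, national U5MR before/after, under-five deaths averted,
#' cost per death averted, the national interindividual Gini (pooled,
#' cohort-weighted ages at death across all regions) and the geographical
#' Gini (regional life expectancies weighted by births).
#'
#' @param spec A [scenario_spec()].
#' @param regions A [region_table()] with `birth_cohort` set for every
#'   region.
#' @param reference_set List of [abridged_life_table()] objects.
#' @param params A [fixed_params()] object.
#' @param cost_table Optional data frame (`region`, `incremental_cost`, and
#'   optionally `total_cost_baseline`, `total_cost_target`) of externally
#'   supplied program costs — e.g. published rounded figures — used in place
#'   of model-computed incremental costs. Rows with unknown region names
#'   (such as a `SUM` row) are ignored.
#' @param match_on Passed to [scale_up_region()].
#' @return A list of class `scenario_result`.
#' @export
run_scenario <- function(spec, regions, reference_set, params,
                         cost_table = NULL,
                         match_on = c("reported", "derived")) {
  stopifnot(inherits(spec, "scenario_spec"))
  match_on <- match.arg(match_on)
  regions <- validate_region_table(regions)
  if (anyNA(regions$birth_cohort)) {
    stop(
      "birth_cohort missing for region(s): ",
      paste(regions$region[is.na(regions$birth_cohort)], collapse = ", "),
      call. = FALSE
    )
  }
  all_results <- lapply(seq_len(nrow(regions)), function(i) {
    scale_up_region(regions[i, ], reference_set, params, match_on = match_on)
  })
  names(all_results) <- regions$region

  selected <- switch(spec$strategy,
    baseline = character(0),
    universal = regions$region,
    health_max = utils::head(rank_regions(all_results, regions, "icer"), spec$k),
    equity = utils::head(rank_regions(all_results, regions, "reported_u5mr"), spec$k)
  )
  if (spec$strategy %in% c("health_max", "equity") && spec$k > nrow(regions)) {
    stop("k exceeds the number of regions", call. = FALSE)
  }

  w <- regions$birth_cohort
  is_sel <- regions$region %in% selected

  # per-region scenario arm: target where selected, baseline elsewhere
  arm <- lapply(seq_along(all_results), function(i) {
    if (is_sel[i]) all_results[[i]]$target else all_results[[i]]$baseline
  })
  base_arm <- lapply(all_results, function(r) r$baseline)

  inc_le <- vapply(all_results, function(r) r$incremental_le, numeric(1))
  u5_base <- vapply(base_arm, function(a) a$u5mr, numeric(1))
  u5_arm <- vapply(arm, function(a) a$u5mr, numeric(1))
  le_arm <- vapply(arm, function(a) a$life_expectancy, numeric(1))
  le_base <- vapply(base_arm, function(a) a$life_expectancy, numeric(1))

  inc_cost <- if (is.null(cost_table)) {
    sum(vapply(all_results[is_sel], function(r) r$incremental_cost, numeric(1)))
  } else {
    ct <- cost_table[cost_table$region %in% selected, , drop = FALSE]
    missing_regions <- setdiff(selected, ct$region)
    if (length(missing_regions)) {
      stop(
        "cost_table missing region(s): ",
        paste(missing_regions, collapse = ", "),
        call. = FALSE
      )
    }
    sum(ct$incremental_cost)
  }

  deaths_averted <- sum(w[is_sel] * (u5_base[is_sel] - u5_arm[is_sel]))
  weighted_le_gain <- sum(w * inc_le * is_sel) / sum(w)
  pooled <- pooled_deaths_by_age(arm, w)

  structure(
    list(
      strategy = spec$strategy,
      selected_regions = selected,
      region_results = all_results,
      total_incremental_cost = inc_cost,
      weighted_le_gain = weighted_le_gain,
      national_le = sum(w * le_arm) / sum(w),
      national_le_baseline = sum(w * le_base) / sum(w),
      national_u5mr_baseline = 1000 * sum(w * u5_base) / sum(w),
      national_u5mr_target = 1000 * sum(w * u5_arm) / sum(w),
      deaths_averted = deaths_averted,
      cost_per_death_averted = if (deaths_averted > 0) inc_cost / deaths_averted else NA_real_,
      interindividual_gini = gini(pooled$ages, pooled$weights),
      geographical_gini = geographical_gini(le_arm, w)
    ),
    class = "scenario_result"
  )
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf(
    "Scenario %s: %d region(s) scaled up\n", x$strategy, length(x$selected_regions)
  ))
  cat(sprintf(
    "  incremental cost %.0f USD | deaths averted %.0f | LE gain %.3f y\n",
    x$total_incremental_cost, x$deaths_averted, x$weighted_le_gain
  ))
  cat(sprintf(
    "  interindividual Gini %.3f | geographical Gini %.3f\n",
    x$interindividual_gini, x$geographical_gini
  ))
  invisible(x)
}

#' Compare scenarios against a baseline
#'
#' @param results List of [run_scenario()] results; must contain at least
#'   two, one of which has strategy `"baseline"`.
#' @return A data frame, one row per scenario, with national aggregates and
#'   deltas versus the baseline scenario (`d_` columns).
#' @export
compare_scenarios <- function(results) {
  if (length(results) < 2L) {
    stop("need at least two scenarios including a baseline", call. = FALSE)
  }
  strategies <- vapply(results, function(r) r$strategy, character(1))
  if (!"baseline" %in% strategies) {
    stop("no baseline scenario supplied", call. = FALSE)
  }
  base <- results[[which(strategies == "baseline")[1L]]]
  rows <- lapply(results, function(r) {
    data.frame(
      scenario = r$strategy,
      n_selected = length(r$selected_regions),
      incremental_cost = r$total_incremental_cost,
      cost_per_death_averted = r$cost_per_death_averted,
      deaths_averted = r$deaths_averted,
      le_gain = r$weighted_le_gain,
      interindividual_gini = r$interindividual_gini,
      geographical_gini = r$geographical_gini,
      d_interindividual_gini = r$interindividual_gini - base$interindividual_gini,
      d_geographical_gini = r$geographical_gini - base$geographical_gini
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
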