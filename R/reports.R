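#' Run the full per-region scale-up analysis and write reports
#'
#' Drives [scale_up_region()] over every region, attaches within-region
#' interindividual Gini coefficients at both coverages, and (optionally)
#' writes `regions.csv` plus a JSON run manifest capturing the parameters,
#' input checksums and package version, so every reported number is
#' reproducible from the manifest alone.
#'
#' @param regions A [region_table()].
#' @param reference_set List of [abridged_life_table()] objects.
#' @param params A [fixed_params()] object.
#' @param out_dir Output directory; created if needed. `NULL` skips writing.
#' @param match_on Passed to [scale_up_region()].
#' @param inputs Optional named character vector of input file paths to
#'   checksum into the manifest.
#' @return Invisibly, a list with `table` (the per-region data frame) and
#'   `results` (the underlying [scale_up_region()] objects).
#' @examples
#' fx <- ethiopia_fixture()
#' run <- run_all(fx$regions, ethiopia_reference_set(), fx$params)
#' head(run$table)
#' @export
run_all <- function(regions, reference_set, params,
                    out_dir = NULL, match_on = c("reported", "derived"),
                    inputs = character(0)) {
  match_on <- match.arg(match_on)
  regions <- validate_region_table(regions)
  results <- lapply(seq_len(nrow(regions)), function(i) {
    scale_up_region(regions[i, ], reference_set, params, match_on = match_on)
  })
  names(results) <- regions$region
  tab <- do.call(rbind, lapply(results, function(r) {
    data.frame(
      region = r$region,
      matched_table = r$matched_table,
      le_baseline = r$le_baseline,
      le_target = r$le_target,
      incremental_le = r$incremental_le,
      incremental_discounted_ly = r$incremental_discounted_ly,
      u5mr_baseline_per1000 = 1000 * r$u5mr_baseline,
      u5mr_target_per1000 = 1000 * r$u5mr_target,
      cost_per_child_baseline = r$cost_per_child_baseline,
      cost_per_child_target = r$cost_per_child_target,
      total_cost_baseline = r$total_cost_baseline,
      total_cost_target = r$total_cost_target,
      incremental_cost = r$incremental_cost,
      icer = r$icer,
      icer_undiscounted = r$icer_undiscounted,
      gini_baseline = interindividual_gini(r$baseline),
      gini_target = interindividual_gini(r$target)
    )
  }))
  rownames(tab) <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_results(tab, file.path(out_dir, "regions.csv"))
    write_manifest(
      file.path(out_dir, "manifest.json"),
      params = params, match_on = match_on, inputs = inputs,
      n_regions = nrow(regions),
      reference_labels = vapply(reference_set, function(t) t$label, character(1))
    )
  }
  invisible(list(table = tab, results = results))
}

#' Run the three scale-up strategies and write a scenario report
#'
#' Evaluates the baseline plus the requested strategies through
#' [run_scenario()] and assembles the comparison table (incremental cost,
#' cost per death averted, life expectancy gain, interindividual and
#' geographical Gini).
#'
#' @inheritParams run_all
#' @param strategies Character vector of strategies to run in addition to
#'   the baseline.
#' @param k_health_max,k_equity Region counts for the ranked strategies.
#' @param cost_table Optional external cost table, passed to
#'   [run_scenario()].
#' @return Invisibly, a list with `table` (the comparison data frame) and
#'   `scenarios` (the [run_scenario()] results).
#' @export
run_scenarios <- function(regions, reference_set, params,
                          strategies = c("health_max", "equity", "universal"),
                          k_health_max = 5L, k_equity = 3L,
                          cost_table = NULL,
                          out_dir = NULL, match_on = c("reported", "derived"),
                          inputs = character(0)) {
  match_on <- match.arg(match_on)
  strategies <- match.arg(strategies, several.ok = TRUE)
  specs <- c(
    list(scenario_spec("baseline")),
    lapply(strategies, function(s) {
      scenario_spec(s, k = switch(s,
        health_max = k_health_max,
        equity = k_equity,
        NULL
      ))
    })
  )
  scen <- lapply(specs, function(sp) {
    run_scenario(sp, regions, reference_set, params,
      cost_table = cost_table, match_on = match_on
    )
  })
  tab <- compare_scenarios(scen)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_results(tab, file.path(out_dir, "scenarios.csv"))
    write_manifest(
      file.path(out_dir, "scenarios_manifest.json"),
      params = params, match_on = match_on, inputs = inputs,
      n_regions = nrow(regions),
      strategies = strategies,
      k_health_max = k_health_max, k_equity = k_equity,
      external_cost_table = !is.null(cost_table),
      reference_labels = vapply(reference_set, function(t) t$label, character(1))
    )
  }
  invisible(list(table = tab, scenarios = scen))
}

write_manifest <- function(path, params, inputs = character(0), ...) {
  checksums <- if (length(inputs)) {
    as.list(tools::md5sum(inputs))
  } else {
    NULL
  }
  manifest <- c(
    list(
      package = "ccmdcea",
      version = as.character(utils::packageVersion("ccmdcea")),
      params = unclass(params),
      input_md5 = checksums
    ),
    list(...)
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Round a machine-precision report the way results tables are printed
#'
#' Machine outputs stay full precision; this helper produces a presentation
#' copy (life expectancy and ICERs to 2 decimals, Gini to 3, program costs
#' to the nearest 100,000 USD).
#'
#' @param table A data frame from [run_all()] or [run_scenarios()].
#' @return The rounded copy.
#' @export
pretty_report <- function(table) {
  out <- table
  for (col in names(out)) {
    if (!is.numeric(out[[col]])) next
    if (grepl("gini", col)) {
      out[[col]] <- round(out[[col]], 3)
    } else if (grepl("cost|usd", col, ignore.case = TRUE) && !grepl("per_", col)) {
      out[[col]] <- round(out[[col]] / 1e5) * 1e5
    } else {
      out[[col]] <- round(out[[col]], 2)
    }
  }
  out
}
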