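#' Fixed (region-invariant) model parameters
#'
#' Bundles the global constants of the cohort model: the untreated case
#' fatality rate of childhood pneumonia, the proportional CFR reduction
#' afforded by community-based treatment (CCM), cycle count, discount rates,
#' the scale-up target coverage, and the unit-cost model. Defaults are the
#' published 2016 Ethiopian analysis inputs.
#'
#' @param cfr_untreated Case fatality rate of an untreated pneumonia episode
#'   (probability per episode).
#' @param efficacy Proportional reduction of the CFR when an episode is
#'   treated, in `[0, 1]`.
#' @param cycles Number of annual Markov cycles; the cohort is followed from
#'   birth until extinction.
#' @param discount_costs,discount_effects Annual discount rates (per 1).
#' @param target_coverage Scale-up target treatment coverage, in `[0, 1]`.
#' @param duration_days Mean duration of a pneumonia episode in days; used to
#'   convert point prevalence to annual incidence.
#' @param urban_unit_cost Cost (USD) of one treated episode for an urban
#'   resident.
#' @param rural_multiplier Rural-to-urban unit cost ratio (dimensionless).
#' @param gdp_per_capita GDP per capita (USD), used for the cost-effectiveness
#'   threshold.
#' @param intervention_ages Number of initial cycles (ages) during which the
#'   intervention operates; pneumonia mortality and treatment costs apply to
#'   these ages only.
#' @param half_cycle_correction Logical; credit half a cycle of survival for
#'   mid-cycle events.
#'
#' @return An object of class `fixed_params` (a validated named list).
#' @examples
#' p <- fixed_params()
#' p$cfr_untreated
#' fixed_params(discount_effects = 0)$discount_effects
#' @export
fixed_params <- function(cfr_untreated = 0.0351,
                         efficacy = 0.70,
                         cycles = 120L,
                         discount_costs = 0.03,
                         discount_effects = 0.03,
                         target_coverage = 0.90,
                         duration_days = 4.6,
                         urban_unit_cost = 45,
                         rural_multiplier = 7.2,
                         gdp_per_capita = 713,
                         intervention_ages = 5L,
                         half_cycle_correction = TRUE) {
  p <- list(
    cfr_untreated = as.numeric(cfr_untreated),
    efficacy = as.numeric(efficacy),
    cycles = as.integer(cycles),
    discount_costs = as.numeric(discount_costs),
    discount_effects = as.numeric(discount_effects),
    target_coverage = as.numeric(target_coverage),
    duration_days = as.numeric(duration_days),
    urban_unit_cost = as.numeric(urban_unit_cost),
    rural_multiplier = as.numeric(rural_multiplier),
    gdp_per_capita = as.numeric(gdp_per_capita),
    intervention_ages = as.integer(intervention_ages),
    half_cycle_correction = isTRUE(half_cycle_correction)
  )
  validate_fixed_params(p)
}

validate_fixed_params <- function(p) {
  stopifnot(is.list(p))
  num_fields <- c(
    "cfr_untreated", "efficacy", "discount_costs", "discount_effects",
    "target_coverage", "duration_days", "urban_unit_cost",
    "rural_multiplier", "gdp_per_capita"
  )
  for (f in num_fields) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0) {
      stop("fixed_params: field '", f, "' must be a single nonnegative number",
        call. = FALSE
      )
    }
  }
  for (f in c("cfr_untreated", "efficacy", "target_coverage")) {
    if (p[[f]] > 1) {
      stop("fixed_params: field '", f, "' must lie in [0, 1]", call. = FALSE)
    }
  }
  if (p$duration_days <= 0) {
    stop("fixed_params: duration_days must be positive", call. = FALSE)
  }
  if (p$cycles < p$intervention_ages) {
    stop("fixed_params: cycles must be >= intervention_ages", call. = FALSE)
  }
  structure(p, class = "fixed_params")
}

#' Read and write fixed parameters as YAML or JSON
#'
#' Configuration files use the field names of [fixed_params()]; missing fields
#' fall back to the defaults, so a config need only state overrides.
#'
#' @param path File path. Format is inferred from the extension
#'   (`.yaml`/`.yml` or `.json`) unless `format` is given.
#' @param format `"yaml"` or `"json"`.
#' @return `read_fixed_params()` returns a `fixed_params` object;
#'   `write_fixed_params()` invisibly returns `path`.
#' @export
read_fixed_params <- function(path, format = c("auto", "yaml", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "yaml"
  }
  if (!file.exists(path)) stop("parameter file not found: ", path, call. = FALSE)
  raw <- if (format == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- names(formals(fixed_params))
  extra <- setdiff(names(raw), known)
  if (length(extra)) {
    stop("unknown parameter field(s): ", paste(extra, collapse = ", "),
      call. = FALSE
    )
  }
  do.call(fixed_params, raw)
}

#' @param params A `fixed_params` object.
#' @rdname read_fixed_params
#' @export
write_fixed_params <- function(params, path, format = c("auto", "yaml", "json")) {
  params <- validate_fixed_params(params)
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "yaml"
  }
  x <- unclass(params)
  if (format == "json") {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(x, path)
  }
  invisible(path)
}

#' @export
print.fixed_params <- function(x, ...) {
  cat("Fixed cohort-model parameters\n")
  cat(sprintf(
    "  CFR untreated %.4f | efficacy %.2f | target coverage %.2f\n",
    x$cfr_untreated, x$efficacy, x$target_coverage
  ))
  cat(sprintf(
    "  cycles %d | intervention ages %d | discounting costs %.2f / effects %.2f\n",
    x$cycles, x$intervention_ages, x$discount_costs, x$discount_effects
  ))
  cat(sprintf(
    "  unit cost urban %.1f USD, rural multiplier %.1f | half-cycle correction %s\n",
    x$urban_unit_cost, x$rural_multiplier,
    if (x$half_cycle_correction) "on" else "off"
  ))
  invisible(x)
}
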