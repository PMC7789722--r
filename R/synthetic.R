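#' Synthetic reference life-table family
#'
#' Generates a family of abridged life tables from a base table by a
#' hazard-power transform: for level `f`, every interval probability becomes
#' `nqx' = 1 - (1 - nqx)^f`. Levels above 1 raise mortality, levels below 1
#' lower it, probabilities stay valid for any `f > 0`, and the family's
#' U5MRs are strictly increasing in `f` — which makes U5MR matching exactly
#' testable without external data.
#'
#' @param base An [abridged_life_table()].
#' @param levels Positive, strictly increasing hazard multipliers.
#' @return A list of `abridged_life_table` objects labelled
#'   `"<base label>-L<level>"`.
#' @examples
#' fam <- synthetic_reference_set(synthetic_base_life_table(), c(0.5, 1, 2))
#' sapply(fam, table_u5mr)
#' @export
synthetic_reference_set <- function(base, levels) {
  stopifnot(inherits(base, "abridged_life_table"))
  if (any(levels <= 0)) stop("hazard levels must be positive", call. = FALSE)
  if (is.unsorted(levels, strictly = TRUE)) {
    stop("hazard levels must be strictly increasing", call. = FALSE)
  }
  lapply(levels, function(f) {
    q <- 1 - (1 - base$nqx)^f
    q[length(q)] <- 1 # terminal interval stays certain death
    abridged_life_table(
      sprintf("%s-L%.3f", base$label, f),
      base$start_age, base$width, q
    )
  })
}

#' Synthetic base abridged life table
#'
#' A synthetic national abridged life table emulating Ethiopian mortality
#' around 2010-2015 (under-five mortality near 68 per 1000, life expectancy
#' at birth near 64-65 years). It is the anchor of the default reference
#' family: hazard-power levels spanning roughly 0.35-3.0 sweep the U5MR
#' through the range national period tables cover historically, standing in
#' for a downloaded set of UN period life tables.
#'
#' @return An [abridged_life_table()] labelled `"synthetic-ethiopia-2015"`.
#' @export
synthetic_base_life_table <- function() {
  abridged_life_table(
    "synthetic-ethiopia-2015",
    start_age = c(0, 1, seq(5, 100, by = 5)),
    width = c(1, 4, rep(5, 19), Inf),
    nqx = c(
      0.048, 0.021, # under five
      0.011, 0.008, 0.011, 0.015, 0.017, 0.019, 0.021, 0.024, # 5-45
      0.031, 0.042, 0.058, 0.090, 0.135, 0.200, 0.300, # 45-80
      0.435, 0.590, 0.740, 0.850, # 80-100
      1 # open-ended
    )
  )
}

#' Default synthetic reference set
#'
#' The [synthetic_base_life_table()] swept through 16 log-spaced
#' hazard-power levels between 0.35 and 3.0, giving reference U5MRs from
#' about 24 to about 190 per 1000 — wide enough to match every Ethiopian
#' region's reported 2016 U5MR (39-125 per 1000).
#'
#' @return A list of [abridged_life_table()] objects.
#' @export
ethiopia_reference_set <- function() {
  levels <- round(exp(seq(log(0.35), log(3.0), length.out = 16)), 3)
  synthetic_reference_set(synthetic_base_life_table(), levels)
}

#' Configuration for synthetic region generation
#'
#' Ranges default to the span observed across the eleven Ethiopian regions
#' in the 2016 DHS: incidence 0.04-0.46 episodes per child-year, baseline
#' coverage 0.25-0.60, infant mortality 16-77 per 1000, child mortality
#' 1.7-11.5 per 1000.
#'
#' @param seed Integer seed; generation is deterministic given the seed.
#' @param n_regions Number of regions to generate (>= 1).
#' @param incidence_range,coverage_range,q_infant_range,q_child_range,urban_fraction_range,birth_cohort_range
#'   Closed intervals to draw from, uniformly.
#' @param mortality_levels Positive strictly increasing hazard multipliers
#'   for the companion reference life-table family.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L,
                             n_regions = 11L,
                             incidence_range = c(0.04, 0.46),
                             coverage_range = c(0.25, 0.60),
                             q_infant_range = c(0.016, 0.077),
                             q_child_range = c(0.0017, 0.0115),
                             urban_fraction_range = c(0.05, 0.95),
                             birth_cohort_range = c(5e4, 1.5e6),
                             mortality_levels = round(
                               exp(seq(log(0.35), log(3.0), length.out = 16)), 3
                             )) {
  cfg <- list(
    seed = as.integer(seed),
    n_regions = as.integer(n_regions),
    incidence_range = incidence_range,
    coverage_range = coverage_range,
    q_infant_range = q_infant_range,
    q_child_range = q_child_range,
    urban_fraction_range = urban_fraction_range,
    birth_cohort_range = birth_cohort_range,
    mortality_levels = mortality_levels
  )
  for (f in c(
    "incidence_range", "coverage_range", "q_infant_range",
    "q_child_range", "urban_fraction_range", "birth_cohort_range"
  )) {
    r <- cfg[[f]]
    if (length(r) != 2L || anyNA(r) || r[1] > r[2] || r[1] < 0) {
      stop("invalid range for ", f, call. = FALSE)
    }
  }
  for (f in c("coverage_range", "q_infant_range", "q_child_range", "urban_fraction_range")) {
    if (cfg[[f]][2] > 1) stop(f, " must stay within [0, 1]", call. = FALSE)
  }
  if (cfg$n_regions < 1L) stop("n_regions must be at least 1", call. = FALSE)
  if (any(cfg$mortality_levels <= 0) ||
    is.unsorted(cfg$mortality_levels, strictly = TRUE)) {
    stop("mortality_levels must be positive and strictly increasing", call. = FALSE)
  }
  structure(cfg, class = "synthetic_config")
}

#' Generate a synthetic region input table
#'
#' Draws `n_regions` rows uniformly from the configured ranges. The unit
#' cost is derived from the drawn urban fraction through
#' [cost_per_treatment()], and `reported_u5mr` is set to the U5MR implied by
#' the drawn mortality probabilities, so equity ranking is self-consistent
#' for synthetic data. Generation is deterministic under a fixed seed.
#'
#' @param config A [synthetic_config()].
#' @param params [fixed_params()] supplying the unit-cost model.
#' @return A [region_table()].
#' @examples
#' synthetic_regions(synthetic_config(seed = 7, n_regions = 3))
#' @export
synthetic_regions <- function(config = synthetic_config(), params = fixed_params()) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n_regions
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit(
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  )
  set.seed(config$seed)
  draw <- function(range) stats::runif(n, range[1], range[2])
  q_inf <- draw(config$q_infant_range)
  q_chi <- draw(config$q_child_range)
  urban <- draw(config$urban_fraction_range)
  df <- data.frame(
    region = sprintf("SynthRegion%02d", seq_len(n)),
    q_infant = q_inf,
    q_child = q_chi,
    cost_per_treatment = cost_per_treatment(urban, params),
    incidence = draw(config$incidence_range),
    baseline_coverage = draw(config$coverage_range),
    birth_cohort = round(draw(config$birth_cohort_range)),
    reported_u5mr = 1000 * u5mr_from_rates(q_inf, q_chi),
    urban_fraction = urban
  )
  region_table(df)
}

#' Synthetic reference set matching a configuration
#'
#' Convenience wrapper: the [synthetic_base_life_table()] swept through the
#' configuration's `mortality_levels`.
#'
#' @param config A [synthetic_config()].
#' @return A list of [abridged_life_table()] objects.
#' @export
synthetic_reference_for <- function(config = synthetic_config()) {
  synthetic_reference_set(synthetic_base_life_table(), config$mortality_levels)
}
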