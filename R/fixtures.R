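#' Ethiopian 2016 region-level inputs, fixed parameters, and program costs
#'
#' Bundles the region-specific model inputs for Ethiopia's eleven major
#' regions, derived from the 2016 Demographic and Health Survey (DHS):
#' background infant and child mortality, average cost per treatment
#' (urban/rural-residency adjusted), annual pneumonia incidence and 2016
#' baseline treatment coverage. Also returns the fixed model constants, the
#' separate national summary row, and the published rounded total/incremental
#' program cost table (USD, nearest 100,000) for the 90% scale-up, used to
#' validate national cost aggregation.
#'
#' `reported_u5mr` carries the DHS-reported regional under-five mortality
#' rates (per 1000), which drive life-table matching and equity ranking; they
#' are survey period estimates and intentionally *not* recomputed from the
#' region's `q_infant`/`q_child`.
#'
#' `birth_cohort` values are synthetic rough estimates of 2016 live births:
#' regional population projections multiplied by regional total fertility
#' rates, normalized so the national total matches the UN World Population
#' Prospects (2015 revision) birth count for Ethiopia (about 3.27 million a
#' year in 2015-2020). They are weights for national aggregation, not census
#' counts.
#'
#' @return A list with components:
#' * `regions` — a [region_table()] of the 11 regions;
#' * `national` — one-row data frame with the national summary inputs
#'   (kept separate from the regions: it is not a region);
#' * `params` — [fixed_params()] with the published constants;
#' * `costs` — data frame `region`, `total_cost_baseline`,
#'   `total_cost_target`, `incremental_cost` (USD, rounded to the nearest
#'   100,000) plus the published `SUM` row. Note the published `SUM` of
#'   incremental costs (1,321,000,000) carries a rounding artefact: the
#'   rounded rows themselves add to 1,320,200,000.
#' @examples
#' fx <- ethiopia_fixture()
#' nrow(fx$regions)
#' fx$regions[fx$regions$region == "Afar", "cost_per_treatment"]
#' @export
ethiopia_fixture <- function() {
  # Survey-derived inputs. Two cells are run-together in the published input
  # table and are parsed as: Harari incidence 0.044 with 45% baseline
  # coverage, Addis incidence 0.153 with 59% coverage (incidence column
  # immediately followed by the coverage column).
  regions <- data.frame(
    region = c(
      "Afar", "Beni-Shangul", "Somali", "Dire Dawa", "Gambela", "SNNP",
      "Amhara", "Oromia", "Harari", "Tigray", "Addis"
    ),
    q_infant = c(
      76.7, 60.2, 50.5, 16.4, 60.2, 64.9, 57.3, 56.6, 52.9, 57.8, 30.0
    ) / 1000,
    q_child = c(
      11.5, 9.2, 4.3, 1.7, 9.2, 7.0, 4.1, 3.9, 7.8, 5.6, 5.0
    ) / 1000,
    cost_per_treatment = c(
      247.8, 271.3, 271.3, 124.8, 124.8, 288, 277.7, 281.6, 163.9, 255.1, 45
    ),
    incidence = c(
      0.244, 0.102, 0.119, 0.221, 0.198, 0.385, 0.453, 0.419, 0.044, 0.436,
      0.153
    ),
    baseline_coverage = c(
      44, 29, 32, 50, 29, 43, 29, 26.4, 45, 34, 59
    ) / 100,
    birth_cohort = c(
      73000, 34000, 305000, 10700, 11300, 621000, 575000, 1409000, 7500,
      178000, 45000
    ),
    # DHS 2016 ten-year regional U5MR estimates, per 1000 live births
    reported_u5mr = c(125, 98, 94, 93, 88, 88, 85, 79, 72, 59, 39),
    urban_fraction = NA_real_
  )
  national <- data.frame(
    region = "National",
    q_infant = 48.5 / 1000,
    q_child = 5.1 / 1000,
    cost_per_treatment = 262.1,
    incidence = 0.397,
    baseline_coverage = 0.33,
    birth_cohort = sum(regions$birth_cohort),
    reported_u5mr = 67,
    urban_fraction = NA_real_
  )
  costs <- data.frame(
    region = c(
      "Addis", "Tigray", "Harari", "Amhara", "Dire Dawa", "Gambela",
      "Somali", "Beni-Shangul", "Oromia", "SNNP", "Afar", "SUM"
    ),
    total_cost_baseline = c(
      1200000, 32100000, 200000, 138400000, 1100000, 500000, 21000000,
      1800000, 273000000, 219500000, 12000000, 700800000
    ),
    total_cost_target = c(
      1900000, 86000000, 400000, 434100000, 1900000, 1600000, 59000000,
      5600000, 943000000, 463500000, 24700000, 2022000000
    ),
    incremental_cost = c(
      600000, 54000000, 200000, 295700000, 900000, 1000000, 38200000,
      3900000, 669000000, 244000000, 12700000, 1321000000
    )
  )
  list(
    regions = region_table(regions),
    national = national,
    params = fixed_params(),
    costs = costs
  )
}
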