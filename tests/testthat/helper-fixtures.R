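# Shared helpers: small builders and published reference values.

# Flat-mortality abridged table: constant annual hazard q at every age.
flat_life_table <- function(q, label = "flat") {
  abridged_life_table(
    label,
    start_age = c(0, 1, 5), width = c(1, 4, Inf),
    nqx = c(q, 1 - (1 - q)^4, 1)
  )
}

toy_region <- function(...) {
  defaults <- list(
    region = "Toy", q_infant = 0.03, q_child = 0.005,
    cost_per_treatment = 45, incidence = 0.15, baseline_coverage = 0.5,
    birth_cohort = 1000, reported_u5mr = NA_real_, urban_fraction = NA_real_
  )
  utils::modifyList(defaults, list(...))
}

# Published per-region life-expectancy gains under 90% scale-up (years).
published_incremental_le <- c(
  Afar = 0.69, Amhara = 1.89, SNNP = 1.24, `Beni-Shangul` = 0.43,
  Gambela = 0.83, Somali = 0.46, `Dire Dawa` = 0.62, Oromia = 1.93,
  Tigray = 1.80, Harari = 0.13, Addis = 0.40
)

# O(n^2) brute-force weighted Gini used as the independent oracle.
gini_bruteforce <- function(values, weights = rep(1, length(values))) {
  W <- sum(weights)
  mu <- sum(weights * values) / W
  s <- 0
  for (i in seq_along(values)) {
    s <- s + sum(weights[i] * weights * abs(values[i] - values))
  }
  s / (2 * W^2 * mu)
}

run_fixture_pipeline <- function() {
  fx <- ethiopia_fixture()
  suppressWarnings(run_all(fx$regions, ethiopia_reference_set(), fx$params))
}
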