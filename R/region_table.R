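#' Construct a validated region input table
#'
#' A region table holds one row per region with the epidemiological, cost,
#' coverage and cohort-size inputs the cohort model needs. Mortality
#' probabilities are stored per 1 (not per 1000) and coverage as a proportion.
#'
#' @param df A data frame with columns `region`, `q_infant`, `q_child`,
#'   `cost_per_treatment`, `incidence`, `baseline_coverage`, and optionally
#'   `birth_cohort`, `reported_u5mr` (per 1000), `urban_fraction`.
#' @return The data frame with class `region_table`, validated.
#' @details Field semantics:
#' * `q_infant` — probability of death before age one (per 1).
#' * `q_child` — annual probability of death at ages 1-4 (per 1).
#' * `incidence` — pneumonia episodes per child-year.
#' * `baseline_coverage` — proportion of episodes treated in 2016, `[0, 1]`.
#' * `birth_cohort` — live births (weight for national aggregation).
#' * `reported_u5mr` — externally reported under-five mortality per 1000,
#'   used for life-table matching and equity ranking; it is *not* derived
#'   from `q_infant`/`q_child`.
#' @examples
#' region_table(data.frame(
#'   region = "Toy", q_infant = 0.03, q_child = 0.005,
#'   cost_per_treatment = 45, incidence = 0.15, baseline_coverage = 0.5
#' ))
#' @export
region_table <- function(df) {
  validate_region_table(df)
}

region_required_cols <- c(
  "region", "q_infant", "q_child", "cost_per_treatment",
  "incidence", "baseline_coverage"
)
region_optional_cols <- c("birth_cohort", "reported_u5mr", "urban_fraction")

validate_region_table <- function(df) {
  if (!is.data.frame(df)) stop("region table must be a data frame", call. = FALSE)
  if (nrow(df) == 0L) stop("no regions: the region table is empty", call. = FALSE)
  missing_cols <- setdiff(region_required_cols, names(df))
  if (length(missing_cols)) {
    stop("region table is missing column(s): ",
      paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  for (col in region_optional_cols) {
    if (!col %in% names(df)) df[[col]] <- NA_real_
  }
  df$region <- as.character(df$region)
  if (any(!nzchar(df$region)) || anyNA(df$region)) {
    stop("region names must be nonempty", call. = FALSE)
  }
  if (anyDuplicated(df$region)) {
    stop("duplicate region name(s): ",
      paste(unique(df$region[duplicated(df$region)]), collapse = ", "),
      call. = FALSE
    )
  }
  check_range <- function(col, lo, hi, allow_na = FALSE) {
    v <- df[[col]]
    bad <- !is.na(v) & (v < lo | v > hi)
    if (!allow_na && anyNA(v)) bad <- bad | is.na(v)
    if (any(bad)) {
      stop(sprintf(
        "invalid %s for region(s) %s: must lie in [%g, %g]",
        col, paste(df$region[bad], collapse = ", "), lo, hi
      ), call. = FALSE)
    }
  }
  check_range("q_infant", 0, 1)
  check_range("q_child", 0, 1)
  check_range("baseline_coverage", 0, 1)
  check_range("cost_per_treatment", 0, Inf)
  check_range("incidence", 0, Inf)
  check_range("urban_fraction", 0, 1, allow_na = TRUE)
  check_range("reported_u5mr", 0, 1000, allow_na = TRUE)
  bc <- df$birth_cohort
  bad <- !is.na(bc) & bc <= 0
  if (any(bad)) {
    stop("birth_cohort must be positive for region(s): ",
      paste(df$region[bad], collapse = ", "),
      call. = FALSE
    )
  }
  df <- df[, c(region_required_cols, region_optional_cols)]
  rownames(df) <- NULL
  class(df) <- c("region_table", "data.frame")
  df
}

# Default CSV schema: column names and the units they are read in. Mortality
# columns are accepted per 1000 (as mortality tables are usually printed) and
# coverage as percent; the reader converts to per-1 internally.
default_region_schema <- function() {
  list(
    columns = c(
      region = "region",
      q_infant = "q_infant_per1000",
      q_child = "q_child_per1000",
      cost_per_treatment = "cost_per_treatment_usd",
      incidence = "incidence_per_child_year",
      baseline_coverage = "baseline_coverage_pct",
      birth_cohort = "birth_cohort",
      reported_u5mr = "reported_u5mr_per1000",
      urban_fraction = "urban_fraction"
    ),
    mortality_per_1000 = TRUE,
    coverage_percent = TRUE
  )
}

#' Read a region input table from CSV
#'
#' @param path Path to a CSV file with a header row.
#' @param schema Column map and unit flags as produced by the default schema:
#'   a list with `columns` (named character vector mapping internal field ->
#'   CSV column), `mortality_per_1000` (divide mortality columns by 1000) and
#'   `coverage_percent` (divide coverage by 100). Pass overrides to read files
#'   that already store per-1 probabilities or proportions.
#' @return A [region_table()].
#' @examples
#' path <- system.file("extdata", "ethiopia_regions_2016.csv", package = "ccmdcea")
#' head(read_region_table(path))
#' @export
read_region_table <- function(path, schema = default_region_schema()) {
  if (!file.exists(path)) stop("region file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(raw) == 0L) stop("no regions: the region table is empty", call. = FALSE)
  cols <- schema$columns
  required <- cols[region_required_cols]
  missing_cols <- required[!required %in% names(raw)]
  if (length(missing_cols)) {
    stop("region CSV is missing column(s): ",
      paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  df <- data.frame(region = as.character(raw[[cols[["region"]]]]))
  grab <- function(field) {
    col <- cols[[field]]
    if (!is.null(col) && col %in% names(raw)) as.numeric(raw[[col]]) else NA_real_
  }
  df$q_infant <- grab("q_infant")
  df$q_child <- grab("q_child")
  df$cost_per_treatment <- grab("cost_per_treatment")
  df$incidence <- grab("incidence")
  df$baseline_coverage <- grab("baseline_coverage")
  df$birth_cohort <- grab("birth_cohort")
  df$reported_u5mr <- grab("reported_u5mr")
  df$urban_fraction <- grab("urban_fraction")
  if (isTRUE(schema$mortality_per_1000)) {
    df$q_infant <- df$q_infant / 1000
    df$q_child <- df$q_child / 1000
  }
  if (isTRUE(schema$coverage_percent)) {
    df$baseline_coverage <- df$baseline_coverage / 100
  }
  validate_region_table(df)
}

#' Write a result or input table to CSV or JSON
#'
#' Writes with full precision so that a read-back reproduces the values
#' exactly (CSV uses up to 17 significant digits; JSON is unrounded).
#'
#' @param results A nonempty data frame.
#' @param path Output file path.
#' @param format `"csv"` or `"json"`; inferred from the extension by default.
#' @return Invisibly, `path`.
#' @export
write_results <- function(results, path, format = c("auto", "csv", "json")) {
  if (!is.data.frame(results) || nrow(results) == 0L) {
    stop("results must be a nonempty data frame", call. = FALSE)
  }
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (format == "json") {
    # I(17) = significant digits; 17 guarantees exact double round-trips
    jsonlite::write_json(as.data.frame(results), path,
      dataframe = "rows", auto_unbox = TRUE, digits = I(17), na = "null"
    )
  } else {
    out <- as.data.frame(results)
    for (col in names(out)) {
      if (is.numeric(out[[col]])) {
        out[[col]] <- vapply(out[[col]], function(v) {
          if (is.na(v)) NA_character_ else format(v, digits = 17, scientific = FALSE)
        }, character(1))
      }
    }
    ok <- tryCatch(
      {
        utils::write.csv(out, path, row.names = FALSE, quote = TRUE, na = "")
        TRUE
      },
      error = function(e) e
    )
    if (!isTRUE(ok)) stop("cannot write to ", path, ": ", conditionMessage(ok), call. = FALSE)
  }
  invisible(path)
}

#' Read back a table written by [write_results()]
#'
#' @param path File path (`.csv` or `.json`).
#' @return A data frame.
#' @export
read_results <- function(path) {
  if (!file.exists(path)) stop("results file not found: ", path, call. = FALSE)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  } else {
    utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  }
}

#' @export
print.region_table <- function(x, ...) {
  cat(sprintf("Region input table: %d region(s)\n", nrow(x)))
  NextMethod()
}
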