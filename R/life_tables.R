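#' Abridged life tables
#'
#' An abridged life table gives the probability of dying within each age
#' interval (0, 1-4, 5-9, ...); the final interval is open-ended with
#' probability 1. The cohort engine matches each region to the reference
#' table whose under-five mortality is closest to the region's, then expands
#' it to single-year probabilities.
#'
#' @param label Identifier, e.g. a period such as `"2010-2015"`.
#' @param start_age Integer vector of interval start ages, beginning at 0 and
#'   strictly increasing with no gaps.
#' @param width Interval widths in years; the last interval's width is
#'   ignored (open-ended).
#' @param nqx Probability of death within each interval, per 1; the terminal
#'   value must be 1.
#' @return An object of class `abridged_life_table`.
#' @examples
#' lt <- abridged_life_table(
#'   "toy",
#'   start_age = c(0, 1, 5), width = c(1, 4, Inf), nqx = c(0.05, 0.02, 1)
#' )
#' table_u5mr(lt)
#' @export
abridged_life_table <- function(label, start_age, width, nqx) {
  stopifnot(length(start_age) == length(width), length(width) == length(nqx))
  n <- length(start_age)
  if (n < 1L) stop("life table must have at least one interval", call. = FALSE)
  if (start_age[1] != 0) stop("life table intervals must start at age 0", call. = FALSE)
  if (n > 1L) {
    implied <- start_age[-n] + width[-n]
    if (any(implied != start_age[-1])) {
      stop("life table intervals must be contiguous and strictly increasing",
        call. = FALSE
      )
    }
  }
  if (any(is.na(nqx)) || any(nqx < 0 | nqx > 1)) {
    stop("all nqx must lie in [0, 1]", call. = FALSE)
  }
  if (nqx[n] != 1) {
    stop("terminal (open-ended) interval must have nqx = 1", call. = FALSE)
  }
  structure(
    list(
      label = as.character(label),
      start_age = as.numeric(start_age),
      width = as.numeric(width),
      nqx = as.numeric(nqx)
    ),
    class = "abridged_life_table"
  )
}

#' @export
print.abridged_life_table <- function(x, ...) {
  cat(sprintf(
    "Abridged life table '%s': %d intervals, U5MR %.4f\n",
    x$label, length(x$nqx), table_u5mr(x)
  ))
  invisible(x)
}

annualize_q <- function(nqx, width) 1 - (1 - nqx)^(1 / width)

#' Under-five mortality of an abridged life table
#'
#' Combines interval death probabilities over ages 0-5:
#' `1 - prod(1 - nqx)` over intervals inside `[0, 5)`. An interval straddling
#' age 5 contributes its constant-hazard annualized probability for the
#' covered years only.
#'
#' @param table An [abridged_life_table()].
#' @return Probability of death before age five (per 1).
#' @export
table_u5mr <- function(table) {
  stopifnot(inherits(table, "abridged_life_table"))
  n <- length(table$nqx)
  end_age <- c(table$start_age[-1], Inf)
  if (end_age[n] < 5 || (n == 1L && table$start_age[1] >= 5)) {
    stop("life table does not cover ages 0-5", call. = FALSE)
  }
  surv <- 1
  for (i in seq_len(n)) {
    a0 <- table$start_age[i]
    a1 <- end_age[i]
    if (a0 >= 5) break
    if (a1 <= 5) {
      surv <- surv * (1 - table$nqx[i])
    } else {
      if (!is.finite(a1)) {
        stop("life table does not cover ages 0-5 with closed intervals",
          call. = FALSE
        )
      }
      qa <- annualize_q(table$nqx[i], a1 - a0)
      surv <- surv * (1 - qa)^(5 - a0)
    }
  }
  1 - surv
}

#' Match a region's U5MR to the closest reference life table
#'
#' Selects, from a reference set of abridged life tables, the one whose
#' under-five mortality is closest to the query. Ties are broken towards the
#' lower-U5MR table, so the result is deterministic and independent of the
#' order of the reference set.
#'
#' @param u5mr Query under-five mortality (per 1).
#' @param reference_set A nonempty list of [abridged_life_table()] objects.
#' @return The matched `abridged_life_table`.
#' @export
match_life_table <- function(u5mr, reference_set) {
  if (!length(reference_set)) stop("reference set is empty", call. = FALSE)
  stopifnot(is.numeric(u5mr), length(u5mr) == 1L, u5mr >= 0, u5mr <= 1)
  u <- vapply(reference_set, table_u5mr, numeric(1))
  d <- abs(u - u5mr)
  best <- which(d == min(d))
  if (length(best) > 1L) best <- best[which.min(u[best])]
  reference_set[[best]]
}

#' Expand an abridged life table to single-year death probabilities
#'
#' Each closed interval of width `n` is split under a constant-hazard
#' assumption: the annual probability is `1 - (1 - nqx)^(1/n)`, identical for
#' every year of the interval (so the interval probability is exactly
#' recovered). Ages at or beyond the start of the terminal open interval
#' carry forward the last closed interval's annual probability, and the final
#' modelled age is forced to certain death so the cohort closes.
#'
#' @param table An [abridged_life_table()].
#' @param max_age Number of single-year ages modelled (default 120; ages
#'   `0 .. max_age - 1`).
#' @return An `annual_mortality_schedule`: numeric vector of length
#'   `max_age`, element `a + 1` holding the death probability at age `a`.
#' @export
expand_to_annual <- function(table, max_age = 120L) {
  stopifnot(inherits(table, "abridged_life_table"), max_age >= 1L)
  n <- length(table$nqx)
  q <- numeric(max_age)
  last_annual <- 0
  end_age <- c(table$start_age[-1], Inf)
  for (i in seq_len(n)) {
    a0 <- table$start_age[i]
    a1 <- end_age[i]
    if (a0 >= max_age) break
    if (is.finite(a1)) {
      qa <- annualize_q(table$nqx[i], a1 - a0)
      last_annual <- qa
      ages <- seq.int(a0, min(a1 - 1, max_age - 1))
      q[ages + 1L] <- qa
    } else {
      # terminal open interval: carry the last closed interval's annual q
      ages <- seq.int(a0, max_age - 1)
      q[ages + 1L] <- last_annual
    }
  }
  q[max_age] <- 1
  annual_mortality_schedule(q)
}

#' Single-year mortality schedule
#'
#' @param q Numeric vector of annual death probabilities, element `a + 1`
#'   for age `a`; all values in `[0, 1]`.
#' @return The vector with class `annual_mortality_schedule`.
#' @export
annual_mortality_schedule <- function(q) {
  if (!is.numeric(q) || anyNA(q) || any(q < 0 | q > 1)) {
    stop("mortality schedule must be probabilities in [0, 1]", call. = FALSE)
  }
  structure(as.numeric(q), class = "annual_mortality_schedule")
}

#' Overlay a region's under-five mortality on a schedule
#'
#' Replaces age 0 with the region's infant mortality and ages 1-4 with its
#' annual child mortality; ages five and above keep the matched life table's
#' (adult-mortality proxy) values.
#'
#' @param schedule An [annual_mortality_schedule()].
#' @param region A single-row [region_table()] (or a list with `q_infant` and
#'   `q_child`).
#' @return The modified schedule.
#' @export
apply_region_under5 <- function(schedule, region) {
  stopifnot(inherits(schedule, "annual_mortality_schedule"), length(schedule) >= 5L)
  q <- unclass(schedule)
  q[1L] <- region$q_infant
  q[2:5] <- region$q_child
  annual_mortality_schedule(q)
}

#' Survival curve implied by a mortality schedule
#'
#' @param schedule An [annual_mortality_schedule()] of length `A`.
#' @return Numeric vector `S` of length `A + 1`: `S[a + 1]` is the
#'   probability of being alive at exact age `a`, with `S(0) = 1` and
#'   `S(a + 1) = S(a) (1 - q(a))`.
#' @export
survival_from_schedule <- function(schedule) {
  stopifnot(inherits(schedule, "annual_mortality_schedule"))
  c(1, cumprod(1 - unclass(schedule)))
}

#' Read and write abridged life tables as CSV
#'
#' One row per interval with columns `label,start_age,width,nqx`; the
#' terminal row's `width` may be empty (open-ended). A directory of such
#' files forms a reference set.
#'
#' @param path CSV file path.
#' @return `read_life_table()` returns an [abridged_life_table()];
#'   `read_life_table_dir()` a list of them, ordered by file name.
#' @export
read_life_table <- function(path) {
  if (!file.exists(path)) stop("life table file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("label", "start_age", "width", "nqx")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("life table CSV is missing column(s): ",
      paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  w <- as.numeric(df$width)
  w[is.na(w)] <- Inf
  abridged_life_table(df$label[1], as.numeric(df$start_age), w, as.numeric(df$nqx))
}

#' @param dir Directory containing life-table CSV files (`*.csv`).
#' @rdname read_life_table
#' @export
read_life_table_dir <- function(dir) {
  if (!dir.exists(dir)) stop("reference set not found: ", dir, call. = FALSE)
  files <- sort(list.files(dir, pattern = "\\.csv$", full.names = TRUE))
  if (!length(files)) stop("reference set not found: no CSV files in ", dir, call. = FALSE)
  lapply(files, read_life_table)
}

#' @param table An [abridged_life_table()].
#' @rdname read_life_table
#' @export
write_life_table <- function(table, path) {
  stopifnot(inherits(table, "abridged_life_table"))
  df <- data.frame(
    label = table$label,
    start_age = table$start_age,
    width = ifelse(is.finite(table$width), table$width, NA),
    nqx = table$nqx
  )
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}
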