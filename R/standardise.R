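#' Expected counts by indirect age-gender standardisation
#'
#' Computes stratum-specific baseline risks from the whole lattice
#' (`risk_j = sum_i Count_ij / sum_i Population_ij` over the 40 gender x
#' age-class strata) and applies them to each area's population to obtain
#' expected counts `e_i = sum_j Population_ij * risk_j`. This is internal
#' indirect standardisation, so expected and observed totals are conserved
#' within each standardisation stratum set.
#'
#' @param population tibble `area_id`, `year`, `gender`, `age_class`, `count`.
#' @param deaths_strata tibble `area_id`, `year`, `gender`, `age_class`,
#'   `deaths` (stratum-level death counts).
#' @param year_mode `"per-year"` (risks re-estimated each year, the
#'   default) or `"pooled"` (one risk set over all years).
#' @return tibble `area_id`, `year`, `y` (observed), `e` (expected), with
#'   the stratum risk table attached as attribute `"risks"` (also
#'   retrievable with [std_risks()]). All risks lie in \[0, 1\].
#' @export
compute_expected_counts <- function(population, deaths_strata,
                                    year_mode = c("per-year", "pooled")) {
  year_mode <- match.arg(year_mode)
  key <- c("area_id", "year", "gender", "age_class")
  joined <- inner_join(population, deaths_strata, by = key)
  assert_that_(nrow(joined) == nrow(deaths_strata),
               "population and stratum deaths tables do not align")

  grp <- if (year_mode == "per-year") c("year", "gender", "age_class") else c("gender", "age_class")
  risks <- joined |>
    group_by(across(dplyr::all_of(grp))) |>
    summarise(deaths = sum(.data$deaths), pop = sum(.data$count), .groups = "drop")
  bad <- risks$pop == 0 & risks$deaths > 0
  assert_that_(!any(bad), "stratum with deaths but zero population")
  risks <- risks |>
    mutate(risk = ifelse(.data$pop > 0, .data$deaths / .data$pop, 0)) |>
    select(dplyr::all_of(grp), "risk")
  assert_that_(all(risks$risk >= 0 & risks$risk <= 1), "risks must lie in [0, 1]")

  by_key <- if (year_mode == "per-year") c("year", "gender", "age_class") else c("gender", "age_class")
  out <- joined |>
    inner_join(risks, by = by_key) |>
    group_by(.data$area_id, .data$year) |>
    summarise(y = sum(.data$deaths), e = sum(.data$count * .data$risk),
              .groups = "drop") |>
    arrange(.data$area_id, .data$year)
  attr(out, "risks") <- risks
  attr(out, "year_mode") <- year_mode
  out
}

#' @rdname compute_expected_counts
#' @param std a table returned by [compute_expected_counts()].
#' @export
std_risks <- function(std) attr(std, "risks")

#' Standardised mortality ratio with exact Poisson intervals
#'
#' The SMR maximum-likelihood estimate `y / e` under `y ~ Poisson(e *
#' theta)`, with 95% limits by the exact Poisson (Garwood) method based on
#' chi-square quantiles: `low = qchisq(0.025, 2y) / (2e)` (0 when `y = 0`)
#' and `high = qchisq(0.975, 2y + 2) / (2e)`.
#'
#' @param y observed counts (nonnegative integers, vectorised).
#' @param e expected counts (positive, vectorised).
#' @param conf confidence level (default 0.95).
#' @return tibble `y`, `e`, `smr`, `ci_low`, `ci_high`.
#' @export
#' @examples
#' compute_smr(c(0, 10), c(2, 5))
compute_smr <- function(y, e, conf = 0.95) {
  assert_that_(is_count(y), "`y` must be nonnegative integer counts")
  assert_that_(all(e > 0), "`e` must be positive")
  k <- pmax(length(y), length(e))
  y <- rep_len(y, k); e <- rep_len(e, k)
  a <- (1 - conf) / 2
  low <- ifelse(y == 0, 0, qchisq(a, 2 * y) / (2 * e))
  high <- qchisq(1 - a, 2 * y + 2) / (2 * e)
  tibble(y = y, e = e, smr = y / e, ci_low = low, ci_high = high)
}

#' Area-year SMR table
#'
#' Convenience wrapper attaching SMRs and exact intervals to a
#' standardisation table, with crude mortality rates per 1000 when a
#' population table is supplied.
#'
#' @param std table from [compute_expected_counts()].
#' @param population optional population table for per-1000 rates.
#' @return tibble `area_id`, `year`, `y`, `e`, `smr`, `ci_low`, `ci_high`
#'   (+ `rate_per_1000`).
#' @export
smr_table <- function(std, population = NULL) {
  ci <- compute_smr(std$y, std$e)
  out <- dplyr::bind_cols(std[, c("area_id", "year")],
                          ci[, c("y", "e", "smr", "ci_low", "ci_high")])
  if (!is.null(population)) {
    pop <- population |>
      group_by(.data$area_id, .data$year) |>
      summarise(pop = sum(.data$count), .groups = "drop")
    out <- out |>
      inner_join(pop, by = c("area_id", "year")) |>
      mutate(rate_per_1000 = 1000 * .data$y / .data$pop) |>
      select(-"pop")
  }
  out
}

#' Crude mortality rates per 1000 against a fixed reference population
#'
#' @param deaths tibble `year`, `gender` (`"M"`/`"F"`), `deaths`.
#' @param ref_population tibble `gender`, `count`: the fixed reference
#'   population the rates are computed against.
#' @return tibble with one row per year x (`M`, `F`, `overall`): `deaths`,
#'   `population`, `rate_raw` (full precision) and `rate` (rounded to 2
#'   decimals for display).
#' @export
#' @examples
#' compute_crude_rates(pavia_deaths(), pavia_reference_population())
compute_crude_rates <- function(deaths, ref_population) {
  assert_that_(all(ref_population$count > 0), "reference populations must be positive")
  by_gender <- deaths |>
    inner_join(ref_population, by = "gender") |>
    mutate(group = .data$gender, population = .data$count) |>
    select("year", "group", "deaths", "population")
  overall <- deaths |>
    group_by(.data$year) |>
    summarise(deaths = sum(.data$deaths), .groups = "drop") |>
    mutate(group = "overall", population = sum(ref_population$count))
  bind_rows(by_gender, overall) |>
    mutate(rate_raw = 1000 * .data$deaths / .data$population,
           rate = round(.data$rate_raw, 2)) |>
    arrange(.data$year, .data$group)
}

#' Province-scale cardiovascular mortality reference tables
#'
#' Yearly cardiovascular death counts by gender (2010-2015) and the fixed
#' 2012 reference population of the emulated province (Province of Pavia:
#' 258,596 males and 277,070 females, 535,666 residents in total), as
#' published in public summaries. Used for crude-rate arithmetic and the
#' descriptive beta-binomial gender model.
#'
#' @return tibbles: `pavia_deaths()` with `year`, `gender`, `deaths`;
#'   `pavia_reference_population()` with `gender`, `count`.
#' @export
pavia_deaths <- function() {
  readr::read_csv(system.file("extdata", "pavia_cvd_deaths.csv",
                              package = "arealrisk"),
                  show_col_types = FALSE, progress = FALSE)
}

#' @rdname pavia_deaths
#' @export
pavia_reference_population <- function() {
  readr::read_csv(system.file("extdata", "pavia_reference_population_2012.csv",
                              package = "arealrisk"),
                  show_col_types = FALSE, progress = FALSE)
}
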