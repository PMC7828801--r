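#' Build the design matrix for the disease-mapping models
#'
#' Covariate coding used throughout the model grid: PM2.5 centred at its
#' grand mean over all area-years and scaled by 15 µg/m³; a rural indicator
#' with urban and peri-urban merged into the reference; in trend models the
#' year scaled with respect to the first study year; and the log expected
#' count as offset.
#'
#' @param bundle a `study_bundle`.
#' @param expected standardisation table from [compute_expected_counts()]
#'   (columns `area_id`, `year`, `y`, `e`); computed from the bundle's
#'   stratum deaths when `NULL`.
#' @param trend include the linear year term?
#' @return tibble of class `dm_design`, rows ordered by (`area_id`,
#'   `year`): `area_id`, `year`, `y`, `e`, `offset` (`log e`), `pm25_c`,
#'   `rural` (+ `year_c`), with the grand mean stored as attribute
#'   `pm_grand_mean`.
#' @export
build_design <- function(bundle, expected = NULL, trend = FALSE) {
  if (is.null(expected)) {
    expected <- compute_expected_counts(bundle$population, bundle$deaths_strata)
  }
  assert_that_(all(expected$e > 0), "offset undefined: expected counts must be positive")
  meta <- bundle$lattice$areas |>
    select("area_id", "degurba") |>
    mutate(rural = as.integer(.data$degurba == "rural"))
  pm_grand <- mean(bundle$exposure$pm25)
  year0 <- min(bundle$years)
  out <- expected |>
    inner_join(bundle$exposure, by = c("area_id", "year")) |>
    inner_join(meta, by = "area_id") |>
    mutate(offset = log(.data$e),
           pm25_c = (.data$pm25 - pm_grand) / 15) |>
    select("area_id", "year", "y", "e", "offset", "pm25_c", "rural") |>
    arrange(.data$area_id, .data$year)
  if (trend) out$year_c <- out$year - year0
  attr(out, "pm_grand_mean") <- pm_grand
  attr(out, "trend") <- trend
  class(out) <- c("dm_design", class(out))
  out
}

design_terms <- function(trend) {
  c("intercept", "pm25_c", "rural", if (trend) "year_c")
}

design_matrix <- function(design) {
  trend <- isTRUE(attr(design, "trend"))
  x <- cbind(intercept = 1, pm25_c = design$pm25_c, rural = design$rural)
  if (trend) x <- cbind(x, year_c = design$year_c)
  x
}

#' The eight-model grid of disease-mapping specifications
#'
#' The 4 x 2 grid crossing the random component (M1 none, M2 IID, M3
#' intrinsic CAR, M4 BYM convolution) with the fixed component (A: no
#' temporal trend, B: linear year trend). Phase-1 defaults put a
#' Normal(0, sd 3) prior on every coefficient (log-scale) and a
#' non-informative Inverse-Gamma(0.01, 0.01) hyperprior on each
#' random-effect variance.
#'
#' @param beta_sd prior SD of the coefficient priors.
#' @return tibble with `grid_id`, `random`, `trend`, `phase`, and a
#'   list-column `priors` of [model_priors()] objects.
#' @export
make_model_grid <- function(beta_sd = 3) {
  grid <- tidyr::crossing(
    m = 1:4,
    letter = c("A", "B")
  ) |>
    mutate(
      grid_id = paste0("M", .data$m, .data$letter),
      random = c("none", "iid", "icar", "bym")[.data$m],
      trend = .data$letter == "B",
      phase = .data$m
    )
  grid$priors <- purrr::map2(grid$random, grid$trend, function(r, tr) {
    model_priors(terms = design_terms(tr), random = r, beta_sd = beta_sd)
  })
  grid[, c("grid_id", "random", "trend", "phase", "priors")]
}

#' Prior specification for one model-grid cell
#'
#' @param terms coefficient names.
#' @param random random component (`none`/`iid`/`icar`/`bym`).
#' @param beta_sd default coefficient prior SD.
#' @param beta_mean default coefficient prior mean.
#' @return list with `beta` (tibble `term`, `mean`, `sd`) and `var_hyper`
#'   (per-component list `family`, `shape`, `rate` or half-normal `sd`).
#' @export
model_priors <- function(terms, random = "none", beta_sd = 3, beta_mean = 0) {
  comps <- switch(random,
                  none = character(0),
                  iid = "iid", icar = "icar", bym = c("iid", "icar"))
  vh <- lapply(comps, function(cmp) list(family = "invgamma", shape = 0.01, rate = 0.01))
  names(vh) <- comps
  list(beta = tibble(term = terms,
                     mean = rep_len(beta_mean, length(terms)),
                     sd = rep_len(beta_sd, length(terms))),
       var_hyper = vh)
}
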