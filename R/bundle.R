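#' @keywords internal
# Spectral basis of the intrinsic CAR (graph Laplacian) on a connected
# lattice: eigenvectors/values of Q = D - W with the null (constant) mode
# removed. An ICAR effect with precision tau is v = V u, u_k ~ N(0, 1/(tau
# lambda_k)); the sum-to-zero constraint holds exactly by orthogonality.
icar_spectral <- function(lattice) {
  assert_that_(lattice_is_connected(lattice),
               "ICAR structure requires a connected lattice")
  w <- adjacency_matrix(lattice)
  q <- diag(rowSums(w)) - w
  eg <- eigen(q, symmetric = TRUE)
  keep <- seq_len(lattice$n_areas - 1L)   # drop the single zero eigenvalue
  list(vectors = eg$vectors[, keep, drop = FALSE],
       values = eg$values[keep])
}

# one draw of an ICAR field with marginal sd scaled to `sd_target`
icar_draw <- function(lattice, sd_target, seed) {
  if (lattice$n_areas == 1) return(0)
  sp <- icar_spectral(lattice)
  u <- with_seed_(seed, rnorm(length(sp$values), 0, 1 / sqrt(sp$values)))
  v <- as.numeric(sp$vectors %*% u)
  v * sd_target / max(sd(v), 1e-12)
}

#' Simulate mortality outcomes from the Poisson log-linear model
#'
#' Given a lattice, a population table, and an exposure field, draws death
#' counts from the generative model `y_it ~ Poisson(e_it * exp(eta_it))`
#' with `eta_it = b0 + b_pm * pm_c + b_rural * rural + b_year * (year -
#' year0) + u_i + v_i`, where `pm_c` is the exposure centred at its grand
#' mean and scaled by 15 µg/m³, `rural` is the indicator of a rural unit
#' (urban and peri-urban merged), `u` is an optional exchangeable (IID)
#' area effect, and `v` an optional intrinsic CAR effect (together the BYM
#' convolution). Expected counts `e_it` come from indirect standardisation
#' of the baseline risk profile. Deaths are drawn at the stratum level
#' (area x gender x age class) so that indirect standardisation can be
#' carried out downstream; area totals are their sums.
#'
#' @param lattice an `area_lattice`.
#' @param population tibble from [generate_population()].
#' @param exposure tibble from [generate_exposure_field()].
#' @param beta0,beta_pm,beta_rural,beta_year log-scale coefficients of the
#'   generative model (defaults 0).
#' @param re_kind random-effect structure: `"none"`, `"iid"`, `"icar"`, or
#'   `"bym"`.
#' @param re_sd named vector `c(iid =, icar =)` of random-effect SDs.
#' @param risk_profile optional tibble from [baseline_risk_profile()];
#'   computed with defaults when `NULL`.
#' @param seed integer seed.
#' @return a `study_bundle`: list with `lattice`, `population`, `exposure`,
#'   `deaths` (`area_id`, `year`, `deaths`), `deaths_strata`, `years`, and a
#'   `truth` block (coefficients, random effects, per-area-year true RR).
#' @export
generate_outcomes <- function(lattice, population, exposure,
                              beta0 = 0, beta_pm = 0, beta_rural = 0,
                              beta_year = 0,
                              re_kind = c("none", "iid", "icar", "bym"),
                              re_sd = c(iid = 0.1, icar = 0.1),
                              risk_profile = NULL, seed = 1L) {
  re_kind <- match.arg(re_kind)
  assert_that_(all(population$count >= 0), "population counts must be nonnegative")
  tot <- population |>
    group_by(.data$area_id, .data$year) |>
    summarise(pop = sum(.data$count), .groups = "drop")
  assert_that_(all(tot$pop > 0), "every area-year must have positive population")

  if (is.null(risk_profile)) risk_profile <- baseline_risk_profile(population)
  seeds <- derive_seeds(seed, 3L)
  years <- sort(unique(population$year))
  year0 <- min(years)

  n <- lattice$n_areas
  u <- if (re_kind %in% c("iid", "bym")) {
    with_seed_(seeds[1], rnorm(n, 0, re_sd[["iid"]]))
  } else rep(0, n)
  v <- if (re_kind %in% c("icar", "bym")) {
    icar_draw(lattice, re_sd[["icar"]], seeds[2])
  } else rep(0, n)

  pm_grand <- mean(exposure$pm25)
  meta <- lattice$areas |> select("area_id", "degurba") |>
    mutate(rural = as.integer(.data$degurba == "rural"))

  strata <- population |>
    inner_join(risk_profile, by = c("gender", "age_class")) |>
    inner_join(exposure, by = c("area_id", "year")) |>
    inner_join(meta, by = "area_id") |>
    mutate(
      eta = beta0 + beta_pm * (.data$pm25 - pm_grand) / 15 +
        beta_rural * .data$rural + beta_year * (.data$year - year0) +
        u[.data$area_id + 1L] + v[.data$area_id + 1L],
      mu = .data$count * .data$risk * exp(.data$eta)
    )
  strata$deaths <- with_seed_(seeds[3], rpois(nrow(strata), strata$mu))
  over <- strata$deaths > strata$count       # cannot exceed stratum population
  strata$deaths[over] <- strata$count[over]

  deaths_strata <- strata |>
    select("area_id", "year", "gender", "age_class", "deaths") |>
    arrange(.data$area_id, .data$year, .data$gender, .data$age_class)
  deaths <- deaths_strata |>
    group_by(.data$area_id, .data$year) |>
    summarise(deaths = sum(.data$deaths), .groups = "drop")

  rr <- strata |>
    distinct(.data$area_id, .data$year, .data$eta) |>
    mutate(true_rr = exp(.data$eta)) |> select(-"eta") |>
    arrange(.data$area_id, .data$year)

  truth <- list(beta0 = beta0, beta_pm = beta_pm, beta_rural = beta_rural,
                beta_year = beta_year, re_kind = re_kind,
                re_sd = as.list(re_sd), u = u, v = v, true_rr = rr,
                pm_grand_mean = pm_grand, seed = as.integer(seed))

  new_study_bundle(lattice, population, exposure, deaths, deaths_strata,
                   years, truth, risk_profile)
}

new_study_bundle <- function(lattice, population, exposure, deaths,
                             deaths_strata, years, truth, risk_profile = NULL) {
  b <- structure(
    list(lattice = lattice, population = population, exposure = exposure,
         deaths = deaths, deaths_strata = deaths_strata,
         years = as.integer(years), truth = truth,
         risk_profile = risk_profile),
    class = "study_bundle"
  )
  validate_bundle(b)
  b
}

validate_bundle <- function(b) {
  ids <- sort(b$lattice$areas$area_id)
  for (nm in c("population", "exposure", "deaths")) {
    tab_ids <- sort(unique(b[[nm]]$area_id))
    missing <- setdiff(ids, tab_ids)
    extra <- setdiff(tab_ids, ids)
    assert_that_(length(missing) == 0,
                 sprintf("table `%s` is missing area_id(s): %s", nm,
                         paste(missing, collapse = ", ")))
    assert_that_(length(extra) == 0,
                 sprintf("table `%s` has unknown area_id(s): %s", nm,
                         paste(extra, collapse = ", ")))
    yrs <- sort(unique(b[[nm]]$year))
    assert_that_(identical(as.integer(yrs), b$years),
                 sprintf("table `%s` years differ from the bundle years", nm))
  }
  assert_that_(all(b$deaths$deaths >= 0), "negative death counts")
  assert_that_(all(b$population$count >= 0), "negative population counts")
  tot <- b$population |>
    group_by(.data$area_id, .data$year) |>
    summarise(pop = sum(.data$count), .groups = "drop") |>
    inner_join(b$deaths, by = c("area_id", "year"))
  assert_that_(all(tot$pop > 0), "every area-year must have positive population")
  assert_that_(all(tot$deaths <= tot$pop), "deaths exceed population in some area-year")
  invisible(b)
}

#' @export
print.study_bundle <- function(x, ...) {
  cat(sprintf("<study_bundle> %d areas x %d years (%d-%d), %s deaths total\n",
              x$lattice$n_areas, length(x$years), min(x$years), max(x$years),
              format(sum(x$deaths$deaths), big.mark = ",")))
  if (!is.null(x$truth)) cat("  synthetic truth block present\n")
  invisible(x)
}

#' Simulate a complete study bundle
#'
#' One-call wrapper chaining [generate_lattice()], [generate_population()],
#' [generate_exposure_field()] and [generate_outcomes()], with all child
#' seeds derived from one `seed`. Defaults emulate the structure of a
#' province-scale mortality study: 188 areas in three contiguous subareas
#' of 53/58/77 units, ~535,666 residents with a 48.28% male share, a
#' strongly autocorrelated PM2.5 field, and six study years.
#'
#' @param n_areas,subarea_sizes,years,total,male_share see the stage
#'   generators.
#' @param beta0,beta_pm,beta_rural,beta_year,re_kind,re_sd generative model
#'   settings, see [generate_outcomes()].
#' @param spatial_range exposure-field smoothness, see
#'   [generate_exposure_field()].
#' @param mean_by_year,sd_by_year exposure calibration; defaults are the
#'   emulated province's annual summaries, recycled/truncated to `years`.
#' @param seed master seed.
#' @return a `study_bundle`.
#' @export
#' @examples
#' b <- simulate_bundle(n_areas = 20, subarea_sizes = c(6, 6, 8),
#'                      years = 2010:2011, total = 50000, seed = 7)
#' b$deaths
simulate_bundle <- function(n_areas = 188L, subarea_sizes = c(53L, 58L, 77L),
                            years = 2010:2015, total = 535666L,
                            male_share = 0.4828,
                            beta0 = 0, beta_pm = 0, beta_rural = 0,
                            beta_year = 0, re_kind = "none",
                            re_sd = c(iid = 0.1, icar = 0.1),
                            spatial_range = 6,
                            mean_by_year = NULL, sd_by_year = NULL,
                            seed = 1L) {
  seeds <- derive_seeds(seed, 4L)
  k <- length(years)
  full_mean <- c(21.28, 22.48, 23.58, 19.40, 17.52, 21.38)
  full_sd <- c(5.37, 6.11, 6.49, 5.77, 5.08, 6.33)
  if (is.null(mean_by_year)) mean_by_year <- rep_len(full_mean, k)
  if (is.null(sd_by_year)) sd_by_year <- rep_len(full_sd, k)

  lat <- generate_lattice(n_areas, subarea_sizes, seed = seeds[1])
  pop <- generate_population(lat, years = years, total = total,
                             male_share = male_share, seed = seeds[2])
  exp_tab <- generate_exposure_field(lat, years = years,
                                     mean_by_year = mean_by_year,
                                     sd_by_year = sd_by_year,
                                     spatial_range = spatial_range,
                                     seed = seeds[3])
  generate_outcomes(lat, pop, exp_tab, beta0 = beta0, beta_pm = beta_pm,
                    beta_rural = beta_rural, beta_year = beta_year,
                    re_kind = re_kind, re_sd = re_sd, seed = seeds[4])
}
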