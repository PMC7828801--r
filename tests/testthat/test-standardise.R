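std_fixture <- function(pops, deaths, ages = 1L, genders = "M") {
  # build aligned single-year population / stratum-death tables
  n <- if (is.matrix(pops)) nrow(pops) else length(pops)
  tidyr::crossing(area_id = 0:(n - 1), year = 2010L, gender = genders,
                  age_class = ages) |>
    dplyr::arrange(area_id) |>
    dplyr::mutate(count = pops_expand(pops), deaths = pops_expand(deaths))
}
pops_expand <- function(x) if (is.matrix(x)) as.integer(t(x)) else as.integer(x)

test_that("expected counts follow the stratum-risk arithmetic", {
  tab <- std_fixture(pops = c(1000, 1000), deaths = c(10, 0))
  std <- compute_expected_counts(tab[, -6], tab[, -5])
  expect_equal(std_risks(std)$risk, 0.005)
  expect_equal(std$e, c(5, 5))

  # single area: internal standardisation is degenerate, e = y
  one <- std_fixture(pops = 5000, deaths = 37)
  std1 <- compute_expected_counts(one[, -6], one[, -5])
  expect_equal(std1$e, 37)
  expect_equal(compute_smr(std1$y, std1$e)$smr, 1)

  # two age strata with opposite population structure: both SMR = 1
  tab2 <- std_fixture(pops = rbind(c(900, 100), c(100, 900)),
                      deaths = rbind(c(0, 10), c(0, 90)), ages = 1:2)
  std2 <- compute_expected_counts(tab2[, -6], tab2[, -5])
  risks <- std_risks(std2)
  expect_equal(risks$risk[risks$age_class == 2], 0.1)
  expect_equal(std2$e, c(10, 90))
  expect_equal(compute_smr(std2$y, std2$e)$smr, c(1, 1))

  # stratum with deaths but no population is rejected
  bad <- std_fixture(pops = c(0, 0), deaths = c(2, 1))
  expect_error(compute_expected_counts(bad[, -6], bad[, -5]),
               "zero population")
})

test_that("internal standardisation conserves totals on synthetic bundles", {
  for (s in c(1, 2)) {
    b <- simulate_bundle(n_areas = 24, subarea_sizes = c(8, 8, 8),
                         years = 2010:2012, total = 50000,
                         beta_pm = log(1.3), re_kind = "iid", seed = s)
    std <- compute_expected_counts(b$population, b$deaths_strata)
    per_year <- dplyr::group_by(std, year) |>
      dplyr::summarise(dy = abs(sum(y) - sum(e)))
    expect_true(all(per_year$dy < 1e-9))
  }
})

test_that("SMR point estimates and exact Poisson intervals are correct", {
  expect_equal(compute_smr(7, 7)$smr, 1)
  expect_equal(compute_smr(10, 5)$smr, 2)
  z <- compute_smr(0, 2)
  expect_equal(z$smr, 0)
  expect_equal(z$ci_low, 0)
  expect_equal(z$ci_high, qchisq(0.975, 2) / 4, tolerance = 1e-6)
  expect_equal(z$ci_high, 1.8444, tolerance = 1e-4)
  expect_error(compute_smr(3, 0), "positive")
  expect_error(compute_smr(-1, 2), "nonnegative")

  # MLE property: y/e maximises the Poisson likelihood (grid-search oracle)
  withr::with_seed(88, {
    for (k in 1:20) {
      y <- rpois(1, 20) + 1L; e <- runif(1, 0.5, 30)
      loglik <- function(th) dpois(y, e * th, log = TRUE)
      opt <- optimise(loglik, c(1e-6, 100), maximum = TRUE)$maximum
      expect_equal(compute_smr(y, e)$smr, opt, tolerance = 1e-4)
    }
  })
})

test_that("exact intervals achieve nominal coverage", {
  withr::with_seed(202, {
    theta <- 1.4; e <- runif(2000, 2, 40)
    y <- rpois(2000, e * theta)
    ci <- compute_smr(y, e)
    cover <- mean(ci$ci_low <= theta & theta <= ci$ci_high)
    expect_gte(cover, 0.94)
  })
})

test_that("crude rates reproduce the published provincial arithmetic", {
  rates <- compute_crude_rates(pavia_deaths(), pavia_reference_population())
  get <- function(yr, g) rates$rate[rates$year == yr & rates$group == g]
  expect_equal(get(2010, "M"), 3.72)
  expect_equal(get(2010, "F"), 5.14)
  expect_equal(get(2012, "overall"), 4.49)
  expect_equal(get(2014, "overall"), 4.22)
  totals <- dplyr::filter(rates, group == "overall")
  expect_equal(sum(totals$deaths), 14183)
  ref <- pavia_reference_population()
  expect_equal(round(100 * ref$count[ref$gender == "M"] / sum(ref$count), 2),
               48.28)
  expect_equal(compute_crude_rates(
    tibble::tibble(year = 2010L, gender = "M", deaths = 0L),
    pavia_reference_population())$rate[1], 0)
})
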