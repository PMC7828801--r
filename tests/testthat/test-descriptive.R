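test_that("beta-binomial conjugate update matches the closed form", {
  prior <- beta_binomial_update(0, 0)
  expect_equal(c(prior$a, prior$b), c(1, 3))

  post <- beta_binomial_update(963, 2387)
  expect_equal(c(post$a, post$b), c(964, 1427))
  expect_equal(post$post_mean, 964 / (964 + 1427))
  expect_lt(post$p_gt_half, 1e-10)

  expect_error(beta_binomial_update(5, 3), "exceed")

  # MC draws agree with the analytic mean within 3 MC standard errors
  draws <- withr::with_seed(9, rbeta(50000, post$a, post$b))
  mc_se <- sd(draws) / sqrt(50000)
  expect_lt(abs(mean(draws) - post$post_mean), 3 * mc_se)
})

test_that("gender-trend posterior probabilities behave as expected", {
  sym <- gender_trend_pp(tibble::tibble(year = 2010:2011, y = c(500, 500),
                                        n = c(1000, 1000)), seed = 4)
  expect_lt(abs(sym$pairs$pp - 0.5), 0.02)

  sep <- gender_trend_pp(tibble::tibble(year = 2010:2011, y = c(900, 100),
                                        n = c(1000, 1000)), seed = 4)
  expect_gt(sep$pairs$pp, 0.999)
  expect_false(sep$no_trend)

  # provincial 2010 vs 2015 male-death shares: no trend under the rule
  tab <- pavia_deaths() |>
    tidyr::pivot_wider(names_from = gender, values_from = deaths) |>
    dplyr::filter(year %in% c(2010, 2015)) |>
    dplyr::transmute(year, y = M, n = M + F)
  res <- gender_trend_pp(tab, seed = 4)
  expect_true(res$no_trend)
})

test_that("robust pooling is exact on degenerate data and sized correctly", {
  smr1 <- tidyr::crossing(subarea = "A", year = 2010:2015) |>
    dplyr::mutate(smr = 1.0)
  pool <- robust_pool_subareas(smr1, n_iter = 12000L, burnin = 2000L, seed = 5)
  expect_equal(nrow(pool$grid), 100)
  expect_true(all(abs(pool$grid$theta_median - 1) < 0.02))
  expect_true(all(pool$grid$sigma2_median > 0))
  expect_error(robust_pool_subareas(smr1[1, ]), "at least two")
})

test_that("pooling recovers a known Student-t location", {
  cover <- vapply(1:20, function(k) {
    x <- withr::with_seed(1000 + k, 1.1 + 0.05 * rt(6, df = 10))
    smr <- tibble::tibble(subarea = "A", year = 2010:2015, smr = x)
    g <- robust_pool_subareas(smr, scale_grid = 0.5, n_iter = 1200,
                              burnin = 400, seed = k)$grid
    g$theta_low <= 1.1 && 1.1 <= g$theta_high
  }, logical(1))
  expect_gte(sum(cover), 18)
})

test_that("smaller prior scales tighten the pooled posterior", {
  x <- withr::with_seed(12, 1 + 0.3 * rt(6, df = 10))
  smr <- tibble::tibble(subarea = "A", year = 2010:2015, smr = x)
  grid <- seq(0.1, 1.5, length.out = 10)
  g <- robust_pool_subareas(smr, scale_grid = grid, n_iter = 2500,
                            burnin = 500, seed = 3)$grid
  width <- g$theta_high - g$theta_low
  expect_lt(width[1], width[10])
  expect_gt(cor(g$scale, width, method = "spearman"), 0.5)
})
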