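test_that("design coding follows the model's covariate conventions", {
  b <- small_bundle()
  d <- build_design(b)
  expect_lt(abs(mean(d$pm25_c)), 1e-9)
  expect_true(all(d$rural %in% c(0, 1)))
  # scaling: +15 ug/m3 above the grand mean is one design unit
  pm_grand <- attr(d, "pm_grand_mean")
  row <- which.max(b$exposure$pm25)
  expect_equal(d$pm25_c[d$area_id == b$exposure$area_id[row] &
                          d$year == b$exposure$year[row]],
               (b$exposure$pm25[row] - pm_grand) / 15)
  # urban and peri-urban both map to rural = 0
  nonrural <- b$lattice$areas$area_id[b$lattice$areas$degurba != "rural"]
  expect_true(all(d$rural[d$area_id %in% nonrural] == 0))

  dt <- build_design(b, trend = TRUE)
  expect_true(all(dt$year_c %in% 0:5))

  std <- compute_expected_counts(b$population, b$deaths_strata)
  std$e[1] <- 0
  expect_error(build_design(b, expected = std), "offset")
})

test_that("the model grid is the 4x2 crossing with sd-3 priors", {
  grid <- make_model_grid()
  expect_equal(nrow(grid), 8)
  expect_equal(grid$random[grid$grid_id == "M4A"], "bym")
  expect_false(grid$trend[grid$grid_id == "M4A"])
  expect_equal(grid$random, rep(c("none", "iid", "icar", "bym"), each = 2))
  for (k in 1:8) expect_true(all(grid$priors[[k]]$beta$sd == 3))
  expect_equal(grid$phase, rep(1:4, each = 2))
})

test_that("null model recovers a zero intercept through the offset", {
  b <- small_bundle()
  d <- build_design(b)
  f <- fit_model(d, model_spec("M1A"), chains = 2, iter = 1500, seed = 21)
  td <- tidy(f)
  b0 <- td[td$term == "intercept", ]
  expect_lt(abs(b0$estimate), 3 * b0$std.error)
  expect_true(all(td$rhat < 1.05, na.rm = TRUE))
})

test_that("doubling the offset shifts the intercept by -log 2", {
  b <- small_bundle()
  d <- build_design(b)
  f1 <- fit_model(d, model_spec("M1A"), chains = 2, iter = 1500, seed = 22)
  d2 <- d
  d2$e <- 2 * d2$e
  d2$offset <- log(d2$e)
  f2 <- fit_model(d2, model_spec("M1A"), chains = 2, iter = 1500, seed = 22)
  shift <- mean(f2$draws$beta[, "intercept"]) - mean(f1$draws$beta[, "intercept"])
  se <- sd(f1$draws$beta[, "intercept"])
  expect_lt(abs(shift + log(2)), 3 * se)
})

test_that("flat-prior posterior matches the ML Poisson oracle", {
  b <- small_bundle()
  d <- build_design(b)
  spec <- model_spec("M1A")
  spec$priors[[1]]$beta$sd <- 30
  f <- fit_model(d, spec, chains = 2, iter = 6000, seed = 23)
  mle <- coef(glm(y ~ pm25_c + rural + offset(offset),
                  family = poisson, data = d))
  post <- colMeans(f$draws$beta)
  expect_lt(max(abs(post - mle)), 0.01)
})

test_that("ICAR effects satisfy the sum-to-zero constraint", {
  b <- small_bundle()
  d <- build_design(b)
  f <- fit_model(d, model_spec("M3A"), lattice = b$lattice,
                 chains = 2, iter = 1500, seed = 24)
  expect_lt(max(abs(rowSums(f$draws$v))), 1e-9)
  expect_error(fit_model(d, model_spec("M3A"), lattice = NULL), "lattice")
})

test_that("prior propagation follows the posterior-moment rule", {
  b <- small_bundle()
  d <- build_design(b)
  f <- fit_model(d, model_spec("M2A"), chains = 2, iter = 2000, seed = 25)
  nxt <- propagate_priors(f, model_spec("M4A"))
  pb <- nxt$priors$beta
  expect_equal(pb$mean[pb$term == "pm25_c"],
               mean(f$draws$beta[, "pm25_c"]), tolerance = 1e-12)
  expect_equal(pb$sd[pb$term == "pm25_c"],
               sd(f$draws$beta[, "pm25_c"]), tolerance = 1e-12)
  # the IID variance hyperprior is re-centred on the posterior median
  expect_equal(nxt$priors$var_hyper$iid$rate, median(f$draws$sig2_u))
  expect_equal(nxt$priors$var_hyper$iid$shape, 2)
  # the ICAR hyperprior was never fit before, so it keeps its default
  expect_equal(nxt$priors$var_hyper$icar$shape, 0.01)

  bad <- f
  bad$converged <- FALSE
  expect_error(propagate_priors(bad, model_spec("M4A")), "unconverged")
})

test_that("propagated priors shrink the exposure effect under collinearity", {
  # exposure proportional to a smooth spatial field that the ICAR component
  # can absorb: the informative prior from the simpler fit stabilises beta_pm
  b <- simulate_bundle(n_areas = 30, subarea_sizes = c(10, 10, 10),
                       years = 2010:2011, total = 100000,
                       beta_pm = log(1.075), re_kind = "icar",
                       re_sd = c(iid = 0.1, icar = 0.2), seed = 71)
  d <- build_design(b)
  f2 <- fit_model(d, model_spec("M2A"), chains = 2, iter = 2000, seed = 72)
  spec3 <- model_spec("M3A")
  f3_default <- fit_model(d, spec3, lattice = b$lattice, chains = 2,
                          iter = 2000, seed = 73)
  f3_inform <- fit_model(d, propagate_priors(f2, spec3), lattice = b$lattice,
                         chains = 2, iter = 2000, seed = 73)
  expect_lt(sd(f3_inform$draws$beta[, "pm25_c"]),
            sd(f3_default$draws$beta[, "pm25_c"]))
})

test_that("risk summaries and the exceedance rule match the definitions", {
  f <- list(
    draws = list(eta = cbind(log(c(0.5, 1.5, 1.5, 1.5)), log(rep(1, 4)))),
    rows = tibble::tibble(area_id = 0:1, year = 2010L)
  )
  class(f) <- "dm_fit"
  r <- summarize_rr(f)
  expect_equal(r$rr_median, c(1.5, 1))
  expect_equal(r$pp, c(0.75, 0))      # strict inequality: RR = 1 never exceeds
  expect_equal(r$class, c("neutral", "neutral"))

  expect_equal(classify_pp(c(0.95, 0.05, 0.5, 0.9, 0.1)),
               c("high", "low", "neutral", "neutral", "neutral"))
})
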