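test_that("WAIC matches hand computation and degenerate limits", {
  ll <- matrix(log(c(0.5, 0.25)), ncol = 1)
  w <- compute_waic(ll)
  lppd <- log(0.375)
  p <- var(log(c(0.5, 0.25)))
  expect_equal(w$estimate, -2 * (lppd - p), tolerance = 1e-12)
  expect_equal(w$estimate, 2.4421, tolerance = 1e-4)
  expect_equal(w$p_eff, 0.2402, tolerance = 1e-3)

  # identical draws: no posterior variance, WAIC = -2 sum(ll) = LOOIC
  ll0 <- matrix(rep(c(-1.3, -0.7, -2.1), each = 4), nrow = 4)
  w0 <- compute_waic(ll0)
  l0 <- compute_loo(ll0)
  expect_equal(w0$p_eff, 0)
  expect_equal(w0$estimate, -2 * sum(c(-1.3, -0.7, -2.1)))
  expect_equal(l0$estimate, w0$estimate)

  expect_error(compute_waic(matrix(-1, nrow = 1)), "2 posterior draws")
})

test_that("WAIC is additive over independent observation blocks", {
  withr::with_seed(40, {
    ll <- matrix(rnorm(200 * 12, -2), 200)
    a <- compute_waic(ll[, 1:5])
    b <- compute_waic(ll[, 6:12])
    whole <- compute_waic(ll)
    expect_equal(whole$estimate, a$estimate + b$estimate, tolerance = 1e-9)
    expect_equal(whole$p_eff, a$p_eff + b$p_eff, tolerance = 1e-9)
  })
})

test_that("PSIS-LOO agrees with exact leave-one-out refits", {
  case <- poisson_grid_case()
  l <- compute_loo(case$loglik)
  expect_lt(abs(l$elpd - case$elpd_exact), 0.5)
  expect_true(all(l$pareto_k < 0.7))
  # WAIC and LOO agree asymptotically on this well-specified model
  w <- compute_waic(case$loglik)
  expect_lte(abs(w$estimate - l$estimate), 2 * (w$se + l$se))
})

test_that("model comparison is antisymmetric with exact self-differences", {
  withr::with_seed(61, {
    llA <- matrix(rnorm(400 * 10, -2, 0.3), 400)
    llB <- llA + rnorm(400 * 10, 0.05, 0.1)
    ics <- list(A = compute_waic(llA), B = compute_waic(llB))
    cmp <- compare_models(ics)
    self <- cmp$pairs[cmp$pairs$model_a == "A" & cmp$pairs$model_b == "A", ]
    expect_equal(self$diff_elpd, 0)
    expect_equal(self$se, 0)
    ab <- cmp$pairs[cmp$pairs$model_a == "A" & cmp$pairs$model_b == "B", ]
    ba <- cmp$pairs[cmp$pairs$model_a == "B" & cmp$pairs$model_b == "A", ]
    expect_equal(ab$diff_elpd, -ba$diff_elpd)
    expect_equal(ab$se, ba$se)

    short <- compute_waic(llA[, 1:5])
    expect_error(compare_models(list(A = ics$A, S = short)), "mismatched")
  })
})

test_that("null refits of the same model are not declared different", {
  flags <- vapply(1:20, function(k) {
    withr::with_seed(700 + k, {
      n <- 40
      mu <- rnorm(n, -2, 0.2)
      ll1 <- t(replicate(300, mu + rnorm(n, 0, 0.15)))
      ll2 <- t(replicate(300, mu + rnorm(n, 0, 0.15)))
      cmp <- compare_models(list(a = compute_waic(ll1), b = compute_waic(ll2)))
      p <- cmp$pairs$p_adj[cmp$pairs$model_a == "a" & cmp$pairs$model_b == "b"]
      p > 0.05
    })
  }, logical(1))
  expect_gte(sum(flags), 18)
})
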