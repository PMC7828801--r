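rook_2x2 <- function() {
  # 4 nodes, rook edges only: 0-1, 0-2, 1-3, 2-3
  w <- matrix(0, 4, 4)
  for (e in list(c(1, 2), c(1, 3), c(2, 4), c(3, 4))) {
    w[e[1], e[2]] <- 1; w[e[2], e[1]] <- 1
  }
  w
}

test_that("Moran's I matches hand computations and rejects constants", {
  # checkerboard on the 2x2 rook grid: perfect negative autocorrelation
  expect_equal(morans_i(c(1, -1, -1, 1), rook_2x2()), -1)
  expect_error(morans_i(rep(2, 4), rook_2x2()), "constant")
})

test_that("Moran's I equals the brute-force double loop", {
  withr::with_seed(7, {
    for (k in 1:20) {
      n <- sample(5:15, 1)
      w <- matrix(rbinom(n * n, 1, 0.4), n)
      w <- 1 * ((w + t(w)) > 0); diag(w) <- 0
      if (sum(w) == 0) w[1, 2] <- w[2, 1] <- 1
      x <- rnorm(n)
      expect_equal(morans_i(x, w), moran_bruteforce(x, w), tolerance = 1e-12)
    }
  })
})

test_that("permutation expectation is -1/(n-1) for iid data", {
  lat <- generate_lattice(188, c(53, 58, 77), seed = 4)
  w <- spatial_weights(lat)
  i_vals <- withr::with_seed(31, {
    vapply(1:200, function(k) morans_i(rnorm(188), w), numeric(1))
  })
  se <- sd(i_vals) / sqrt(200)
  expect_lt(abs(mean(i_vals) - (-1 / 187)), 3 * se)
})

test_that("Moran's I is invariant under joint relabelling", {
  withr::with_seed(17, {
    lat <- tiny_lattice()
    w <- adjacency_matrix(lat)
    x <- rnorm(nrow(w))
    perm <- sample(nrow(w))
    expect_equal(morans_i(x[perm], w[perm, perm]), morans_i(x, w),
                 tolerance = 1e-12)
  })
})

test_that("the Monte-Carlo test is calibrated and bounded", {
  lat <- tiny_lattice()
  x <- withr::with_seed(5, rnorm(lat$n_areas))
  res <- morans_mc_test(x, lat, n_sims = 99, seed = 2)
  expect_gte(res$p_mc, 1 / 100)
  expect_lte(res$p_mc, 1)

  # a strongly autocorrelated field at full study scale: no permutation
  # ever exceeds the observed statistic
  lat188 <- generate_lattice(188, c(53, 58, 77), seed = 1)
  ex <- generate_exposure_field(lat188, years = 2012, mean_by_year = 23.58,
                                sd_by_year = 6.49, seed = 8)
  x188 <- ex$pm25[order(ex$area_id)]
  expect_gte(morans_i(x188, lat188), 0.9)
  res188 <- morans_mc_test(x188, lat188, n_sims = 10000, seed = 3)
  expect_equal(res188$p_mc, 1 / 10001)
})

test_that("type-I error of the permutation test is near nominal", {
  lat <- tiny_lattice()
  rej <- withr::with_seed(1234, {
    vapply(1:200, function(k) {
      morans_mc_test(rnorm(lat$n_areas), lat, n_sims = 199,
                     seed = k)$p_mc <= 0.05
    }, logical(1))
  })
  expect_gte(mean(rej), 0.02)
  expect_lte(mean(rej), 0.10)
})
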