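# shared small fixtures, built once per test run

tiny_lattice <- function(n = 24, sizes = c(8, 8, 8), seed = 11, ...) {
  generate_lattice(n, sizes, seed = seed, ...)
}

# a modest bundle used by several files; memoised for speed
small_bundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_bundle(
        n_areas = 30, subarea_sizes = c(10, 10, 10), years = 2010:2011,
        total = 60000, beta_pm = 0, beta_rural = 0, re_kind = "none",
        seed = 404
      )
    }
    cache
  }
})

model_spec <- function(grid_id) {
  grid <- make_model_grid()
  grid[grid$grid_id == grid_id, ]
}

# grid posterior for a one-parameter Poisson model; returns draws of the
# log-likelihood matrix plus the exact leave-one-out elpd by re-integration
poisson_grid_case <- function(n = 20, seed = 50) {
  withr::with_seed(seed, {
    e <- runif(n, 2, 10)
    y <- rpois(n, e * exp(0.3))
    th <- seq(-2, 2, length.out = 4000)
    logpost_terms <- sapply(th, function(t) dpois(y, e * exp(t), log = TRUE))
    # rows: observations; columns: grid points
    logprior <- dnorm(th, 0, 1.5, log = TRUE)
    lp_full <- colSums(logpost_terms) + logprior
    w_full <- exp(lp_full - max(lp_full)); w_full <- w_full / sum(w_full)
    draws_idx <- sample.int(length(th), 4000, replace = TRUE, prob = w_full)
    loglik <- t(logpost_terms)[draws_idx, ]
    elpd_exact <- vapply(seq_len(n), function(i) {
      lp_i <- lp_full - logpost_terms[i, ]      # posterior without obs i
      w_i <- exp(lp_i - max(lp_i)); w_i <- w_i / sum(w_i)
      log(sum(w_i * exp(logpost_terms[i, ])))
    }, numeric(1))
    list(loglik = loglik, elpd_exact = sum(elpd_exact))
  })
}

# brute-force double-loop Moran's I oracle
moran_bruteforce <- function(x, w) {
  n <- length(x)
  z <- x - mean(x)
  num <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) num <- num + w[i, j] * z[i] * z[j]
  (n / sum(w)) * num / sum(z^2)
}
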