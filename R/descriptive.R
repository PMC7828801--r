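#' Conjugate beta-binomial update for a gender share
#'
#' For `y ~ Binomial(pi, n)` with prior `pi ~ Beta(a0, b0)` (default
#' Beta(1, 3)), returns the closed-form posterior `Beta(a0 + y, b0 + n -
#' y)` with its mean, 95% equal-tailed interval, and `P(pi > 0.5)` via the
#' regularised incomplete beta function.
#'
#' @param y successes (e.g. male deaths in a year).
#' @param n trials (total deaths in the year); `y <= n`.
#' @param a0,b0 prior shapes.
#' @return one-row tibble `a`, `b`, `post_mean`, `ci_low`, `ci_high`,
#'   `p_gt_half`.
#' @export
#' @examples
#' beta_binomial_update(963, 2387)
beta_binomial_update <- function(y, n, a0 = 1, b0 = 3) {
  assert_that_(is_count(y) && is_count(n), "`y` and `n` must be nonnegative integers")
  assert_that_(y <= n, "`y` must not exceed `n`")
  assert_that_(a0 > 0 && b0 > 0, "prior shapes must be positive")
  a <- a0 + y
  b <- b0 + n - y
  tibble(a = a, b = b, post_mean = a / (a + b),
         ci_low = qbeta(0.025, a, b), ci_high = qbeta(0.975, a, b),
         p_gt_half = pbeta(0.5, a, b, lower.tail = FALSE))
}

#' Pairwise posterior probabilities of a gender-share trend across years
#'
#' Fits the conjugate beta-binomial model independently per year and, for
#' each pair of years, estimates `P(pi_t > pi_u)` by Monte-Carlo draws from
#' the two posteriors. The "no trend" verdict holds when every pairwise
#' posterior probability lies strictly inside `(0.05, 0.95)`.
#'
#' @param counts tibble `year`, `y` (e.g. male deaths), `n` (total deaths).
#' @param a0,b0 prior shapes.
#' @param n_draws Monte-Carlo draws per posterior.
#' @param seed integer seed.
#' @return list with `pairs` (tibble `year_t`, `year_u`, `pp` =
#'   `P(pi_t > pi_u)`) and logical `no_trend`.
#' @export
gender_trend_pp <- function(counts, a0 = 1, b0 = 3, n_draws = 20000L,
                            seed = 1L) {
  assert_that_(nrow(counts) >= 2, "need at least two years")
  post <- purrr::pmap(counts, function(year, y, n, ...) {
    c(beta_binomial_update(y, n, a0, b0)[, c("a", "b")], year = year)
  })
  draws <- with_seed_(seed, {
    lapply(post, function(p) rbeta(n_draws, p$a, p$b))
  })
  yrs <- vapply(post, function(p) p$year, numeric(1))
  idx <- utils::combn(seq_along(yrs), 2)
  pairs <- tibble(
    year_t = yrs[idx[1, ]],
    year_u = yrs[idx[2, ]],
    pp = vapply(seq_len(ncol(idx)), function(k) {
      mean(draws[[idx[1, k]]] > draws[[idx[2, k]]])
    }, numeric(1))
  )
  list(pairs = pairs, no_trend = all(pairs$pp > 0.05 & pairs$pp < 0.95))
}

#' Robust Student-t hierarchical pooling of subarea SMR means
#'
#' Pools subarea-year mean SMRs with a robust hierarchical model: each
#' observed subarea-year mean is Student-t distributed (`nu = 10`) around a
#' subarea-level mean `theta_s` with scale `sigma`, `theta_s` has a weak
#' normal prior centred at the null SMR of 1, and `sigma^2` carries a
#' scaled-inverse-chi-square(10, scale) prior whose scale runs over a grid
#' of 100 values in \[0.1, 1.5\]. Sampling uses a Gibbs sampler on the
#' normal scale-mixture representation of the Student-t. Subareas are
#' judged not significantly different when their 95% posterior intervals
#' for `theta_s` overlap at every grid point.
#'
#' @param smr_delta tibble `subarea`, `year`, `smr` of subarea-year mean
#'   SMRs (unweighted means of area SMRs).
#' @param nu Student-t and inverse-chi-square degrees of freedom.
#' @param scale_grid vector of prior scale values (default 100 points in
#'   \[0.1, 1.5\]).
#' @param n_iter,burnin Gibbs iterations and burn-in per grid point.
#' @param seed integer seed.
#' @return list with `grid`: tibble (`scale`, `subarea`, `theta_median`,
#'   `theta_low`, `theta_high`, `sigma2_median`) over all grid points, and
#'   `overlap`: logical, `TRUE` when all subarea intervals overlap at every
#'   grid point.
#' @export
robust_pool_subareas <- function(smr_delta, nu = 10,
                                 scale_grid = seq(0.1, 1.5, length.out = 100),
                                 n_iter = 1500L, burnin = NULL, seed = 1L) {
  assert_that_(nrow(smr_delta) >= 2, "need at least two subarea-year SMR means")
  if (is.null(burnin)) burnin <- floor(n_iter / 3)
  assert_that_(burnin < n_iter, "`burnin` must be smaller than `n_iter`")
  subareas <- sort(unique(smr_delta$subarea))
  seeds <- derive_seeds(seed, length(subareas) * length(scale_grid))
  k <- 0L
  rows <- list()
  for (s in subareas) {
    x <- smr_delta$smr[smr_delta$subarea == s]
    for (sc in scale_grid) {
      k <- k + 1L
      fit <- gibbs_t_pool(x, nu = nu, tau2 = sc, n_iter = n_iter,
                          burnin = burnin, seed = seeds[k])
      rows[[k]] <- tibble(
        scale = sc, subarea = s,
        theta_median = median(fit$theta),
        theta_low = quantile(fit$theta, 0.025, names = FALSE),
        theta_high = quantile(fit$theta, 0.975, names = FALSE),
        sigma2_median = median(fit$sigma2)
      )
    }
  }
  grid <- bind_rows(rows)
  overlap <- grid |>
    group_by(.data$scale) |>
    summarise(ok = max(.data$theta_low) <= min(.data$theta_high),
              .groups = "drop")
  list(grid = grid, overlap = all(overlap$ok))
}

# Gibbs sampler for x_k ~ t_nu(theta, sigma) via the scale mixture
# x_k | lam_k ~ N(theta, sigma^2 / lam_k), lam_k ~ Gamma(nu/2, nu/2);
# theta ~ N(m0, s0^2); sigma^2 ~ Scaled-Inv-Chi2(nu0, tau2)
gibbs_t_pool <- function(x, nu = 10, tau2 = 1, m0 = 1, s02 = 100,
                         nu0 = 10, n_iter = 1500L, burnin = 500L, seed = 1L) {
  n <- length(x)
  with_seed_(seed, {
    theta <- mean(x); sigma2 <- max(var(x), 1e-4)
    if (!is.finite(sigma2)) sigma2 <- 1e-2
    lam <- rep(1, n)
    keep <- n_iter - burnin
    th_out <- numeric(keep); s2_out <- numeric(keep)
    for (it in seq_len(n_iter)) {
      lam <- rgamma(n, (nu + 1) / 2, rate = (nu + (x - theta)^2 / sigma2) / 2)
      prec <- 1 / s02 + sum(lam) / sigma2
      mu <- (m0 / s02 + sum(lam * x) / sigma2) / prec
      theta <- rnorm(1, mu, sqrt(1 / prec))
      sigma2 <- (nu0 * tau2 + sum(lam * (x - theta)^2)) /
        rchisq(1, nu0 + n)
      if (it > burnin) {
        th_out[it - burnin] <- theta
        s2_out[it - burnin] <- sigma2
      }
    }
    list(theta = th_out, sigma2 = s2_out)
  })
}

#' Subarea-year mean SMRs from an SMR table
#'
#' Unweighted mean of area SMRs within each subarea-year.
#'
#' @param smr tibble from [smr_table()] (`area_id`, `year`, `smr`, ...).
#' @param lattice an `area_lattice` supplying the subarea of each area.
#' @return tibble `subarea`, `year`, `smr`.
#' @export
subarea_smr_means <- function(smr, lattice) {
  smr |>
    inner_join(lattice$areas[, c("area_id", "subarea")], by = "area_id") |>
    group_by(.data$subarea, .data$year) |>
    summarise(smr = mean(.data$smr), .groups = "drop")
}
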