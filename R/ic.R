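log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}
log_mean_exp <- function(x) log_sum_exp(x) - log(length(x))

#' Widely applicable information criterion (WAIC)
#'
#' Computed from a draws x observations matrix of per-observation log
#' likelihoods: `lppd_i = log mean_d exp(ll_di)`, effective parameters
#' `p_waic = sum_i var_d(ll_di)` (sample variance, n-1 denominator), and
#' `WAIC = -2 (lppd - p_waic)` on the deviance scale. The standard error
#' comes from the pointwise contributions: `se = 2 sqrt(n var_i(elpd_i))`.
#'
#' @param loglik matrix of posterior log-likelihood draws, draws in rows,
#'   observations in columns; at least 2 draws.
#' @return object of class `dm_ic`: `criterion = "waic"`, `estimate`
#'   (deviance scale), `se`, `elpd`, `p_eff`, and the pointwise elpd
#'   contributions.
#' @export
#' @examples
#' compute_waic(matrix(log(c(0.5, 0.25)), ncol = 1))
compute_waic <- function(loglik) {
  loglik <- as.matrix(loglik)
  assert_that_(nrow(loglik) >= 2, "WAIC needs at least 2 posterior draws")
  assert_that_(ncol(loglik) >= 1, "WAIC needs at least 1 observation")
  lppd_i <- apply(loglik, 2, log_mean_exp)
  p_i <- apply(loglik, 2, var)
  pointwise <- lppd_i - p_i
  new_dm_ic("waic", pointwise, p_eff = sum(p_i))
}

#' Pareto-smoothed importance-sampling leave-one-out cross-validation
#'
#' PSIS-LOO from per-observation log-likelihood draws: raw importance
#' ratios `1/p(y_i | theta_d)` have their upper tail replaced by quantiles
#' of a generalized Pareto distribution fitted to the tail (Zhang-Stephens
#' estimator with a weakly informative prior on the shape), the smoothed
#' log-weights are truncated at the raw maximum, and
#' `elpd_i = log sum_d w_d p(y_i|theta_d) / sum_d w_d`. The fitted Pareto
#' shape `k` is reported per observation; values above 0.7 flag an
#' unreliable approximation.
#'
#' @inheritParams compute_waic
#' @return `dm_ic` with `criterion = "loo"`, plus per-observation
#'   `pareto_k`.
#' @export
compute_loo <- function(loglik) {
  loglik <- as.matrix(loglik)
  assert_that_(nrow(loglik) >= 2, "LOO needs at least 2 posterior draws")
  assert_that_(ncol(loglik) >= 1, "LOO needs at least 1 observation")
  n <- ncol(loglik)
  res <- vapply(seq_len(n), function(i) {
    psis_elpd(loglik[, i])
  }, numeric(2))
  pointwise <- res[1, ]
  lppd_i <- apply(loglik, 2, log_mean_exp)
  ic <- new_dm_ic("loo", pointwise, p_eff = sum(lppd_i - pointwise))
  ic$pareto_k <- res[2, ]
  ic
}

# smoothed elpd and pareto-k for one observation
psis_elpd <- function(ll) {
  s <- length(ll)
  lw <- -ll
  lw <- lw - max(lw)
  m <- ceiling(min(0.2 * s, 3 * sqrt(s)))
  khat <- Inf
  if (m >= 5 && m < s) {
    ord <- order(lw)
    cutoff <- lw[ord[s - m]]
    tail_ids <- which(lw > cutoff)       # strictly above: ties stay untouched
    if (length(tail_ids) >= 5) {
      exc <- exp(lw[tail_ids]) - exp(cutoff)
      if (length(unique(exc)) >= 2) {
        gp <- gpd_fit(sort(exc))
        khat <- gp$k
        if (is.finite(khat)) {
          mt <- length(tail_ids)
          p <- (seq_len(mt) - 0.5) / mt
          qs <- qgpd(p, gp$k, gp$sigma)
          sm <- log(qs + exp(cutoff))
          lw[tail_ids[order(lw[tail_ids])]] <- pmin(sm, 0)
        }
      }
    }
  }
  lw <- lw - log_sum_exp(lw)
  c(elpd = log_sum_exp(lw + ll), k = khat)
}

# Zhang & Stephens (2009) quasi-Bayesian generalized-Pareto fit to sorted
# exceedances, with the weakly informative shape prior used in PSIS
gpd_fit <- function(x) {
  n <- length(x)
  prior_b <- 3; prior_k <- 10
  m <- 30 + floor(sqrt(n))
  jj <- seq_len(m)
  xstar <- x[max(1L, floor(n / 4 + 0.5))]
  b <- 1 / x[n] + (1 - sqrt(m / (jj - 0.5))) / (prior_b * xstar)
  k_b <- vapply(b, function(bj) mean(log1p(-bj * x)), numeric(1))
  ll <- n * (log(-b / k_b) - k_b - 1)
  w <- 1 / vapply(seq_len(m), function(j) sum(exp(ll - ll[j])), numeric(1))
  b_post <- sum(b * w)
  k_post <- mean(log1p(-b_post * x))
  sigma <- -k_post / b_post
  k_post <- (n * k_post + prior_k * 0.5) / (n + prior_k)
  list(k = k_post, sigma = sigma)
}

qgpd <- function(p, k, sigma) {
  if (abs(k) < 1e-12) return(-sigma * log1p(-p))
  sigma * expm1(-k * log1p(-p)) / k
}

new_dm_ic <- function(criterion, pointwise, p_eff, pareto_k = NULL) {
  elpd <- sum(pointwise)
  n <- length(pointwise)
  structure(
    list(criterion = criterion, estimate = -2 * elpd,
         se = 2 * sqrt(n * var(pointwise)), elpd = elpd,
         p_eff = p_eff, n_obs = n, pointwise = pointwise,
         pareto_k = pareto_k),
    class = "dm_ic"
  )
}

#' @export
print.dm_ic <- function(x, ...) {
  cat(sprintf("<dm_ic> %s = %.1f +/- %.1f (elpd %.1f, p_eff %.1f, n %d)\n",
              toupper(x$criterion), x$estimate, x$se, x$elpd, x$p_eff, x$n_obs))
  if (!is.null(x$pareto_k) && any(x$pareto_k > 0.7)) {
    cat(sprintf("  %d observation(s) with pareto k > 0.7\n", sum(x$pareto_k > 0.7)))
  }
  invisible(x)
}

#' Pairwise model comparison from information criteria
#'
#' Pairwise differences of pointwise elpd contributions with their
#' asymptotically normal standard errors (`se = sqrt(n var_i(d_i))` on the
#' elpd scale, doubled on the deviance scale), two-sided normal p-values,
#' and Bonferroni correction over the number of distinct pairs compared.
#' All criteria must come from fits to the identical observation set.
#'
#' @param ics named list of `dm_ic` objects (same criterion, same
#'   observations).
#' @return list with `criteria` (per-model tibble, ordered best first),
#'   `pairs` (tibble `model_a`, `model_b`, `diff_deviance`, `diff_elpd`,
#'   `se`, `z`, `p`, `p_adj`), and `best` (model name with the lowest
#'   criterion).
#' @export
compare_models <- function(ics) {
  assert_that_(length(ics) >= 1 && all(vapply(ics, inherits, logical(1), "dm_ic")),
               "`ics` must be a list of dm_ic objects")
  if (is.null(names(ics)) || any(names(ics) == "")) {
    names(ics) <- paste0("model", seq_along(ics))
  }
  n_obs <- vapply(ics, function(x) x$n_obs, numeric(1))
  assert_that_(length(unique(n_obs)) == 1,
               "mismatched observation sets: all models must be fit to identical observations")

  criteria <- tibble(
    model = names(ics),
    criterion = vapply(ics, function(x) x$criterion, character(1)),
    estimate = vapply(ics, function(x) x$estimate, numeric(1)),
    se = vapply(ics, function(x) x$se, numeric(1)),
    elpd = vapply(ics, function(x) x$elpd, numeric(1)),
    p_eff = vapply(ics, function(x) x$p_eff, numeric(1))
  ) |> arrange(.data$estimate)

  nm <- names(ics)
  grid <- expand.grid(a = nm, b = nm, stringsAsFactors = FALSE)
  n_pairs <- max(1, choose(length(nm), 2))
  pairs <- purrr::pmap(grid, function(a, b) {
    d <- ics[[a]]$pointwise - ics[[b]]$pointwise
    diff_elpd <- sum(d)
    se <- sqrt(length(d) * var(d))
    z <- if (se > 0) diff_elpd / se else if (a == b) NA_real_ else Inf
    p <- if (is.na(z)) NA_real_ else 2 * pnorm(-abs(z))
    tibble(model_a = a, model_b = b, diff_elpd = diff_elpd,
           diff_deviance = -2 * diff_elpd, se = se, z = z, p = p,
           p_adj = pmin(1, p * n_pairs))
  }) |> bind_rows()

  list(criteria = criteria, pairs = pairs, best = criteria$model[1])
}
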