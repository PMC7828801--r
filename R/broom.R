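#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy posterior coefficient summaries of a disease-mapping fit
#'
#' @param x a `dm_fit`.
#' @param conf_level credible-interval mass (default 0.95).
#' @param exponentiate report `exp(beta)` (rate-ratio scale)?
#' @param ... unused.
#' @return tibble `term`, `estimate` (posterior mean), `std.error`
#'   (posterior SD), `conf.low`, `conf.high` (equal-tailed), `pp`
#'   (`P(beta > 0)`), `rhat`.
#' @export
tidy.dm_fit <- function(x, conf_level = 0.95, exponentiate = FALSE, ...) {
  b <- x$draws$beta
  a <- (1 - conf_level) / 2
  out <- tibble(
    term = colnames(b),
    estimate = colMeans(b),
    std.error = apply(b, 2, sd),
    conf.low = apply(b, 2, quantile, a, names = FALSE),
    conf.high = apply(b, 2, quantile, 1 - a, names = FALSE),
    pp = colMeans(b > 0)
  ) |>
    left_join(x$rhat, by = "term")
  if (exponentiate) {
    out <- out |>
      mutate(across(c("estimate", "conf.low", "conf.high"), exp))
  }
  out
}

#' One-row model-level summary of a disease-mapping fit
#'
#' @param x a `dm_fit`.
#' @param ... unused.
#' @return tibble with model id, random component, draw counts,
#'   convergence flag, max Rhat, WAIC and LOOIC.
#' @export
glance.dm_fit <- function(x, ...) {
  w <- compute_waic(x$draws$loglik)
  l <- compute_loo(x$draws$loglik)
  tibble(
    grid_id = x$spec$grid_id,
    random = x$spec$random,
    trend = isTRUE(x$spec$trend),
    n_obs = ncol(x$draws$loglik),
    n_draws = x$n_draws,
    n_chains = x$n_chains,
    converged = x$converged,
    max_rhat = max(x$rhat$rhat, na.rm = TRUE),
    waic = w$estimate, waic_se = w$se,
    looic = l$estimate, looic_se = l$se
  )
}

#' @rdname tidy.dm_fit
#' @export
tidy.dm_ic <- function(x, ...) {
  tibble(criterion = x$criterion, estimate = x$estimate, se = x$se,
         elpd = x$elpd, p_eff = x$p_eff, n_obs = x$n_obs)
}

#' @rdname glance.dm_fit
#' @export
glance.dm_ic <- function(x, ...) tidy.dm_ic(x)
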