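# JAGS model code for one grid cell. The ICAR component is sampled in the
# spectral basis of the graph Laplacian (coefficients u_k with precision
# tau_v * lambda_k), which is the exact intrinsic CAR constrained to sum to
# zero; the BYM convolution adds an exchangeable intercept per area.
jags_model_code <- function(random, hyper_family = "invgamma") {
  re_term <- switch(random,
                    none = "",
                    iid = " + u[area[t]]",
                    icar = " + v[area[t]]",
                    bym = " + u[area[t]] + v[area[t]]")
  blocks <- c(
    "model {",
    "  for (t in 1:N) {",
    "    y[t] ~ dpois(mu[t])",
    sprintf("    eta[t] <- inprod(X[t,], beta[])%s", re_term),
    "    log(mu[t]) <- log_e[t] + eta[t]",
    "    loglik[t] <- logdensity.pois(y[t], mu[t])",
    "  }",
    "  for (p in 1:P) { beta[p] ~ dnorm(b_mean[p], b_prec[p]) }"
  )
  hyper <- function(tag) {
    if (hyper_family == "invgamma") {
      c(sprintf("  tau_%s ~ dgamma(%s_shape, %s_rate)", tag, tag, tag),
        sprintf("  sig2_%s <- 1 / tau_%s", tag, tag))
    } else {
      c(sprintf("  sd_%s ~ dnorm(0, 1) T(0,)", tag),
        sprintf("  tau_%s <- pow(sd_%s, -2)", tag, tag),
        sprintf("  sig2_%s <- pow(sd_%s, 2)", tag, tag))
    }
  }
  if (random %in% c("iid", "bym")) {
    blocks <- c(blocks,
                "  for (i in 1:A) { u[i] ~ dnorm(0, tau_u) }",
                hyper("u"))
  }
  if (random %in% c("icar", "bym")) {
    blocks <- c(blocks,
                "  for (k in 1:K) { uraw[k] ~ dnorm(0, tau_v * lam[k]) }",
                "  for (i in 1:A) { v[i] <- inprod(V[i,], uraw[]) }",
                hyper("v"))
  }
  paste(c(blocks, "}"), collapse = "\n")
}

#' Fit one disease-mapping model by MCMC
#'
#' Samples the hierarchical Poisson log-linear model of one model-grid cell
#' with JAGS: `y_it ~ Poisson(e_it * exp(eta_it))`, `eta = X beta (+ u_i)
#' (+ v_i)` with the random components of the cell (exchangeable intercepts
#' shared across years within an area; intrinsic CAR on the contiguity
#' graph with an exact sum-to-zero constraint via the Laplacian spectral
#' basis; BYM = both with separate variances). Per-observation Poisson
#' log-likelihoods are retained for WAIC/LOO, and convergence is gated on
#' the Gelman-Rubin Rhat of all reported parameters.
#'
#' @param design a `dm_design` from [build_design()].
#' @param spec one row of [make_model_grid()] (a one-row tibble or a list
#'   with `grid_id`, `random`, `trend`, `priors`).
#' @param lattice the `area_lattice`; required for `icar`/`bym` components
#'   (must be connected).
#' @param chains number of MCMC chains.
#' @param iter total iterations per chain; the first `warmup` fraction is
#'   discarded (`chains * iter * (1 - warmup)` draws are retained).
#' @param warmup warmup fraction (default 0.5).
#' @param seed integer seed (drives all chains).
#' @param hyper_family `"invgamma"` (default) or `"halfnormal"` hyperprior
#'   on random-effect variances.
#' @param rhat_threshold convergence gate (default 1.01). Exceeding it
#'   flags the fit with a warning; it never fails silently.
#' @param n_adapt JAGS adaptation steps.
#' @param quiet suppress JAGS progress output.
#' @return object of class `dm_fit`: draws (`beta`, `eta`, `loglik`,
#'   random effects, variances), `rhat` tibble, `converged` flag, and the
#'   row metadata (`area_id`, `year`) aligned with `eta`/`loglik` columns.
#' @export
fit_model <- function(design, spec, lattice = NULL, chains = 4L,
                      iter = 2000L, warmup = 0.5, seed = 1L,
                      hyper_family = c("invgamma", "halfnormal"),
                      rhat_threshold = 1.01, n_adapt = 500L, quiet = TRUE) {
  hyper_family <- match.arg(hyper_family)
  spec <- as_model_spec(spec)
  assert_that_(all(design$e > 0), "offset undefined: expected counts must be positive")

  x <- design_matrix(design)
  terms <- colnames(x)
  pb <- spec$priors$beta
  assert_that_(identical(sort(pb$term), sort(terms)),
               "prior terms do not match the design terms (trend mismatch?)")
  pb <- pb[match(terms, pb$term), ]

  area_idx <- match(design$area_id, sort(unique(design$area_id)))
  dat <- list(N = nrow(design), P = ncol(x), y = design$y,
              log_e = design$offset, X = x,
              b_mean = pb$mean, b_prec = 1 / pb$sd^2)
  monitors <- c("beta", "eta", "loglik")

  if (spec$random != "none") {
    dat$area <- area_idx
    dat$A <- max(area_idx)
  }
  add_hyper <- function(dat, tag, cmp) {
    vh <- spec$priors$var_hyper[[cmp]]
    if (hyper_family == "invgamma") {
      dat[[paste0(tag, "_shape")]] <- vh$shape %||% 0.01
      dat[[paste0(tag, "_rate")]] <- vh$rate %||% 0.01
    }
    dat
  }
  if (spec$random %in% c("iid", "bym")) {
    dat <- add_hyper(dat, "u", "iid")
    monitors <- c(monitors, "u", "sig2_u")
  }
  if (spec$random %in% c("icar", "bym")) {
    assert_that_(!is.null(lattice),
                 "`lattice` is required for icar/bym random components")
    sp <- icar_spectral(lattice)   # errors on a disconnected graph
    keep_areas <- sort(unique(design$area_id)) + 1L
    dat$V <- sp$vectors[keep_areas, , drop = FALSE]
    dat$lam <- sp$values
    dat$K <- length(sp$values)
    dat <- add_hyper(dat, "v", "icar")
    monitors <- c(monitors, "v", "sig2_v")
  }

  code <- jags_model_code(spec$random, hyper_family)
  chain_seeds <- derive_seeds(seed, chains)
  inits <- lapply(chain_seeds, function(s) {
    list(.RNG.name = "base::Mersenne-Twister", .RNG.seed = s)
  })

  run <- function() {
    # block/auxiliary samplers for log-linear Poisson nodes: much better
    # mixing than the default slice samplers
    try(rjags::load.module("glm", quiet = TRUE), silent = TRUE)
    m <- rjags::jags.model(textConnection(code), data = dat, inits = inits,
                           n.chains = chains, n.adapt = n_adapt, quiet = TRUE)
    stats::update(m, n.iter = ceiling(iter * warmup), progress.bar = "none")
    rjags::coda.samples(m, variable.names = monitors,
                        n.iter = iter - ceiling(iter * warmup),
                        progress.bar = "none")
  }
  samp <- if (quiet) suppressWarnings(run()) else run()

  pull <- function(prefix) {
    cols <- grep(sprintf("^%s(\\[|$)", prefix), coda::varnames(samp), value = TRUE)
    if (length(cols) == 0) return(NULL)
    # order by index inside the brackets
    idx <- suppressWarnings(as.integer(sub(".*\\[(\\d+)\\]$", "\\1", cols)))
    if (all(is.na(idx))) idx <- 1L
    cols <- cols[order(idx)]
    do.call(rbind, lapply(samp, function(ch) as.matrix(ch[, cols, drop = FALSE]))) |>
      unname()
  }
  beta <- pull("beta"); colnames(beta) <- terms
  draws <- list(beta = beta, eta = pull("eta"), loglik = pull("loglik"),
                u = pull("u"), v = pull("v"),
                sig2_u = pull("sig2_u"), sig2_v = pull("sig2_v"))

  # Rhat gate on the reported (non-latent-per-observation) parameters
  report <- c(paste0("beta[", seq_along(terms), "]"),
              intersect(c("sig2_u", "sig2_v"), coda::varnames(samp)))
  rhat_vals <- if (chains >= 2) {
    gd <- coda::gelman.diag(samp[, report, drop = FALSE],
                            autoburnin = FALSE, multivariate = FALSE)
    as.numeric(gd$psrf[, 1])
  } else rep(NA_real_, length(report))
  rhat <- tibble(term = c(terms, intersect(c("sig2_u", "sig2_v"),
                                           coda::varnames(samp))),
                 rhat = rhat_vals)
  converged <- all(is.na(rhat$rhat) | rhat$rhat <= rhat_threshold)
  if (!converged) {
    warning(sprintf("model %s: Rhat above %.3f for %s; treat results with caution",
                    spec$grid_id, rhat_threshold,
                    paste(rhat$term[!is.na(rhat$rhat) &
                                      rhat$rhat > rhat_threshold], collapse = ", ")))
  }

  structure(
    list(spec = spec, draws = draws, rhat = rhat, converged = converged,
         rows = design[, c("area_id", "year")],
         n_chains = chains, n_draws = nrow(beta), seed = as.integer(seed),
         hyper_family = hyper_family),
    class = "dm_fit"
  )
}

as_model_spec <- function(spec) {
  if (is.data.frame(spec)) {
    assert_that_(nrow(spec) == 1, "`spec` must be a single model specification")
    spec <- list(grid_id = spec$grid_id, random = spec$random,
                 trend = spec$trend, phase = spec$phase,
                 priors = spec$priors[[1]])
  }
  assert_that_(all(c("grid_id", "random", "priors") %in% names(spec)),
               "`spec` must carry grid_id, random, trend and priors")
  spec
}

#' @export
print.dm_fit <- function(x, ...) {
  cat(sprintf("<dm_fit> %s (random: %s%s), %d draws x %d chains, %s\n",
              x$spec$grid_id, x$spec$random,
              if (isTRUE(x$spec$trend)) ", trend" else "",
              x$n_draws, x$n_chains,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Propagate posterior information into the next modelling phase
#'
#' Implements informative-prior propagation between modelling phases: each
#' coefficient prior of the next specification becomes Normal(posterior
#' mean, posterior SD) of the same term in the previous fit(s), and each
#' random-effect variance hyperprior is re-centred as Inverse-Gamma(shape
#' 2, rate = previous posterior median of that variance), so its prior mean
#' equals the previous phase's posterior median. Terms or components absent
#' from every previous fit keep their defaults.
#'
#' @param previous a converged `dm_fit`, or a list of them (later elements
#'   take precedence for coefficients; variance components are matched by
#'   name across the list).
#' @param next_spec one row of [make_model_grid()].
#' @return `next_spec` with updated `priors`.
#' @export
propagate_priors <- function(previous, next_spec) {
  if (inherits(previous, "dm_fit")) previous <- list(previous)
  ok <- vapply(previous, function(f) isTRUE(f$converged), logical(1))
  assert_that_(all(ok), "refusing to propagate priors from an unconverged fit")

  next_spec <- as_model_spec(next_spec)
  pr <- next_spec$priors
  for (f in previous) {
    bm <- colMeans(f$draws$beta)
    bs <- apply(f$draws$beta, 2, sd)
    hit <- pr$beta$term %in% names(bm)
    pr$beta$mean[hit] <- bm[pr$beta$term[hit]]
    pr$beta$sd[hit] <- bs[pr$beta$term[hit]]
    for (cmp in names(pr$var_hyper)) {
      col <- switch(cmp, iid = "sig2_u", icar = "sig2_v")
      if (!is.null(f$draws[[col]])) {
        med <- median(f$draws[[col]])
        pr$var_hyper[[cmp]] <- list(family = "invgamma", shape = 2, rate = med)
      }
    }
  }
  next_spec$priors <- pr
  next_spec
}

#' Posterior relative-risk summaries and exceedance classification
#'
#' Per area-year: the median of the posterior fitted relative risk
#' `RR = exp(eta)` (linear predictor including random effects, excluding
#' the offset), the exceedance probability `PP = P(RR > 1)` computed as the
#' relative frequency over all retained draws (strict inequality), and the
#' risk class: `"high"` when PP > 0.90, `"low"` when PP < 0.10, else
#' `"neutral"`.
#'
#' @param fit a `dm_fit`.
#' @param cutoff RR cut-off (default 1).
#' @param high,low PP classification bounds (defaults 0.90 / 0.10). An area
#'   is `"high"` when `P(RR > cutoff) > high` and `"low"` when
#'   `P(RR < cutoff) > 1 - low`; for posteriors with no mass exactly at the
#'   cut-off the latter is identical to `pp < low`, while a degenerate
#'   posterior at the cut-off is classified neutral.
#' @return tibble of class `dm_risk`: `area_id`, `year`, `rr_median`,
#'   `pp`, `class`.
#' @export
summarize_rr <- function(fit, cutoff = 1, high = 0.90, low = 0.10) {
  eta <- fit$draws$eta
  assert_that_(!is.null(eta) && nrow(eta) > 0, "fit carries no posterior draws")
  rr <- exp(eta)
  out <- fit$rows |>
    mutate(rr_median = apply(rr, 2, median),
           pp = colMeans(rr > cutoff),
           pp_below = colMeans(rr < cutoff),
           class = dplyr::case_when(
             .data$pp > high ~ "high",
             .data$pp_below > 1 - low ~ "low",
             TRUE ~ "neutral"
           )) |>
    select(-"pp_below")
  class(out) <- c("dm_risk", class(out))
  out
}

#' Classify exceedance probabilities
#'
#' The bare 0.90/0.10 rule on a vector of exceedance probabilities.
#'
#' @param pp numeric vector in \[0, 1\].
#' @param high,low bounds.
#' @return character vector `"high"`/`"low"`/`"neutral"`.
#' @export
classify_pp <- function(pp, high = 0.90, low = 0.10) {
  assert_that_(all(pp >= 0 & pp <= 1), "`pp` must lie in [0, 1]")
  dplyr::case_when(pp > high ~ "high", pp < low ~ "low", TRUE ~ "neutral")
}
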