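#' @importFrom rlang .data %||% abort
#' @importFrom dplyr mutate filter select arrange group_by ungroup summarise
#'   left_join inner_join bind_rows across n count rename distinct pull
#' @importFrom tibble tibble as_tibble
#' @importFrom stats rnorm rpois rgamma rbeta rlnorm rmultinom rbinom runif
#'   qchisq qbeta pbeta qnorm pnorm dpois var sd median quantile rchisq
#'   glm poisson coef setNames aggregate optimise
#' @importFrom utils head tail
NULL

# single entry point for seeded randomness: evaluates `expr` under a local RNG
# state so package functions never clobber the caller's .Random.seed
with_seed_ <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  withr::with_seed(as.integer(seed), expr)
}

# derive a stream of child seeds from one parent seed (kept below 2^31)
derive_seeds <- function(seed, n) {
  with_seed_(seed, sample.int(.Machine$integer.max - 1L, n))
}

assert_that_ <- function(ok, msg) {
  if (!isTRUE(ok)) abort(msg)
  invisible(TRUE)
}

is_count <- function(x) is.numeric(x) && all(is.finite(x)) && all(x >= 0) &&
  all(abs(x - round(x)) < 1e-8)
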