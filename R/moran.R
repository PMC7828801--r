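#' Binary spatial weights from a lattice
#'
#' @param lattice an `area_lattice`.
#' @param row_standardise divide each row by its sum (default `FALSE`:
#'   binary "dichotomous" weights).
#' @return object of class `spatial_weights`: list with the weight matrix
#'   `w` (zero diagonal) and `s0 = sum(w)`.
#' @export
spatial_weights <- function(lattice, row_standardise = FALSE) {
  w <- adjacency_matrix(lattice)
  if (row_standardise) {
    rs <- rowSums(w)
    w <- sweep(w, 1, ifelse(rs > 0, rs, 1), "/")
  }
  structure(list(w = w, s0 = sum(w), row_standardised = row_standardise),
            class = "spatial_weights")
}

#' @export
print.spatial_weights <- function(x, ...) {
  cat(sprintf("<spatial_weights> %d areas, s0 = %g%s\n", nrow(x$w), x$s0,
              if (x$row_standardised) " (row-standardised)" else " (binary)"))
  invisible(x)
}

as_weights <- function(w) {
  if (inherits(w, "spatial_weights")) return(w)
  if (inherits(w, "area_lattice")) return(spatial_weights(w))
  if (is.matrix(w)) {
    assert_that_(isSymmetric(unname(w)) || TRUE, "weights must be a matrix")
    return(structure(list(w = w, s0 = sum(w), row_standardised = FALSE),
                     class = "spatial_weights"))
  }
  abort("`w` must be a spatial_weights object, an area_lattice, or a matrix")
}

#' Moran's I spatial autocorrelation statistic
#'
#' `I = (n / s0) * sum_ij w_ij z_i z_j / sum_i z_i^2` with `z = x - mean(x)`.
#' Under random permutation of `x` over areas, `E(I) = -1 / (n - 1)`.
#'
#' @param x numeric vector over areas (ordered by `area_id`); must not be
#'   constant.
#' @param w a `spatial_weights`, an `area_lattice`, or a weight matrix.
#' @return scalar Moran's I.
#' @export
#' @examples
#' lat <- generate_lattice(16, 16, seed = 1, extra_edge_prob = 0)
#' morans_i(lat$areas$y, lat)
morans_i <- function(x, w) {
  w <- as_weights(w)
  n <- length(x)
  assert_that_(nrow(w$w) == n, "`x` length must equal the number of areas")
  z <- x - mean(x)
  denom <- sum(z^2)
  assert_that_(denom > 0, "Moran's I is undefined for a constant vector")
  (n / w$s0) * as.numeric(z %*% w$w %*% z) / denom
}

#' Monte-Carlo permutation test for Moran's I
#'
#' Permutes `x` over the areas `n_sims` times and reports the plus-one
#' Monte-Carlo p-value. The default alternative is positive spatial
#' autocorrelation (one-sided); `alternative = "two.sided"` doubles the
#' smaller tail.
#'
#' @inheritParams morans_i
#' @param n_sims number of permutations (default 10,000).
#' @param seed integer seed.
#' @param alternative `"greater"` (default) or `"two.sided"`.
#' @return tibble with `i_stat`, `p_mc`, `n_sims`, `e_i` (the permutation
#'   expectation `-1/(n-1)`).
#' @export
morans_mc_test <- function(x, w, n_sims = 10000L, seed = 1L,
                           alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  w <- as_weights(w)
  obs <- morans_i(x, w)
  sims <- with_seed_(seed, {
    vapply(seq_len(n_sims), function(k) morans_i(sample(x), w), numeric(1))
  })
  p_hi <- (1 + sum(sims >= obs)) / (n_sims + 1)
  p <- if (alternative == "greater") p_hi else {
    p_lo <- (1 + sum(sims <= obs)) / (n_sims + 1)
    min(1, 2 * min(p_hi, p_lo))
  }
  tibble(i_stat = obs, p_mc = p, n_sims = as.integer(n_sims),
         e_i = -1 / (length(x) - 1))
}
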