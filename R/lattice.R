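#' Generate a synthetic areal lattice with contiguous subareas
#'
#' Builds a connected planar contiguity lattice of `n_areas` units laid out on
#' a jittered rectangular grid (rook contiguity, plus optional diagonal edges
#' so that vertex degrees are irregular, as in real municipal maps). Subareas
#' are assigned as consecutive segments of a snake path through the grid,
#' which guarantees that each subarea is contiguous and has exactly the
#' requested size. Degree-of-urbanisation (DEGURBA) labels are assigned
#' spatially: urban units form two compact clusters, peri-urban units ring
#' them, and the remainder is rural.
#'
#' @param n_areas number of areal units.
#' @param subarea_sizes integer vector of subarea sizes; must sum to
#'   `n_areas`. Default `c(53, 58, 77)`, the three-subarea structure of a
#'   province of 188 municipalities.
#' @param seed integer seed; all randomness in the function flows from it.
#' @param degurba_counts named integer vector `c(urban=, periurban=, rural=)`
#'   summing to `n_areas`, or `NULL` for the default in which 160/188 of the
#'   units are non-urban (scaled and rounded for other `n_areas`).
#' @param extra_edge_prob probability that an occupied diagonal cell pair is
#'   joined by an edge (degree irregularity); 0 gives a pure rook grid.
#'
#' @return An object of class `area_lattice`: a list with tibbles `areas`
#'   (`area_id`, `subarea`, `degurba`, `row`, `col`, `x`, `y`) and `edges`
#'   (`from`, `to`, each unordered pair stored once with `from < to`), plus
#'   grid dimensions. Area ids run from 0 to `n_areas - 1`.
#' @export
#' @examples
#' lat <- generate_lattice(24, c(8, 8, 8), seed = 1)
#' lat$areas
generate_lattice <- function(n_areas,
                             subarea_sizes = c(53L, 58L, 77L),
                             seed = 1L,
                             degurba_counts = NULL,
                             extra_edge_prob = 0.15) {
  assert_that_(is_count(n_areas) && n_areas >= 1, "`n_areas` must be a positive integer")
  assert_that_(sum(subarea_sizes) == n_areas,
               sprintf("`subarea_sizes` must sum to `n_areas` (%d != %d)",
                       sum(subarea_sizes), n_areas))
  if (is.null(degurba_counts)) {
    frac <- c(urban = 28, periurban = 28, rural = 132) / 188
    degurba_counts <- round(frac * n_areas)
    degurba_counts["rural"] <- n_areas - sum(degurba_counts[c("urban", "periurban")])
  }
  assert_that_(sum(degurba_counts) == n_areas && all(degurba_counts >= 0),
               "`degurba_counts` must be nonnegative and sum to `n_areas`")

  nc <- ceiling(sqrt(n_areas))
  nr <- ceiling(n_areas / nc)

  # snake path through the grid, column by column; any consecutive block of
  # path positions is connected under rook contiguity
  cells <- do.call(rbind, lapply(seq_len(nc), function(cl) {
    rows <- if (cl %% 2 == 1) seq_len(nr) else rev(seq_len(nr))
    cbind(row = rows, col = cl)
  }))
  cells <- cells[seq_len(n_areas), , drop = FALSE]

  occ <- matrix(NA_integer_, nr, nc)              # cell -> area_id (0-based)
  occ[cells] <- seq_len(n_areas) - 1L

  rook <- list()
  diag_pairs <- list()
  for (k in seq_len(n_areas)) {
    r <- cells[k, 1]; cl <- cells[k, 2]
    id <- occ[r, cl]
    nb <- function(dr, dc) {
      r2 <- r + dr; c2 <- cl + dc
      if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc && !is.na(occ[r2, c2])) occ[r2, c2] else NA_integer_
    }
    for (d in list(c(0, 1), c(1, 0))) {
      j <- nb(d[1], d[2])
      if (!is.na(j)) rook[[length(rook) + 1L]] <- c(id, j)
    }
    for (d in list(c(1, 1), c(1, -1))) {
      j <- nb(d[1], d[2])
      if (!is.na(j)) diag_pairs[[length(diag_pairs) + 1L]] <- c(id, j)
    }
  }
  edges <- do.call(rbind, rook)
  seeds <- derive_seeds(seed, 3L)
  if (length(diag_pairs) > 0 && extra_edge_prob > 0) {
    dmat <- do.call(rbind, diag_pairs)
    keep <- with_seed_(seeds[1], runif(nrow(dmat)) < extra_edge_prob)
    edges <- rbind(edges, dmat[keep, , drop = FALSE])
  }
  if (is.null(edges)) edges <- matrix(integer(), ncol = 2)
  edges <- unique(t(apply(edges, 1, sort)))
  if (nrow(edges) == 0) edges <- matrix(integer(), ncol = 2)
  edges_tb <- tibble(from = as.integer(edges[, 1]), to = as.integer(edges[, 2]))

  subarea <- rep(LETTERS[seq_along(subarea_sizes)], times = subarea_sizes)

  areas <- tibble(
    area_id = occ[cells],
    subarea = subarea,
    row = as.integer(cells[, 1]),
    col = as.integer(cells[, 2]),
    # y grows northward; small seeded jitter so coordinates look irregular
    x = cells[, 2] + with_seed_(seeds[2], runif(n_areas, -0.15, 0.15)),
    y = (nr - cells[, 1] + 1) + with_seed_(seeds[2] + 1, runif(n_areas, -0.15, 0.15))
  )
  areas$degurba <- assign_degurba(areas, edges_tb, degurba_counts, seeds[3])
  areas <- areas[, c("area_id", "subarea", "degurba", "row", "col", "x", "y")]

  lat <- structure(
    list(areas = areas, edges = edges_tb, n_areas = as.integer(n_areas),
         nr = nr, nc = nc),
    class = "area_lattice"
  )
  assert_that_(lattice_is_connected(lat), "generated lattice is not connected")
  lat
}

# urban as (up to) two compact BFS-grown clusters, peri-urban as the ring of
# their neighbours, remainder rural
assign_degurba <- function(areas, edges, counts, seed) {
  n <- nrow(areas)
  lab <- rep("rural", n)
  n_urb <- counts[["urban"]]
  n_per <- counts[["periurban"]]
  if (n_urb > 0) {
    adj <- neighbour_list(edges, n)
    k1 <- ceiling(n_urb / 2); k2 <- n_urb - k1
    s1 <- max(1L, round(n * 0.2)); s2 <- max(1L, round(n * 0.75))
    grow <- function(start, size, taken) {
      picked <- integer(0); frontier <- start
      while (length(picked) < size && length(frontier) > 0) {
        v <- frontier[1]; frontier <- frontier[-1]
        if (v %in% picked || v %in% taken) next
        picked <- c(picked, v)
        frontier <- c(frontier, setdiff(adj[[v]], c(picked, taken)))
      }
      picked
    }
    u1 <- grow(s1, k1, integer(0))
    u2 <- grow(s2, k2, u1)
    urb <- c(u1, u2)
    lab[urb] <- "urban"
    if (n_per > 0) {
      ring <- setdiff(unique(unlist(adj[urb])), urb)
      ring <- head(ring, n_per)
      lab[ring] <- "periurban"
      # top up from remaining rural units if the ring is too small
      short <- n_per - length(ring)
      if (short > 0) {
        pool <- which(lab == "rural")
        lab[with_seed_(seed, sample(pool, short))] <- "periurban"
      }
    }
  } else if (n_per > 0) {
    pool <- seq_len(n)
    lab[with_seed_(seed, sample(pool, n_per))] <- "periurban"
  }
  lab
}

neighbour_list <- function(edges, n) {
  adj <- vector("list", n)
  for (i in seq_len(n)) adj[[i]] <- integer(0)
  if (nrow(edges) > 0) {
    for (k in seq_len(nrow(edges))) {
      i <- edges$from[k] + 1L; j <- edges$to[k] + 1L
      adj[[i]] <- c(adj[[i]], j)
      adj[[j]] <- c(adj[[j]], i)
    }
  }
  adj
}

lattice_is_connected <- function(lattice) {
  n <- lattice$n_areas
  if (n == 1) return(TRUE)
  adj <- neighbour_list(lattice$edges, n)
  seen <- logical(n); seen[1] <- TRUE; queue <- 1L
  while (length(queue) > 0) {
    v <- queue[1]; queue <- queue[-1]
    nxt <- adj[[v]][!seen[adj[[v]]]]
    seen[nxt] <- TRUE
    queue <- c(queue, nxt)
  }
  all(seen)
}

#' Dense binary adjacency matrix of a lattice
#'
#' @param lattice an `area_lattice`.
#' @return an `n x n` symmetric 0/1 matrix with zero diagonal, rows and
#'   columns ordered by `area_id`.
#' @export
adjacency_matrix <- function(lattice) {
  n <- lattice$n_areas
  w <- matrix(0, n, n)
  if (nrow(lattice$edges) > 0) {
    idx <- cbind(lattice$edges$from + 1L, lattice$edges$to + 1L)
    w[idx] <- 1
    w[idx[, c(2, 1), drop = FALSE]] <- 1
  }
  dimnames(w) <- list(0:(n - 1), 0:(n - 1))
  w
}

#' @export
print.area_lattice <- function(x, ...) {
  cat(sprintf("<area_lattice> %d areas, %d edges, subareas: %s\n",
              x$n_areas, nrow(x$edges),
              paste(sprintf("%s=%d", names(table(x$areas$subarea)),
                            table(x$areas$subarea)), collapse = " ")))
  invisible(x)
}

#' Write / read an adjacency structure in GAL neighbour-list format
#'
#' GAL is the plain-text neighbour list used by spatial-econometrics tools:
#' a header with the number of units, then for each unit a line `id k`
#' followed by a line with its `k` neighbour ids.
#'
#' @param lattice an `area_lattice`.
#' @param path file path.
#' @return `write_gal` returns `path` invisibly; `read_gal` returns a tibble
#'   of edges (`from`, `to`, `from < to`).
#' @export
write_gal <- function(lattice, path) {
  n <- lattice$n_areas
  adj <- neighbour_list(lattice$edges, n)
  lines <- as.character(n)
  for (i in seq_len(n)) {
    nb <- sort(adj[[i]] - 1L)
    lines <- c(lines, paste(i - 1L, length(nb)), paste(nb, collapse = " "))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gal
#' @export
read_gal <- function(path) {
  lines <- readLines(path)
  n <- as.integer(lines[1])
  out <- list()
  pos <- 2L
  for (i in seq_len(n)) {
    hd <- as.integer(strsplit(trimws(lines[pos]), "\\s+")[[1]])
    id <- hd[1]; k <- hd[2]
    nbs <- if (k > 0) as.integer(strsplit(trimws(lines[pos + 1L]), "\\s+")[[1]]) else integer(0)
    assert_that_(length(nbs) == k, sprintf("GAL record for area %d is malformed", id))
    if (k > 0) out[[length(out) + 1L]] <- tibble(from = id, to = nbs)
    pos <- pos + 2L
  }
  if (length(out) == 0) return(tibble(from = integer(), to = integer()))
  ed <- bind_rows(out)
  # keep each undirected pair once, but first check symmetry
  key_fwd <- paste(ed$from, ed$to)
  key_rev <- paste(ed$to, ed$from)
  assert_that_(all(key_rev %in% key_fwd), "GAL adjacency is not symmetric")
  ed <- ed[ed$from < ed$to, ]
  distinct(arrange(ed, .data$from, .data$to))
}
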