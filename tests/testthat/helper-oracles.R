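# Independent reference implementations used as test oracles.  These are
# deliberately naive (dense matrices, O(n^2) double sums, union-find) and
# share no code with the package internals they check.

# queen contiguity: areas sharing at least one snapped vertex
queen_adjacency_ref <- function(polygons, tol = 1e-8) {
  n <- length(polygons$area_ids)
  vertex_keys <- lapply(polygons$geometries, function(rings) {
    unique(unlist(lapply(rings, function(r) {
      paste(round(r[, 1] / tol), round(r[, 2] / tol))
    })))
  })
  edges <- matrix(FALSE, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (length(intersect(vertex_keys[[i]], vertex_keys[[j]]))) {
        edges[i, j] <- edges[j, i] <- TRUE
      }
    }
  }
  edges
}

# dense weight matrix from an edge-list spatial_weights object
dense_weights <- function(W) {
  n <- length(W$area_ids)
  M <- matrix(0, n, n)
  for (k in seq_along(W$i)) M[W$i[k], W$j[k]] <- W$w[k]
  M
}

# textbook O(n^2) global Moran's I
brute_moran <- function(x, Wmat) {
  n <- length(x)
  z <- x - mean(x)
  num <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) num <- num + Wmat[i, j] * z[i] * z[j]
  }
  (n / sum(Wmat)) * num / sum(z^2)
}

# union-find component count over an explicit edge list
union_find_components <- function(n, edges) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  if (nrow(edges)) {
    for (k in seq_len(nrow(edges))) {
      a <- find(edges[k, 1]); b <- find(edges[k, 2])
      if (a != b) parent[a] <- b
    }
  }
  length(unique(vapply(seq_len(n), find, integer(1))))
}

# two separated 2x1 strips (a gap of 5 units between them)
disjoint_strips <- function() {
  sq <- function(x0, y0) {
    rbind(c(x0, y0), c(x0 + 1, y0), c(x0 + 1, y0 + 1), c(x0, y0 + 1),
          c(x0, y0))
  }
  area_polygons(c("L1", "L2", "R1", "R2"),
                list(list(sq(0, 0)), list(sq(1, 0)),
                     list(sq(7, 0)), list(sq(8, 0))))
}

# checkerboard values on an r x c lattice (0/1 by parity)
checkerboard <- function(rows, cols) {
  vals <- numeric(rows * cols)
  k <- 0
  for (i in seq_len(rows)) {
    for (j in seq_len(cols)) {
      k <- k + 1
      vals[k] <- (i + j) %% 2
    }
  }
  vals
}

# shared registry fixture (built once per test file that sources it lazily)
fixture_cache <- new.env(parent = emptyenv())
get_fixture <- function(seed = 20240601) {
  key <- as.character(seed)
  if (is.null(fixture_cache[[key]]))
    fixture_cache[[key]] <- make_registry_fixture(seed = seed)
  fixture_cache[[key]]
}
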