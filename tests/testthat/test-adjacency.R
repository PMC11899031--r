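test_that("rook contiguity on lattices matches known neighbor structure", {
  g2 <- build_rook_adjacency(make_lattice_geography(2, 2))
  expect_true(all(g2$degree == 2))

  g3 <- build_rook_adjacency(make_lattice_geography(3, 3))
  ids <- g3$area_ids
  center <- match("r2c2", ids)
  expect_equal(g3$degree[center], 4)
  corners <- match(c("r1c1", "r1c3", "r3c1", "r3c3"), ids)
  expect_true(all(g3$degree[corners] == 2))
  # diagonal (corner-touching) cells are not neighbors under rook
  expect_false(match("r2c2", ids) %in% g3$neighbors[[match("r1c1", ids)]])
  expect_false(match("r1c3", ids) %in% g3$neighbors[[match("r1c1", ids)]])
})

test_that("lattice edge count follows the closed form r(c-1) + c(r-1)", {
  for (r in c(1, 2, 3, 5, 7)) {
    for (cc in c(1, 2, 4, 6)) {
      g <- build_rook_adjacency(make_lattice_geography(r, cc))
      expect_equal(sum(g$degree) / 2, r * (cc - 1) + cc * (r - 1),
                   info = sprintf("lattice %dx%d", r, cc))
    }
  }
})

test_that("adjacency is symmetric and invariant under rigid motion", {
  poly <- make_lattice_geography(3, 4)
  g <- build_rook_adjacency(poly)
  for (i in seq_along(g$neighbors)) {
    for (j in g$neighbors[[i]]) expect_true(i %in% g$neighbors[[j]])
  }
  # rotate + translate all coordinates
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  moved <- area_polygons(poly$area_ids, lapply(poly$geometries, function(rs)
    lapply(rs, function(ring) sweep(ring %*% R, 2, c(13.7, -2.9), "+"))))
  g2 <- build_rook_adjacency(moved)
  expect_identical(g$neighbors, g2$neighbors)
})

test_that("rook edges are a subset of queen edges", {
  for (poly in list(make_lattice_geography(3, 3), disjoint_strips())) {
    g <- build_rook_adjacency(poly)
    queen <- queen_adjacency_ref(poly)
    for (i in seq_along(g$neighbors)) {
      for (j in g$neighbors[[i]]) expect_true(queen[i, j])
    }
  }
  # on a lattice queen has strictly more edges (diagonals)
  q <- queen_adjacency_ref(make_lattice_geography(3, 3))
  g <- build_rook_adjacency(make_lattice_geography(3, 3))
  expect_gt(sum(q) / 2, sum(g$degree) / 2)
})

test_that("disjoint geometry yields multiple components", {
  g <- build_rook_adjacency(disjoint_strips())
  expect_equal(g$n_components, 2)
  expect_true(all(g$degree == 1))
  expect_equal(g$component_id[1], g$component_id[2])
  expect_false(g$component_id[1] == g$component_id[3])
})

test_that("polygon validation rejects malformed input", {
  open_ring <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  expect_error(area_polygons("a", list(list(open_ring))), "closed")
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1), c(0, 0))
  expect_error(area_polygons(c("a", "a"), list(list(sq), list(sq))),
               "duplicate")
})

test_that("assign_neighbor connects islands and recomputes components", {
  strips <- disjoint_strips()
  g <- build_rook_adjacency(strips)
  expect_error(assign_neighbor(g, "L1", "R1"), "already has neighbors")

  sq <- rbind(c(20, 0), c(21, 0), c(21, 1), c(20, 1), c(20, 0))
  poly <- area_polygons(c(strips$area_ids, "ISL"),
                        c(strips$geometries, list(list(sq))))
  g3 <- build_rook_adjacency(poly)
  expect_equal(g3$n_components, 3)
  expect_equal(isolates(g3), "ISL")

  fixed <- assign_neighbor(g3, "ISL", "R2")
  i <- match("ISL", fixed$area_ids); j <- match("R2", fixed$area_ids)
  expect_equal(fixed$degree[i], 1)
  expect_equal(fixed$degree[j], g3$degree[j] + 1)
  expect_true(i %in% fixed$neighbors[[j]])
  expect_error(assign_neighbor(fixed, "ISL", "L1"), "force")
  expect_error(assign_neighbor(g3, "nope", "R2"), "unknown")

  # component count after each fix matches the union-find oracle
  for (g_now in list(g3, fixed)) {
    edges <- do.call(rbind, lapply(seq_along(g_now$neighbors), function(a)
      if (length(g_now$neighbors[[a]]))
        cbind(a, g_now$neighbors[[a]]) else NULL))
    if (is.null(edges)) edges <- matrix(integer(0), 0, 2)
    expect_equal(g_now$n_components,
                 union_find_components(length(g_now$area_ids), edges))
  }
  # chaining two fixes merges all three components into one
  both <- assign_neighbor(fixed, "ISL", "L1", force = TRUE)
  expect_equal(both$n_components, 1)
})

test_that("row standardization yields unit row sums and flags isolates", {
  g <- build_rook_adjacency(make_lattice_geography(3, 3))
  W <- row_standardize(g)
  center <- match("r2c2", g$area_ids)
  wc <- W$w[W$i == center]
  expect_equal(wc, rep(0.25, 4))
  expect_equal(W$S0, 9)  # all rows sum to 1, no isolates
  expect_length(W$flagged_isolates, 0)

  g1 <- build_rook_adjacency(make_lattice_geography(1, 1))
  W1 <- row_standardize(g1)
  expect_equal(W1$flagged_isolates, "r1c1")
  expect_length(W1$w, 0)

  B <- binary_weights(g)
  expect_true(all(B$w == 1))
  expect_equal(B$S0, sum(g$degree))
})

test_that("GAL round trip is lossless and malformed files are rejected", {
  g <- build_rook_adjacency(make_lattice_geography(3, 3))
  path <- withr::local_tempfile(fileext = ".gal")
  write_gal(g, path)
  g2 <- read_gal(path)
  expect_identical(g2$area_ids, g$area_ids)
  expect_identical(g2$neighbors, g$neighbors)
  expect_equal(g2$n_components, g$n_components)

  # a graph containing an isolate also round-trips
  sq <- rbind(c(9, 9), c(10, 9), c(10, 10), c(9, 10), c(9, 9))
  poly <- make_lattice_geography(1, 2)
  poly2 <- area_polygons(c(poly$area_ids, "ISL"),
                         c(poly$geometries, list(list(sq))))
  gi <- build_rook_adjacency(poly2)
  write_gal(gi, path)
  expect_identical(read_gal(path)$neighbors, gi$neighbors)

  writeLines(c("2", "a 3", "b b", "b 1", "a"), path)
  expect_error(read_gal(path), "declares 3 neighbors but lists")
  writeLines(c("2", "a 1", "b", "b 0", ""), path)
  expect_error(read_gal(path), "asymmetric.*a -> b")
})

test_that("GeoJSON polygons round trip through write and read", {
  poly <- make_lattice_geography(2, 3)
  path <- withr::local_tempfile(fileext = ".geojson")
  write_geojson_polygons(poly, path)
  back <- read_geojson_polygons(path)
  expect_identical(back$area_ids, poly$area_ids)
  expect_identical(build_rook_adjacency(back)$neighbors,
                   build_rook_adjacency(poly)$neighbors)
})
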