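#' Area polygon sets
#'
#' An `area_polygons` object stores one or more planar polygon rings per
#' area.  Rings are closed two-column coordinate matrices (first vertex
#' equals last).  This is the geometry input for rook-contiguity
#' construction and choropleth export.
#'
#' @param area_ids character vector of unique area identifiers.
#' @param geometries list (one element per area) of lists of closed rings;
#'   each ring is a numeric matrix with columns x, y.
#' @return an object of class `area_polygons`.
#' @export
area_polygons <- function(area_ids, geometries) {
  area_ids <- as.character(area_ids)
  if (anyDuplicated(area_ids))
    stop("duplicate area_id: ", paste(unique(area_ids[duplicated(area_ids)]),
                                      collapse = ", "))
  if (length(area_ids) != length(geometries))
    stop("area_ids and geometries lengths differ")
  for (i in seq_along(geometries)) {
    rings <- geometries[[i]]
    if (length(rings) < 1) stop("area ", area_ids[i], " has no polygon")
    for (r in rings) {
      if (!is.matrix(r) || ncol(r) != 2 || nrow(r) < 4)
        stop("ring of area ", area_ids[i],
             " must be a closed 2-column matrix with >= 4 vertices")
      if (!isTRUE(all.equal(r[1, ], r[nrow(r), ], check.attributes = FALSE)))
        stop("non-closed ring in area ", area_ids[i],
             ": first vertex must equal last")
    }
  }
  structure(list(area_ids = area_ids, geometries = geometries),
            class = "area_polygons")
}

#' @export
print.area_polygons <- function(x, ...) {
  cat("area_polygons:", length(x$area_ids), "areas\n")
  invisible(x)
}

# connected components by breadth-first search over neighbor lists
graph_components <- function(neighbors) {
  n <- length(neighbors)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] > 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      i <- queue[[1]]
      queue <- queue[-1]
      nb <- neighbors[[i]]
      fresh <- nb[comp[nb] == 0L]
      comp[fresh] <- cur
      queue <- c(queue, fresh)
    }
  }
  comp
}

new_adjacency_graph <- function(area_ids, neighbors) {
  neighbors <- lapply(neighbors, function(v) sort(unique(as.integer(v))))
  comp <- graph_components(neighbors)
  structure(list(area_ids = as.character(area_ids),
                 neighbors = neighbors,
                 degree = vapply(neighbors, length, integer(1)),
                 component_id = comp,
                 n_components = max(comp, 0L)),
            class = "adjacency_graph")
}

#' @export
print.adjacency_graph <- function(x, ...) {
  cat("adjacency_graph:", length(x$area_ids), "areas,",
      sum(x$degree) / 2, "edges,",
      x$n_components, "component(s)")
  iso <- sum(x$degree == 0)
  if (iso) cat(",", iso, "isolate(s)")
  cat("\n")
  invisible(x)
}

#' Number of areas in a graph or weights object
#' @param graph an `adjacency_graph` or `spatial_weights` object.
#' @export
n_areas <- function(graph) length(graph$area_ids)

#' Isolated (neighborless) areas of an adjacency graph
#' @param graph an `adjacency_graph`.
#' @return character vector of area ids with degree zero.
#' @export
isolates <- function(graph) graph$area_ids[graph$degree == 0]

#' Build rook contiguity from polygons
#'
#' Two areas are rook neighbors when they share at least one full boundary
#' segment of positive length; corner-only (queen) contacts do not create
#' edges.  Segments are matched after snapping coordinates to a grid of
#' size `tol` and normalizing segment orientation, which makes detection
#' deterministic and robust to floating-point jitter in shared borders.
#'
#' @param polygons an [area_polygons] object.
#' @param tol coordinate snapping tolerance (same units as the
#'   coordinates); default 1e-8.
#' @return an `adjacency_graph` with symmetric neighbor sets, degrees and
#'   connected-component labels.
#' @export
build_rook_adjacency <- function(polygons, tol = 1e-8) {
  stopifnot(inherits(polygons, "area_polygons"), tol >= 0)
  n <- length(polygons$area_ids)
  seg_owner <- new.env(hash = TRUE, parent = emptyenv())
  snap <- function(v) if (tol > 0) round(v / tol) else v
  for (i in seq_len(n)) {
    for (ring in polygons$geometries[[i]]) {
      xs <- snap(ring[, 1]); ys <- snap(ring[, 2])
      m <- length(xs) - 1L
      for (k in seq_len(m)) {
        a <- c(xs[k], ys[k]); b <- c(xs[k + 1L], ys[k + 1L])
        if (a[1] == b[1] && a[2] == b[2]) next  # zero-length after snapping
        key <- if (a[1] < b[1] || (a[1] == b[1] && a[2] < b[2]))
          paste(a[1], a[2], b[1], b[2]) else paste(b[1], b[2], a[1], a[2])
        seg_owner[[key]] <- c(seg_owner[[key]], i)
      }
    }
  }
  nb <- vector("list", n)
  for (key in ls(seg_owner)) {
    owners <- unique(seg_owner[[key]])
    if (length(owners) >= 2) {
      for (i in owners) nb[[i]] <- c(nb[[i]], setdiff(owners, i))
    }
  }
  nb <- lapply(nb, function(v) if (is.null(v)) integer(0) else v)
  new_adjacency_graph(polygons$area_ids, nb)
}

#' Manually assign a neighbor to an island area
#'
#' Mirrors the manual fix applied when an island area has no shared land
#' boundary: a symmetric edge is added between the island and its chosen
#' nearest neighbor, and connected components are recomputed.  Refuses to
#' modify an area that already has neighbors unless `force = TRUE`, to
#' guard against accidental graph edits.
#'
#' @param graph an `adjacency_graph`.
#' @param island_id id of the neighborless area.
#' @param neighbor_id id of the area to connect it to.
#' @param force allow adding an edge to an already-connected area.
#' @return the updated `adjacency_graph`.
#' @export
assign_neighbor <- function(graph, island_id, neighbor_id, force = FALSE) {
  stopifnot(inherits(graph, "adjacency_graph"))
  i <- match(island_id, graph$area_ids)
  j <- match(neighbor_id, graph$area_ids)
  if (is.na(i)) stop("unknown area id: ", island_id)
  if (is.na(j)) stop("unknown area id: ", neighbor_id)
  if (i == j) stop("cannot connect an area to itself")
  if (graph$degree[i] > 0 && !force)
    stop("area '", island_id, "' already has neighbors; ",
         "use force = TRUE if this edit is intended")
  nb <- graph$neighbors
  nb[[i]] <- union(nb[[i]], j)
  nb[[j]] <- union(nb[[j]], i)
  new_adjacency_graph(graph$area_ids, nb)
}

new_spatial_weights <- function(graph, i, j, w, style) {
  structure(list(area_ids = graph$area_ids,
                 i = as.integer(i), j = as.integer(j), w = as.numeric(w),
                 S0 = sum(w), style = style,
                 flagged_isolates = isolates(graph),
                 neighbors = graph$neighbors),
            class = "spatial_weights")
}

#' @export
print.spatial_weights <- function(x, ...) {
  cat("spatial_weights (", x$style, "): ", length(x$area_ids), " areas, S0 = ",
      format(x$S0), "\n", sep = "")
  if (length(x$flagged_isolates))
    cat("  all-zero rows (isolates):",
        paste(x$flagged_isolates, collapse = ", "), "\n")
  invisible(x)
}

#' Row-standardized spatial weights
#'
#' Converts a binary contiguity graph into row-standardized weights
#' (`w_ij = 1/d_i` for neighbors), the GeoDa default used for Moran's I.
#' Rows of neighborless areas are all zero and the ids are flagged in the
#' result.
#'
#' @param graph an `adjacency_graph`.
#' @return a `spatial_weights` object (edge-list form with total weight S0).
#' @export
row_standardize <- function(graph) {
  stopifnot(inherits(graph, "adjacency_graph"))
  ii <- rep(seq_along(graph$neighbors), graph$degree)
  jj <- unlist(graph$neighbors, use.names = FALSE)
  if (is.null(jj)) jj <- integer(0)
  w <- 1 / graph$degree[ii]
  new_spatial_weights(graph, ii, jj, w, "row_standardized")
}

#' Binary spatial weights
#'
#' @param graph an `adjacency_graph`.
#' @return a `spatial_weights` object with `w_ij = 1` on every edge.
#' @export
binary_weights <- function(graph) {
  ii <- rep(seq_along(graph$neighbors), graph$degree)
  jj <- unlist(graph$neighbors, use.names = FALSE)
  if (is.null(jj)) jj <- integer(0)
  new_spatial_weights(graph, ii, jj, rep(1, length(ii)), "binary")
}

#' Read and write GAL contiguity files
#'
#' GAL is the plain-text contiguity-list format used by GeoDa: a header
#' line carrying the area count (optionally preceded by dataset metadata
#' fields), then for each area one `id degree` line followed by one line
#' of neighbor ids.  `read_gal` validates the declared degrees and the
#' symmetry of the listed edges.
#'
#' @param path file path.
#' @return `read_gal`: an `adjacency_graph`; `write_gal`: the path,
#'   invisibly.
#' @export
read_gal <- function(path) {
  lines <- readLines(path)
  while (length(lines) && !nzchar(trimws(lines[[length(lines)]])))
    lines <- lines[-length(lines)]  # isolate rows keep their blank line
  if (!length(lines)) stop("empty GAL file")
  hdr <- strsplit(trimws(lines[[1]]), "\\s+")[[1]]
  n <- if (length(hdr) == 1) as.integer(hdr[1]) else as.integer(hdr[2])
  if (is.na(n) || n < 0) stop("GAL format error: bad header line")
  if (length(lines) == 2 * n) lines <- c(lines, "")  # file ends at an isolate
  if (length(lines) != 1 + 2 * n)
    stop("GAL format error: expected ", 1 + 2 * n, " lines, found ",
         length(lines))
  ids <- character(n)
  nb_ids <- vector("list", n)
  for (k in seq_len(n)) {
    hd <- strsplit(trimws(lines[[2 * k]]), "\\s+")[[1]]
    if (length(hd) != 2) stop("GAL format error: bad id/degree line ", 2 * k)
    ids[k] <- hd[1]
    deg <- as.integer(hd[2])
    nbl <- if (deg == 0) character(0) else
      strsplit(trimws(lines[[2 * k + 1]]), "\\s+")[[1]]
    if (deg == 0 && nzchar(trimws(lines[[2 * k + 1]])))
      nbl <- strsplit(trimws(lines[[2 * k + 1]]), "\\s+")[[1]]
    if (length(nbl) != deg)
      stop("GAL format error: area '", hd[1], "' declares ", deg,
           " neighbors but lists ", length(nbl))
    nb_ids[[k]] <- nbl
  }
  if (anyDuplicated(ids)) stop("duplicate area_id in GAL file")
  nb <- lapply(nb_ids, function(v) {
    idx <- match(v, ids)
    if (anyNA(idx)) stop("GAL format error: unknown neighbor id ",
                         paste(v[is.na(idx)], collapse = ", "))
    idx
  })
  for (i in seq_len(n)) {
    for (j in nb[[i]]) {
      if (!(i %in% nb[[j]]))
        stop("asymmetric GAL file: edge ", ids[i], " -> ", ids[j],
             " has no reverse entry")
    }
  }
  new_adjacency_graph(ids, nb)
}

#' @param graph an `adjacency_graph` to serialize.
#' @rdname read_gal
#' @export
write_gal <- function(graph, path) {
  stopifnot(inherits(graph, "adjacency_graph"))
  n <- length(graph$area_ids)
  out <- character(1 + 2 * n)
  out[1] <- as.character(n)
  for (k in seq_len(n)) {
    out[2 * k] <- paste(graph$area_ids[k], graph$degree[k])
    out[2 * k + 1] <- paste(graph$area_ids[graph$neighbors[[k]]],
                            collapse = " ")
  }
  writeLines(out, path)
  invisible(path)
}

#' Read polygons from a GeoJSON FeatureCollection
#'
#' Accepts Polygon and MultiPolygon features; the feature property that
#' carries the area identifier is configurable.
#'
#' @param path GeoJSON file path.
#' @param id_property property key holding the area id (default
#'   `"area_id"`).
#' @return an [area_polygons] object.
#' @export
read_geojson_polygons <- function(path, id_property = "area_id") {
  gj <- jsonlite::read_json(path)
  if (!identical(gj$type, "FeatureCollection"))
    stop("expected a GeoJSON FeatureCollection")
  ids <- character(0)
  geoms <- list()
  for (ft in gj$features) {
    id <- ft$properties[[id_property]]
    if (is.null(id)) stop("feature missing id property '", id_property, "'")
    g <- ft$geometry
    ring_to_mat <- function(ring)
      do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
    rings <- switch(g$type,
      Polygon = lapply(g$coordinates, ring_to_mat),
      MultiPolygon = unlist(lapply(g$coordinates,
                                   function(poly) lapply(poly, ring_to_mat)),
                            recursive = FALSE),
      stop("unsupported geometry type: ", g$type))
    ids <- c(ids, as.character(id))
    geoms <- c(geoms, list(rings))
  }
  area_polygons(ids, geoms)
}
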