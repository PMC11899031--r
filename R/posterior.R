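#' Per-area posterior summaries of relative risk
#'
#' Median and equal-tailed credible interval of the retained
#' relative-risk draws, using linear interpolation between order
#' statistics (quantile type 7).
#'
#' @param draws a `bym_draws` object (or a draws x areas matrix with
#'   column names).
#' @param prob credible-interval mass (default 0.95).
#' @return data.frame `area_id`, `median`, `lower`, `upper`.
#' @export
summarize_draws <- function(draws, prob = 0.95) {
  theta <- if (inherits(draws, "bym_draws")) draws$theta else as.matrix(draws)
  stopifnot(prob > 0, prob < 1)
  if (nrow(theta) < 100)
    stop("need at least 100 retained draws for a ", prob,
         " interval; have ", nrow(theta))
  if (nrow(theta) < 2 / (1 - prob))
    stop("too few draws for the requested tail probability")
  qs <- apply(theta, 2, quantile,
              probs = c((1 - prob) / 2, 0.5, (1 + prob) / 2),
              names = FALSE, type = 7)
  ids <- colnames(theta)
  if (is.null(ids)) ids <- as.character(seq_len(ncol(theta)))
  data.frame(area_id = ids, median = qs[2, ], lower = qs[1, ],
             upper = qs[3, ], row.names = NULL, stringsAsFactors = FALSE)
}

hotspot_levels <- c("significant_low", "not_significant", "elevated_1_100",
                    "high_over_100", "consistently_over_100")

#' Classify areas into credible-interval risk bands
#'
#' Significance follows the lower (or upper) limit of the 95% credible
#' interval: an area is significantly high when `lower > 1`, low when
#' `upper < 1`, and not significant otherwise.  Significant-high areas
#' split into three bands: `elevated_1_100` (median risk between 1% and
#' 100% above the reference), `high_over_100` (median more than double
#' the reference), and `consistently_over_100` (the entire interval
#' above double the reference, i.e. `lower > 2`).  All inequalities are
#' strict; the reference risk is 1 by construction of internal
#' standardization.
#'
#' @param median,lower,upper numeric vectors (or a data.frame from
#'   [summarize_draws] as the first argument).
#' @return factor with levels `significant_low`, `not_significant`,
#'   `elevated_1_100`, `high_over_100`, `consistently_over_100`.
#' @export
classify_hotspot <- function(median, lower = NULL, upper = NULL) {
  if (is.data.frame(median)) {
    df <- median
    median <- df$median; lower <- df$lower; upper <- df$upper
  }
  stopifnot(length(median) == length(lower), length(lower) == length(upper),
            all(lower <= median + 1e-12), all(median <= upper + 1e-12))
  out <- rep("not_significant", length(median))
  out[upper < 1] <- "significant_low"
  hi <- lower > 1
  out[hi] <- "elevated_1_100"
  out[hi & median > 2] <- "high_over_100"
  out[hi & lower > 2] <- "consistently_over_100"
  factor(out, levels = hotspot_levels)
}

#' Tabulate hotspot categories
#'
#' @param summaries data.frame with `area_id` and `category` columns (or
#'   output of [summarize_draws], in which case categories are computed).
#' @return named integer vector of per-category counts plus
#'   `significant_high`, the total of the three significant-high bands.
#' @export
count_categories <- function(summaries) {
  if (anyDuplicated(summaries$area_id))
    stop("duplicate area_id in summaries")
  cat <- summaries$category
  if (is.null(cat)) cat <- classify_hotspot(summaries)
  cat <- factor(cat, levels = hotspot_levels)
  counts <- table(cat)
  out <- c(as.vector(counts),
           sum(counts[c("elevated_1_100", "high_over_100",
                        "consistently_over_100")]))
  names(out) <- c(hotspot_levels, "significant_high")
  out
}

ring_to_coords <- function(ring) {
  lapply(seq_len(nrow(ring)), function(k) c(ring[k, 1], ring[k, 2]))
}

#' Export a choropleth-ready GeoJSON FeatureCollection
#'
#' One feature per area carrying the posterior median, credible-interval
#' limits and hotspot category as properties.
#'
#' @param summaries data.frame with `area_id`, `median`, `lower`,
#'   `upper` and optionally `category` (computed if absent).
#' @param polygons an [area_polygons] object covering the same areas.
#' @param path optional output file; if `NULL` the GeoJSON list is
#'   returned.
#' @return the GeoJSON structure (invisibly when written to `path`).
#' @export
export_choropleth <- function(summaries, polygons, path = NULL) {
  stopifnot(inherits(polygons, "area_polygons"))
  missing_geo <- setdiff(summaries$area_id, polygons$area_ids)
  if (length(missing_geo))
    stop("no geometry for area(s): ", paste(missing_geo, collapse = ", "))
  category <- summaries$category
  if (is.null(category)) category <- classify_hotspot(summaries)
  features <- lapply(seq_len(nrow(summaries)), function(k) {
    gi <- match(summaries$area_id[k], polygons$area_ids)
    rings <- polygons$geometries[[gi]]
    geom <- if (length(rings) == 1)
      list(type = "Polygon", coordinates = list(ring_to_coords(rings[[1]])))
    else
      list(type = "MultiPolygon",
           coordinates = lapply(rings, function(r) list(ring_to_coords(r))))
    list(type = "Feature",
         properties = list(area_id = summaries$area_id[k],
                           median = summaries$median[k],
                           lower = summaries$lower[k],
                           upper = summaries$upper[k],
                           category = as.character(category[k])),
         geometry = geom)
  })
  gj <- list(type = "FeatureCollection", features = features)
  if (is.null(path)) return(gj)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(gj)
}

#' Write the per-area summary table as CSV
#'
#' @param summaries data.frame from [summarize_draws] (category added if
#'   absent).
#' @param path output CSV path.
#' @param digits decimals for the risk columns (default 2, matching the
#'   usual reporting style).
#' @return `path`, invisibly.
#' @export
write_summary_csv <- function(summaries, path, digits = 2) {
  if (is.null(summaries$category))
    summaries$category <- classify_hotspot(summaries)
  for (cl in c("median", "lower", "upper"))
    summaries[[cl]] <- round_half_up(summaries[[cl]], digits)
  write.csv(summaries, path, row.names = FALSE)
  invisible(path)
}
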