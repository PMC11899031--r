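#' Pipeline run configuration
#'
#' Collects file paths, the outcome to model, MCMC settings and
#' autocorrelation settings for [run_pipeline].  When `geometry` is
#' `NULL` the pipeline starts from a simulated scenario (lattice
#' geography, skewed populations, spatially correlated counts), the
#' self-contained demo mode.  The MCMC seed is derived from the master
#' `seed` so that a single integer reproduces the whole run.
#'
#' @param outdir output directory (created if needed).
#' @param geometry optional GeoJSON path; `NULL` simulates a lattice.
#' @param counts optional areal-counts CSV path (`area_id`,
#'   `population`, `observed`); `NULL` simulates or aggregates.
#' @param registry optional registry CSV path; when given, counts are
#'   aggregated from it for the chosen `outcome`.
#' @param outcome one of `"incidence"`, `"overall_mortality"`,
#'   `"mortality_36m"`, `"mortality_60m"`.
#' @param sim_rows,sim_cols lattice dimensions for simulation mode.
#' @param sim_alpha,sim_tau_u,sim_tau_v risk-surface parameters for
#'   simulation mode.
#' @param mcmc a [bym_config]; the default is a reduced demo schedule
#'   (20,000 / 10,000 / 10); pass `bym_config()` for the full published
#'   schedule (500,000 / 300,000 / 20).
#' @param n_perm Moran/LISA permutations (default 99,999).
#' @param lisa_alpha LISA significance level.
#' @param seed master seed for every stochastic stage.
#' @return a `run_config` list.
#' @export
run_config <- function(outdir, geometry = NULL, counts = NULL,
                       registry = NULL,
                       outcome = c("incidence", "overall_mortality",
                                   "mortality_36m", "mortality_60m"),
                       sim_rows = 8, sim_cols = 8, sim_alpha = 0,
                       sim_tau_u = 4, sim_tau_v = 20,
                       mcmc = bym_config(total_iterations = 20000,
                                         burn_in = 10000, thin = 10),
                       n_perm = 99999, lisa_alpha = 0.05, seed = 1) {
  outcome <- match.arg(outcome)
  mcmc$seed <- substream_seed(seed, "mcmc")
  structure(list(outdir = outdir, geometry = geometry, counts = counts,
                 registry = registry, outcome = outcome,
                 sim_rows = sim_rows, sim_cols = sim_cols,
                 sim_alpha = sim_alpha, sim_tau_u = sim_tau_u,
                 sim_tau_v = sim_tau_v, mcmc = mcmc, n_perm = n_perm,
                 lisa_alpha = lisa_alpha, seed = as.integer(seed)),
            class = "run_config")
}

pipeline_paths <- function(config) {
  o <- config$outdir
  list(geometry = if (is.null(config$geometry))
         file.path(o, "geometry.geojson") else config$geometry,
       counts = file.path(o, "areal_counts.csv"),
       adjacency = file.path(o, "adjacency.gal"),
       draws = file.path(o, "draws.csv"),
       diagnostics = file.path(o, "diagnostics.json"),
       summary = file.path(o, "summary.csv"),
       choropleth = file.path(o, "choropleth.geojson"),
       moran = file.path(o, "moran.json"),
       lisa = file.path(o, "lisa.csv"),
       manifest = file.path(o, "manifest.json"))
}

require_upstream <- function(path, producer) {
  if (!file.exists(path))
    stop("missing input file '", path, "'; run ", producer, " first")
}

#' Pipeline stages
#'
#' Each stage reads its inputs from files under `config$outdir` (or the
#' configured external paths) and writes its artifacts back, so every
#' intermediate product is inspectable and any stage can be re-run
#' independently.  [run_pipeline] is exactly these stages in order.
#'
#' * `stage_inputs`: simulate or ingest geometry and areal counts.
#' * `stage_adjacency`: rook contiguity, written as a GAL file.
#' * `stage_fit`: internal standardization + BYM fit; draws CSV,
#'   run manifest and convergence diagnostics JSON.
#' * `stage_summarize`: posterior medians, credible intervals, hotspot
#'   categories; summary CSV and choropleth GeoJSON.
#' * `stage_moran`, `stage_lisa`: global and local Moran's I on the
#'   smoothed medians.
#'
#' @param config a [run_config].
#' @return each stage returns its main artifact path(s), invisibly.
#' @name pipeline_stages
NULL

#' @rdname pipeline_stages
#' @export
stage_inputs <- function(config) {
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  p <- pipeline_paths(config)
  if (is.null(config$geometry)) {
    polygons <- make_lattice_geography(config$sim_rows, config$sim_cols)
    write_geojson_polygons(polygons, p$geometry)
  } else {
    polygons <- read_geojson_polygons(config$geometry)
  }
  if (!is.null(config$counts)) {
    counts <- read.csv(config$counts, stringsAsFactors = FALSE)
    needed <- c("area_id", "population", "observed")
    if (!all(needed %in% names(counts)))
      stop("counts file must have columns: ", paste(needed, collapse = ", "))
  } else if (!is.null(config$registry)) {
    registry <- read.csv(config$registry, stringsAsFactors = FALSE)
    registry$diagnosis_date <- as.Date(registry$diagnosis_date)
    registry$death_date <- as.Date(registry$death_date)
    registry <- apply_exclusions(registry)$included
    pops <- data.frame(area_id = polygons$area_ids,
                       population = make_populations(
                         length(polygons$area_ids),
                         seed = substream_seed(config$seed, "pops")))
    counts <- areal_counts(registry, pops, config$outcome)
  } else {
    counts <- simulate_scenario_counts(polygons, config)
  }
  counts <- counts[match(polygons$area_ids, counts$area_id), , drop = FALSE]
  if (anyNA(counts$area_id)) stop("counts/geometry area_id mismatch")
  write.csv(counts, p$counts, row.names = FALSE)
  invisible(c(p$geometry, p$counts))
}

#' @rdname pipeline_stages
#' @export
stage_adjacency <- function(config) {
  p <- pipeline_paths(config)
  require_upstream(p$geometry, "stage_inputs()")
  graph <- build_rook_adjacency(read_geojson_polygons(p$geometry))
  write_gal(graph, p$adjacency)
  invisible(p$adjacency)
}

#' @rdname pipeline_stages
#' @export
stage_fit <- function(config) {
  p <- pipeline_paths(config)
  require_upstream(p$counts, "stage_inputs()")
  require_upstream(p$adjacency, "stage_adjacency()")
  counts <- read.csv(p$counts, stringsAsFactors = FALSE)
  graph <- read_gal(p$adjacency)
  E <- compute_expected(counts)$expected
  draws <- fit_bym(counts$observed, E, graph, config$mcmc)
  write_draws(draws, p$draws)
  diag <- diagnose_draws(draws, E = E)
  jsonlite::write_json(diag, p$diagnostics, dataframe = "rows",
                       auto_unbox = TRUE, digits = NA)
  invisible(c(p$draws, p$diagnostics))
}

read_draws_theta <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  theta <- as.matrix(df[, grep("^theta\\.", names(df)), drop = FALSE])
  colnames(theta) <- sub("^theta\\.", "", colnames(theta))
  theta
}

#' @rdname pipeline_stages
#' @export
stage_summarize <- function(config) {
  p <- pipeline_paths(config)
  require_upstream(p$draws, "stage_fit()")
  require_upstream(p$geometry, "stage_inputs()")
  summ <- summarize_draws(read_draws_theta(p$draws))
  summ$category <- classify_hotspot(summ)
  write_summary_csv(summ, p$summary)
  export_choropleth(summ, read_geojson_polygons(p$geometry), p$choropleth)
  invisible(c(p$summary, p$choropleth))
}

read_summary_medians <- function(p) {
  summ <- read.csv(p$summary, stringsAsFactors = FALSE)
  graph <- read_gal(p$adjacency)
  summ <- summ[match(graph$area_ids, summ$area_id), , drop = FALSE]
  list(x = summ$median, W = row_standardize(graph))
}

#' @rdname pipeline_stages
#' @export
stage_moran <- function(config) {
  p <- pipeline_paths(config)
  require_upstream(p$summary, "stage_summarize()")
  require_upstream(p$adjacency, "stage_adjacency()")
  sm <- read_summary_medians(p)
  moran <- moran_permutation(sm$x, sm$W, n_perm = config$n_perm,
                             seed = substream_seed(config$seed, "moran"))
  jsonlite::write_json(moran, p$moran, auto_unbox = TRUE, digits = NA)
  invisible(p$moran)
}

#' @rdname pipeline_stages
#' @export
stage_lisa <- function(config) {
  p <- pipeline_paths(config)
  require_upstream(p$summary, "stage_summarize()")
  require_upstream(p$adjacency, "stage_adjacency()")
  sm <- read_summary_medians(p)
  lisa <- lisa_permutation(sm$x, sm$W, n_perm = config$n_perm,
                           alpha = config$lisa_alpha,
                           seed = substream_seed(config$seed, "lisa"))
  write.csv(lisa, p$lisa, row.names = FALSE)
  invisible(p$lisa)
}

#' Run the full disease-mapping pipeline
#'
#' Executes the stages of [pipeline_stages] in order — simulate/ingest,
#' rook adjacency, internal standardization + BYM fit, convergence
#' diagnostics, posterior summarization and hotspot classification,
#' choropleth export, global and local Moran's I — and writes a run
#' manifest with an md5 content hash for every artifact, the seed,
#' acceptance rates and flagged diagnostics.  Errors abort with a
#' stage-labelled message; the isolate error surfaces the
#' `assign_neighbor()` remedy.
#'
#' @param config a [run_config].
#' @return the manifest list, invisibly; artifacts on disk.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  t0 <- Sys.time()
  warn_log <- character(0)
  stages <- list(inputs = stage_inputs, adjacency = stage_adjacency,
                 fit = stage_fit, summarize = stage_summarize,
                 moran = stage_moran, lisa = stage_lisa)
  for (nm in names(stages)) {
    message("[baymap] stage: ", nm)
    withCallingHandlers(
      tryCatch(stages[[nm]](config),
               error = function(e)
                 stop("pipeline stage '", nm, "' failed: ",
                      conditionMessage(e), call. = FALSE)),
      warning = function(w) {
        warn_log <<- c(warn_log, paste0(nm, ": ", conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
  }
  p <- pipeline_paths(config)
  artifacts <- p[c("counts", "adjacency", "draws", "diagnostics",
                   "summary", "choropleth", "moran", "lisa")]
  diag <- jsonlite::read_json(p$diagnostics, simplifyVector = TRUE)
  manifest <- list(
    config = unclass_config(config),
    seed = config$seed,
    outcome = config$outcome,
    artifacts = lapply(artifacts, function(f)
      list(path = f, md5 = unname(tools::md5sum(f)))),
    geweke_flagged = diag$parameter[diag$flagged],
    warnings = warn_log,
    runtime_seconds = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    package_version = as.character(utils::packageVersion("baymap")))
  jsonlite::write_json(manifest, p$manifest, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

unclass_config <- function(config) {
  cfg <- unclass(config)
  cfg$mcmc <- unclass(cfg$mcmc)
  cfg
}

simulate_scenario_counts <- function(polygons, config) {
  graph <- build_rook_adjacency(polygons)
  n <- length(polygons$area_ids)
  pops <- make_populations(n, seed = substream_seed(config$seed, "pops"))
  u <- simulate_icar_field(graph, config$sim_tau_u,
                           seed = substream_seed(config$seed, "field"))
  E <- pops * 5e-4  # fixed crude rate: expected events scale with population
  sim <- simulate_counts(E, config$sim_alpha, u, config$sim_tau_v,
                         seed = substream_seed(config$seed, "sim"))
  data.frame(area_id = polygons$area_ids, population = pops,
             observed = sim$observed, stringsAsFactors = FALSE)
}

#' Write polygons as a GeoJSON FeatureCollection
#'
#' @param polygons an [area_polygons] object.
#' @param path output file.
#' @param id_property property key to carry the area id.
#' @return `path`, invisibly.
#' @export
write_geojson_polygons <- function(polygons, path, id_property = "area_id") {
  stopifnot(inherits(polygons, "area_polygons"))
  features <- lapply(seq_along(polygons$area_ids), function(k) {
    rings <- polygons$geometries[[k]]
    geom <- if (length(rings) == 1)
      list(type = "Polygon", coordinates = list(ring_to_coords(rings[[1]])))
    else
      list(type = "MultiPolygon",
           coordinates = lapply(rings, function(r) list(ring_to_coords(r))))
    props <- list()
    props[[id_property]] <- polygons$area_ids[k]
    list(type = "Feature", properties = props, geometry = geom)
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
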