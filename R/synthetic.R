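#' Regular lattice geography
#'
#' Unit-square lattice of `rows` x `cols` areas with deterministic ids
#' `"r{i}c{j}"`.  The standard synthetic geography for exercising
#' adjacency construction and the spatial model.
#'
#' @param rows,cols lattice dimensions (>= 1).
#' @return an [area_polygons] object with `rows * cols` areas.
#' @export
make_lattice_geography <- function(rows, cols) {
  stopifnot(rows >= 1, cols >= 1)
  ids <- character(rows * cols)
  geoms <- vector("list", rows * cols)
  k <- 0L
  for (i in seq_len(rows)) {
    for (j in seq_len(cols)) {
      k <- k + 1L
      ids[k] <- sprintf("r%dc%d", i, j)
      x0 <- j - 1; y0 <- i - 1
      ring <- rbind(c(x0, y0), c(x0 + 1, y0), c(x0 + 1, y0 + 1),
                    c(x0, y0 + 1), c(x0, y0))
      geoms[[k]] <- list(ring)
    }
  }
  area_polygons(ids, geoms)
}

#' Simulate an intrinsic CAR (ICAR) field
#'
#' Draws a spatially structured random effect from the intrinsic
#' conditional autoregressive density
#' proportional to `exp(-(tau_u/2) * sum_{i~j} (u_i - u_j)^2)`,
#' restricted to the subspace where `u` sums to zero within each
#' connected component.  Sampling is exact, by spectral decomposition of
#' the graph Laplacian with zero variance assigned to each component's
#' constant mode.
#'
#' @param graph an `adjacency_graph` without isolates.
#' @param tau_u ICAR precision (> 0).
#' @param seed integer seed.
#' @return numeric vector of per-area effects, named by area id.
#' @export
simulate_icar_field <- function(graph, tau_u, seed) {
  stopifnot(inherits(graph, "adjacency_graph"), tau_u > 0)
  if (length(isolates(graph)))
    stop("ICAR field undefined for neighborless areas: ",
         paste(isolates(graph), collapse = ", "),
         "; use assign_neighbor() first")
  n <- length(graph$area_ids)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) A[i, graph$neighbors[[i]]] <- 1
  L <- diag(graph$degree) - A
  eig <- eigen(L, symmetric = TRUE)
  # one zero eigenvalue per connected component
  G <- graph$n_components
  lam <- eig$values
  lam[(n - G + 1):n] <- Inf  # null modes get zero variance
  set.seed(substream_seed(seed, "icar"))
  z <- rnorm(n)
  u <- as.vector(eig$vectors %*% (z / sqrt(tau_u * lam)))
  names(u) <- graph$area_ids
  u
}

#' Simulate areal Poisson counts under the BYM data-generating model
#'
#' Adds an independent unstructured effect `v_i ~ N(0, 1/tau_v)` to the
#' supplied spatial field and draws
#' `O_i ~ Poisson(E_i * exp(alpha + u_i + v_i))`.  The true relative
#' risks `theta_i = exp(alpha + u_i + v_i)` are returned alongside for
#' parameter-recovery checks.
#'
#' @param E positive expected counts per area.
#' @param alpha overall log relative risk.
#' @param u per-area spatial effect (e.g. from [simulate_icar_field]).
#' @param tau_v precision of the unstructured effect (> 0).
#' @param seed integer seed.
#' @return data.frame with columns `area_id`, `expected`, `observed`,
#'   `theta_true`.
#' @export
simulate_counts <- function(E, alpha, u, tau_v, seed) {
  stopifnot(all(E > 0), tau_v > 0, length(E) == length(u))
  set.seed(substream_seed(seed, "counts"))
  v <- rnorm(length(E), 0, 1 / sqrt(tau_v))
  theta <- exp(alpha + u + v)
  O <- rpois(length(E), E * theta)
  data.frame(area_id = if (is.null(names(u))) as.character(seq_along(u))
                       else names(u),
             expected = as.numeric(E), observed = O, theta_true = theta,
             stringsAsFactors = FALSE)
}

#' Simulate skewed area populations
#'
#' Adult populations drawn log-uniformly between bounds, emulating the
#' highly skewed population sizes of local government areas (a few large
#' urban areas, many small remote ones).
#'
#' @param n_areas number of areas.
#' @param lower,upper population bounds (defaults 500 and 500,000).
#' @param seed integer seed.
#' @return integer vector of populations.
#' @export
make_populations <- function(n_areas, lower = 500, upper = 500000, seed = 1) {
  stopifnot(n_areas >= 1, lower >= 1, upper >= lower)
  set.seed(substream_seed(seed, "populations"))
  pmax(1L, as.integer(round(exp(runif(n_areas, log(lower), log(upper))))))
}

# Table-1 cohort structure the registry fixture reproduces exactly.
# Counts are for the included cohort (after the three exclusions).
fixture_marginals <- function() {
  list(
    n_total = 23917L,
    n_included = 23853L,
    exclusions = c(under15 = 5L, branchial_cleft = 2L, unspecified_site = 57L),
    sex = c(male = 18491L, female = 5362L),
    age_band = c("<40" = 1349L, "40-64" = 12077L, ">=65" = 10427L),
    site = c(lip = 6512L, oral_cavity = 6166L, oropharynx = 5118L,
             nasopharynx = 334L, hypopharynx = 1261L, larynx = 4024L,
             nasal_paranasal = 374L, salivary = 64L),
    grade = c(well = 4878L, moderate = 10985L, poor = 4305L,
              undifferentiated = 84L, unknown = 3601L),
    status = c(alive = 9721L, dead = 14132L),
    deaths_within_60m = 8338L,
    deaths_within_36m = 6714L
  )
}

# ICD-10-style codes available for each site group; fixture records draw a
# concrete code uniformly within their assigned group.
site_group_codes <- list(
  lip = c("C00.0", "C00.1", "C00.9"),
  oral_cavity = c("C01", "C02.1", "C03.0", "C04.0", "C05.0", "C06.9"),
  salivary = c("C07", "C08.0", "C08.9"),
  oropharynx = c("C09.0", "C09.9", "C10.0", "C10.9"),
  nasopharynx = c("C11.0", "C11.9"),
  hypopharynx = c("C12", "C13.0", "C13.9"),
  larynx = c("C32.0", "C32.1", "C32.9"),
  nasal_paranasal = c("C30.0", "C31.0", "C31.9"),
  branchial_cleft = "C10.4",
  unspecified = c("C14.0", "C14.8")
)

#' Synthetic patient-level registry fixture
#'
#' Generates a patient-level table with the exact cohort structure of a
#' state head-and-neck-cancer registry extract: 23,917 records of which 5
#' are aged under 15, 2 carry branchial-cleft tumour codes (C10.4) and 57
#' carry unspecified-site codes (C14.x); the remaining 23,853 reproduce
#' the published cohort marginals exactly (sex, age band, site group,
#' tumour grade, vital status, and 36/60-month window mortality).  Joint
#' structure beyond the marginals is independent given the marginals:
#' each attribute vector carries its exact counts and is shuffled
#' independently.
#'
#' Survival months for deceased patients are drawn uniformly inside the
#' window that their record must satisfy — (0, 36), (36, 60) or
#' (60, 483) months, with a small guard band so that date round-tripping
#' through day arithmetic cannot move a record across a window boundary.
#' Living patients have no death date.
#'
#' @param seed integer seed.
#' @param area_ids optional area identifiers to assign patients to
#'   (default: 78 synthetic areas `"a01".."a78"`).
#' @param area_weights optional assignment weights (e.g. populations);
#'   default uniform.
#' @return data.frame with columns `patient_id`, `area_id`, `age`, `sex`,
#'   `site_code`, `grade`, `diagnosis_date`, `death_date`,
#'   `exclusion_tag`.
#' @export
make_registry_fixture <- function(seed = 1, area_ids = NULL,
                                  area_weights = NULL) {
  m <- fixture_marginals()
  set.seed(substream_seed(seed, "registry"))
  if (is.null(area_ids)) area_ids <- sprintf("a%02d", 1:78)
  if (is.null(area_weights)) area_weights <- rep(1, length(area_ids))

  n_inc <- m$n_included
  shuffle_counts <- function(counts) sample(rep(names(counts), counts))

  sex <- shuffle_counts(m$sex)
  band <- shuffle_counts(m$age_band)
  site <- shuffle_counts(m$site)
  grade <- shuffle_counts(m$grade)
  status <- shuffle_counts(m$status)

  age <- integer(n_inc)
  age[band == "<40"] <- sample(15:39, sum(band == "<40"), replace = TRUE)
  age[band == "40-64"] <- sample(40:64, sum(band == "40-64"), replace = TRUE)
  age[band == ">=65"] <- sample(65:105, sum(band == ">=65"), replace = TRUE)

  code_for <- function(groups) {
    vapply(groups, function(g) {
      pool <- site_group_codes[[g]]
      pool[sample.int(length(pool), 1)]
    }, character(1), USE.NAMES = FALSE)
  }
  site_code <- code_for(site)

  # survival windows: exact counts in (0,36], (36,60], (60,483] months,
  # drawn away from the boundaries (guard band 0.2 months)
  n_dead <- m$status[["dead"]]
  n36 <- m$deaths_within_36m
  n60 <- m$deaths_within_60m - n36
  nlate <- n_dead - m$deaths_within_60m
  surv_dead <- sample(c(runif(n36, 0.2, 35.8), runif(n60, 36.2, 59.8),
                        runif(nlate, 60.2, 482.8)))
  surv <- rep(NA_real_, n_inc)
  surv[status == "dead"] <- surv_dead

  diag_date <- as.Date("1982-01-01") +
    sample.int(as.integer(as.Date("2018-12-31") - as.Date("1982-01-01")) + 1L,
               n_inc, replace = TRUE) - 1L
  death_date <- as.Date(rep(NA, n_inc))
  dead <- status == "dead"
  death_date[dead] <- diag_date[dead] + round(surv[dead] * 30.4375)

  included <- data.frame(
    age = age, sex = sex, site_code = site_code, grade = grade,
    diagnosis_date = diag_date, death_date = death_date,
    exclusion_tag = "none", stringsAsFactors = FALSE)

  # excluded records: disjoint by construction (under-15s carry ordinary
  # adult-site codes; the code-based exclusions are aged >= 15)
  mk_excl <- function(n, tag, codes, ages) {
    dd <- as.Date("1982-01-01") +
      sample.int(13514L, n, replace = TRUE) - 1L
    data.frame(age = sample(ages, n, replace = TRUE),
               sex = sample(c("male", "female"), n, replace = TRUE),
               site_code = sample(codes, n, replace = TRUE),
               grade = "unknown",
               diagnosis_date = dd, death_date = as.Date(rep(NA, n)),
               exclusion_tag = tag, stringsAsFactors = FALSE)
  }
  excl <- rbind(
    mk_excl(m$exclusions[["under15"]], "under15",
            site_group_codes$oral_cavity, 0:14),
    mk_excl(m$exclusions[["branchial_cleft"]], "branchial_cleft",
            site_group_codes$branchial_cleft, 15:90),
    mk_excl(m$exclusions[["unspecified_site"]], "unspecified_site",
            site_group_codes$unspecified, 15:90))

  reg <- rbind(included, excl)
  reg <- reg[sample.int(nrow(reg)), , drop = FALSE]
  reg$patient_id <- sprintf("p%05d", seq_len(nrow(reg)))
  reg$area_id <- sample(area_ids, nrow(reg), replace = TRUE,
                        prob = area_weights / sum(area_weights))
  rownames(reg) <- NULL
  reg[, c("patient_id", "area_id", "age", "sex", "site_code", "grade",
          "diagnosis_date", "death_date", "exclusion_tag")]
}
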