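#' Group ICD-10 head-and-neck codes into anatomical site groups
#'
#' Maps codes in C00-C14, C30.0, C31.x and C32.x to the eight analysed
#' anatomical site groups.  Two special labels mark excludable records:
#' `branchial_cleft` (C10.4, the branchial-cleft rubric) and
#' `unspecified` (C14.x, ill-defined head/neck sites).
#'
#' The assignment of C01 (base of tongue) to the oral cavity group is a
#' configurable convention: pass a modified `table` to move codes between
#' groups.
#'
#' @param icd_code character vector of ICD-10-style codes (e.g.
#'   `"C32.0"`).
#' @param table named list mapping group label -> character vector of
#'   3-character code prefixes (plus exact codes for the C10.4 and C30.0
#'   special cases); default [site_grouping_table()].
#' @return character vector of group labels.
#' @export
group_sites <- function(icd_code, table = site_grouping_table()) {
  code <- toupper(trimws(as.character(icd_code)))
  out <- rep(NA_character_, length(code))
  prefix <- substr(code, 1, 3)
  for (grp in names(table)) {
    spec <- table[[grp]]
    exact <- spec[nchar(spec) > 3]
    pref <- spec[nchar(spec) <= 3]
    out[code %in% exact] <- grp
    hit <- is.na(out) & prefix %in% pref
    out[hit] <- grp
  }
  if (anyNA(out))
    stop("ICD code(s) outside the accepted head/neck set (C00-C14, C30.0, ",
         "C31, C32): ", paste(unique(code[is.na(out)]), collapse = ", "))
  out
}

#' Default ICD-10 site-grouping table
#'
#' @return named list mapping site-group labels to ICD-10 code prefixes;
#'   exact codes (e.g. `"C10.4"`) take precedence over prefixes.
#' @export
site_grouping_table <- function() {
  list(
    branchial_cleft = "C10.4",            # exact match wins over C10 prefix
    lip = "C00",
    oral_cavity = c("C01", "C02", "C03", "C04", "C05", "C06"),
    salivary = c("C07", "C08"),
    oropharynx = c("C09", "C10"),
    nasopharynx = "C11",
    hypopharynx = c("C12", "C13"),
    unspecified = "C14",
    nasal_paranasal = c("C30.0", "C31"),
    larynx = "C32"
  )
}

#' Apply the cohort exclusion rules
#'
#' Removes patients aged under 15 years, branchial-cleft tumours (C10.4)
#' and unspecified head/neck sites (C14.x) from a registry table, and
#' reports the per-reason exclusion counts.  Rules are applied in that
#' order of precedence, so each excluded record counts once.
#'
#' @param registry data.frame with at least `age` and `site_code`
#'   columns (as produced by [make_registry_fixture]).
#' @return list with elements `included` (the filtered data.frame) and
#'   `report` (named integer vector: `under15`, `branchial_cleft`,
#'   `unspecified_site`).
#' @export
apply_exclusions <- function(registry) {
  stopifnot(is.data.frame(registry))
  if (nrow(registry) == 0)
    return(list(included = registry,
                report = c(under15 = 0L, branchial_cleft = 0L,
                           unspecified_site = 0L)))
  grp <- group_sites(registry$site_code)
  reason <- rep(NA_character_, nrow(registry))
  reason[grp == "unspecified"] <- "unspecified_site"
  reason[grp == "branchial_cleft"] <- "branchial_cleft"
  reason[registry$age < 15] <- "under15"
  report <- c(under15 = sum(reason == "under15", na.rm = TRUE),
              branchial_cleft = sum(reason == "branchial_cleft", na.rm = TRUE),
              unspecified_site = sum(reason == "unspecified_site",
                                     na.rm = TRUE))
  list(included = registry[is.na(reason), , drop = FALSE], report = report)
}

#' Expected counts by internal indirect standardization
#'
#' Applies the pooled event rate of the whole study region to each area's
#' adult population: `E_i = population_i * (sum O / sum population)`.
#' By construction `sum E_i = sum O_i`, so a relative risk of 1 means
#' "at the state average".
#'
#' @param counts data.frame with columns `area_id`, `population`,
#'   `observed`.
#' @return data.frame `area_id`, `expected`.
#' @export
compute_expected <- function(counts) {
  stopifnot(is.data.frame(counts), nrow(counts) >= 1,
            all(c("area_id", "population", "observed") %in% names(counts)))
  if (any(counts$population <= 0)) stop("populations must be positive")
  total_O <- sum(counts$observed)
  if (total_O == 0) stop("zero total events: reference rate undefined")
  rate <- total_O / sum(counts$population)
  data.frame(area_id = counts$area_id,
             expected = counts$population * rate,
             stringsAsFactors = FALSE)
}

#' Raw standardized incidence/mortality ratios
#'
#' @param O observed counts.
#' @param E expected counts (> 0).
#' @return numeric vector `O / E`.
#' @export
raw_ratio <- function(O, E) {
  stopifnot(length(O) == length(E), all(E > 0))
  O / E
}

# elapsed months between two dates, by the fixed 30.4375 days/month
# convention (365.25 / 12)
months_between <- function(from, to) {
  as.numeric(to - from) / 30.4375
}

#' Per-area death counts within a survival window
#'
#' Counts deaths occurring within `window_months` of diagnosis
#' (`Inf` counts all deaths, i.e. overall mortality).  Months are
#' computed as elapsed days / 30.4375.
#'
#' @param registry included registry data.frame with `area_id`,
#'   `diagnosis_date`, `death_date` columns.
#' @param window_months 36, 60 or `Inf`.
#' @return data.frame `area_id`, `deaths`, one row per area present in
#'   the registry.
#' @export
window_mortality <- function(registry, window_months = Inf) {
  stopifnot(is.data.frame(registry))
  surv <- months_between(registry$diagnosis_date, registry$death_date)
  if (any(surv < 0, na.rm = TRUE))
    stop("death before diagnosis for patient(s): ",
         paste(registry$patient_id[which(surv < 0)], collapse = ", "))
  hit <- !is.na(surv) & surv <= window_months
  tab <- table(factor(registry$area_id[hit],
                      levels = sort(unique(registry$area_id))))
  data.frame(area_id = names(tab), deaths = as.integer(tab),
             stringsAsFactors = FALSE)
}

#' Annual crude rates per 100,000
#'
#' @param registry included registry with a `diagnosis_date` column.
#' @param total_population denominator population (single value; the
#'   census adult population).
#' @return data.frame `year`, `events`, `rate_per_100k`.
#' @export
annual_rates <- function(registry, total_population) {
  stopifnot(total_population > 0)
  yr <- as.integer(format(registry$diagnosis_date, "%Y"))
  tab <- table(factor(yr, levels = seq(min(yr), max(yr))))
  data.frame(year = as.integer(names(tab)),
             events = as.integer(tab),
             rate_per_100k = 1e5 * as.integer(tab) / total_population)
}

#' Cohort characteristics table
#'
#' Frequency table (counts and percentages, one decimal, round-half-up)
#' of age band, sex, site group, tumour grade and vital status for an
#' included registry.
#'
#' @param registry included registry data.frame.
#' @return data.frame `variable`, `category`, `n`, `pct`.
#' @export
cohort_summary <- function(registry) {
  stopifnot(is.data.frame(registry), nrow(registry) >= 1)
  n <- nrow(registry)
  band <- cut(registry$age, c(-Inf, 39, 64, Inf),
              labels = c("<40", "40-64", ">=65"))
  status <- ifelse(is.na(registry$death_date), "alive", "dead")
  vars <- list(age_band = as.character(band),
               sex = registry$sex,
               site = group_sites(registry$site_code),
               grade = registry$grade,
               status = status)
  out <- do.call(rbind, lapply(names(vars), function(vn) {
    tab <- table(vars[[vn]])
    data.frame(variable = vn, category = names(tab), n = as.integer(tab),
               pct = round_half_up(100 * as.integer(tab) / n, 1),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Build per-area observed-count tables from a registry
#'
#' Aggregates an included registry into the areal-count table the
#' spatial model consumes, for one of the four outcomes: incidence,
#' overall mortality, or 36-/60-month window mortality.
#'
#' @param registry included registry data.frame.
#' @param populations data.frame `area_id`, `population`.
#' @param outcome one of `"incidence"`, `"overall_mortality"`,
#'   `"mortality_36m"`, `"mortality_60m"`.
#' @return data.frame `area_id`, `population`, `observed`, one row per
#'   area in `populations`.
#' @export
areal_counts <- function(registry, populations,
                         outcome = c("incidence", "overall_mortality",
                                     "mortality_36m", "mortality_60m")) {
  outcome <- match.arg(outcome)
  stopifnot(all(c("area_id", "population") %in% names(populations)))
  if (outcome == "incidence") {
    tab <- table(factor(registry$area_id, levels = populations$area_id))
    obs <- as.integer(tab)
  } else {
    win <- switch(outcome, overall_mortality = Inf,
                  mortality_36m = 36, mortality_60m = 60)
    wm <- window_mortality(registry, win)
    obs <- wm$deaths[match(populations$area_id, wm$area_id)]
    obs[is.na(obs)] <- 0L
  }
  data.frame(area_id = populations$area_id,
             population = populations$population,
             observed = obs, stringsAsFactors = FALSE)
}
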