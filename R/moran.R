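weights_edges <- function(W) {
  stopifnot(inherits(W, "spatial_weights"))
  W
}

#' Global Moran's I
#'
#' `I = (n / S0) * sum_ij w_ij z_i z_j / sum_i z_i^2` with
#' `z_i = x_i - mean(x)`.  Areas with all-zero weight rows (isolates)
#' are not allowed; the expectation under the permutation null is
#' `-1/(n - 1)`.
#'
#' @param x per-area values (same order as the weights object).
#' @param W a `spatial_weights` object ([row_standardize] or
#'   [binary_weights]).
#' @return list with `I`, `expected`, `n`.
#' @export
global_moran <- function(x, W) {
  W <- weights_edges(W)
  n <- length(W$area_ids)
  stopifnot(length(x) == n, n >= 3)
  if (length(W$flagged_isolates))
    stop("weights contain all-zero rows (isolates): ",
         paste(W$flagged_isolates, collapse = ", "))
  z <- x - mean(x)
  if (all(z == 0)) stop("zero variance: x is constant")
  I <- (n / W$S0) * sum(W$w * z[W$i] * z[W$j]) / sum(z^2)
  list(I = I, expected = -1 / (n - 1), n = n)
}

#' Monte Carlo permutation test for global Moran's I
#'
#' Pseudo p-value `(m + 1) / (n_perm + 1)` where `m` counts permuted
#' datasets with a statistic at least as extreme as observed, one-sided
#' in the direction of the observed departure from the null expectation
#' `-1/(n-1)` (the GeoDa convention).  The permutation stream comes from
#' a dedicated counter-based generator keyed on `seed`.
#'
#' @inheritParams global_moran
#' @param n_perm number of permutations (default 99,999).
#' @param seed integer seed.
#' @return list with `I`, `expected`, `p`, `n_permutations`, `direction`.
#' @export
moran_permutation <- function(x, W, n_perm = 99999, seed = 1) {
  gm <- global_moran(x, W)
  z <- x - mean(x)
  obs_num <- sum(W$w * z[W$i] * z[W$j])
  # direction of departure from E[I]: numerator scale
  e_num <- gm$expected * W$S0 * sum(z^2) / gm$n
  dir <- if (obs_num >= e_num) 1L else -1L
  m <- moran_perm_count_cpp(z, W$i - 1L, W$j - 1L, W$w, obs_num, dir,
                            as.integer(n_perm), as.numeric(seed))
  list(I = gm$I, expected = gm$expected, p = (m + 1) / (n_perm + 1),
       n_permutations = as.integer(n_perm),
       direction = if (dir > 0) "positive" else "negative")
}

#' Local Moran's I (LISA statistics)
#'
#' `I_i = (z_i / m2) * sum_j w_ij z_j` with `m2 = sum(z^2)/n` (divisor
#' n, which preserves the identity `mean(I_i) = I` under
#' row-standardized weights).  The quadrant is determined by the signs
#' of the centered value and its spatial lag.
#'
#' @inheritParams global_moran
#' @return data.frame `area_id`, `local_I`, `lag`, `quadrant`.
#' @export
local_moran <- function(x, W) {
  W <- weights_edges(W)
  n <- length(W$area_ids)
  stopifnot(length(x) == n)
  z <- x - mean(x)
  if (all(z == 0)) stop("zero variance: x is constant")
  m2 <- sum(z^2) / n
  lag <- numeric(n)
  for (k in seq_along(W$i)) lag[W$i[k]] <- lag[W$i[k]] + W$w[k] * z[W$j[k]]
  deg <- vapply(W$neighbors, length, integer(1))
  lag[deg == 0] <- NA_real_
  quadrant <- ifelse(z >= 0,
                     ifelse(lag >= 0, "high-high", "high-low"),
                     ifelse(lag >= 0, "low-high", "low-low"))
  data.frame(area_id = W$area_ids, local_I = z * lag / m2, lag = lag,
             quadrant = quadrant, stringsAsFactors = FALSE)
}

#' Conditional permutation inference for local Moran's I
#'
#' For each area the observed value is held fixed and the remaining
#' `n - 1` values are permuted among its neighbors `n_perm` times;
#' the pseudo p-value is one-sided in the direction of the observed
#' departure from the conditional null expectation.  Each area draws
#' from its own reproducible substream, so results do not depend on the
#' order areas are processed in.  Areas without neighbors are excluded
#' with a warning (their spatial lag is undefined).
#'
#' @inheritParams global_moran
#' @param n_perm permutations per area (default 99,999).
#' @param alpha significance level for cluster labelling (default 0.05).
#' @param seed integer seed.
#' @param fdr apply Benjamini-Hochberg adjustment to the pseudo
#'   p-values before labelling (off by default, the GeoDa convention).
#' @return data.frame `area_id`, `local_I`, `p`, `quadrant`,
#'   `significant`, `label` (quadrant for significant areas, otherwise
#'   `"not significant"`).
#' @export
lisa_permutation <- function(x, W, n_perm = 99999, alpha = 0.05, seed = 1,
                             fdr = FALSE) {
  lm <- local_moran(x, W)
  n <- length(W$area_ids)
  z <- x - mean(x)
  deg <- vapply(W$neighbors, length, integer(1))
  if (any(deg == 0))
    warning("excluding neighborless area(s) from LISA: ",
            paste(W$area_ids[deg == 0], collapse = ", "))
  # per-area neighbor weight vectors aligned with the neighbor lists
  wlist <- vector("list", n)
  for (i in seq_len(n)) wlist[[i]] <- numeric(0)
  ord <- order(W$i, W$j)
  for (k in ord) wlist[[W$i[k]]] <- c(wlist[[W$i[k]]], W$w[k])
  nb0 <- lapply(W$neighbors, function(v) as.integer(v) - 1L)
  # direction: observed lag vs conditional expectation of the lag
  e_lag <- vapply(seq_len(n), function(i)
    sum(wlist[[i]]) * (-z[i] / (n - 1)), numeric(1))
  dir <- ifelse(lm$lag >= e_lag, 1L, -1L)
  dir[is.na(lm$lag)] <- 1L
  cnt <- lisa_perm_count_cpp(z, nb0, wlist,
                             ifelse(is.na(lm$lag), 0, lm$lag),
                             as.integer(dir), as.integer(n_perm),
                             as.numeric(seed))
  p <- (cnt + 1) / (n_perm + 1)
  p_eff <- if (fdr) stats::p.adjust(p, "BH") else p
  signif <- !is.na(p_eff) & p_eff < alpha
  label <- ifelse(signif, lm$quadrant, "not significant")
  label[is.na(p)] <- NA_character_
  data.frame(area_id = lm$area_id, local_I = lm$local_I, p = p,
             quadrant = lm$quadrant, significant = signif, label = label,
             stringsAsFactors = FALSE)
}
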