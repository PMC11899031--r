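#' MCMC configuration for the BYM model
#'
#' Defaults follow the published analysis schedule: a single chain of
#' 500,000 iterations with a 300,000-iteration burn-in and thinning
#' interval 20, retaining 10,000 draws.  Vague priors: intercept
#' N(0, 1e6); Gamma(0.5, 0.0005) hyperpriors on both precisions (a
#' common WinBUGS convention for BYM models; Gamma(0.001, 0.001) is the
#' usual sensitivity alternative).
#'
#' @param total_iterations,burn_in,thin MCMC schedule.
#' @param n_chains number of chains (the analysis default is 1).
#' @param a_u,b_u shape/rate of the Gamma hyperprior on the spatial
#'   precision tau_u.
#' @param a_v,b_v shape/rate of the Gamma hyperprior on the unstructured
#'   precision tau_v.
#' @param intercept_prior_var prior variance of the intercept.
#' @param step_alpha,step_u,step_v initial random-walk proposal standard
#'   deviations.
#' @param adapt_during_burnin adapt proposal scales toward 0.44
#'   acceptance during burn-in (frozen afterwards).
#' @param seed integer seed.
#' @return a `bym_config` list.
#' @export
bym_config <- function(total_iterations = 500000, burn_in = 300000,
                       thin = 20, n_chains = 1,
                       a_u = 0.5, b_u = 0.0005, a_v = 0.5, b_v = 0.0005,
                       intercept_prior_var = 1e6,
                       step_alpha = 0.05, step_u = 0.3, step_v = 0.3,
                       adapt_during_burnin = TRUE, seed = 1) {
  stopifnot(burn_in < total_iterations, thin >= 1, n_chains >= 1,
            a_u > 0, b_u > 0, a_v > 0, b_v > 0, intercept_prior_var > 0)
  structure(list(total_iterations = as.integer(total_iterations),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 n_chains = as.integer(n_chains),
                 a_u = a_u, b_u = b_u, a_v = a_v, b_v = b_v,
                 intercept_prior_var = intercept_prior_var,
                 step_alpha = step_alpha, step_u = step_u, step_v = step_v,
                 adapt_during_burnin = isTRUE(adapt_during_burnin),
                 seed = as.integer(seed)),
            class = "bym_config")
}

#' Number of retained draws implied by an MCMC schedule
#'
#' `floor((total_iterations - burn_in) / thin)`; the published schedule
#' (500,000 / 300,000 / 20) gives 10,000.
#'
#' @param config a [bym_config].
#' @return integer draw count.
#' @export
n_retained <- function(config) {
  (config$total_iterations - config$burn_in) %/% config$thin
}

graph_csr <- function(graph) {
  list(adj = as.integer(unlist(graph$neighbors, use.names = FALSE)) - 1L,
       ptr = as.integer(c(0L, cumsum(graph$degree))),
       comp = as.integer(graph$component_id) - 1L,
       n_comp = graph$n_components)
}

check_no_isolates <- function(graph) {
  iso <- isolates(graph)
  if (length(iso))
    stop("graph has neighborless area(s): ", paste(iso, collapse = ", "),
         ". The ICAR prior is undefined for isolates; connect each one ",
         "explicitly with assign_neighbor() before fitting.")
}

#' Initialize the chain state
#'
#' Starts at the maximum-likelihood intercept `alpha = log(sum O / sum
#' E)` with all random effects zero and unit precisions.
#'
#' @param O,E observed and expected counts.
#' @param graph the `adjacency_graph`.
#' @return a `bym_state` list (`alpha`, `u`, `v`, `tau_u`, `tau_v`).
#' @export
initialize_state <- function(O, E, graph) {
  stopifnot(all(E > 0), length(O) == length(E),
            length(O) == length(graph$area_ids))
  if (sum(O) == 0) {
    warning("no events observed; flooring alpha at -10")
    alpha <- -10
  } else {
    alpha <- log(sum(O) / sum(E))
  }
  structure(list(alpha = alpha, u = numeric(length(O)),
                 v = numeric(length(O)), tau_u = 1, tau_v = 1),
            class = "bym_state")
}

#' Unnormalized log posterior of the BYM model
#'
#' Poisson log likelihood plus the intrinsic CAR prior on `u` (with its
#' rank-deficient normalizing power `(n - G)/2` on `tau_u`), the
#' exchangeable normal prior on `v`, the vague normal intercept prior,
#' and the Gamma hyperpriors, up to additive constants.
#'
#' @param state a `bym_state`.
#' @param O,E observed and expected counts.
#' @param graph the `adjacency_graph` (no isolates).
#' @param config a [bym_config].
#' @return scalar log density (unnormalized).
#' @export
log_posterior <- function(state, O, E, graph, config) {
  check_no_isolates(graph)
  n <- length(O)
  G <- graph$n_components
  eta <- state$alpha + state$u + state$v
  loglik <- sum(O * eta - E * exp(eta))
  ii <- rep(seq_along(graph$neighbors), graph$degree)
  jj <- unlist(graph$neighbors, use.names = FALSE)
  pair_ss <- sum((state$u[ii] - state$u[jj])^2) / 2  # each pair once
  loglik +
    (n - G) / 2 * log(state$tau_u) - state$tau_u / 2 * pair_ss +
    n / 2 * log(state$tau_v) - state$tau_v / 2 * sum(state$v^2) -
    state$alpha^2 / (2 * config$intercept_prior_var) +
    (config$a_u - 1) * log(state$tau_u) - config$b_u * state$tau_u +
    (config$a_v - 1) * log(state$tau_v) - config$b_v * state$tau_v
}

#' Conjugate Gibbs draw of the two precisions
#'
#' `tau_v ~ Gamma(a_v + n/2, b_v + sum(v^2)/2)` and
#' `tau_u ~ Gamma(a_u + (n - G)/2, b_u + sum_{i~j}(u_i - u_j)^2 / 2)`
#' (unordered neighbor pairs).  Draws use the current R RNG stream.
#'
#' @inheritParams log_posterior
#' @return the state with updated `tau_u`, `tau_v`.
#' @export
gibbs_update_tau <- function(state, graph, config) {
  n <- length(state$u)
  G <- graph$n_components
  ii <- rep(seq_along(graph$neighbors), graph$degree)
  jj <- unlist(graph$neighbors, use.names = FALSE)
  pair_ss <- sum((state$u[ii] - state$u[jj])^2) / 2
  state$tau_v <- rgamma(1, config$a_v + n / 2,
                        rate = config$b_v + sum(state$v^2) / 2)
  state$tau_u <- rgamma(1, config$a_u + (n - G) / 2,
                        rate = config$b_u + pair_ss / 2)
  state
}

#' One Metropolis sweep over alpha, u and v
#'
#' Random-walk Metropolis updates of the intercept and each random
#' effect against their full conditionals, followed by per-component
#' recentring of `u` (sum-to-zero) with the subtracted mean absorbed
#' into `alpha`.  Precisions are held fixed.  Uses the current R RNG
#' stream.
#'
#' @inheritParams log_posterior
#' @return the updated `bym_state`.
#' @export
mh_update_effects <- function(state, O, E, graph, config) {
  check_no_isolates(graph)
  csr <- graph_csr(graph)
  n <- length(O)
  res <- bym_mcmc_cpp(as.numeric(O), as.numeric(E), csr$adj, csr$ptr,
                      csr$comp, csr$n_comp,
                      n_iter = 1L, burn_in = 0L, thin = 1L,
                      config$a_u, config$b_u, config$a_v, config$b_v,
                      config$intercept_prior_var,
                      config$step_alpha, rep(config$step_u, n),
                      rep(config$step_v, n), FALSE,
                      state$alpha, state$u, state$v,
                      state$tau_u, state$tau_v,
                      update_tau_u = FALSE, update_tau_v = FALSE,
                      store_uv = FALSE)
  state$alpha <- res$final_alpha
  state$u <- res$final_u
  state$v <- res$final_v
  state
}

#' Fit the BYM model by Metropolis-within-Gibbs
#'
#' Runs the configured schedule on observed/expected areal counts and an
#' adjacency graph, returning retained posterior draws of the intercept,
#' the precisions, and the per-area relative risks
#' `theta_i = exp(alpha + u_i + v_i)`.  Proposal scales adapt toward
#' 0.44 acceptance during burn-in and are frozen afterwards, so the
#' retained draws target the exact posterior.  Deterministic given
#' `config$seed`.
#'
#' @param O,E observed and expected counts (E > 0).
#' @param graph `adjacency_graph` without isolates.
#' @param config a [bym_config].
#' @param fix_tau_u,fix_tau_v optionally hold a precision fixed at the
#'   given value (used for oracle checks); `NULL` (default) samples it.
#' @param store_uv keep the per-draw `u` and `v` matrices.
#' @return a `bym_draws` object: list with `theta` (draws x areas
#'   matrix, columns named by area), `alpha`, `tau_u`, `tau_v` vectors,
#'   acceptance rates, the final state and the config.
#' @export
fit_bym <- function(O, E, graph, config = bym_config(),
                    fix_tau_u = NULL, fix_tau_v = NULL, store_uv = FALSE) {
  stopifnot(all(E > 0), length(O) == length(E),
            length(O) == length(graph$area_ids))
  check_no_isolates(graph)
  state <- initialize_state(O, E, graph)
  if (!is.null(fix_tau_u)) state$tau_u <- fix_tau_u
  if (!is.null(fix_tau_v)) state$tau_v <- fix_tau_v
  lp0 <- log_posterior(state, O, E, graph, config)
  if (!is.finite(lp0))
    stop("non-finite log posterior at initialization; state: alpha = ",
         state$alpha, ", tau_u = ", state$tau_u, ", tau_v = ", state$tau_v)
  csr <- graph_csr(graph)
  n <- length(O)
  set.seed(config$seed)
  res <- bym_mcmc_cpp(as.numeric(O), as.numeric(E), csr$adj, csr$ptr,
                      csr$comp, csr$n_comp,
                      config$total_iterations, config$burn_in, config$thin,
                      config$a_u, config$b_u, config$a_v, config$b_v,
                      config$intercept_prior_var,
                      config$step_alpha, rep(config$step_u, n),
                      rep(config$step_v, n), config$adapt_during_burnin,
                      state$alpha, state$u, state$v,
                      state$tau_u, state$tau_v,
                      update_tau_u = is.null(fix_tau_u),
                      update_tau_v = is.null(fix_tau_v),
                      store_uv = store_uv)
  colnames(res$theta) <- graph$area_ids
  out <- list(theta = res$theta, alpha = res$alpha,
              tau_u = res$tau_u, tau_v = res$tau_v,
              u = if (store_uv) res$u else NULL,
              v = if (store_uv) res$v else NULL,
              acceptance = list(alpha = res$acc_alpha, u = res$acc_u,
                                v = res$acc_v),
              final_state = structure(
                list(alpha = res$final_alpha, u = res$final_u,
                     v = res$final_v, tau_u = res$final_tau_u,
                     tau_v = res$final_tau_v), class = "bym_state"),
              area_ids = graph$area_ids, config = config)
  class(out) <- "bym_draws"
  out
}

#' @export
print.bym_draws <- function(x, ...) {
  cat("bym_draws:", nrow(x$theta), "retained draws,",
      ncol(x$theta), "areas\n")
  cat("  schedule:", x$config$total_iterations, "iterations, burn-in",
      x$config$burn_in, ", thin", x$config$thin, "\n")
  cat("  mean acceptance: alpha", round(x$acceptance$alpha, 2),
      "| u", round(mean(x$acceptance$u), 2),
      "| v", round(mean(x$acceptance$v), 2), "\n")
  invisible(x)
}

#' Serialize retained draws and a run manifest
#'
#' Writes one row per retained draw (alpha, tau_u, tau_v, per-area
#' theta) as CSV, plus a JSON manifest recording the configuration,
#' seed and acceptance rates.
#'
#' @param draws a `bym_draws` object.
#' @param path CSV output path (manifest written alongside with
#'   extension `.manifest.json`).
#' @return `path`, invisibly.
#' @export
write_draws <- function(draws, path) {
  df <- data.frame(alpha = draws$alpha, tau_u = draws$tau_u,
                   tau_v = draws$tau_v,
                   draws$theta, check.names = FALSE)
  names(df) <- c("alpha", "tau_u", "tau_v",
                 paste0("theta.", draws$area_ids))
  write.csv(df, path, row.names = FALSE)
  manifest <- list(config = unclass(draws$config),
                   n_retained = nrow(draws$theta),
                   acceptance = list(alpha = draws$acceptance$alpha,
                                     u_mean = mean(draws$acceptance$u),
                                     v_mean = mean(draws$acceptance$v)))
  jsonlite::write_json(manifest, sub("\\.csv$", ".manifest.json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
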