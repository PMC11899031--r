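# Spectral density at frequency zero, estimated by a modified-Daniell
# smoothed periodogram.  Scaled so that for white noise the estimate
# approaches var(x); sqrt(S0/n) is then the long-run standard error of
# the chain mean.
spectrum0 <- function(x) {
  n <- length(x)
  span <- max(3, 2 * floor(sqrt(n) / 2) + 1)  # odd, ~sqrt(n)
  sp <- spec.pgram(x, spans = span, taper = 0.1, detrend = FALSE,
                   demean = TRUE, plot = FALSE)
  # average the lowest few smoothed ordinates as the f(0) estimate
  k <- max(1, min(5, length(sp$spec)))
  mean(sp$spec[seq_len(k)])
}

#' Geweke convergence diagnostic
#'
#' Standardized difference between the mean of the first `first`
#' fraction and the last `last` fraction of a chain,
#' `z = (mean_A - mean_B) / sqrt(S_A/n_A + S_B/n_B)`, where `S` is the
#' spectral density at frequency zero estimated within each window by a
#' modified-Daniell smoothed periodogram.  Approximately standard normal
#' for a stationary chain.
#'
#' @param chain numeric vector (length >= 100).
#' @param first,last window fractions (defaults 0.1 and 0.5, the Geweke
#'   convention).
#' @return list with `z`, `first`, `last`.
#' @export
geweke_z <- function(chain, first = 0.1, last = 0.5) {
  stopifnot(length(chain) >= 100, first > 0, last > 0, first + last <= 1)
  if (var(chain) == 0) stop("degenerate chain: zero variance")
  n <- length(chain)
  a <- chain[seq_len(floor(first * n))]
  b <- chain[seq.int(n - floor(last * n) + 1, n)]
  z <- (mean(a) - mean(b)) /
    sqrt(spectrum0(a) / length(a) + spectrum0(b) / length(b))
  list(z = z, first = first, last = last)
}

#' Chain autocorrelation
#'
#' Biased (divide-by-n) autocorrelation estimates up to `max_lag`;
#' lag 0 is exactly 1.
#'
#' @param chain numeric vector.
#' @param max_lag maximum lag (< length/2).
#' @return numeric vector of length `max_lag + 1` (lags 0..max_lag).
#' @export
autocorr <- function(chain, max_lag) {
  stopifnot(max_lag < length(chain) / 2)
  if (var(chain) == 0) stop("degenerate chain: zero variance")
  as.vector(acf(chain, lag.max = max_lag, plot = FALSE,
                demean = TRUE)$acf)
}

#' Effective sample size
#'
#' `n / (1 + 2 * sum r(k))`, the autocorrelation sum truncated at the
#' first lag pair whose sum `r(2t-1) + r(2t)` is negative (Geyer's
#' initial-positive rule), and the result floored at 1.
#'
#' @param chain numeric vector (length >= 100).
#' @return effective sample size (1 <= ESS <= n).
#' @export
effective_sample_size <- function(chain) {
  stopifnot(length(chain) >= 100)
  if (var(chain) == 0) stop("degenerate chain: zero variance")
  n <- length(chain)
  r <- autocorr(chain, max_lag = min(n %/% 2 - 1, 2000))[-1]
  s <- 0
  t <- 1
  while (t + 1 <= length(r)) {
    pair <- r[t] + r[t + 1]
    if (pair < 0) break
    s <- s + pair
    t <- t + 2
  }
  max(1, min(n, n / (1 + 2 * s)))
}

#' Convergence report for a fitted BYM model
#'
#' Geweke z, effective sample size and lag-1 autocorrelation for the
#' intercept, both precisions and a subset of area-level relative
#' risks (default: the five areas with the largest expected counts, to
#' bound cost).  The |z| < 2 threshold is a reported flag, not an
#' enforcement.
#'
#' @param draws a `bym_draws` object.
#' @param E expected counts (used to pick the monitored areas); if
#'   `NULL` the first `n_theta` areas are monitored.
#' @param n_theta number of area parameters to monitor.
#' @param z_flag |z| threshold used for the `flagged` column.
#' @return data.frame `parameter`, `geweke_z`, `ess`, `acf1`, `flagged`.
#' @export
diagnose_draws <- function(draws, E = NULL, n_theta = 5, z_flag = 2) {
  stopifnot(inherits(draws, "bym_draws"))
  sel <- if (is.null(E)) seq_len(min(n_theta, ncol(draws$theta)))
         else order(E, decreasing = TRUE)[seq_len(min(n_theta, length(E)))]
  chains <- c(list(alpha = draws$alpha, tau_u = draws$tau_u,
                   tau_v = draws$tau_v),
              setNames(lapply(sel, function(i) draws$theta[, i]),
                       paste0("theta.", draws$area_ids[sel])))
  out <- do.call(rbind, lapply(names(chains), function(nm) {
    x <- chains[[nm]]
    z <- tryCatch(geweke_z(x)$z, error = function(e) NA_real_)
    data.frame(parameter = nm, geweke_z = z,
               ess = effective_sample_size(x),
               acf1 = autocorr(x, 1)[2],
               flagged = is.finite(z) && abs(z) > z_flag,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
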