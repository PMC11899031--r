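path3 <- function() build_rook_adjacency(make_lattice_geography(1, 3))

test_that("retained-draw count follows the schedule identity", {
  cases <- list(c(500000, 300000, 20, 10000),
                c(20000, 10000, 10, 1000),
                c(1001, 1000, 1, 1),
                c(50000, 25000, 7, 3571))
  for (cs in cases) {
    cfg <- bym_config(total_iterations = cs[1], burn_in = cs[2],
                      thin = cs[3])
    expect_equal(n_retained(cfg), cs[4])
  }
  expect_error(bym_config(total_iterations = 100, burn_in = 100))
})

test_that("initialization starts at the pooled-rate intercept", {
  g <- path3()
  E <- c(10, 20, 30)
  s1 <- initialize_state(E, E, g)
  expect_equal(s1$alpha, 0)
  s2 <- initialize_state(2 * E, E, g)
  expect_equal(s2$alpha, log(2))
  expect_true(all(s2$u == 0) && all(s2$v == 0))
  cfg <- bym_config()
  expect_true(is.finite(log_posterior(s2, 2 * E, E, g, cfg)))
  expect_warning(s0 <- initialize_state(c(0, 0, 0), E, g), "no events")
  expect_equal(s0$alpha, -10)
})

test_that("log posterior matches closed-form values and algebra", {
  g <- path3()
  E <- c(5, 7, 9)
  cfg <- bym_config(a_u = 0.5, b_u = 0.0005, a_v = 0.5, b_v = 0.0005)
  st <- initialize_state(E, E, g)  # alpha = 0, u = v = 0, taus = 1
  # Poisson term collapses to -sum(E); tau terms: log(1) = 0, -b tau
  expect_equal(log_posterior(st, E, E, g, cfg),
               -sum(E) - cfg$b_u - cfg$b_v)

  st2 <- st
  st2$tau_v <- 2
  n <- 3
  delta <- (n / 2) * log(2) + (cfg$a_v - 1) * log(2) - cfg$b_v * (2 - 1)
  expect_equal(log_posterior(st2, E, E, g, cfg) -
                 log_posterior(st, E, E, g, cfg), delta)
})

test_that("analytic u-gradient of the log posterior matches finite differences", {
  g <- build_rook_adjacency(make_lattice_geography(2, 3))
  set.seed(31)
  E <- runif(6, 5, 50)
  O <- rpois(6, E)
  cfg <- bym_config()
  st <- initialize_state(O, E, g)
  st$u <- rnorm(6, 0, 0.3)
  st$v <- rnorm(6, 0, 0.2)
  st$tau_u <- 1.7
  st$tau_v <- 2.4
  h <- 1e-6
  for (i in c(1, 4, 6)) {
    eta <- st$alpha + st$u[i] + st$v[i]
    grad <- O[i] - E[i] * exp(eta) -
      st$tau_u * sum(st$u[i] - st$u[g$neighbors[[i]]])
    up <- st; up$u[i] <- up$u[i] + h
    dn <- st; dn$u[i] <- dn$u[i] - h
    num <- (log_posterior(up, O, E, g, cfg) -
              log_posterior(dn, O, E, g, cfg)) / (2 * h)
    expect_equal(num, grad, tolerance = 1e-4)
  }
})

test_that("precision updates are exact conjugate Gamma draws", {
  g <- build_rook_adjacency(make_lattice_geography(3, 3))
  cfg <- bym_config(a_u = 0.5, b_u = 0.0005, a_v = 2, b_v = 3)
  st <- initialize_state(rep(10, 9), rep(10, 9), g)
  # v = 0: tau_v ~ Gamma(a_v + n/2, b_v); check both moments
  set.seed(99)
  draws <- replicate(10000, gibbs_update_tau(st, g, cfg)$tau_v)
  shape <- cfg$a_v + 9 / 2
  m <- shape / cfg$b_v
  v <- shape / cfg$b_v^2
  expect_lt(abs(mean(draws) - m), 3 * sqrt(v / 10000))
  expect_lt(abs(var(draws) - v), 3 * v * sqrt(2 / 9999) * 1.5)

  # u constant per component: pairwise sum is 0, so the rate is b_u
  st2 <- st
  st2$u <- rep(0.7, 9)
  set.seed(100)
  tu <- replicate(5000, gibbs_update_tau(st2, g, cfg)$tau_u)
  shape_u <- cfg$a_u + (9 - 1) / 2
  expect_lt(abs(mean(tu) - shape_u / cfg$b_u),
            3 * sqrt(shape_u / cfg$b_u^2 / 5000))

  set.seed(7)
  a <- gibbs_update_tau(st, g, cfg)
  set.seed(7)
  b <- gibbs_update_tau(st, g, cfg)
  expect_identical(a, b)
})

test_that("metropolis sweep degenerates gracefully and recentres u", {
  g <- build_rook_adjacency(make_lattice_geography(2, 3))
  set.seed(5)
  E <- rep(20, 6)
  O <- rpois(6, 20)
  cfg0 <- bym_config(step_alpha = 1e-13, step_u = 1e-13, step_v = 1e-13)
  st <- initialize_state(O, E, g)
  st$u <- rnorm(6, 0, 0.2)
  st$u <- st$u - mean(st$u)
  set.seed(1)
  out <- mh_update_effects(st, O, E, g, cfg0)
  expect_equal(out$alpha + mean(out$u), st$alpha, tolerance = 1e-10)
  expect_equal(out$u - mean(out$u), st$u - mean(st$u), tolerance = 1e-10)

  cfg <- bym_config(step_alpha = 0.2, step_u = 0.5, step_v = 0.5)
  set.seed(2)
  st2 <- st
  for (k in 1:20) st2 <- mh_update_effects(st2, O, E, g, cfg)
  expect_lt(abs(sum(st2$u)), 1e-10)
})

test_that("fitting errors on isolates with a remedy and on bad input", {
  poly <- disjoint_strips()
  sq <- rbind(c(30, 0), c(31, 0), c(31, 1), c(30, 1), c(30, 0))
  poly2 <- area_polygons(c(poly$area_ids, "ISL"),
                         c(poly$geometries, list(list(sq))))
  g <- build_rook_adjacency(poly2)
  expect_error(fit_bym(rep(5, 5), rep(5, 5), g), "assign_neighbor")
})

test_that("posterior concentrates near 1 when observed equals expected", {
  g <- build_rook_adjacency(make_lattice_geography(1, 2))
  cfg <- bym_config(total_iterations = 20000, burn_in = 5000, thin = 5,
                    seed = 17)
  fit <- fit_bym(c(1000, 1000), c(1000, 1000), g, cfg)
  s <- summarize_draws(fit)
  expect_true(all(s$median > 0.95 & s$median < 1.05))
})

test_that("fits are bit-reproducible for a fixed seed", {
  g <- build_rook_adjacency(make_lattice_geography(3, 3))
  set.seed(3)
  E <- rep(30, 9)
  O <- rpois(9, 40)
  cfg <- bym_config(total_iterations = 3000, burn_in = 1000, thin = 2,
                    seed = 11)
  f1 <- fit_bym(O, E, g, cfg)
  f2 <- fit_bym(O, E, g, cfg)
  expect_identical(f1$theta, f2$theta)
  expect_identical(f1$alpha, f2$alpha)
  cfg2 <- cfg; cfg2$seed <- 12L
  expect_false(identical(fit_bym(O, E, g, cfg2)$theta, f1$theta))
})

test_that("small-E areas shrink more toward the global mean", {
  # spatial effect suppressed: shrinkage toward exp(alpha) is stronger
  # where the likelihood is weaker (small expected counts)
  g <- build_rook_adjacency(make_lattice_geography(1, 4))
  E <- c(10, 1000, 10, 1000)
  O <- c(20, 2000, 5, 500)  # raw ratios 2, 2, 0.5, 0.5
  cfg <- bym_config(total_iterations = 30000, burn_in = 10000, thin = 4,
                    seed = 23)
  fit <- fit_bym(O, E, g, cfg, fix_tau_u = 1e8)
  s <- summarize_draws(fit)
  # same raw ratio, weaker likelihood: the small-E area sits closer to 1
  expect_gt(abs(log(s$median[1]) - log(2)), abs(log(s$median[2]) - log(2)))
  expect_gt(abs(log(s$median[3]) - log(0.5)),
            abs(log(s$median[4]) - log(0.5)))
})
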