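test_that("lattice geography has the expected areas and contiguity", {
  p12 <- make_lattice_geography(1, 2)
  g12 <- build_rook_adjacency(p12)
  expect_equal(g12$area_ids, c("r1c1", "r1c2"))
  expect_equal(g12$degree, c(1L, 1L))

  g33 <- build_rook_adjacency(make_lattice_geography(3, 3))
  expect_equal(sum(g33$degree) / 2, 12)

  g11 <- build_rook_adjacency(make_lattice_geography(1, 1))
  expect_equal(g11$degree, 0L)
  expect_equal(isolates(g11), "r1c1")
})

test_that("ICAR draws satisfy the per-component sum-to-zero constraint", {
  g <- build_rook_adjacency(make_lattice_geography(4, 4))
  u <- simulate_icar_field(g, tau_u = 2, seed = 7)
  expect_lt(abs(sum(u)), 1e-10)

  # disconnected geometry: each component sums to zero separately
  strips <- disjoint_strips()
  gs <- build_rook_adjacency(strips)
  us <- simulate_icar_field(gs, tau_u = 1, seed = 3)
  for (comp in unique(gs$component_id)) {
    expect_lt(abs(sum(us[gs$component_id == comp])), 1e-10)
  }

  g1 <- build_rook_adjacency(make_lattice_geography(1, 1))
  expect_error(simulate_icar_field(g1, 1, 1), "assign_neighbor")
})

test_that("two-area ICAR marginal variance matches the closed form 1/4", {
  # pairwise density exp(-tau/2 (u1-u2)^2) with u1 + u2 = 0 gives
  # u1 ~ N(0, 1/(4 tau)); at tau = 1 the variance is 0.25
  g <- build_rook_adjacency(make_lattice_geography(1, 2))
  draws <- vapply(1:10000, function(s) simulate_icar_field(g, 1, s)[1],
                  numeric(1))
  expect_lt(abs(mean(draws)), 0.02)
  # MC error on a variance estimate: sd ~ sqrt(2/n) * var = 0.0035
  expect_lt(abs(var(draws) - 0.25), 0.012)
})

test_that("ICAR smoothness scales inversely with the precision", {
  g <- build_rook_adjacency(make_lattice_geography(10, 10))
  ii <- rep(seq_along(g$neighbors), g$degree)
  jj <- unlist(g$neighbors)
  msnd <- function(tau, seeds) {
    vapply(seeds, function(s) {
      u <- simulate_icar_field(g, tau, s)
      mean((u[ii] - u[jj])^2)
    }, numeric(1))
  }
  m1 <- mean(msnd(1, 1:500))
  m4 <- mean(msnd(4, 501:1000))
  expect_lt(abs(m1 / m4 - 4), 0.5)
})

test_that("ICAR distribution is invariant under area relabeling", {
  # generating from a graph whose areas are listed in a different order
  # must give the same distribution of any field summary statistic
  poly <- make_lattice_geography(3, 3)
  g <- build_rook_adjacency(poly)
  set.seed(42)
  perm <- sample(9)
  poly_perm <- area_polygons(poly$area_ids[perm], poly$geometries[perm])
  g_perm <- build_rook_adjacency(poly_perm)
  stat <- function(graph, seeds) {
    vapply(seeds, function(s) {
      u <- simulate_icar_field(graph, 1, s)
      c(sd(u), mean(abs(u)))
    }, numeric(2))
  }
  s1 <- stat(g, 1:400)
  s2 <- stat(g_perm, 401:800)
  expect_lt(abs(mean(s1[1, ]) - mean(s2[1, ])), 0.08)
  expect_lt(abs(mean(s1[2, ]) - mean(s2[2, ])), 0.08)
})

test_that("simulated counts have Poisson moments and are reproducible", {
  n <- 100
  E <- rep(1000, n)
  sim <- simulate_counts(E, alpha = 0, u = numeric(n), tau_v = 1e8, seed = 5)
  expect_lt(abs(mean(sim$observed / E) - 1), 3 / sqrt(n * 1000) * 3)
  # with tau_v huge the log-ratio variance is Poisson-only, about 1/E
  expect_lt(var(log(sim$observed / E)), 3 / 1000)

  sim2 <- simulate_counts(E, alpha = 0, u = numeric(n), tau_v = 1e8, seed = 5)
  expect_identical(sim$observed, sim2$observed)
  sim3 <- simulate_counts(E, alpha = 0, u = numeric(n), tau_v = 1e8, seed = 6)
  expect_false(identical(sim$observed, sim3$observed))
})

test_that("populations respect the configured law", {
  expect_true(all(make_populations(50, 1000, 1000, seed = 2) == 1000))
  p <- make_populations(78, seed = 4)
  expect_true(all(p >= 500 & p <= 500000))
  expect_identical(p, make_populations(78, seed = 4))
})

test_that("registry fixture reproduces the cohort marginals for any seed", {
  for (seed in c(1, 99)) {
    reg <- make_registry_fixture(seed = seed)
    expect_equal(nrow(reg), 23917)
    expect_equal(sum(reg$age < 15), 5)
    expect_equal(sum(reg$site_code == "C10.4"), 2)
    expect_equal(sum(startsWith(reg$site_code, "C14")), 57)

    inc <- apply_exclusions(reg)$included
    expect_equal(nrow(inc), 23853)
    expect_equal(as.integer(table(inc$sex)[c("male", "female")]),
                 c(18491L, 5362L))
    band <- table(cut(inc$age, c(-Inf, 39, 64, Inf)))
    expect_equal(unname(as.integer(band)), c(1349L, 12077L, 10427L))
    site <- table(group_sites(inc$site_code))
    expect_equal(site[["lip"]], 6512)
    expect_equal(site[["oral_cavity"]], 6166)
    expect_equal(site[["oropharynx"]], 5118)
    expect_equal(site[["nasopharynx"]], 334)
    expect_equal(site[["hypopharynx"]], 1261)
    expect_equal(site[["larynx"]], 4024)
    expect_equal(site[["nasal_paranasal"]], 374)
    expect_equal(site[["salivary"]], 64)
    expect_equal(sum(is.na(inc$death_date)), 9721)
    expect_equal(sum(!is.na(inc$death_date)), 14132)
  }
})

test_that("fixture survival windows carry the exact death counts", {
  reg <- get_fixture()
  inc <- apply_exclusions(reg)$included
  surv <- as.numeric(inc$death_date - inc$diagnosis_date) / 30.4375
  expect_true(all(surv >= 0, na.rm = TRUE))
  expect_equal(sum(surv <= 60, na.rm = TRUE), 8338)
  expect_equal(sum(surv <= 36, na.rm = TRUE), 6714)
  expect_true(max(surv, na.rm = TRUE) <= 483)
})
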