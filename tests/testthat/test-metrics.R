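test_that("degree and strength match hand-computed values", {
  # star: center connected to 5 leaves with unit weights
  w <- matrix(0, 6, 6); w[1, 2:6] <- 1; w <- w + t(w) * 0; w[2:6, 1] <- 1
  g <- weighted_graph(w)
  ds <- degree_strength(g)
  expect_equal(ds$degree, c(5L, rep(1L, 5)))
  expect_equal(ds$degree_norm, c(1, rep(0, 5)))

  # path a-b-c with weights 0.5, 1.0
  wp <- matrix(0, 3, 3)
  wp[1, 2] <- wp[2, 1] <- 0.5; wp[2, 3] <- wp[3, 2] <- 1.0
  expect_equal(degree_strength(weighted_graph(wp))$strength, c(0.5, 1.5, 1.0))

  # degenerate: uniform complete graph -> all normalized to 1 with warning
  gu <- weighted_graph(matrix(0.4, 4, 4) - diag(0.4, 4))
  expect_warning(expect_warning(dsu <- degree_strength(gu), "degenerate"),
                 "degenerate")  # one warning each for degree and strength
  expect_equal(dsu$strength_norm, rep(1, 4))
})

test_that("clustering matches spec fixtures", {
  gu <- weighted_graph(matrix(1, 4, 4) - diag(4))
  expect_equal(clustering_coefficient(gu)$local, rep(1, 4),
               ignore_attr = TRUE)
  expect_equal(clustering_coefficient(gu)$global, 1)

  # triangle 0.8 / 0.4 / 0.2: after max-scaling every c_i = (1*0.5*0.25)^(1/3)
  w <- matrix(0, 3, 3)
  w[1, 2] <- w[2, 1] <- 0.8; w[1, 3] <- w[3, 1] <- 0.4
  w[2, 3] <- w[3, 2] <- 0.2
  expect_equal(clustering_coefficient(weighted_graph(w))$local,
               rep(0.5, 3), ignore_attr = TRUE)

  # star: no triangles
  ws <- matrix(0, 5, 5); ws[1, 2:5] <- 1; ws[2:5, 1] <- 1
  expect_equal(clustering_coefficient(weighted_graph(ws))$local, rep(0, 5),
               ignore_attr = TRUE)
})

test_that("global efficiency matches enumerated shortest paths", {
  gu <- weighted_graph(matrix(1, 4, 4) - diag(4))
  expect_equal(global_efficiency(gu), 1.0)

  wp <- matrix(0, 3, 3)
  wp[1, 2] <- wp[2, 1] <- 1; wp[2, 3] <- wp[3, 2] <- 1
  expect_equal(global_efficiency(weighted_graph(wp)), (1 + 1 + 0.5) / 3)

  # disconnected pair contributes zero
  w0 <- matrix(0, 3, 3); w0[1, 2] <- w0[2, 1] <- 1
  expect_equal(global_efficiency(weighted_graph(w0)), (1 + 1) / 6)
})

test_that("clustering and efficiency agree with brute force on random graphs", {
  for (seed in 1:15) {
    n <- sample(4:8, 1)
    g <- rand_graph(n, density = runif(1, 0.3, 0.9), seed = seed + 100)
    expect_equal(unname(clustering_coefficient(g)$local),
                 bf_clustering(g$weights), tolerance = 1e-10)
    expect_equal(global_efficiency(g), bf_efficiency(g$weights),
                 tolerance = 1e-10)
    ci <- clustering_coefficient(g)$local
    expect_true(all(ci >= 0 & ci <= 1))
  }
})

test_that("null ensembles preserve degree sequence and weight multiset", {
  g <- rand_graph(40, density = 0.4, seed = 2)
  ens <- null_ensemble(g, count = 10, seed = 5)
  deg0 <- sort(rowSums(g$weights > 0))
  wts0 <- sort(g$weights[upper.tri(g$weights)])
  for (nl in ens) {
    expect_identical(sort(rowSums(nl$weights > 0)), deg0)
    expect_equal(sort(nl$weights[upper.tri(nl$weights)]), wts0,
                 tolerance = 1e-12)
  }
})

test_that("null ensembles approximately preserve strength on hub graphs", {
  spec <- simulation_spec(n_nodes = 60, n_subjects = 2, n_time = 150,
                          n_modules = 4, hub_cross_loading = 0.2,
                          condition_gain = 1)
  p <- panels_of(simulate_panel(spec, seed = 3), "rest")[[1]]
  g <- threshold_to_density(correlation_graph(p), 0.5)
  ens <- null_ensemble(g, count = 20, seed = 9)
  expect_lt(mean(attr(ens, "strength_error")), 0.10)
})

test_that("complete graphs fall back to weight shuffling with a warning", {
  a <- matrix(runif(25, 0.1, 1), 5, 5)
  g <- weighted_graph(a + t(a))
  expect_warning(ens <- null_ensemble(g, count = 3, seed = 1), "rewiring")
  expect_equal(sort(ens[[1]]$weights[upper.tri(ens[[1]]$weights)]),
               sort(g$weights[upper.tri(g$weights)]))
})

test_that("small-world index follows its defining ratio and sigma identities", {
  expect_equal(small_world_index(1, 1), 1)
  expect_equal(small_world_index(1.56, 1.0), 1.56)
  expect_error(small_world_index(0, 1), "positive")

  # sigma of a graph normalized against itself is exactly 1
  g <- rand_graph(20, density = 0.5, seed = 8)
  C <- clustering_coefficient(g)$global
  E <- global_efficiency(g)
  expect_identical(small_world_index(C / C, E / E), 1)
})

test_that("a lattice-with-shortcuts graph is small-world against its nulls", {
  g <- lattice_shortcut_graph(n = 30, k = 2, shortcuts = 6, seed = 5)
  rep <- metric_report(g, nulls = 30, seed = 17)
  expect_gt(rep$sigma, 1)
})

test_that("metric reports across a schedule echo densities and are reproducible", {
  g <- rand_graph(40, density = 0.9, seed = 13)
  graphs <- apply_schedule(g, density_schedule(c(0.4, 0.5, 0.6)))
  reps <- metrics_over_schedule(graphs, nulls = 5, seed = 3)
  expect_length(reps, 3)
  expect_equal(vapply(reps, `[[`, 0, "density"), c(0.4, 0.5, 0.6),
               ignore_attr = TRUE, tolerance = 1e-9)
  reps2 <- metrics_over_schedule(graphs, nulls = 5, seed = 3)
  expect_identical(vapply(reps, `[[`, 0, "sigma"),
                   vapply(reps2, `[[`, 0, "sigma"))
  # nested construction on a modular graph: C stays bounded and varies
  # smoothly (adding weaker edges dilutes the geometric-mean triangles,
  # so C drifts monotonically rather than jumping)
  spec <- simulation_spec(n_nodes = 40, n_subjects = 2, n_time = 150,
                          n_modules = 4)
  gm <- correlation_graph(panels_of(simulate_panel(spec, seed = 2),
                                    "rest")[[1]])
  gs <- apply_schedule(gm, density_schedule(seq(0.3, 0.7, 0.1)))
  cc <- vapply(gs, function(x) clustering_coefficient(x)$global, 0)
  expect_true(all(cc > 0 & cc <= 1))
  expect_true(all(diff(cc) <= 1e-9))
})
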