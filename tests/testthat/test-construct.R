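make_panel <- function(x, ...) roi_panel(as.matrix(x), ...)

test_that("correlation graphs clamp negatives and match hand-computed r", {
  x <- cbind(a = c(1, 2, 3, 4), b = c(2, 4, 6, 8), c = c(-1, -2, -3, -4),
             d = c(1, 3, 2, 4))
  g <- correlation_graph(make_panel(x))
  expect_equal(g$weights["a", "b"], 1.0)
  expect_equal(g$weights["a", "c"], 0)          # r = -1, clamped
  expect_equal(g$weights["a", "d"], 4.0 / 5.0)  # hand-computed Pearson r
  expect_gte(attr(g, "negative_count"), 1)
})

test_that("correlation graphs are invariant to affine rescaling of series", {
  set.seed(21)
  x <- matrix(rnorm(200), 20, 10)
  g1 <- correlation_graph(make_panel(x))
  x2 <- sweep(sweep(x, 2, runif(10, 0.5, 3), `*`), 2, rnorm(10), `+`)
  g2 <- correlation_graph(make_panel(x2))
  expect_equal(g1$weights, g2$weights, tolerance = 1e-12)
})

test_that("density counts positive upper-triangle entries", {
  w <- matrix(1, 4, 4); diag(w) <- 0
  expect_equal(graph_density(weighted_graph(w)), 1.0)
  w0 <- matrix(0, 4, 4); w0[1, 2] <- w0[2, 1] <- 1e-9
  expect_equal(graph_density(weighted_graph(w0)), 1 / 6)
})

test_that("threshold_to_density keeps the strongest edges and nothing else", {
  w <- matrix(0, 4, 4)
  vals <- c(0.9, 0.8, 0.7, 0.6, 0.5, 0.4)
  w[upper.tri(w)] <- vals
  g <- weighted_graph(w + t(w))
  thr <- threshold_to_density(g, 0.5)
  kept <- sort(thr$weights[upper.tri(thr$weights)][
    thr$weights[upper.tri(thr$weights)] > 0], decreasing = TRUE)
  expect_equal(kept, c(0.9, 0.8, 0.7))
  expect_equal(graph_density(thr), 0.5)

  # identity at the current density; error above it
  expect_equal(threshold_to_density(g, 1)$weights, g$weights)
  half <- threshold_to_density(g, 0.5)
  expect_error(threshold_to_density(half, 0.9), "exceeds")

  # ties at the cut: deterministic lexicographic node-pair rule
  wt <- matrix(0, 4, 4)
  wt[1, 2] <- wt[2, 1] <- 0.5; wt[1, 3] <- wt[3, 1] <- 0.5
  wt[1, 4] <- wt[4, 1] <- 0.5; wt[2, 3] <- wt[3, 2] <- 0.9
  gt <- weighted_graph(wt)
  cut <- threshold_to_density(gt, 2 / 6)
  expect_equal(n_edges(cut), 2L)
  expect_equal(cut$weights[2, 3], 0.9)
  expect_equal(cut$weights[1, 2], 0.5)  # (1,2) beats (1,3), (1,4) on ties
  expect_identical(threshold_to_density(gt, 2 / 6)$weights, cut$weights)
})

test_that("thresholding never increases weights and schedules are nested", {
  g <- rand_graph(30, density = 0.9, seed = 3)
  sched <- density_schedule(seq(0.3, 0.8, by = 0.1))
  graphs <- apply_schedule(g, sched)
  expect_length(graphs, 6)
  for (k in seq_along(graphs)) {
    expect_lte(graph_density(graphs[[k]]), sched[k] + 1e-12)
    expect_true(all(graphs[[k]]$weights <= g$weights + 1e-15))
    if (k > 1) {
      lo <- graphs[[k - 1]]$weights > 0
      hi <- graphs[[k]]$weights > 0
      expect_true(all(hi[lo]))  # nested edge sets
    }
  }
  expect_error(apply_schedule(threshold_to_density(g, 0.5),
                              density_schedule(c(0.4, 0.9))), "0.9")
  expect_error(density_schedule(c(0.5, 0.4)), "increasing")
})

test_that("nodal elimination removes detached and low-degree nodes", {
  # 6-node graph: node 6 has only weak edges that fall below the 50% cut
  w <- matrix(0, 6, 6)
  for (i in 1:5) for (j in 1:5) if (i < j) w[i, j] <- w[j, i] <- 0.8
  w[6, 1] <- w[1, 6] <- 0.01
  g <- weighted_graph(w)
  keep <- eliminate_nodes(list(g), target_density = 0.5,
                          min_degree_frac = 0.05)
  expect_identical(keep, g$labels[1:5])

  # every node strongly connected -> keep all
  keep_all <- eliminate_nodes(list(weighted_graph(
    matrix(0.5, 6, 6) - diag(0.5, 6))), 0.5, 0.05)
  expect_length(keep_all, 6)
})

test_that("planted weak nodes reproduce a 212 -> 150 style reduction", {
  spec <- simulation_spec(n_nodes = 212, n_subjects = 14, n_time = 150,
                          weak_nodes = 151:212)
  panels <- panels_of(simulate_panel(spec, seed = 9), "task")
  graphs <- lapply(panels, correlation_graph)
  keep <- eliminate_nodes(graphs, target_density = 0.5,
                          min_degree_frac = 0.05)
  keep_idx <- match(keep, graphs[[1]]$labels)
  expect_true(all(keep_idx <= 150))           # no weak node survives
  expect_gte(length(keep), 148)               # essentially all normal nodes
})

test_that("group averaging applies the consensus-presence rule", {
  w1 <- matrix(0, 3, 3); w1[1, 2] <- w1[2, 1] <- 0.4
  w2 <- matrix(0, 3, 3); w2[1, 2] <- w2[2, 1] <- 0.6
  w2[1, 3] <- w2[3, 1] <- 0.5
  g1 <- weighted_graph(w1); g2 <- weighted_graph(w2)

  avg <- group_average(list(g1, g2), min_presence = 1.0)
  expect_equal(avg$weights[1, 2], 0.5)  # mean of 0.4 and 0.6
  expect_equal(avg$weights[1, 3], 0)    # present in only 1 of 2 subjects

  avg2 <- group_average(list(g1, g1))
  expect_equal(avg2$weights, g1$weights)

  expect_error(group_average(list()), "empty")
  expect_lte(graph_density(group_average(list(g1, g2))),
             min(graph_density(g1), graph_density(g2)))
})

test_that("random surrogate control preserves degree-distribution shape", {
  set.seed(4)
  graphs <- lapply(1:4, function(k) rand_graph(80, density = 0.7, seed = k))
  rep1 <- random_network_control(graphs, 0.5, 0.05, seed = 11)
  expect_true(abs(rep1$cv_ratio - 1) < 0.2)
  rep2 <- random_network_control(graphs, 0.5, 0.05, seed = 11)
  expect_identical(rep1, rep2)  # deterministic under a fixed seed
})
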