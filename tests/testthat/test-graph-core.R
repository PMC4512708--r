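test_that("weighted_graph enforces symmetry, nonnegativity and zero diagonal", {
  w <- matrix(c(0, 0.5, 0.5, 0), 2, 2)
  g <- weighted_graph(w)
  expect_identical(dim(g$weights), c(2L, 2L))
  expect_equal(g$weights[1, 2], 0.5)

  # random matrices: constructor post-conditions hold
  set.seed(11)
  for (rep in 1:20) {
    n <- sample(3:12, 1)
    a <- matrix(rnorm(n * n), n, n)
    g <- weighted_graph((a + t(a)) / 2)
    expect_true(all(g$weights >= 0))
    expect_true(all(diag(g$weights) == 0))
    expect_identical(g$weights, t(g$weights))
  }

  expect_error(weighted_graph(matrix(0, 3, 4)), "square")
  expect_error(weighted_graph(matrix(1, 1, 1)), "at least 2")
  asym <- matrix(c(0, 1, 0.2, 0), 2, 2)
  expect_error(weighted_graph(asym), "asymmetric")
})

test_that("negative weights are clamped with a recorded count", {
  w <- matrix(c(0, -0.2, 0.4, -0.2, 0, 0.3, 0.4, 0.3, 0), 3, 3)
  g <- weighted_graph(w)
  expect_equal(g$weights[1, 2], 0)
  expect_equal(attr(g, "negative_count"), 2L)  # symmetric pair
})

test_that("matrix files round-trip, clamp negatives, and reject bad shapes", {
  w <- matrix(0, 3, 3)
  w[1, 2] <- w[2, 1] <- 0.5
  w[1, 3] <- w[3, 1] <- 0.5
  w[2, 3] <- w[3, 2] <- 0.5
  g <- weighted_graph(w, labels = c("a", "b", "c"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_matrix(g, path)
  g2 <- read_matrix(path)
  expect_equal(g2$weights, g$weights)
  expect_identical(g2$labels, g$labels)

  # file with a negative entry: clamped, counted
  neg <- matrix(c(1, -0.2, -0.2, 1), 2, 2,
                dimnames = list(c("x", "y"), c("x", "y")))
  p2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.table(data.frame(region = c("x", "y"), neg),
                     p2, sep = ",", quote = FALSE, row.names = FALSE)
  gneg <- read_matrix(p2)
  expect_equal(gneg$weights[1, 2], 0)
  expect_equal(attr(gneg, "negative_count"), 2L)

  # non-square file
  p3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("1\t2\t3\t4", "5\t6\t7\t8", "1\t2\t3\t4"), p3)
  expect_error(read_matrix(p3, labels = NULL), "square|headerless")

  # headerless numeric file requires a label table
  p4 <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(matrix(c(0, 0.3, 0.3, 0), 2, 2), p4, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  expect_error(read_matrix(p4), "label")
  labs <- roi_label_table(c("x", "y"), c("L", "R"), "cortical", 1:2)
  g4 <- read_matrix(p4, labels = labs)
  expect_identical(g4$labels, c("x", "y"))
  # label-count mismatch
  labs3 <- roi_label_table(c("x", "y", "z"), "L", "cortical", 1:3)
  expect_error(read_matrix(p4, labels = labs3), "rows")
})

test_that("partitions canonicalize with node #1 anchoring and round-trip", {
  expect_identical(node_partition(c(2, 2, 1, 1))$assignment, c(1L, 1L, 2L, 2L))
  expect_identical(node_partition(c(1, 3, 3, 1))$assignment, c(1L, 2L, 2L, 1L))
  expect_equal(node_partition(c(5, 5, 9, 9))$m, 2L)

  p <- node_partition(c(1, 1, 2, 2))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_partition(p, path, node_labels = c("a", "b", "c", "d"))
  p2 <- read_partition(path)
  expect_identical(unname(p2$assignment), p$assignment)

  # non-canonical file is canonicalized with a warning
  writeLines(c("node\tmodule", "a\t2", "b\t2", "c\t1", "d\t1"), path)
  expect_warning(p3 <- read_partition(path), "canonical")
  expect_identical(unname(p3$assignment), c(1L, 1L, 2L, 2L))

  # gap ids relabeled
  writeLines(c("node\tmodule", "a\t1", "b\t3"), path)
  expect_warning(p4 <- read_partition(path), "canonical")
  expect_identical(unname(p4$assignment), c(1L, 2L))

  # unknown labels rejected
  expect_error(read_partition(path, labels = c("a", "zzz")), "labels")
})

test_that("ROI panels validate dimensions, variance and label matching", {
  x <- matrix(rnorm(30), 10, 3)
  labs <- roi_label_table(c("r1", "r2", "r3"), c("L", "R", "midline"),
                          c("cortical", "subcortical", "cerebellar"))
  p <- roi_panel(x, "S01", "rest", labs)
  expect_identical(colnames(p$data), labs$region_name)

  expect_error(roi_panel(matrix(rnorm(4), 2, 2)), "3 time points")
  xc <- x; xc[, 2] <- 1
  expect_error(roi_panel(xc), "constant")
  expect_error(roi_panel(x, roi_labels = roi_label_table("a", "L", "cortical")),
               "rows|columns")
  expect_error(roi_label_table(c("a", "a"), "L", "cortical", 1:2), "unique")
})

test_that("label tables round-trip through TSV", {
  labs <- roi_label_table(c("r1", "r2"), c("L", "R"),
                          c("cortical", "cerebellar"), c(4L, 9L))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_label_table(labs, path)
  labs2 <- read_label_table(path)
  expect_equal(as.data.frame(labs2), as.data.frame(labs))
})
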